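#!/usr/bin/env Rscript
# Simulate the traced-fibril cohort: 195 discrete worm-like chains at a
# persistence length of 0.74 um, contour lengths uniform on 0.3-2.0 um,
# 10-nm segments, no tracing noise. Writes the trace table and a manifest.

suppressPackageStartupMessages(library(alfibril))
dir.create("results", showWarnings = FALSE)

spec <- simulation_spec(
  n_fibrils = 195L, p_um = 0.74,
  length_dist = list(kind = "uniform", lo_um = 0.3, hi_um = 2.0),
  seg_nm = 10, noise_sd_nm = 0, seed = 20211105L
)
sim <- simulate_study(spec)

write_traces(sim$traces, "results/traces.csv")
write_report(sim$manifest, "results/simulation_manifest.json",
             seed = spec$seed, config = unclass(spec))

cat(sprintf("simulated %d chains, contour lengths %.2f-%.2f um (mean %.2f)\n",
            length(sim$traces),
            min(sim$manifest$realized_length_um),
            max(sim$manifest$realized_length_um),
            mean(sim$manifest$realized_length_um)))
cat("wrote results/traces.csv and results/simulation_manifest.json\n")
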