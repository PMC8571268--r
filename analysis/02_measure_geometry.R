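#!/usr/bin/env Rscript
# Measure per-fibril contour length L and end-to-end distance R from the
# trace table, in 3D. Writes the geometry TSV the fit consumes.

suppressPackageStartupMessages(library(alfibril))

traces <- read_traces("results/traces.csv")
geom <- measure_all(traces, mode = "spatial3d")
write_geometry(geom, "results/geometry.tsv")

excl <- attr(geom, "exclusions")
cat(sprintf("measured %d fibrils (%d excluded)\n", nrow(geom), nrow(excl)))
if (nrow(excl)) print(excl)
cat(sprintf("all chains satisfy R <= L: %s\n",
            all(geom$end_to_end_um <= geom$contour_length_um)))
cat("wrote results/geometry.tsv\n")
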