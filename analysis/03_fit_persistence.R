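#!/usr/bin/env Rscript
# Fit the worm-like-chain relation R^2 = 2PL(1 - (P/L)(1 - exp(-L/P))) to
# the measured (L, R^2) pairs by unweighted nonlinear least squares,
# report the persistence length with linearized and bootstrap 95% CIs,
# and convert to a bending rigidity at 300 K. Also draws the fit.

suppressPackageStartupMessages(library(alfibril))

geom <- read_geometry("results/geometry.tsv")
fit_lin <- fit_persistence_length(geom, ci_method = "linearized")
fit_boot <- fit_persistence_length(geom, ci_method = "bootstrap",
                                   bootstrap_B = 1000, seed = 20211105)
rig <- bending_rigidity(fit_lin$p_hat_um, temperature_K = 300,
                        se_um = fit_lin$se_um)

print(fit_lin)
print(fit_boot)
print(rig)

write_report(
  list(linearized = unclass(fit_lin), bootstrap = unclass(fit_boot),
       rigidity = unclass(rig)),
  "results/wlc_fit.json", seed = 20211105,
  config = list(ci_methods = c("linearized", "bootstrap"),
                bootstrap_B = 1000, temperature_K = 300))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  curve_df <- data.frame(l = seq(min(geom$contour_length_um),
                                 max(geom$contour_length_um),
                                 length.out = 200))
  curve_df$r2 <- wlc_expected_r2(fit_lin$p_hat_um, curve_df$l)
  p <- ggplot(geom, aes(contour_length_um, r2_um2)) +
    geom_point(colour = "steelblue", alpha = 0.6) +
    geom_line(data = curve_df, aes(l, r2), colour = "red",
              linewidth = 0.8) +
    labs(x = "contour length L (µm)",
         y = expression("squared end-to-end distance" ~ R^2 ~ (mu * m^2)),
         title = sprintf("Worm-like-chain fit: P = %.2f µm (n = %d)",
                         fit_lin$p_hat_um, fit_lin$n_fibrils)) +
    theme_classic()
  ggsave("results/wlc_fit.pdf", p, width = 5, height = 4)
  cat("wrote results/wlc_fit.pdf\n")
}
cat("wrote results/wlc_fit.json\n")
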