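#!/usr/bin/env Rscript
# Step 2 — the two-regime flux curve: pure respiration below the switch
# threshold, mixed aerobic glycolysis + respiration above it.

suppressPackageStartupMessages(library(crowdfba))

dir.create("results", showWarnings = FALSE)

m <- crowding_profile("printed", phi_ATP = 0.07)
f1 <- threshold_f1(m)
cat(sprintf("printed profile: f1 = %.3f mM/min, f2 = %.2f mM/min\n",
            f1, threshold_f2(m)))
cat(sprintf("post-threshold ATP slope: %.3f (vs 38 below the switch)\n",
            2 - 36 * (m$a_G + m$a_L) / (m$a_M - m$a_L)))
cat(sprintf("predicted lactate-vs-glucose slope above f1: %.3f\n",
            predicted_lactate_slope(m)))

grid <- seq(0, 3 * f1, length.out = 121)
curve <- atp_curve(grid, m)
write_flux_tsv(curve, "results/regime_curve.tsv")
cat("wrote results/regime_curve.tsv (", nrow(curve), "rows )\n")

n_glc <- sum(curve$regime == "glucose-limited")
cat(sprintf("%d glucose-limited rows, %d space-limited rows\n",
            n_glc, nrow(curve) - n_glc))

# regime figure (optional output; the tables above are the deliverable)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  long <- rbind(
    data.frame(f_G = curve$f_G, flux = curve$lactate_excretion,
               series = "lactate excretion (2 f_L)"),
    data.frame(f_G = curve$f_G, flux = curve$f_M, series = "respiration (f_M)"),
    data.frame(f_G = curve$f_G, flux = curve$f_ATP / 10,
               series = "ATP production / 10"))
  gg <- ggplot(long, aes(f_G, flux, colour = series)) +
    annotate("rect", xmin = f1, xmax = max(grid), ymin = -Inf, ymax = Inf,
             alpha = 0.12) +
    geom_line(linewidth = 0.8) +
    geom_vline(xintercept = f1, linetype = 2) +
    labs(x = "glucose uptake rate (mM/min)", y = "flux (mM/min)",
         title = "Two catabolic regimes under a solvent-capacity constraint",
         subtitle = "shaded: space-limited regime (crowding constraint binding)") +
    theme_minimal()
  ggsave("results/regime_curve.pdf", gg, width = 7, height = 4.5)
  cat("wrote results/regime_curve.pdf\n")
}
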