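#!/usr/bin/env Rscript

# Forward simulations of the cofermentation model: the three strain presets
# across the fermentation lignin levels, on artificial medium. Writes the
# trajectories and a per-run summary (fermentation time, final lactate,
# biomass maximum) under results/.

suppressPackageStartupMessages(library(coagferm))
dir.create("results/fermentations", recursive = TRUE, showWarnings = FALSE)

lignin_levels <- c(0, 0.625, 1.25, 2.5, 3.75)
strains <- c("dsm2314", "id14_298", "id14_301")
grid <- seq(0, 48, 1)

rows <- list()
for (strain in strains) {
  for (L in lignin_levels) {
    spec <- scenario_spec(seed = 100, strain = strain, lignin_gL = L,
                          noise_rel = 0, noise_floor = 0, grid = grid)
    g <- gen_fermentation(spec)
    tr <- g$truth
    write_fermentation_csv(
      tr, sprintf("results/fermentations/%s_lignin%.3f.csv", strain, L))
    rows[[length(rows) + 1]] <- data.frame(
      strain = strain, lignin_gL = L,
      FT_h = fermentation_time(tr),
      C_BM_max = max(tr$X_gL), C_LA_max = max(tr$la_gL),
      residual_sugar_gL = tr$glc_gL[nrow(tr)] + tr$xyl_gL[nrow(tr)] +
        tr$ara_gL[nrow(tr)])
  }
}
summary <- do.call(rbind, rows)
summary$P <- productivity(summary$C_LA_max, summary$FT_h)
write.csv(summary, "results/fermentation_summary.csv", row.names = FALSE)

cat("Simulated", nrow(summary), "runs (3 strain presets x 5 lignin levels).\n")
cat("Zero-lignin fast preset: FT =",
    summary$FT_h[summary$strain == "dsm2314" & summary$lignin_gL == 0],
    "h, final lactate =",
    round(summary$C_LA_max[summary$strain == "dsm2314" &
                             summary$lignin_gL == 0], 1), "g/L\n")
cat("Lignin slows every preset: fermentation time rises monotonically",
    "with the lignin level in all three strains:",
    all(tapply(summary$FT_h, summary$strain, function(x) all(diff(x) >= 0))),
    "\n")
cat("Wrote results/fermentation_summary.csv and per-run trajectories.\n")
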