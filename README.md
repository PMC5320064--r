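# coagferm

Model-based evaluation of thermophilic *Bacillus coagulans* cofermentation
of lignocellulose-derived sugars (glucose, xylose, arabinose) to L-lactic
acid in alkali-lignin-supplemented media — for bioprocess researchers who
screen strains for lignin endurance and characterize fermentations with
unstructured kinetic models.

## What it computes

**Cofermentation kinetics.** An unstructured Monod ODE model with specific
growth rate per sugar

    mu_i = mu_max_i * S_i/(K_S_i + S_i) * rep_i(S_glc)
           * 1/(1 + L/K_L) * max(0, 1 - P/P_max)^n_P

(catabolite repression of pentoses `rep = K_rep/(K_rep + S_glc)`, hyperbolic
lignin inhibition, power-law lactate inhibition) and balances `dX/dt = mu X`,
`dS_i/dt = -(mu_i/Y_XS_i) X`, `dP/dt = (sum alpha_i mu_i) X + beta_LP X`
(Luedeking–Piret). Parameters are estimated by a real-coded genetic
algorithm minimizing the weighted pooled least squares between observed and
simulated series.

**Fit quality.** Pooled residual sigma (RMSE), R², and a two-group
single-factor ANOVA at 95% confidence testing the equality of experimental
and model data (`F`, `F_critical`, `p` at df (1, 2n−2)).

**Plate screening.** Blank correction by the honeycomb-plate layout,
modified-logistic growth-curve fits `y(t) = A / (1 + exp(4 mu_max/A
(lambda − t) + 2))` per well (parameters: amplitude `A`, maximum specific
growth rate `mu_max`, lag time `lambda`), the composite screening parameter
beta per condition, and the beta-vs-lignin OLS regression whose x-intercept
extrapolates the lignin tolerance.

**Performance metrics.** Volumetric productivity `P = C_LA_max/FT`, yield
coefficients (`Y_LA/Sub`, `Y_BM/Sub`, `Y_LA/BM`), fermentation time from a
residual-sugar stop rule, and the total-cell-count regression
`TCC = 1.66e12 * BM`.

**Decolorization.** Difference UV spectra (250–400 nm) and pointwise plus
band-integrated uptake fractions for alkali-lignin, ferulic acid and
vanillin.

**Synthetic data.** Generators for all three raw-data types with embedded
ground truth and seeds, so the whole pipeline runs and is validated without
any external data.

## Worked example

Recompute the performance metrics of the bundled reference fermentation
summaries (the fast strain at 0 and 0.625 g/L lignin):

```r
library(coagferm)
runs <- reference_run_summaries()
d <- runs[runs$strain == "DSM_2314", ]
performance_table(d)[, c("lignin_gL", "P", "Y_LA_Sub", "Y_BM_Sub", "Y_LA_BM")]
#>   lignin_gL         P  Y_LA_Sub   Y_BM_Sub   Y_LA_BM
#> 1     0.000 2.6480769 0.8775172 0.07761917 11.305419
#> 2     0.625 0.8848611 0.8193158 0.10005144  8.188946
```

`P` is the volumetric productivity in g/L/h (68.85 g/L lactate in 26 h gives
2.648); the yields are g lactate (or biomass) per g supplied sugar, and
`Y_LA_BM` g lactate per g biomass. All eight values match the reported ones
to the printed precision.

Fit kinetics to a noisy synthetic run and judge the fit:

```r
truth <- monod_params(mu_max = c(glc = 0.40, xyl = 0.20, ara = 0.15))
init  <- ferment_state(X = 0.05, S_glc = 20, S_xyl = 0, S_ara = 0)
obs   <- gen_fermentation(scenario_spec(seed = 1))$observed  # or your CSV
fit   <- fit_kinetics(obs, truth,
                      ga_config(list("mu_max.glc" = c(0.1, 1),
                                     "K_S.glc"    = c(0.05, 3),
                                     "Y_XS.glc"   = c(0.02, 0.3)),
                                population_size = 40, generations = 60,
                                seed = 202))
```

The numbered drivers under `analysis/` run each stage end to end and print
what they find; e.g. `Rscript analysis/02_fit_kinetics.R` recovers
`mu_max.glc = 0.4007, K_S.glc = 0.4937, Y_XS.glc = 0.0795` from a
2%-noise series (truth 0.40 / 0.50 / 0.08) and reports

```
sigma = 0.1668   R^2 = 0.9994
ANOVA: F = 0.0004, F_critical = 3.9151 (df 1, 128), p = 0.9848
observed and model data indistinguishable at the 95% level
```

and `Rscript analysis/03_plate_screening.R` extrapolates lignin tolerances
of 1.62 / 1.21 / 1.39 g/L against programmed truths of 1.6 / 1.2 / 1.4.

## Layout

- `R/` — model, GA, statistics, screening, metrics, decolorization,
  generators, I/O
- `analysis/01..05_*.R` — narrative drivers writing tables under `results/`
- `tests/testthat/` — unit, property and acceptance tests with independent
  oracles (fixed-step RK4, naive statistic loops, normal equations)
- `vignettes/cofermentation-methods.Rmd` — the model, its assumptions,
  design choices and limitations
- `inst/extdata/run_summaries.csv` — reference fermentation summary table
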