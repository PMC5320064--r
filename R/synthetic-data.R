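#' Kinetic parameter presets per strain
#'
#' Order-of-magnitude parameter sets for the three *B. coagulans* isolates,
#' chosen to reproduce the observed scales of the lab fermentations (biomass
#' maxima of 4-8 g/L, lactate near 65-70 g/L from ~78 g/L mixed sugar within
#' 26-48 h, near-homolactic substrate-to-lactate yields). They are synthetic
#' presets for generator ground truth, not fitted constants. The
#' `dsm2314`-like preset is fast and deplets all sugars; the `id14_301`-like
#' preset has stronger catabolite repression and slower pentose uptake,
#' leaving residual pentoses at 48 h.
#'
#' @param strain one of `"dsm2314"`, `"id14_298"`, `"id14_301"`.
#' @return a [monod_params()] object.
#' @export
strain_preset <- function(strain = c("dsm2314", "id14_298", "id14_301")) {
  strain <- match.arg(strain)
  switch(strain,
         dsm2314 = monod_params(
           mu_max = c(glc = 0.33, xyl = 0.19, ara = 0.14),
           K_S = c(glc = 0.50, xyl = 0.80, ara = 1.00),
           Y_XS = c(glc = 0.080, xyl = 0.075, ara = 0.070),
           K_rep = 2.0, K_L = 2.5, P_max = 80, n_P = 1.2,
           alpha = c(glc = 11.0, xyl = 11.5, ara = 12.0), beta_LP = 0),
         id14_298 = monod_params(
           mu_max = c(glc = 0.30, xyl = 0.17, ara = 0.13),
           K_S = c(glc = 0.60, xyl = 0.90, ara = 1.10),
           Y_XS = c(glc = 0.065, xyl = 0.060, ara = 0.055),
           K_rep = 1.5, K_L = 3.0, P_max = 85, n_P = 1.0,
           alpha = c(glc = 9.0, xyl = 9.5, ara = 10.0), beta_LP = 0),
         id14_301 = monod_params(
           mu_max = c(glc = 0.28, xyl = 0.09, ara = 0.06),
           K_S = c(glc = 0.70, xyl = 1.50, ara = 2.00),
           Y_XS = c(glc = 0.075, xyl = 0.070, ara = 0.065),
           K_rep = 0.5, K_L = 4.0, P_max = 48, n_P = 2.0,
           alpha = c(glc = 9.0, xyl = 9.0, ara = 9.0), beta_LP = 0))
}

#' Scenario specification for the synthetic-data generators
#'
#' Describes one synthetic study condition. Every generated artifact embeds
#' its spec (seed included) so it can be regenerated exactly.
#'
#' @param seed integer seed driving all noise.
#' @param strain strain preset name, see [strain_preset()].
#' @param medium `"am"` (artificial medium, ~46/21/10.6 g/L
#'   glucose/xylose/arabinose) or `"hydrolysate"` (~7/2.5/0.5 g/L).
#' @param lignin_gL alkali-lignin level of the run (g/L); fermentations use
#'   levels from `c(0, 0.625, 1.25, 2.5, 3.75)`, screening from
#'   `c(0, 0.2, 0.4, 0.6, 0.8)`.
#' @param noise_rel multiplicative lognormal noise sigma (relative), default
#'   0.02 (HPLC-like precision).
#' @param noise_floor additive noise standard deviation (g/L), default 0.05.
#' @param grid sampling time grid (h).
#' @param X0 inoculum biomass (g/L).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L,
                          strain = "dsm2314",
                          medium = c("am", "hydrolysate"),
                          lignin_gL = 0,
                          noise_rel = 0.02,
                          noise_floor = 0.05,
                          grid = seq(0, 48, by = 2),
                          X0 = 0.03) {
  medium <- match.arg(medium)
  stopifnot(noise_rel >= 0, noise_floor >= 0, lignin_gL >= 0, X0 >= 0)
  structure(list(seed = as.integer(seed), strain = strain, medium = medium,
                 lignin_gL = lignin_gL, noise_rel = noise_rel,
                 noise_floor = noise_floor, grid = grid, X0 = X0),
            class = "scenario_spec")
}

sugar_preset <- function(medium) {
  switch(medium,
         am = c(glc = 46, xyl = 21, ara = 10.6),
         hydrolysate = c(glc = 7, xyl = 2.5, ara = 0.5))
}

#' Generate a synthetic fermentation series with known truth
#'
#' Simulates the cofermentation model under the scenario's strain preset and
#' medium, samples the trajectory on the scenario grid, and applies the noise
#' model (multiplicative lognormal with relative sigma `noise_rel`, plus an
#' additive Gaussian floor of `noise_floor` g/L), clipping at zero. The
#' noise-free truth and the true parameters are returned alongside for
#' parameter-recovery experiments.
#'
#' @param spec a [scenario_spec()].
#' @return list: `observed` (data.frame
#'   `t_h, X_gL, glc_gL, xyl_gL, ara_gL, la_gL, lignin_gL`), `truth`
#'   (same columns, noise-free), `params` (true [monod_params()]), `init`,
#'   `spec`.
#' @export
gen_fermentation <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  params <- strain_preset(spec$strain)
  s0 <- sugar_preset(spec$medium)
  init <- ferment_state(X = spec$X0, S_glc = s0[["glc"]],
                        S_xyl = s0[["xyl"]], S_ara = s0[["ara"]],
                        P_la = 0, L = spec$lignin_gL, t = spec$grid[1])
  truth <- simulate_fermentation(params, init, spec$grid)
  obs <- as.data.frame(truth)
  set.seed(spec$seed)
  vars <- c("X_gL", "glc_gL", "xyl_gL", "ara_gL", "la_gL")
  n <- nrow(obs)
  for (v in vars) {
    noisy <- obs[[v]]
    if (spec$noise_rel > 0) {
      noisy <- noisy * exp(stats::rnorm(n, 0, spec$noise_rel))
    }
    if (spec$noise_floor > 0) {
      noisy <- noisy + stats::rnorm(n, 0, spec$noise_floor)
    }
    obs[[v]] <- pmax(noisy, 0)
  }
  structure(list(observed = obs, truth = as.data.frame(truth),
                 params = params, init = init, spec = spec),
            class = "synthetic_fermentation")
}

#' Generate a synthetic screening plate with known truth
#'
#' Populates a honeycomb plate per the screening layout: growth wells receive
#' logistic OD curves whose true maximum growth rate declines linearly with
#' lignin down to a programmed lignin tolerance per sugar variant; medium
#' blanks carry a baseline plus slow drift; all wells get additive
#' measurement noise (default 0.01 AU).
#'
#' @param spec a [scenario_spec()]; its `grid` is the read schedule (h) and
#'   its seed drives the noise.
#' @param lignin_levels screening lignin set (g/L).
#' @param mu0 true maximum growth rate at zero lignin, per sugar variant
#'   (1/h).
#' @param lignin_tolerance programmed lignin level at which growth
#'   extrapolates to zero, per variant (g/L); the true beta-vs-lignin
#'   x-intercept.
#' @param A0 true log-growth amplitude at zero lignin.
#' @param lambda0 true lag time at zero lignin (h).
#' @param od0 inoculum OD contribution; `baseline` medium blank OD;
#'   `drift_per_h` blank drift (AU/h); `noise_od` additive OD noise sd (AU).
#' @param baseline,drift_per_h,noise_od see `od0`.
#' @return list: `curves` (long `well, t_h, od`), `layout`
#'   ([plate_layout()]), `truth` (per-condition true A, mu_max, lambda),
#'   `tolerance` (named per-variant true x-intercepts), `spec`.
#' @export
gen_plate <- function(spec,
                      lignin_levels = c(0, 0.2, 0.4, 0.6, 0.8),
                      mu0 = c(glc60 = 0.50, xyl60 = 0.35, glc40_xyl20 = 0.45),
                      lignin_tolerance = c(glc60 = 1.6, xyl60 = 1.2,
                                           glc40_xyl20 = 1.4),
                      A0 = 2.4, lambda0 = 2.0, od0 = 0.10,
                      baseline = 0.09, drift_per_h = 0.002,
                      noise_od = 0.01) {
  stopifnot(inherits(spec, "scenario_spec"))
  layout <- plate_layout(sugar_variants = names(mu0),
                         lignin_levels = lignin_levels)
  tt <- spec$grid
  set.seed(spec$seed)
  truth <- expand.grid(sugar_variant = names(mu0), lignin_gL = lignin_levels,
                       stringsAsFactors = FALSE)
  truth$mu_max <- mu0[truth$sugar_variant] *
    (1 - truth$lignin_gL / lignin_tolerance[truth$sugar_variant])
  truth$A <- A0 - 0.3 * truth$lignin_gL
  truth$lambda <- lambda0 + 1.5 * truth$lignin_gL

  logis <- function(t, A, mu, lam) A / (1 + exp(4 * mu / A * (lam - t) + 2))
  curves <- lapply(seq_len(nrow(layout)), function(i) {
    w <- layout[i, ]
    if (w$role == "water_blank") {
      od <- 0.03 + stats::rnorm(length(tt), 0, noise_od)
    } else {
      blank_sig <- baseline + drift_per_h * tt
      if (w$role == "medium_blank") {
        od <- blank_sig + stats::rnorm(length(tt), 0, noise_od)
      } else {
        k <- truth$sugar_variant == w$sugar_variant &
          truth$lignin_gL == w$lignin_gL
        y <- logis(tt, truth$A[k], truth$mu_max[k], truth$lambda[k])
        od <- blank_sig + od0 * exp(y) + stats::rnorm(length(tt), 0, noise_od)
      }
    }
    data.frame(well = w$well, t_h = tt, od = pmax(od, 0),
               stringsAsFactors = FALSE)
  })
  structure(list(curves = do.call(rbind, curves), layout = layout,
                 truth = truth, tolerance = lignin_tolerance, spec = spec),
            class = "synthetic_plate")
}

#' Generate synthetic decolorization spectra with known uptake
#'
#' Builds a Gaussian-peak blank spectrum at a compound-typical wavelength
#' (alkali-lignin 280 nm, ferulic acid 315 nm, vanillin 305 nm) over the
#' 250-400 nm range, and scales it by the programmed uptake fractions at the
#' 2.5 h and 5 h sampling points. Noise-free by default (UV scans are
#' smooth); optional additive noise available.
#'
#' @param spec a [scenario_spec()] (seed used only when `noise_au > 0`).
#' @param compound `"AL"`, `"FA"` or `"VAN"`.
#' @param uptake named fractions `c(t2.5h =, t5h =)` in `[0, 1)`.
#' @param noise_au additive absorbance noise sd (AU), default 0.
#' @return list of [uv_spectrum()]: `blank`, `t2.5h`, `t5h`; plus `uptake`,
#'   `compound`, `spec`.
#' @export
gen_spectra <- function(spec, compound = c("AL", "FA", "VAN"),
                        uptake = c(t2.5h = 0.2, t5h = 0.5),
                        noise_au = 0) {
  stopifnot(inherits(spec, "scenario_spec"))
  compound <- match.arg(compound)
  if (any(uptake < 0)) stop("uptake fractions must be >= 0", call. = FALSE)
  if (any(uptake >= 1)) stop("uptake fractions must be < 1", call. = FALSE)
  wl <- 250:400
  center <- switch(compound, AL = 280, FA = 315, VAN = 305)
  base <- 0.05 + 1.0 * exp(-(wl - center)^2 / (2 * 15^2))
  set.seed(spec$seed)
  mk <- function(scale, label) {
    a <- base * scale
    if (noise_au > 0) a <- a + stats::rnorm(length(wl), 0, noise_au)
    uv_spectrum(wl, a, label = label, compound = compound)
  }
  structure(list(blank = mk(1, "blank"),
                 t2.5h = mk(1 - uptake[["t2.5h"]], "t2.5h"),
                 t5h = mk(1 - uptake[["t5h"]], "t5h"),
                 uptake = uptake, compound = compound, spec = spec),
            class = "synthetic_spectra")
}
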