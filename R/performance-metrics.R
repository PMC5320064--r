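#' Volumetric lactate productivity
#'
#' `P = C_LA_max / FT` in g/L/h, the maximum lactate concentration divided by
#' the fermentation time.
#'
#' @param c_la_max maximum lactate concentration (g/L), >= 0.
#' @param ft_h fermentation time (h), > 0.
#' @return productivity (g/L/h).
#' @export
productivity <- function(c_la_max, ft_h) {
  if (any(ft_h <= 0)) stop("fermentation time must be > 0", call. = FALSE)
  if (any(c_la_max < 0)) stop("lactate concentration must be >= 0", call. = FALSE)
  c_la_max / ft_h
}

#' Fermentation yield coefficients
#'
#' Computes the yield coefficients of a fermentation run from its summary
#' concentrations. Substrate-based yields use the total supplied sugar
#' (sum of the per-sugar maxima) as denominator, which matches the printed
#' reference values for runs that exhaust their sugars; yields on consumed
#' sugar (sum of max - min) are also reported, since for runs with residual
#' sugar the two conventions differ.
#'
#' @param c_bm_max maximum biomass (g/L).
#' @param c_la_max maximum lactate (g/L).
#' @param sugar_max named or unnamed numeric of the per-sugar maximum
#'   (initial) concentrations (g/L).
#' @param sugar_min per-sugar minimum (residual) concentrations (g/L),
#'   default all zero.
#' @return list: `sugar_supplied`, `sugar_consumed`, `Y_LA_Sub`, `Y_BM_Sub`,
#'   `Y_LA_BM`, `Y_LA_Sub_consumed`, `Y_BM_Sub_consumed` (all g/g except the
#'   sugar totals, g/L).
#' @export
yields <- function(c_bm_max, c_la_max, sugar_max,
                   sugar_min = rep(0, length(sugar_max))) {
  stopifnot(length(sugar_max) == length(sugar_min))
  if (any(sugar_max < sugar_min)) {
    stop("every sugar max must be >= its min", call. = FALSE)
  }
  supplied <- sum(sugar_max)
  consumed <- sum(sugar_max - sugar_min)
  if (supplied <= 0) stop("zero supplied sugar", call. = FALSE)
  if (c_bm_max <= 0 && c_la_max > 0) {
    stop("zero biomass denominator with nonzero lactate", call. = FALSE)
  }
  list(sugar_supplied = supplied,
       sugar_consumed = consumed,
       Y_LA_Sub = c_la_max / supplied,
       Y_BM_Sub = c_bm_max / supplied,
       Y_LA_BM = if (c_bm_max > 0) c_la_max / c_bm_max else 0,
       Y_LA_Sub_consumed = if (consumed > 0) c_la_max / consumed else NA_real_,
       Y_BM_Sub_consumed = if (consumed > 0) c_bm_max / consumed else NA_real_)
}

#' Performance table from run summaries
#'
#' Applies [productivity()] and [yields()] to every row of a run-summary
#' table (one fermentation per row).
#'
#' @param summaries data.frame with columns `C_BM_max, C_LA_max, C_Glc_min,
#'   C_Glc_max, C_Xyl_min, C_Xyl_max, C_Ara_min, C_Ara_max, FT_h` (and any
#'   identifying columns, which are carried through).
#' @return data.frame with added columns `P, sugar_supplied, sugar_consumed,
#'   Y_LA_Sub, Y_BM_Sub, Y_LA_BM`.
#' @export
performance_table <- function(summaries) {
  need <- c("C_BM_max", "C_LA_max", "C_Glc_min", "C_Glc_max", "C_Xyl_min",
            "C_Xyl_max", "C_Ara_min", "C_Ara_max", "FT_h")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    y <- yields(s$C_BM_max, s$C_LA_max,
                sugar_max = c(s$C_Glc_max, s$C_Xyl_max, s$C_Ara_max),
                sugar_min = c(s$C_Glc_min, s$C_Xyl_min, s$C_Ara_min))
    data.frame(P = productivity(s$C_LA_max, s$FT_h),
               sugar_supplied = y$sugar_supplied,
               sugar_consumed = y$sugar_consumed,
               Y_LA_Sub = y$Y_LA_Sub, Y_BM_Sub = y$Y_BM_Sub,
               Y_LA_BM = y$Y_LA_BM)
  })
  cbind(summaries, do.call(rbind, rows))
}

#' Total cell count from biomass
#'
#' Linear regression between total cell count and biomass established from
#' the screening experiments: `TCC = 1.66e12 * BM` (cells/L per g/L).
#'
#' @param bm_gL biomass (g/L), >= 0.
#' @return total cell count (cells/L).
#' @seealso [biomass_from_tcc()] for the inverse.
#' @export
tcc_from_biomass <- function(bm_gL) {
  if (any(bm_gL < 0)) stop("biomass must be >= 0", call. = FALSE)
  1.66e12 * bm_gL
}

#' Biomass from total cell count
#'
#' Inverse of [tcc_from_biomass()].
#'
#' @param tcc cells/L, >= 0.
#' @return biomass (g/L).
#' @export
biomass_from_tcc <- function(tcc) {
  if (any(tcc < 0)) stop("cell count must be >= 0", call. = FALSE)
  tcc / 1.66e12
}

#' Reference fermentation run summaries
#'
#' Loads the bundled table of lab-scale fermentation summaries for the three
#' *B. coagulans* strains across alkali-lignin levels (initial and stop
#' concentrations of biomass, sugars and lactate, fermentation time, optical
#' purity, and the originally reported performance values for comparison).
#'
#' @return data.frame, one fermentation per row.
#' @export
reference_run_summaries <- function() {
  path <- system.file("extdata", "run_summaries.csv", package = "coagferm",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
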