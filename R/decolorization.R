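#' UV absorbance spectrum
#'
#' Validated container for a UV absorbance scan in the 250-400 nm range used
#' by the decolorization assays of alkali-lignin (AL), ferulic acid (FA) and
#' vanillin (VAN) uptake.
#'
#' @param wavelength_nm strictly increasing wavelengths (nm).
#' @param absorbance finite absorbance values (AU).
#' @param label one of `blank`, `t2.5h`, `t5h` (free-form allowed).
#' @param compound one of `AL`, `FA`, `VAN` (free-form allowed).
#' @param strain optional strain identifier.
#' @return data.frame of class `uv_spectrum` with the label metadata as
#'   attributes.
#' @export
uv_spectrum <- function(wavelength_nm, absorbance, label = "blank",
                        compound = "AL", strain = NA_character_) {
  stopifnot(length(wavelength_nm) == length(absorbance))
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("absorbance must be finite", call. = FALSE)
  }
  structure(data.frame(wavelength_nm = wavelength_nm,
                       absorbance = absorbance),
            class = c("uv_spectrum", "data.frame"),
            label = label, compound = compound, strain = strain)
}

#' Difference spectrum (blank minus sample)
#'
#' Interpolates the sample spectrum linearly onto the blank's wavelength grid
#' (restricted to the overlapping support) and returns the pointwise
#' difference `blank - sample`, the decolorization signal.
#'
#' @param blank,sample [uv_spectrum()] objects of the same compound.
#' @return data.frame `wavelength_nm, delta` on the blank grid within the
#'   overlap.
#' @export
delta_spectrum <- function(blank, sample) {
  cb <- attr(blank, "compound"); cs <- attr(sample, "compound")
  if (!is.null(cb) && !is.null(cs) && !identical(cb, cs)) {
    stop("blank and sample are different compounds", call. = FALSE)
  }
  lo <- max(min(blank$wavelength_nm), min(sample$wavelength_nm))
  hi <- min(max(blank$wavelength_nm), max(sample$wavelength_nm))
  if (lo >= hi) stop("disjoint wavelength ranges", call. = FALSE)
  keep <- blank$wavelength_nm >= lo & blank$wavelength_nm <= hi
  wl <- blank$wavelength_nm[keep]
  s <- stats::approx(sample$wavelength_nm, sample$absorbance, xout = wl)$y
  data.frame(wavelength_nm = wl, delta = blank$absorbance[keep] - s)
}

#' Decolorization (uptake) metrics in a wavelength band
#'
#' Locates the blank's absorbance maximum within `band` and reports the peak
#' absorbance drop, its wavelength, the pointwise fractional decolorization
#' `1 - A_sample/A_blank` at that wavelength, and the band-integrated
#' (trapezoid) fraction. Negative fractions (apparent release or turbidity)
#' are reported unclipped and flagged.
#'
#' @param blank,sample [uv_spectrum()] objects.
#' @param band `c(lambda_lo, lambda_hi)` in nm, within both spectra.
#' @param noise_floor blank absorbance below which the fraction is undefined.
#' @return list: `lambda_peak`, `delta_peak`, `fraction_peak`,
#'   `fraction_integrated`, `negative_uptake` flag.
#' @export
uptake_metrics <- function(blank, sample, band, noise_floor = 0.01) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] < min(blank$wavelength_nm) || band[2] > max(blank$wavelength_nm) ||
      band[1] < min(sample$wavelength_nm) || band[2] > max(sample$wavelength_nm)) {
    stop("band must lie within both spectra", call. = FALSE)
  }
  keep <- blank$wavelength_nm >= band[1] & blank$wavelength_nm <= band[2]
  wl <- blank$wavelength_nm[keep]
  ab <- blank$absorbance[keep]
  as_ <- stats::approx(sample$wavelength_nm, sample$absorbance, xout = wl)$y
  i <- which.max(ab)
  if (ab[i] <= noise_floor) {
    stop(sprintf("blank absorbance at band maximum (%.3g AU) is at or below the noise floor",
                 ab[i]), call. = FALSE)
  }
  frac_peak <- 1 - as_[i] / ab[i]
  int_b <- pracma::trapz(wl, ab)
  int_s <- pracma::trapz(wl, as_)
  frac_int <- 1 - int_s / int_b
  list(lambda_peak = wl[i],
       delta_peak = ab[i] - as_[i],
       fraction_peak = frac_peak,
       fraction_integrated = frac_int,
       negative_uptake = frac_peak < 0 || frac_int < 0)
}

#' Default analysis bands per compound
#'
#' Wavelength windows in which the blank's absorption maximum is searched:
#' typical aromatic absorption regions for alkali-lignin (270-290 nm),
#' ferulic acid (300-330 nm) and vanillin (290-320 nm). Fully overridable in
#' [uptake_metrics()].
#'
#' @param compound one of `"AL"`, `"FA"`, `"VAN"`.
#' @return numeric `c(lambda_lo, lambda_hi)` (nm).
#' @export
default_band <- function(compound = c("AL", "FA", "VAN")) {
  compound <- match.arg(compound)
  switch(compound,
         AL = c(270, 290),
         FA = c(300, 330),
         VAN = c(290, 320))
}
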