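#' Read a fermentation series CSV
#'
#' Interchange schema: header `t_h,X_gL,glc_gL,xyl_gL,ara_gL,la_gL,lignin_gL`;
#' empty cells are missing observations (`NA`), never zeros. Validation
#' errors carry row/column coordinates.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_fermentation_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- c("t_h", "X_gL", "glc_gL", "xyl_gL", "ara_gL", "la_gL",
              "lignin_gL")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!identical(names(d), header)) {
    stop("unknown header: expected ", paste(header, collapse = ","),
         call. = FALSE)
  }
  for (col in header) {
    raw <- trimws(d[[col]])
    raw[raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row %d, column %s: '%s'",
                   bad[1] + 1L, col, raw[bad[1]]), call. = FALSE)
    }
    d[[col]] <- num
  }
  if (anyNA(d$t_h)) {
    stop(sprintf("missing time at row %d",
                 which(is.na(d$t_h))[1] + 1L), call. = FALSE)
  }
  nd <- which(diff(d$t_h) <= 0)
  if (length(nd)) {
    stop(sprintf("time not strictly increasing at row %d (t_h = %g)",
                 nd[1] + 2L, d$t_h[nd[1] + 1L]), call. = FALSE)
  }
  d
}

#' Write a fermentation series or trajectory CSV
#'
#' Deterministic column order per the documented schema; `NA` is written as
#' an empty cell.
#'
#' @param x data.frame with the series columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fermentation_csv <- function(x, path) {
  header <- c("t_h", "X_gL", "glc_gL", "xyl_gL", "ara_gL", "la_gL",
              "lignin_gL")
  stopifnot(all(header %in% names(x)))
  utils::write.csv(as.data.frame(x)[header], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read/write kinetic parameters as JSON
#'
#' Lossless round trip of a [monod_params()] object through a flat JSON
#' table (full double precision).
#'
#' @param params a [monod_params()].
#' @param path JSON file path.
#' @return `write_monod_params` returns `path` invisibly;
#'   `read_monod_params` returns a validated [monod_params()].
#' @export
write_monod_params <- function(params, path) {
  stopifnot(inherits(params, "monod_params"))
  jsonlite::write_json(unclass(params), path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_monod_params
#' @export
read_monod_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(monod_params, raw)
}

#' Read/write plate OD curves as long CSV
#'
#' Schema `well,t_h,od`; times must be strictly increasing within each well.
#'
#' @param curves long data.frame `well, t_h, od`.
#' @param path CSV path.
#' @return `read_plate_csv` returns the validated data.frame.
#' @export
write_plate_csv <- function(curves, path) {
  stopifnot(all(c("well", "t_h", "od") %in% names(curves)))
  utils::write.csv(curves[c("well", "t_h", "od")], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), c("well", "t_h", "od"))) {
    stop("unknown header: expected well,t_h,od", call. = FALSE)
  }
  for (w in unique(d$well)) {
    tw <- d$t_h[d$well == w]
    if (any(diff(tw) <= 0)) {
      stop(sprintf("time not strictly increasing in well %s", w),
           call. = FALSE)
    }
  }
  d
}

#' Read/write a plate layout as JSON
#'
#' @param layout a [plate_layout()].
#' @param path JSON path.
#' @return `read_plate_layout` returns the layout data.frame (lossless
#'   round trip).
#' @export
write_plate_layout <- function(layout, path) {
  jsonlite::write_json(as.data.frame(layout), path, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(d), class = c("plate_layout", "data.frame"))
}

#' Read/write a UV spectrum CSV
#'
#' Schema `wavelength_nm,absorbance`; metadata (label, compound, strain) as a
#' JSON sidecar written next to the CSV when provided through the spectrum's
#' attributes.
#'
#' @param spectrum a [uv_spectrum()].
#' @param path CSV path.
#' @return `read_spectrum_csv` returns a [uv_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum)[c("wavelength_nm", "absorbance")],
                   path, row.names = FALSE)
  meta <- list(label = attr(spectrum, "label"),
               compound = attr(spectrum, "compound"),
               strain = attr(spectrum, "strain"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), c("wavelength_nm", "absorbance"))) {
    stop("unknown header: expected wavelength_nm,absorbance", call. = FALSE)
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(label = "unknown", compound = "unknown", strain = NA_character_)
  uv_spectrum(d$wavelength_nm, d$absorbance, label = meta$label,
              compound = meta$compound,
              strain = if (is.null(meta$strain)) NA_character_ else meta$strain)
}

#' Write a GA fit result as JSON
#'
#' Serializes a [ga_minimize()]/[fit_kinetics()] result with its full
#' configuration for provenance; deterministic field order.
#'
#' @param fit a `ga_fit`.
#' @param path JSON path.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "ga_fit"))
  out <- list(best_params = as.list(fit$best_params),
              best_value = fit$best_value,
              history = fit$history,
              evaluations = fit$evaluations,
              seed = fit$seed,
              config = list(
                bounds = fit$config$bounds,
                population_size = fit$config$population_size,
                generations = fit$config$generations,
                crossover_prob = fit$config$crossover_prob,
                mutation_prob = fit$config$mutation_prob,
                mutation_scale = fit$config$mutation_scale,
                elite_count = fit$config$elite_count,
                tournament_size = fit$config$tournament_size,
                seed = fit$config$seed))
  jsonlite::write_json(out, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}
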