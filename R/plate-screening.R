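#' Honeycomb-plate layout for lignin-endurance screening
#'
#' Builds the 10 x 10 well map of the Bioscreen honeycomb plate used for the
#' optical-density screening: columns 1-3 are medium blanks (one column per
#' saccharide combination, two wells per lignin concentration), column 4 is a
#' water blank, and columns 5-10 determine growth with two columns per
#' saccharide combination and two rows per lignin concentration — four growth
#' replicates per (sugar, lignin) condition.
#'
#' @param sugar_variants character vector of the three saccharide
#'   combinations; defaults to 60 g/L glucose, 60 g/L xylose, and
#'   40 g/L glucose + 20 g/L xylose.
#' @param lignin_levels alkali-lignin concentrations (g/L), default
#'   `c(0, 0.2, 0.4, 0.6, 0.8)`.
#' @return data.frame of class `plate_layout` with columns
#'   `well, row, col, role, sugar_variant, lignin_gL` (role one of
#'   `medium_blank`, `water_blank`, `growth`).
#' @export
plate_layout <- function(sugar_variants = c("glc60", "xyl60", "glc40_xyl20"),
                         lignin_levels = c(0, 0.2, 0.4, 0.6, 0.8)) {
  stopifnot(length(sugar_variants) == 3, length(lignin_levels) == 5)
  rows <- 1:10
  cols <- 1:10
  grid <- expand.grid(row = rows, col = cols)
  lig_of_row <- lignin_levels[ceiling(grid$row / 2)]
  role <- ifelse(grid$col <= 3, "medium_blank",
                 ifelse(grid$col == 4, "water_blank", "growth"))
  variant <- rep(NA_character_, nrow(grid))
  blank_cols <- grid$col <= 3
  variant[blank_cols] <- sugar_variants[grid$col[blank_cols]]
  growth_cols <- grid$col >= 5
  variant[growth_cols] <- sugar_variants[ceiling((grid$col[growth_cols] - 4) / 2)]
  lig <- ifelse(role == "water_blank", NA_real_, lig_of_row)
  layout <- data.frame(
    well = sprintf("%s%02d", LETTERS[grid$row], grid$col),
    row = grid$row, col = grid$col, role = role,
    sugar_variant = variant, lignin_gL = lig,
    stringsAsFactors = FALSE)
  structure(layout, class = c("plate_layout", "data.frame"))
}

#' Blank-correct plate OD curves
#'
#' Subtracts from every growth well, at each measurement time, the mean OD of
#' the medium-blank wells sharing its (sugar variant, lignin level)
#' condition. Negative corrected values are floored at 0 and counted in the
#' `floored` attribute.
#'
#' @param curves long data.frame `well, t_h, od` covering all wells on a
#'   common time grid.
#' @param layout a [plate_layout()].
#' @return long data.frame of the growth wells with columns
#'   `well, t_h, od, sugar_variant, lignin_gL`; attribute `floored`.
#' @export
blank_correct <- function(curves, layout) {
  stopifnot(all(c("well", "t_h", "od") %in% names(curves)))
  lay <- as.data.frame(layout)
  key <- function(v, l) paste(v, sprintf("%.10g", l), sep = "|")
  growth <- lay[lay$role == "growth", ]
  blanks <- lay[lay$role == "medium_blank", ]
  blank_key <- key(blanks$sugar_variant, blanks$lignin_gL)
  out <- vector("list", nrow(growth) )
  floored <- 0L
  for (i in seq_len(nrow(growth))) {
    gw <- growth[i, ]
    k <- key(gw$sugar_variant, gw$lignin_gL)
    bwells <- blanks$well[blank_key == k]
    if (length(bwells) == 0L) {
      stop(sprintf("no medium blank for condition %s at %.3g g/L lignin",
                   gw$sugar_variant, gw$lignin_gL), call. = FALSE)
    }
    gcur <- curves[curves$well == gw$well, ]
    if (nrow(gcur) == 0L) next
    gcur <- gcur[order(gcur$t_h), ]
    bcur <- curves[curves$well %in% bwells, ]
    bmean <- tapply(bcur$od, bcur$t_h, mean)
    bt <- as.numeric(names(bmean))
    corr <- gcur$od - stats::approx(bt, as.numeric(bmean), xout = gcur$t_h,
                                    rule = 2)$y
    floored <- floored + sum(corr < 0)
    out[[i]] <- data.frame(well = gw$well, t_h = gcur$t_h,
                           od = pmax(corr, 0),
                           sugar_variant = gw$sugar_variant,
                           lignin_gL = gw$lignin_gL,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "floored") <- floored
  res
}

#' Fit a logistic growth model to an OD curve
#'
#' Fits the modified (Zwietering-type) logistic growth model in log-growth
#' coordinates
#' \deqn{y(t) = \frac{A}{1 + \exp\left(\frac{4\mu_{max}}{A}(\lambda - t) + 2\right)}}
#' to a blank-corrected OD curve, where `A` is the asymptotic log-growth
#' amplitude \eqn{\ln(OD_{max}/OD_0)}, `mu_max` the maximum specific growth
#' rate (1/h) and `lambda` the lag time (h).
#'
#' The least squares is solved in OD space, `OD(t) = OD0 * exp(y(t))`, with
#' the inoculum scale `OD0` as a free fourth parameter initialized from the
#' mean of the first two corrected points. Fitting in OD space matches the
#' additive noise of turbidimetric readers and avoids the lag-time bias that
#' a fixed log-reference incurs when the logistic is not exactly zero at the
#' first read. Bounded Levenberg-Marquardt with three heuristic starts.
#'
#' Curves whose maximum corrected OD stays below `no_growth_threshold` are
#' returned as flagged no-growth fits with `A = 0`, `mu_max = 0`,
#' `lambda = ` last time.
#'
#' @param t_h measurement times (h), strictly increasing, >= 6 points.
#' @param od blank-corrected OD values.
#' @param od0 optional fixed inoculum OD; when given, `OD0` is not fitted.
#' @param od_floor positive floor applied before the log transform used for
#'   the starting values.
#' @param no_growth_threshold maximum-OD level below which the well is
#'   declared no-growth.
#' @return object of class `growth_curve_fit`: `A`, `mu_max`, `lambda`,
#'   `od0`, `rss` (OD-space residual sum of squares), `n`, `no_growth`.
#' @export
fit_growth_curve <- function(t_h, od, od0 = NULL, od_floor = 1e-3,
                             no_growth_threshold = 0.05) {
  stopifnot(length(t_h) == length(od), length(t_h) >= 6,
            all(diff(t_h) > 0), all(is.finite(od)))
  if (max(od) < no_growth_threshold) {
    return(structure(list(A = 0, mu_max = 0, lambda = t_h[length(t_h)],
                          od0 = NA_real_, rss = NA_real_, n = length(t_h),
                          no_growth = TRUE),
                     class = "growth_curve_fit"))
  }
  fixed_od0 <- !is.null(od0)
  C0 <- if (fixed_od0) od0 else max(mean(od[1:2]), od_floor)

  ## heuristic starts from the log curve: amplitude from the plateau, slope
  ## from the steepest finite difference, lag from the tangent intercept
  y <- log(pmax(od, od_floor) / C0)
  A0 <- max(max(y), 0.1)
  dy <- diff(y) / diff(t_h)
  i <- which.max(dy)
  mu0 <- max(dy[i], 1e-3)
  lam0 <- min(max(t_h[i] - y[i] / mu0, 0), max(t_h))
  starts <- list(
    c(A = A0, mu = mu0, lam = lam0),
    c(A = A0, mu = mu0 / 2, lam = min(lam0 + 2, max(t_h))),
    c(A = max(A0 / 2, 0.1), mu = mu0 * 2, lam = max(lam0 - 1, 0))
  )
  dat <- data.frame(t = t_h, od = od)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch({
      if (fixed_od0) {
        minpack.lm::nlsLM(
          od ~ C0 * exp(A / (1 + exp(4 * mu / A * (lam - t) + 2))),
          data = dat, start = as.list(s),
          lower = c(A = 1e-6, mu = 1e-6, lam = 0),
          upper = c(A = 2 * A0 + 1, mu = 10, lam = max(t_h)),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          od ~ C * exp(A / (1 + exp(4 * mu / A * (lam - t) + 2))),
          data = dat, start = c(as.list(s), list(C = C0)),
          lower = c(A = 1e-6, mu = 1e-6, lam = 0, C = od_floor / 10),
          upper = c(A = 2 * A0 + 1, mu = 10, lam = max(t_h), C = max(od)),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- stats::coef(fit)
        best <- list(A = unname(cf["A"]), mu_max = unname(cf["mu"]),
                     lambda = unname(cf["lam"]),
                     od0 = if (fixed_od0) C0 else unname(cf["C"]),
                     rss = rss)
      }
    }
  }
  if (is.null(best)) {
    stop("logistic fit failed to converge from every start", call. = FALSE)
  }
  structure(c(best, list(n = length(t_h), no_growth = FALSE)),
            class = "growth_curve_fit")
}

#' Composite screening parameter beta from a growth-curve fit
#'
#' The screening parameter beta summarizes growth performance per condition.
#' Its exact formula is configurable; the default is the fitted maximum
#' specific growth rate. A no-growth fit gives beta 0 under every definition.
#'
#' @param fit a [fit_growth_curve()] result.
#' @param definition one of `"mu_max"`, `"A_mu_max"` (product), `"A"`.
#' @return numeric beta; the definition used is attached as attribute
#'   `definition`.
#' @export
beta_from_fit <- function(fit, definition = c("mu_max", "A_mu_max", "A")) {
  definition <- match.arg(definition)
  b <- switch(definition,
              mu_max = fit$mu_max,
              A_mu_max = fit$A * fit$mu_max,
              A = fit$A)
  structure(b, definition = definition)
}

#' Linear regression of beta against lignin concentration
#'
#' Ordinary least squares on the included (lignin, beta) points; points can
#' be excluded from regression and extrapolation via `exclude`. When the
#' slope is negative, the x-intercept `-intercept/slope` is reported as the
#' extrapolated lignin tolerance; otherwise the tolerance is flagged
#' non-finite.
#'
#' @param lignin_gL lignin concentrations (g/L).
#' @param beta beta values.
#' @param exclude logical mask of points to leave out (default none).
#' @return list `slope, intercept, r2, x_intercept, n_used, finite_tolerance`.
#' @export
beta_regression <- function(lignin_gL, beta, exclude = NULL) {
  stopifnot(length(lignin_gL) == length(beta))
  if (is.null(exclude)) exclude <- rep(FALSE, length(beta))
  keep <- !exclude
  x <- lignin_gL[keep]; y <- beta[keep]
  if (length(x) < 2 || length(unique(x)) < 2) {
    stop("need >= 2 included points with distinct lignin levels", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  finite <- slope < 0
  list(slope = slope, intercept = intercept, r2 = r2,
       x_intercept = if (finite) -intercept / slope else NA_real_,
       n_used = length(x), finite_tolerance = finite)
}

#' End-to-end screening analysis of a plate
#'
#' Blank-corrects all growth wells, fits the logistic growth model per well,
#' aggregates replicate fits per (sugar variant, lignin level) condition by
#' the median, extracts beta, and regresses beta against lignin per sugar
#' variant to extrapolate the lignin tolerance.
#'
#' @param curves long data.frame `well, t_h, od` for the whole plate.
#' @param layout a [plate_layout()].
#' @param beta_definition passed to [beta_from_fit()].
#' @param exclude optional function `(lignin_gL, beta) -> logical mask`
#'   applied per sugar variant before regression (explicit exclusion input;
#'   default excludes nothing).
#' @return list with `well_fits` (per-well data.frame), `conditions`
#'   (per-condition medians of A, mu_max, lambda plus beta), and
#'   `regressions` (per sugar variant, see [beta_regression()]).
#' @export
screen_plate <- function(curves, layout,
                         beta_definition = "mu_max", exclude = NULL) {
  corr <- blank_correct(curves, layout)
  wells <- unique(corr$well)
  well_fits <- do.call(rbind, lapply(wells, function(w) {
    d <- corr[corr$well == w, ]
    f <- fit_growth_curve(d$t_h, d$od)
    data.frame(well = w, sugar_variant = d$sugar_variant[1],
               lignin_gL = d$lignin_gL[1], A = f$A, mu_max = f$mu_max,
               lambda = f$lambda, no_growth = f$no_growth,
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(cbind(A, mu_max, lambda) ~ sugar_variant + lignin_gL,
                          data = well_fits, FUN = stats::median)
  agg$beta <- vapply(seq_len(nrow(agg)), function(i) {
    f <- list(A = agg$A[i], mu_max = agg$mu_max[i], lambda = agg$lambda[i])
    as.numeric(beta_from_fit(f, beta_definition))
  }, numeric(1))
  regs <- lapply(split(agg, agg$sugar_variant), function(d) {
    d <- d[order(d$lignin_gL), ]
    mask <- if (is.null(exclude)) NULL else exclude(d$lignin_gL, d$beta)
    c(beta_regression(d$lignin_gL, d$beta, exclude = mask),
      list(lignin_gL = d$lignin_gL, beta = d$beta))
  })
  list(well_fits = well_fits, conditions = agg, regressions = regs,
       beta_definition = beta_definition)
}
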