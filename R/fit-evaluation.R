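#' Residual standard deviation (pooled RMSE)
#'
#' Root-mean-square distance between observed and model values, pooled over
#' all paired points: `sqrt(sum((obs - model)^2) / n)`. Used as the sigma
#' statistic of model-fit quality; it carries the units of the data, so its
#' magnitude scales with the concentration level of the run.
#'
#' @param obs,model numeric vectors of equal length (>= 2 pairs after
#'   dropping pairs with missing values).
#' @return sigma >= 0.
#' @export
residual_sigma <- function(obs, model) {
  if (length(obs) != length(model)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(obs) & is.finite(model)
  obs <- obs[ok]; model <- model[ok]
  if (length(obs) < 2) stop("need >= 2 paired values", call. = FALSE)
  sqrt(sum((obs - model)^2) / length(obs))
}

#' Coefficient of determination
#'
#' `1 - SS_res/SS_tot` with the total sum of squares taken about the observed
#' mean. Constant observations leave R^2 undefined and raise an error.
#'
#' @param obs,model numeric vectors of equal length (>= 3 pairs).
#' @return r2 <= 1.
#' @export
r_squared <- function(obs, model) {
  if (length(obs) != length(model)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(obs) & is.finite(model)
  obs <- obs[ok]; model <- model[ok]
  if (length(obs) < 3) stop("need >= 3 paired values", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant observations", call. = FALSE)
  1 - sum((obs - model)^2) / ss_tot
}

#' Single-factor ANOVA of observed versus model values
#'
#' One-way ANOVA with two groups (the observed values and the model values),
#' testing at confidence level `1 - alpha` the hypothesis that experimental
#' and model-derived data are equal. Degrees of freedom are `(1, 2n - 2)`;
#' the decision "equal at 95%" is `F < F_critical`, equivalently `p > alpha`.
#'
#' @param obs,model numeric vectors of equal length (>= 2 pairs).
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `F_critical`, `p`, `df = c(1, 2n-2)`, `n`, and
#'   `degenerate` (TRUE when within-group variance is zero with a nonzero
#'   between-group difference, giving `F = Inf`, `p = 0`).
#' @export
anova_obs_vs_model <- function(obs, model, alpha = 0.05) {
  if (length(obs) != length(model)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(obs) & is.finite(model)
  obs <- obs[ok]; model <- model[ok]
  n <- length(obs)
  if (n < 2) stop("need >= 2 paired values", call. = FALSE)
  df <- c(1L, 2L * n - 2L)
  fcrit <- stats::qf(1 - alpha, df[1], df[2])
  msw <- (stats::var(obs) + stats::var(model)) / 2
  degenerate <- FALSE
  if (msw == 0) {
    if (mean(obs) == mean(model)) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    ow <- stats::oneway.test(
      value ~ group,
      data = data.frame(value = c(obs, model),
                        group = rep(c("obs", "model"), each = n)),
      var.equal = TRUE)
    f <- unname(ow$statistic)
    p <- ow$p.value
  }
  list(F = f, F_critical = fcrit, p = p, df = df, n = n,
       degenerate = degenerate)
}

#' Model-fit quality report
#'
#' Pools all paired state-variable values of an observed series and a model
#' trajectory on the same time grid, and reports the residual sigma, R^2 and
#' the two-group single-factor ANOVA, plus a per-variable sigma breakdown and
#' the residual dump for auditability.
#'
#' @param observed,model data.frames sharing column `t_h` and the state
#'   columns in `variables`.
#' @param variables state columns to pool (default all concentration columns
#'   present in both).
#' @param alpha ANOVA significance level.
#' @return object of class `fit_report`: `sigma`, `r2`, `F`, `F_critical`,
#'   `p`, `df`, `n`, `sigma_by_variable`, `residuals` (long data.frame).
#' @export
fit_report <- function(observed, model,
                       variables = NULL, alpha = 0.05) {
  if (is.null(variables)) {
    variables <- intersect(intersect(c("X_gL", "glc_gL", "xyl_gL", "ara_gL",
                                       "la_gL"), names(observed)),
                           names(model))
  }
  stopifnot(length(variables) >= 1)
  if (!isTRUE(all.equal(observed$t_h, model$t_h))) {
    stop("observed and model must share the same time grid", call. = FALSE)
  }
  long <- do.call(rbind, lapply(variables, function(v) {
    data.frame(t_h = observed$t_h, variable = v,
               obs = observed[[v]], model = model[[v]])
  }))
  long <- long[is.finite(long$obs) & is.finite(long$model), ]
  an <- anova_obs_vs_model(long$obs, long$model, alpha = alpha)
  sig_by <- vapply(split(long, long$variable), function(d) {
    sqrt(sum((d$obs - d$model)^2) / nrow(d))
  }, numeric(1))
  structure(list(sigma = residual_sigma(long$obs, long$model),
                 r2 = r_squared(long$obs, long$model),
                 F = an$F, F_critical = an$F_critical, p = an$p,
                 df = an$df, n = an$n, degenerate = an$degenerate,
                 sigma_by_variable = sig_by,
                 residuals = long),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit report: n = %d paired points\n", x$n))
  cat(sprintf("  sigma = %.4f   R^2 = %.4f\n", x$sigma, x$r2))
  cat(sprintf("  ANOVA: F = %.4f, F_critical = %.4f (df %d, %d), p = %.4f\n",
              x$F, x$F_critical, x$df[1], x$df[2], x$p))
  cat(sprintf("  observed and model data %s at the %d%% level\n",
              if (x$F < x$F_critical) "indistinguishable" else "differ",
              round(100 * (1 - 0.05))))
  invisible(x)
}
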