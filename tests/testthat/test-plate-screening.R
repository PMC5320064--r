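logistic_y <- function(t, A, mu, lam) A / (1 + exp(4 * mu / A * (lam - t) + 2))

test_that("plate layout follows the honeycomb pipetting scheme", {
  lay <- plate_layout()
  expect_equal(nrow(lay), 100)
  expect_equal(sum(lay$role == "medium_blank"), 30)
  expect_equal(sum(lay$role == "water_blank"), 10)
  expect_equal(sum(lay$role == "growth"), 60)
  # two wells per lignin level in each blank column
  b1 <- lay[lay$role == "medium_blank" & lay$col == 1, ]
  expect_equal(as.vector(table(b1$lignin_gL)), rep(2L, 5))
  # four growth replicates per (sugar, lignin) condition
  g <- lay[lay$role == "growth", ]
  expect_true(all(table(g$sugar_variant, g$lignin_gL) == 4))
})

test_that("blank correction removes the medium signal", {
  lay <- plate_layout()
  tt <- seq(0, 10, 0.5)
  blank_sig <- 0.1 + 0.003 * tt   # drifting blank
  y <- logistic_y(tt, A = 2, mu = 0.5, lam = 3)
  signal <- 0.08 * exp(y)
  curves <- do.call(rbind, lapply(seq_len(nrow(lay)), function(i) {
    w <- lay[i, ]
    od <- if (w$role == "growth" && w$sugar_variant == "glc60" &&
              w$lignin_gL == 0) blank_sig + signal else blank_sig
    data.frame(well = w$well, t_h = tt, od = od)
  }))
  corr <- blank_correct(curves, lay)

  # wells identical to their blanks come out flat zero
  flat <- corr[corr$sugar_variant == "xyl60", ]
  expect_true(all(abs(flat$od) < 1e-12))

  # the drifting blank is removed exactly; the pure signal is recovered
  g <- corr[corr$sugar_variant == "glc60" & corr$lignin_gL == 0 &
              corr$well == "A05", ]
  expect_equal(g$od, signal, tolerance = 1e-12)

  # missing blank for a condition is a named error
  lay2 <- lay[!(lay$role == "medium_blank" & lay$sugar_variant == "glc60"), ]
  expect_error(blank_correct(curves, lay2), "glc60")
})

test_that("logistic fit is self-inverse on noise-free curves", {
  tt <- seq(0, 30, 0.5)
  y <- logistic_y(tt, A = 2, mu = 0.5, lam = 3)
  fit <- fit_growth_curve(tt, 0.1 * exp(y))
  expect_equal(fit$A, 2, tolerance = 1e-6)
  expect_equal(fit$mu_max, 0.5, tolerance = 1e-6)
  expect_equal(fit$lambda, 3, tolerance = 1e-6)
  expect_false(fit$no_growth)
})

test_that("flat curves yield a flagged no-growth fit with beta 0", {
  tt <- seq(0, 12, 1)
  fit <- fit_growth_curve(tt, rep(0.01, length(tt)))
  expect_true(fit$no_growth)
  expect_equal(fit$A, 0)
  expect_equal(fit$mu_max, 0)
  expect_equal(fit$lambda, 12)
  for (d in c("mu_max", "A_mu_max", "A")) {
    expect_equal(as.numeric(beta_from_fit(fit, d)), 0)
  }
})

test_that("time shift moves the lag and leaves A and mu_max unchanged", {
  tt <- seq(0, 30, 0.5)
  od <- 0.1 * exp(logistic_y(tt, A = 2.2, mu = 0.4, lam = 2.5))
  f0 <- fit_growth_curve(tt, od)
  f5 <- fit_growth_curve(tt + 5, od)
  expect_equal(f5$A, f0$A, tolerance = 1e-5)
  expect_equal(f5$mu_max, f0$mu_max, tolerance = 1e-5)
  expect_equal(f5$lambda, f0$lambda + 5, tolerance = 1e-4)
})

test_that("beta definitions are selectable and recorded", {
  fit <- list(A = 2, mu_max = 0.5, lambda = 3)
  expect_equal(as.numeric(beta_from_fit(fit, "mu_max")), 0.5)
  expect_equal(as.numeric(beta_from_fit(fit, "A_mu_max")), 1.0)
  expect_equal(as.numeric(beta_from_fit(fit, "A")), 2)
  expect_equal(attr(beta_from_fit(fit, "A_mu_max"), "definition"),
               "A_mu_max")
  expect_error(beta_from_fit(fit, "nonsense"))
})

test_that("beta regression matches the exact line and the normal-equation oracle", {
  # exact line beta = 0.4 - 0.5 L
  L <- c(0, 0.2, 0.4, 0.6, 0.8)
  r <- beta_regression(L, 0.4 - 0.5 * L)
  expect_equal(r$slope, -0.5, tolerance = 1e-12)
  expect_equal(r$intercept, 0.4, tolerance = 1e-12)
  expect_equal(r$x_intercept, 0.8, tolerance = 1e-12)
  expect_true(r$finite_tolerance)

  # non-negative slope: no finite tolerance
  r2 <- beta_regression(L, 0.1 + 0.2 * L)
  expect_false(r2$finite_tolerance)
  expect_true(is.na(r2$x_intercept))

  # random points vs closed-form normal equations
  set.seed(5)
  for (i in 1:10) {
    x <- runif(8, 0, 1)
    y <- runif(8)
    r3 <- beta_regression(x, y)
    o <- ols_normal_equations(x, y)
    expect_equal(r3$slope, unname(o["slope"]), tolerance = 1e-12)
    expect_equal(r3$intercept, unname(o["intercept"]), tolerance = 1e-12)
  }

  # exclusion mask: excluded points do not influence the line
  xx <- c(0, 0.2, 0.4, 0.6, 0.8)
  yy <- 0.4 - 0.5 * xx
  yy[5] <- 0.9  # outlier, excluded like a "black symbol"
  r4 <- beta_regression(xx, yy, exclude = c(F, F, F, F, T))
  expect_equal(r4$slope, -0.5, tolerance = 1e-12)
  expect_equal(r4$n_used, 4)
  expect_error(beta_regression(xx, yy, exclude = rep(TRUE, 5)), "included")
})

test_that("replicate aggregation is permutation-invariant", {
  spec <- scenario_spec(seed = 3, grid = seq(0, 48, 1))
  pl <- gen_plate(spec)
  sc1 <- screen_plate(pl$curves, pl$layout)
  perm <- sample(nrow(pl$curves))
  sc2 <- screen_plate(pl$curves[perm, ], pl$layout)
  c1 <- sc1$conditions[order(sc1$conditions$sugar_variant,
                             sc1$conditions$lignin_gL), ]
  c2 <- sc2$conditions[order(sc2$conditions$sugar_variant,
                             sc2$conditions$lignin_gL), ]
  expect_equal(c1$beta, c2$beta, tolerance = 1e-9)
})
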