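test_that("sse objective is zero on self-consistent data and matches hand arithmetic", {
  p <- monod_params()
  init <- ferment_state(X = 0.05, S_glc = 20, S_xyl = 10, S_ara = 5)
  grid <- seq(0, 24, 3)
  obs <- as.data.frame(simulate_fermentation(p, init, grid))

  # data generated by the model itself
  expect_lt(sse_objective(obs, p, init = init), 1e-8)

  # all-zero weights
  w <- c(X_gL = 0, glc_gL = 0, xyl_gL = 0, ara_gL = 0, la_gL = 0)
  expect_equal(sse_objective(obs, p, weights = w, init = init), 0)

  # 3-point toy series against a constant model: hand-summable squares.
  # A zero-inoculum simulation holds every state at its initial value, so
  # the model prediction for lactate is constant 0.
  toy <- data.frame(t_h = c(0, 1, 2), la_gL = c(1, 2, 3))
  p0 <- monod_params()
  init0 <- ferment_state(X = 0, S_glc = 10, S_xyl = 0, S_ara = 0, P_la = 0)
  # residuals 1, 2, 3 -> weighted by 1/range^2 = 1/4 -> (1+4+9)/4
  expect_equal(sse_objective(toy, p0, init = init0), 14 / 4,
               tolerance = 1e-8)
  # with explicit unit weight: 14 exactly
  expect_equal(sse_objective(toy, p0, weights = c(la_gL = 1), init = init0),
               14, tolerance = 1e-8)
})

test_that("missing observations are skipped in the objective", {
  p <- monod_params()
  init <- ferment_state(X = 0.05, S_glc = 20, S_xyl = 10, S_ara = 5)
  grid <- seq(0, 12, 2)
  obs <- as.data.frame(simulate_fermentation(p, init, grid))
  obs$X_gL[3] <- NA
  obs$la_gL[c(2, 5)] <- NA
  expect_lt(sse_objective(obs, p, init = init), 1e-8)
})

test_that("GA solves the 5-dimensional sphere benchmark", {
  sphere <- function(x) sum(x^2)
  bounds <- setNames(rep(list(c(-5, 5)), 5), paste0("x", 1:5))
  cfg <- ga_config(bounds, population_size = 60, generations = 100, seed = 1)
  fit <- ga_minimize(sphere, cfg)
  expect_lt(fit$best_value, 1e-3)
})

test_that("GA is reproducible, monotone under elitism, and handles edge objectives", {
  bounds <- list(a = c(0, 1), b = c(-2, 2))
  cfg <- ga_config(bounds, population_size = 20, generations = 30, seed = 42)
  rosen <- function(x) (1 - x[["a"]])^2 + 100 * (x[["b"]] - x[["a"]]^2)^2

  f1 <- ga_minimize(rosen, cfg)
  f2 <- ga_minimize(rosen, cfg)
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$history, f2$history)

  # elitism: per-generation best objective never increases
  expect_true(all(diff(f1$history) <= 0))
  expect_equal(f1$best_value, f1$history[length(f1$history)])

  # constant objective: flat history at that constant
  fc <- ga_minimize(function(x) 7.5, cfg)
  expect_equal(fc$best_value, 7.5)
  expect_true(all(fc$history == 7.5))

  # non-finite objective values are penalized, not propagated
  fn <- ga_minimize(function(x) if (x[["a"]] < 0.5) NaN else x[["a"]], cfg)
  expect_true(is.finite(fn$best_value))

  # zero-measure bounds rejected
  expect_error(ga_config(list(a = c(1, 1))), "low < high")
})

test_that("GA recovers kinetic parameters from a noise-free single-sugar run", {
  truth <- monod_params(mu_max = c(glc = 0.40, xyl = 0.20, ara = 0.15))
  init <- ferment_state(X = 0.05, S_glc = 20, S_xyl = 0, S_ara = 0)
  obs <- as.data.frame(simulate_fermentation(truth, init, seq(0, 24, 2)))
  bounds <- list("mu_max.glc" = c(0.1, 1), "K_S.glc" = c(0.05, 3),
                 "Y_XS.glc" = c(0.02, 0.3))
  cfg <- ga_config(bounds, population_size = 40, generations = 60, seed = 1)
  fit <- fit_kinetics(obs, truth, cfg, init = init)
  expect_lt(abs(fit$best_params[["mu_max.glc"]] - 0.40) / 0.40, 0.05)
  expect_lt(abs(fit$best_params[["Y_XS.glc"]] - 0.08) / 0.08, 0.05)
  expect_true(all(diff(fit$history) <= 0))
  # the fitted full parameter object carries the recovered values
  expect_equal(fit$best_monod$mu_max[["glc"]],
               fit$best_params[["mu_max.glc"]])
})
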