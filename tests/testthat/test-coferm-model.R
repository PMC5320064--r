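test_that("specific rates follow the Monod/inhibition formula", {
  p <- monod_params()

  # no substrate, no growth
  st <- ferment_state(X = 1, S_glc = 0, S_xyl = 0, S_ara = 0)
  expect_equal(specific_rates(st, p)$mu, 0)

  # saturation limit: at very high glucose the rate approaches mu_max
  st <- ferment_state(X = 1, S_glc = 1e9, S_xyl = 0, S_ara = 0)
  expect_equal(specific_rates(st, p)$mu_i[["glc"]], p$mu_max[["glc"]],
               tolerance = 1e-6)

  # half saturation x half lignin inhibition = mu_max/4
  st <- ferment_state(X = 1, S_glc = p$K_S[["glc"]], S_xyl = 0, S_ara = 0,
                      P_la = 0, L = p$K_L)
  expect_equal(specific_rates(st, p)$mu, p$mu_max[["glc"]] / 4,
               tolerance = 1e-12)

  # full product inhibition stops growth
  st <- ferment_state(X = 1, S_glc = 10, S_xyl = 5, S_ara = 2,
                      P_la = p$P_max)
  expect_equal(specific_rates(st, p)$mu, 0)

  # pentose repression factor: glucose present halves pentose rates at
  # S_glc = K_rep
  st0 <- ferment_state(X = 1, S_glc = 0, S_xyl = 5, S_ara = 0)
  st1 <- ferment_state(X = 1, S_glc = p$K_rep, S_xyl = 5, S_ara = 0)
  r0 <- specific_rates(st0, p)$mu_i[["xyl"]]
  r1 <- specific_rates(st1, p)$mu_i[["xyl"]]
  expect_equal(r1 / r0, 0.5, tolerance = 1e-12)

  # non-finite state rejected
  st_bad <- st0
  st_bad[["S_glc"]] <- NaN
  expect_error(specific_rates(st_bad, p), "non-finite")
})

test_that("inhibition terms are individually switchable", {
  st <- ferment_state(X = 1, S_glc = 5, S_xyl = 5, S_ara = 5, P_la = 20,
                      L = 1)
  p_all_off <- monod_params(K_rep = Inf, K_L = Inf, n_P = 0)
  r <- specific_rates(st, p_all_off)
  expected <- p_all_off$mu_max * 5 / (p_all_off$K_S + 5)
  expect_equal(unname(r$mu_i), unname(expected), tolerance = 1e-12)
})

test_that("simulation with no inoculum stays constant", {
  p <- monod_params()
  init <- ferment_state(X = 0, S_glc = 40, S_xyl = 20, S_ara = 10)
  tr <- simulate_fermentation(p, init, seq(0, 24, 2))
  for (col in c("X_gL", "glc_gL", "xyl_gL", "ara_gL", "la_gL")) {
    expect_equal(tr[[col]], rep(tr[[col]][1], nrow(tr)), tolerance = 1e-10)
  }
})

test_that("biomass-substrate mass coupling holds on a single-sugar run", {
  p <- monod_params(alpha = c(glc = 0, xyl = 0, ara = 0), beta_LP = 0)
  init <- ferment_state(X = 0.05, S_glc = 20, S_xyl = 0, S_ara = 0)
  tr <- simulate_fermentation(p, init, seq(0, 48, 2))
  dX <- tr$X_gL[nrow(tr)] - tr$X_gL[1]
  dS <- tr$glc_gL[1] - tr$glc_gL[nrow(tr)]
  expect_equal(dX, p$Y_XS[["glc"]] * dS, tolerance = 1e-5)
})

test_that("catabolite repression delays xylose relative to glucose, monotonically in K_rep", {
  half_time <- function(tr, col) {
    s <- tr[[col]]
    i <- which(s <= s[1] / 2)[1]
    # linear interpolation between the bracketing grid points
    tr$t_h[i - 1] + (s[i - 1] - s[1] / 2) / (s[i - 1] - s[i]) *
      (tr$t_h[i] - tr$t_h[i - 1])
  }
  init <- ferment_state(X = 0.05, S_glc = 40, S_xyl = 20, S_ara = 0)
  grid <- seq(0, 60, 0.5)
  t_xyl <- c()
  for (krep in c(0.2, 1, 5)) {
    p <- monod_params(K_rep = krep, n_P = 0)
    tr <- simulate_fermentation(p, init, grid)
    expect_gt(half_time(tr, "xyl_gL"), half_time(tr, "glc_gL"))
    t_xyl <- c(t_xyl, half_time(tr, "xyl_gL"))
  }
  # stronger repression (smaller K_rep) postpones xylose consumption
  expect_true(all(diff(t_xyl) < 0))
})

test_that("adaptive integrator agrees with a fixed-step RK4 oracle", {
  p <- monod_params()
  init <- ferment_state(X = 0.1, S_glc = 20, S_xyl = 10, S_ara = 5)
  t_end <- 12
  tr <- simulate_fermentation(p, init, c(0, t_end))
  oracle <- rk4_simulate(p, init, t_end, dt = 1e-3)
  got <- c(tr$X_gL[2], tr$glc_gL[2], tr$xyl_gL[2], tr$ara_gL[2], tr$la_gL[2])
  want <- unname(oracle[c("X", "S_glc", "S_xyl", "S_ara", "P_la")])
  rel <- abs(got - want) / pmax(abs(want), 1e-6)
  expect_lt(max(rel), 1e-3)
})

test_that("trajectories stay non-negative and finite on random parameter draws", {
  for (s in 1:25) {
    p <- draw_params(s)
    init <- draw_init(s, lignin = (s %% 4) * 0.8)
    tr <- simulate_fermentation(p, init, seq(0, 48, 3))
    vals <- as.matrix(tr[-1])
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})

test_that("growth is monotonically suppressed by lignin", {
  p <- monod_params()
  grid <- seq(0, 16, 2)
  x_at_end <- vapply(c(0, 0.625, 1.25, 2.5, 3.75), function(L) {
    init <- ferment_state(X = 0.03, S_glc = 46, S_xyl = 21, S_ara = 10.6,
                          L = L)
    tr <- simulate_fermentation(p, init, grid)
    tr$X_gL[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(x_at_end) < 0))
})

test_that("fermentation time follows the residual-sugar stop rule", {
  # constructed trajectory exhausting sugars at exactly t = 26 h on the grid
  tgrid <- seq(0, 48, 2)
  traj <- data.frame(t_h = tgrid,
                     glc_gL = pmax(30 - 1.5 * tgrid, 0),
                     xyl_gL = pmax(9.1 - 0.35 * tgrid, 0),
                     ara_gL = 0)
  expect_equal(fermentation_time(traj), 26)

  # sugars never depleted: last grid time
  traj2 <- data.frame(t_h = tgrid, glc_gL = 10, xyl_gL = 5, ara_gL = 1)
  expect_equal(fermentation_time(traj2), 48)

  # degenerate infinite threshold: first grid time
  expect_equal(fermentation_time(traj2, threshold = Inf), 0)
})

test_that("integrator RHS is consistent with the public rate function", {
  for (s in 1:5) {
    p <- draw_params(s)
    set.seed(s)
    y <- c(stats::runif(1, 0, 5), stats::runif(3, 0, 30),
           stats::runif(1, 0, 40), stats::runif(1, 0, 3))
    st <- ferment_state(X = y[1], S_glc = y[2], S_xyl = y[3], S_ara = y[4],
                        P_la = y[5], L = y[6])
    r <- specific_rates(st, p)
    manual <- c(r$mu * y[1],
                -(r$mu_i / p$Y_XS) * y[1],
                sum(p$alpha * r$mu_i) * y[1] + p$beta_LP * y[1], 0)
    rhs <- coagferm:::coferm_rhs_factory(p)
    expect_equal(unname(rhs(0, y, NULL)[[1]]), unname(manual),
                 tolerance = 1e-12)
  }
})
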