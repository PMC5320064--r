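# Independent oracles, deliberately written as naive loops / textbook
# formulas so they share no code path with the implementation they check.

# Fixed-step RK4 integration of the cofermentation system, driven only by
# the public single-state rate function.
rk4_simulate <- function(params, init, t_end, dt = 1e-3) {
  deriv <- function(y) {
    st <- c(t = 0, X = max(y[1], 0), S_glc = max(y[2], 0),
            S_xyl = max(y[3], 0), S_ara = max(y[4], 0),
            P_la = max(y[5], 0), L = max(y[6], 0))
    r <- specific_rates(st, params)
    X <- max(y[1], 0)
    c(r$mu * X,
      -(r$mu_i / params$Y_XS) * X,
      sum(params$alpha * r$mu_i) * X + params$beta_LP * X,
      0)
  }
  y <- c(unname(init[["X"]]), unname(init[["S_glc"]]), unname(init[["S_xyl"]]),
         unname(init[["S_ara"]]), unname(init[["P_la"]]), unname(init[["L"]]))
  n <- round(t_end / dt)
  for (k in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[y < 0] <- 0
  }
  names(y) <- c("X", "S_glc", "S_xyl", "S_ara", "P_la", "L")
  y
}

naive_sigma <- function(obs, model) {
  s <- 0
  for (i in seq_along(obs)) s <- s + (obs[i] - model[i])^2
  sqrt(s / length(obs))
}

naive_r2 <- function(obs, model) {
  m <- 0
  for (i in seq_along(obs)) m <- m + obs[i]
  m <- m / length(obs)
  ss_res <- 0
  ss_tot <- 0
  for (i in seq_along(obs)) {
    ss_res <- ss_res + (obs[i] - model[i])^2
    ss_tot <- ss_tot + (obs[i] - m)^2
  }
  1 - ss_res / ss_tot
}

# Textbook one-way ANOVA table for two equal-sized groups.
naive_anova_F <- function(g1, g2) {
  n <- length(g1)
  grand <- mean(c(g1, g2))
  ssb <- n * (mean(g1) - grand)^2 + n * (mean(g2) - grand)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  (ssb / 1) / (ssw / (2 * n - 2))
}

# Closed-form OLS via the normal equations.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Random but valid kinetic parameter draws for property tests.
draw_params <- function(seed, alpha_zero = FALSE) {
  set.seed(seed)
  a <- if (alpha_zero) c(glc = 0, xyl = 0, ara = 0) else
    stats::runif(3, 5, 12)
  monod_params(
    mu_max = c(glc = stats::runif(1, 0.25, 0.7),
               xyl = stats::runif(1, 0.1, 0.4),
               ara = stats::runif(1, 0.05, 0.3)),
    K_S = stats::runif(3, 0.2, 2),
    Y_XS = stats::runif(3, 0.04, 0.12),
    K_rep = stats::runif(1, 0.5, 5),
    K_L = stats::runif(1, 1, 5),
    P_max = stats::runif(1, 60, 120),
    n_P = stats::runif(1, 0.5, 2),
    alpha = a,
    beta_LP = 0)
}

draw_init <- function(seed, lignin = 0) {
  set.seed(seed + 10000)
  ferment_state(X = stats::runif(1, 0.02, 0.1),
                S_glc = stats::runif(1, 30, 50),
                S_xyl = stats::runif(1, 15, 25),
                S_ara = stats::runif(1, 5, 12),
                P_la = 0, L = lignin, t = 0)
}
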