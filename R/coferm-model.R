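#' Kinetic parameters of the triple-sugar cofermentation model
#'
#' Constructs and validates the parameter set of the unstructured
#' Monod-kinetics model of *Bacillus coagulans* cofermentation of glucose,
#' xylose and arabinose to lactate under alkali-lignin stress.
#'
#' The specific growth rate on sugar \eqn{i} is
#' \deqn{\mu_i = \mu_{max,i} \frac{S_i}{K_{S,i}+S_i} \cdot rep_i(S_{glc})
#'       \cdot \frac{1}{1+L/K_L} \cdot \max(0, 1-P/P_{max})^{n_P}}
#' with \eqn{rep_{glc} \equiv 1} and, for the pentoses, the catabolite
#' repression factor \eqn{rep = K_{rep}/(K_{rep}+S_{glc})}. Each inhibition
#' term can be switched off individually by setting its constant to the
#' neutral value: `K_rep = Inf` (no repression), `K_L = Inf` (no lignin
#' inhibition), `n_P = 0` (no product inhibition).
#'
#' Biomass, sugar and lactate balances are
#' \deqn{dX/dt = \mu X, \quad dS_i/dt = -(\mu_i/Y_{XS,i}) X, \quad
#'       dP/dt = \left(\sum_i \alpha_i \mu_i\right) X + \beta_{LP} X}
#' (Luedeking-Piret product formation); lignin is treated as a non-consumed
#' inhibitor (\eqn{dL/dt = 0}).
#'
#' @param mu_max named numeric, maximum specific growth rates (1/h) on
#'   `c(glc=, xyl=, ara=)`.
#' @param K_S named numeric, Monod half-saturation constants (g/L) per sugar.
#' @param Y_XS named numeric, biomass yields on each sugar (g/g), in (0, 1].
#' @param K_rep glucose catabolite-repression constant for pentose uptake
#'   (g/L); smaller values mean stronger repression. `Inf` disables it.
#' @param K_L lignin inhibition constant (g/L); `Inf` disables it.
#' @param P_max lactate concentration at full growth arrest (g/L).
#' @param n_P product-inhibition exponent (dimensionless, >= 0).
#' @param alpha named numeric, growth-associated lactate coefficients (g/g)
#'   per sugar.
#' @param beta_LP non-growth-associated lactate formation rate (g/g/h).
#' @return an object of class `monod_params` (a validated named list).
#' @export
monod_params <- function(mu_max = c(glc = 0.60, xyl = 0.35, ara = 0.25),
                         K_S = c(glc = 0.50, xyl = 0.80, ara = 1.00),
                         Y_XS = c(glc = 0.080, xyl = 0.075, ara = 0.070),
                         K_rep = 2.0,
                         K_L = 2.5,
                         P_max = 80,
                         n_P = 1.2,
                         alpha = c(glc = 11.0, xyl = 11.5, ara = 12.0),
                         beta_LP = 0.0) {
  sugars <- c("glc", "xyl", "ara")
  for (v in list(mu_max = mu_max, K_S = K_S, Y_XS = Y_XS, alpha = alpha)) {
    stopifnot(is.numeric(v), length(v) == 3L)
  }
  name_or_die <- function(x, what) {
    if (is.null(names(x))) names(x) <- sugars
    if (!identical(sort(names(x)), sort(sugars))) {
      stop(sprintf("'%s' must be named glc, xyl, ara", what), call. = FALSE)
    }
    x[sugars]
  }
  p <- list(
    mu_max = name_or_die(mu_max, "mu_max"),
    K_S = name_or_die(K_S, "K_S"),
    Y_XS = name_or_die(Y_XS, "Y_XS"),
    K_rep = as.numeric(K_rep),
    K_L = as.numeric(K_L),
    P_max = as.numeric(P_max),
    n_P = as.numeric(n_P),
    alpha = name_or_die(alpha, "alpha"),
    beta_LP = as.numeric(beta_LP)
  )
  if (any(p$mu_max < 0) || any(p$K_S <= 0)) {
    stop("rate and saturation constants must be positive", call. = FALSE)
  }
  if (any(p$Y_XS <= 0) || any(p$Y_XS > 1)) {
    stop("Y_XS must lie in (0, 1]", call. = FALSE)
  }
  if (p$K_rep <= 0 || p$K_L <= 0 || p$P_max <= 0) {
    stop("K_rep, K_L and P_max must be positive", call. = FALSE)
  }
  if (p$n_P < 0) stop("n_P must be >= 0", call. = FALSE)
  if (any(p$alpha < 0) || p$beta_LP < 0) {
    stop("lactate formation coefficients must be >= 0", call. = FALSE)
  }
  structure(p, class = "monod_params")
}

#' Initial fermentation state
#'
#' @param X biomass (g/L); `S_glc,S_xyl,S_ara` sugar concentrations (g/L);
#'   `P_la` lactate (g/L); `L` alkali-lignin (g/L, constant over a run);
#'   `t` time (h).
#' @param S_glc,S_xyl,S_ara,P_la,L,t see `X`.
#' @return named numeric of class `ferment_state`.
#' @export
ferment_state <- function(X, S_glc, S_xyl, S_ara, P_la = 0, L = 0, t = 0) {
  s <- c(t = t, X = X, S_glc = S_glc, S_xyl = S_xyl, S_ara = S_ara,
         P_la = P_la, L = L)
  if (!all(is.finite(s))) stop("non-finite state", call. = FALSE)
  if (any(s[-1] < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(s, class = "ferment_state")
}

#' Per-sugar specific growth rates
#'
#' Evaluates the Monod rate law with catabolite repression, lignin and
#' product inhibition (see [monod_params()]) at a single state.
#'
#' @param state a [ferment_state()] (or named numeric with the same fields).
#' @param params a [monod_params()] object.
#' @return list with `mu_i` (named numeric, 1/h, per sugar) and `mu` (total).
#' @export
specific_rates <- function(state, params) {
  if (!all(is.finite(unclass(state)))) {
    stop("non-finite state passed to specific_rates", call. = FALSE)
  }
  mu_i <- coferm_mu(max(state[["S_glc"]], 0), max(state[["S_xyl"]], 0),
                    max(state[["S_ara"]], 0), max(state[["P_la"]], 0),
                    max(state[["L"]], 0), params)
  names(mu_i) <- c("glc", "xyl", "ara")
  list(mu_i = mu_i, mu = sum(mu_i))
}

## Lean rate kernel shared by specific_rates and the integrator RHS: Monod
## saturation x catabolite repression x lignin inhibition x product
## inhibition, per sugar. Arguments must already be non-negative.
coferm_mu <- function(s_glc, s_xyl, s_ara, p_la, lig, params) {
  S <- c(s_glc, s_xyl, s_ara)
  monod <- S / (unname(params$K_S) + S)
  rep_pent <- if (is.infinite(params$K_rep)) 1 else
    params$K_rep / (params$K_rep + s_glc)
  ligf <- if (is.infinite(params$K_L)) 1 else 1 / (1 + lig / params$K_L)
  prod_inh <- max(0, 1 - p_la / params$P_max)^params$n_P
  unname(params$mu_max) * monod * c(1, rep_pent, rep_pent) * ligf * prod_inh
}

## RHS factory for the production integrator: strips parameter names and
## branch decisions out of the hot loop. States are clamped at zero so stiff
## end-of-substrate dynamics cannot drive rates with negative sugar.
## y layout: X, S_glc, S_xyl, S_ara, P_la, L.
coferm_rhs_factory <- function(params) {
  mu_max <- unname(params$mu_max)
  K_S <- unname(params$K_S)
  inv_Y <- 1 / unname(params$Y_XS)
  alpha <- unname(params$alpha)
  K_rep <- params$K_rep
  K_L <- params$K_L
  P_max <- params$P_max
  n_P <- params$n_P
  beta_LP <- params$beta_LP
  rep_on <- is.finite(K_rep)
  lig_on <- is.finite(K_L)
  function(t, y, parms) {
    X <- if (y[1L] > 0) y[1L] else 0
    S <- y[2:4]
    S[S < 0] <- 0
    P <- if (y[5L] > 0) y[5L] else 0
    L <- if (y[6L] > 0) y[6L] else 0
    monod <- S / (K_S + S)
    rp <- if (rep_on) K_rep / (K_rep + S[1L]) else 1
    lf <- if (lig_on) 1 / (1 + L / K_L) else 1
    pin <- 1 - P / P_max
    pin <- if (pin > 0) pin^n_P else 0
    mu_i <- mu_max * monod * c(1, rp, rp) * (lf * pin)
    list(c(sum(mu_i) * X, -(mu_i * inv_Y) * X,
           sum(alpha * mu_i) * X + beta_LP * X, 0))
  }
}

#' Simulate a cofermentation run
#'
#' Integrates the cofermentation ODE system forward on a stated time grid
#' using `deSolve::ode` (lsoda). Any negative concentrations produced by the
#' adaptive integrator near substrate exhaustion are clipped at zero; the
#' number of clipped values is recorded in the `clipped` attribute.
#'
#' @param params a [monod_params()] object.
#' @param init a [ferment_state()]; `init["t"]` must equal `t_grid[1]`.
#' @param t_grid strictly increasing time grid (h) starting at `init["t"]`.
#' @param rtol,atol integrator tolerances (recorded in the result attributes).
#' @return data.frame of class `ferment_trajectory` with columns
#'   `t_h, X_gL, glc_gL, xyl_gL, ara_gL, la_gL, lignin_gL`; attributes
#'   `clipped`, `rtol`, `atol`, `params`, `provenance = "simulated"`.
#' @export
simulate_fermentation <- function(params, init, t_grid,
                                  rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(params, "monod_params"))
  if (!all(is.finite(t_grid)) || any(diff(t_grid) <= 0)) {
    stop("t_grid must be finite and strictly increasing", call. = FALSE)
  }
  if (abs(t_grid[1] - init[["t"]]) > 1e-12) {
    stop("t_grid must start at init time", call. = FALSE)
  }
  y0 <- c(X = unname(init[["X"]]),
          S_glc = unname(init[["S_glc"]]),
          S_xyl = unname(init[["S_xyl"]]),
          S_ara = unname(init[["S_ara"]]),
          P_la = unname(init[["P_la"]]),
          L = unname(init[["L"]]))
  sol <- deSolve::ode(y = y0, times = t_grid, func = coferm_rhs_factory(params),
                      parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("integrator failure (istate %d); last good time %.4g h",
                 attr(sol, "istate")[1], max(sol[, "time"])), call. = FALSE)
  }
  m <- as.data.frame(sol)
  conc <- c("X", "S_glc", "S_xyl", "S_ara", "P_la", "L")
  n_clip <- sum(m[conc] < 0)
  m[conc] <- lapply(m[conc], pmax, 0)
  out <- data.frame(t_h = m$time, X_gL = m$X, glc_gL = m$S_glc,
                    xyl_gL = m$S_xyl, ara_gL = m$S_ara, la_gL = m$P_la,
                    lignin_gL = m$L)
  structure(out,
            class = c("ferment_trajectory", "data.frame"),
            clipped = n_clip, rtol = rtol, atol = atol,
            params = params, provenance = "simulated")
}

#' Fermentation time from a trajectory
#'
#' Returns the first grid time at which the total residual sugar
#' (glucose + xylose + arabinose) drops below `threshold`; if it never does,
#' the last grid time. An infinite threshold therefore returns the first
#' time point (degenerate rule), matching a fixed-harvest reading of the
#' duration. `threshold` defaults to 0.5 g/L residual sugar.
#'
#' @param traj a trajectory or observed series with columns
#'   `t_h, glc_gL, xyl_gL, ara_gL`.
#' @param threshold residual-sugar stop level (g/L).
#' @return fermentation time FT (h).
#' @export
fermentation_time <- function(traj, threshold = 0.5) {
  stopifnot(nrow(traj) >= 1)
  total <- traj$glc_gL + traj$xyl_gL + traj$ara_gL
  hit <- which(total < threshold)
  if (length(hit) == 0L) traj$t_h[nrow(traj)] else traj$t_h[hit[1]]
}
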