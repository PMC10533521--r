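# Independent oracles and shared fixtures for the test suite.

# Residual form of the discretized RD system, coded directly from the
# printed finite-difference equations (independently of rd_rhs): given a
# state and a proposed time derivative, returns the residual vector that
# must vanish.
rd_residual_oracle <- function(state, deriv, params, w2) {
  g <- state$gamma; np <- state$n_plus; nm <- state$n_minus
  gt <- deriv$gamma; npt <- deriv$n_plus; nmt <- deriv$n_minus
  m <- length(g)
  nbar <- np + nm; ntil <- nm - np
  res_g <- numeric(m)
  res_g[1] <- gt[1] + g[1]
  for (i in 2:(m - 1)) {
    res_g[i] <- params$mu * g[i] - w2 * (g[i + 1] - 2 * g[i] + g[i - 1]) +
      params$mu_a * (params$zeta * nbar[i] * gt[i] - ntil[i])
  }
  res_g[m] <- params$mu * g[m] - 2 * w2 * (g[m - 1] - g[m]) +
    params$mu_a * (params$zeta * nbar[m] * gt[m] - ntil[m])
  res_np <- npt - params$eta * (1 - np) +
    (1 - params$eta) * np * exp(params$fstar * (1 + params$zeta * gt))
  res_nm <- nmt - params$eta * (1 - nm) +
    (1 - params$eta) * nm * exp(params$fstar * (1 - params$zeta * gt))
  c(res_g, res_np, res_nm)
}

# Brute-force minimizer of sum |e - exp(i phi) s|^2 over a dense phase
# grid; oracle for the closed-form optimal_phase.
brute_force_phase <- function(e, s, n_grid = 1e4) {
  phis <- seq(-pi, pi, length.out = n_grid)
  obj <- vapply(phis, function(p) sum(Mod(e - exp(1i * p) * s)^2),
                numeric(1))
  phis[which.min(obj)]
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# Oscillation period from upward zero crossings of a single time trace
# (linearly interpolated crossing instants).
crossing_period <- function(t, x) {
  x <- x - mean(x)
  up <- which(x[-length(x)] < 0 & x[-1] >= 0)
  stopifnot(length(up) >= 3)
  tc <- t[up] - x[up] * (t[up + 1] - t[up]) / (x[up + 1] - x[up])
  mean(diff(tc))
}

# Shared cache so expensive simulations are run once per suite.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Shared small fit problem: ground truth on the grid, no noise.
fit_fixture <- function() {
  cached("fit_fixture", {
    truth <- rd_params(2500, 100, 0.14, 0.3, 2)
    rec <- synthesize_beat_record(truth, "chlamy_theta_19pt_1ms",
                                  noise_sigma = 0, seed = 1)
    grid <- parameter_grid(100, mu_a = c(1000, 2000, 2500, 3000),
                           eta = c(0.10, 0.14), zeta = c(0.3, 0.4))
    sims <- candidate_modes(grid, mu = 100)
    list(truth = truth, rec = rec, grid = grid, sims = sims,
         target = fundamental_mode(preprocess_record(rec)))
  })
}

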