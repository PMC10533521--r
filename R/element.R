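#' Right-hand side of the isolated shearing element
#'
#' An isolated element experiences no contact forces from neighbouring
#' material, so the tangential force balance reads f^t = 0: active motor
#' force, motor friction and elastic shear resistance cancel pointwise.
#' Solving the balance for the shear rate gives (time in tau units)
#' `gamma_t = (nu_a ntilde - gamma) / (nu_a zeta nbar)` with
#' `ntilde = n_minus - n_plus`, `nbar = n_minus + n_plus`, and the bound
#' fractions follow the tug-of-war rate equations
#' `n+-_t = eta (1 - n+-) - (1 - eta) n+- exp[fstar (1 +- zeta gamma_t)]`.
#'
#' @param state numeric vector `c(gamma, n_plus, n_minus)`.
#' @param nu_a activity ratio `mu_a/mu` of motor force to shear stiffness.
#' @param zeta,eta,fstar motor parameters.
#' @return Named vector of time derivatives
#'   `c(gamma, n_plus, n_minus)`.
#' @export
element_rhs <- function(state, nu_a, zeta, eta, fstar) {
  gamma <- state[[1]]; np <- state[[2]]; nm <- state[[3]]
  nbar <- np + nm
  if (nbar <= 0)
    stop("element_rhs: singular mass (n_plus + n_minus = 0)", call. = FALSE)
  ntil <- nm - np
  gamma_t <- (nu_a * ntil - gamma) / (nu_a * zeta * nbar)
  dnp <- eta * (1 - np) - (1 - eta) * np * exp(fstar * (1 + zeta * gamma_t))
  dnm <- eta * (1 - nm) - (1 - eta) * nm * exp(fstar * (1 - zeta * gamma_t))
  c(gamma = gamma_t, n_plus = dnp, n_minus = dnm)
}

#' Simulate the isolated shearing element
#'
#' Integrates the element's tug-of-war dynamics with a stiff solver.
#' Subcritical activity (`nu_a` below [critical_activity_element()])
#' decays back to the quiescent equilibrium `(0, n0, n0)`; supercritical
#' activity saturates into a limit cycle.
#'
#' @param nu_a activity ratio.
#' @param eta,zeta,fstar motor parameters.
#' @param initial optional numeric vector `c(gamma, n_plus, n_minus)`;
#'   defaults to the equilibrium perturbed by `gamma = 1e-3`.
#' @param t_end integration horizon in tau units.
#' @param dt_out output sampling interval.
#' @param rtol,atol solver tolerances (the exponential detachment terms
#'   are stiff at large `fstar * zeta * gamma_t`).
#' @return An object of class `element_sim`: a data frame with columns
#'   `t`, `gamma`, `n_plus`, `n_minus` and the parameters as attributes.
#' @export
simulate_element <- function(nu_a, eta, zeta, fstar = 2, initial = NULL,
                             t_end = 200, dt_out = 0.01,
                             rtol = 1e-8, atol = 1e-10) {
  n0 <- equilibrium_attachment(eta, fstar)
  if (is.null(initial)) initial <- c(1e-3, n0, n0)
  if (length(initial) != 3L)
    stop("simulate_element: 'initial' must be c(gamma, n_plus, n_minus)",
         call. = FALSE)
  times <- seq(0, t_end, by = dt_out)
  deriv <- function(t, y, parms) {
    list(element_rhs(y, nu_a = nu_a, zeta = zeta, eta = eta, fstar = fstar))
  }
  sol <- deSolve::ode(y = c(gamma = initial[[1]], n_plus = initial[[2]],
                            n_minus = initial[[3]]),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      hmax = 1)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("simulate_element: integrator failure (istate = ", diagn[1], ")",
         call. = FALSE)
  out <- as.data.frame(unclass(sol))
  names(out)[1] <- "t"
  structure(out, class = c("element_sim", "data.frame"),
            nu_a = nu_a, eta = eta, zeta = zeta, fstar = fstar, n0 = n0)
}

#' @export
print.element_sim <- function(x, ...) {
  cat(sprintf("Isolated-element simulation: nu_a = %g, eta = %g, zeta = %g, f* = %g\n",
              attr(x, "nu_a"), attr(x, "eta"), attr(x, "zeta"),
              attr(x, "fstar")))
  cat(sprintf("  %d samples over t in [0, %g] tau; final gamma = %.4g\n",
              nrow(x), x$t[nrow(x)], x$gamma[nrow(x)]))
  invisible(x)
}

#' @export
plot.element_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$gamma, type = "l", xlab = "t (tau)",
                 ylab = expression(gamma), ...)
  graphics::plot(x$t, x$n_plus, type = "l", col = "blue", xlab = "t (tau)",
                 ylab = "bound fraction", ylim = range(x$n_plus, x$n_minus))
  graphics::lines(x$t, x$n_minus, col = "darkgreen")
  graphics::legend("topright", c("n+", "n-"), lty = 1,
                   col = c("blue", "darkgreen"), bty = "n")
  invisible(x)
}

#' Force components of an element trajectory
#'
#' Recovers the three terms of the tangential force balance along a
#' stored trajectory, in units of the shear stiffness force scale:
#' active `nu_a ntilde`, elastic `-gamma`, motor friction
#' `-nu_a zeta nbar gamma_t`. They sum to zero by the force balance
#' defining `gamma_t`.
#'
#' @param sim an `element_sim` object.
#' @return Data frame with columns `t`, `f_active`, `f_elastic`,
#'   `f_friction`.
#' @export
element_forces <- function(sim) {
  stopifnot(inherits(sim, "element_sim"))
  nu_a <- attr(sim, "nu_a"); zeta <- attr(sim, "zeta")
  nbar <- sim$n_plus + sim$n_minus
  ntil <- sim$n_minus - sim$n_plus
  gamma_t <- (nu_a * ntil - sim$gamma) / (nu_a * zeta * nbar)
  data.frame(t = sim$t,
             f_active = nu_a * ntil,
             f_elastic = -sim$gamma,
             f_friction = -nu_a * zeta * nbar * gamma_t)
}

#' Limit-cycle metrics of an element trajectory
#'
#' Discards a transient, locates upward zero crossings of the centred
#' shear angle, and reports the oscillation period (mean crossing
#' spacing), amplitude (half the peak-to-peak excursion) and the force
#' traces of the tangential balance.
#'
#' @param sim an `element_sim` object.
#' @param transient_frac fraction of the record discarded as transient.
#' @param min_cycles minimum number of full cycles required after the
#'   transient; fewer raises a "not converged" error.
#' @return A list of class `limit_cycle_metrics` with `amplitude`,
#'   `period`, `n_cycles` and `force_traces`.
#' @export
limit_cycle_metrics <- function(sim, transient_frac = 0.5, min_cycles = 5) {
  stopifnot(inherits(sim, "element_sim"))
  keep <- sim$t >= transient_frac * sim$t[nrow(sim)]
  tt <- sim$t[keep]
  g <- sim$gamma[keep] - mean(sim$gamma[keep])
  up <- which(g[-length(g)] < 0 & g[-1] >= 0)
  if (length(up) < min_cycles + 1L || (max(g) - min(g)) / 2 < 1e-8)
    stop("limit_cycle_metrics: not converged (fewer than ", min_cycles,
         " full cycles above noise floor after the transient)",
         call. = FALSE)
  # linear interpolation of each crossing instant
  tc <- tt[up] - g[up] * (tt[up + 1] - tt[up]) / (g[up + 1] - g[up])
  forces <- element_forces(sim)[keep, ]
  structure(list(amplitude = (max(g) - min(g)) / 2,
                 period = mean(diff(tc)),
                 n_cycles = length(up) - 1L,
                 force_traces = forces),
            class = "limit_cycle_metrics")
}

#' @export
print.limit_cycle_metrics <- function(x, ...) {
  cat(sprintf("Limit cycle: amplitude %.4g rad, period %.4g tau (%d cycles)\n",
              x$amplitude, x$period, x$n_cycles))
  invisible(x)
}

#' Locate the element Hopf bifurcation numerically
#'
#' Bisects on the activity ratio `nu_a`, classifying each candidate by
#' whether a small perturbation of the equilibrium grows or decays in
#' simulation. Serves as an independent check of the closed-form
#' [critical_activity_element()].
#'
#' @param eta,zeta,fstar motor parameters.
#' @param lower,upper initial bracket for `nu_a`; defaults bracket the
#'   closed-form value generously.
#' @param rel_tol relative bracket width at which to stop.
#' @param t_end horizon for each classification run.
#' @return A list with the bracket (`lower`, `upper`), its midpoint
#'   `nu_a_crit`, and `omega_onset`, the oscillation frequency measured
#'   just above onset.
#' @export
find_element_hopf <- function(eta, zeta, fstar = 2, lower = NULL,
                              upper = NULL, rel_tol = 0.002, t_end = 400) {
  crit_guess <- critical_activity_element(eta, zeta, fstar)
  initial_gamma <- 1e-3
  if (is.null(lower)) lower <- crit_guess / 4
  if (is.null(upper)) upper <- crit_guess * 4
  grows <- function(nu_a) {
    sim <- simulate_element(nu_a, eta, zeta, fstar, t_end = t_end,
                            dt_out = 0.05)
    g <- abs(sim$gamma - mean(sim$gamma))
    n <- length(g)
    late <- max(g[seq(floor(0.75 * n), n)])
    early <- max(g[seq(floor(0.25 * n), floor(0.5 * n))])
    # growth: still amplifying late in the record, or already saturated
    # well above the initial perturbation; roundoff-floor trajectories
    # classify as subcritical
    late > 1e-9 && (late > 3 * early || late > 10 * abs(initial_gamma))
  }
  if (grows(lower) || !grows(upper))
    stop("find_element_hopf: initial bracket does not straddle the onset",
         call. = FALSE)
  while ((upper - lower) / lower > rel_tol) {
    mid <- (lower + upper) / 2
    if (grows(mid)) upper <- mid else lower <- mid
  }
  # frequency just above onset from zero-crossing spacing
  sim <- simulate_element(upper * 1.02, eta, zeta, fstar, t_end = t_end,
                          dt_out = 0.01)
  g <- sim$gamma - mean(sim$gamma[sim$t > t_end / 2])
  keep <- sim$t > t_end / 2
  tt <- sim$t[keep]; gg <- g[keep]
  up <- which(gg[-length(gg)] < 0 & gg[-1] >= 0)
  omega <- if (length(up) >= 3) 2 * pi / mean(diff(tt[up])) else NA_real_
  list(lower = lower, upper = upper, nu_a_crit = (lower + upper) / 2,
       omega_onset = omega)
}

#' Write an element trajectory as delimited text
#'
#' Columns `t, gamma, n_plus, n_minus, f_active, f_elastic, f_friction`,
#' with a JSON sidecar (`<path>.json`) recording the parameters.
#'
#' @param sim an `element_sim` object.
#' @param path output CSV path.
#' @export
write_element_sim <- function(sim, path) {
  stopifnot(inherits(sim, "element_sim"))
  out <- cbind(sim[, c("t", "gamma", "n_plus", "n_minus")],
               element_forces(sim)[, c("f_active", "f_elastic", "f_friction")])
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(list(nu_a = attr(sim, "nu_a"), eta = attr(sim, "eta"),
                            zeta = attr(sim, "zeta"),
                            fstar = attr(sim, "fstar"),
                            n0 = attr(sim, "n0")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
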