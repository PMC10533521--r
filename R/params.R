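#' Dimensional axoneme and motor parameters
#'
#' Bundles the ten dimensional constants of the sliding-controlled
#' flagellum model: the geometry and elasticity of the axoneme and the
#' kinetic constants of the dynein motors. All fields must be strictly
#' positive.
#'
#' @param a inter-filament spacing (length).
#' @param rho line density of motors along the filament pair (1/length).
#' @param f0 motor stall force (force).
#' @param v0 zero-load motor walking velocity (length/time).
#' @param K inter-filament elastic shear stiffness (force/length^2).
#' @param B bending rigidity of the filament bundle (force x length^2).
#' @param L flagellum length (length).
#' @param pi0 base motor attachment rate (1/time).
#' @param eps0 base motor detachment rate (1/time).
#' @param fc characteristic unbinding force of the load-dependent
#'   detachment law (force).
#' @param provenance optional string recording where the values came from.
#'
#' @return An object of class `dim_params` (a named list).
#' @seealso [nondimensionalize()]
#' @export
dim_params <- function(a, rho, f0, v0, K, B, L, pi0, eps0, fc,
                       provenance = "user") {
  vals <- list(a = a, rho = rho, f0 = f0, v0 = v0, K = K, B = B, L = L,
               pi0 = pi0, eps0 = eps0, fc = fc)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("dim_params: field '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(c(vals, list(provenance = provenance)), class = "dim_params")
}

#' @export
print.dim_params <- function(x, ...) {
  cat("Dimensional flagellum parameters (", x$provenance, ")\n", sep = "")
  for (nm in setdiff(names(x), "provenance"))
    cat(sprintf("  %-5s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Nondimensional model parameters
#'
#' The five dimensionless constants governing the reaction-diffusion
#' flagellum: activity `mu_a = a rho f0 L^2 / B`, shear/bend stiffness
#' ratio `mu = a^2 K L^2 / B`, motor duty parameter `eta = pi0 tau`,
#' motor friction parameter `zeta = a/(v0 tau)` and force ratio
#' `fstar = f0/fc`, where `tau = 1/(pi0 + eps0)` is the motor time scale.
#'
#' @param mu_a activity parameter, > 0.
#' @param mu shear resistance relative to bending resistance, >= 0.
#' @param eta duty parameter, in (0, 1).
#' @param zeta motor friction parameter, > 0.
#' @param fstar force ratio, >= 0. Defaults to 2.
#' @param provenance optional string recording where the values came from.
#'
#' @return An object of class `rd_params`.
#' @export
rd_params <- function(mu_a, mu, eta, zeta, fstar = 2, provenance = "user") {
  if (!is.numeric(mu_a) || length(mu_a) != 1L || !is.finite(mu_a) || mu_a <= 0)
    stop("rd_params: 'mu_a' must be a single positive number", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0)
    stop("rd_params: 'mu' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) ||
      eta <= 0 || eta >= 1)
    stop("rd_params: 'eta' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta) || zeta <= 0)
    stop("rd_params: 'zeta' must be a single positive number", call. = FALSE)
  if (!is.numeric(fstar) || length(fstar) != 1L || !is.finite(fstar) ||
      fstar < 0)
    stop("rd_params: 'fstar' must be a single non-negative number",
         call. = FALSE)
  structure(list(mu_a = mu_a, mu = mu, eta = eta, zeta = zeta, fstar = fstar,
                 provenance = provenance),
            class = "rd_params")
}

#' @export
print.rd_params <- function(x, ...) {
  cat("Nondimensional RD parameters (", x$provenance, ")\n", sep = "")
  cat(sprintf("  mu_a = %g, mu = %g, eta = %g, zeta = %g, f* = %g\n",
              x$mu_a, x$mu, x$eta, x$zeta, x$fstar))
  eps <- tryCatch(bifurcation_distance(x$mu_a, x$mu, x$eta, x$zeta, x$fstar),
                  error = function(e) NA_real_)
  if (is.finite(eps))
    cat(sprintf("  distance to Hopf bifurcation: epsilon = %.4g\n", eps))
  invisible(x)
}

#' Nondimensionalize a dimensional parameter set
#'
#' Maps the ten dimensional constants to the five nondimensional ones:
#' `mu_a = a rho f0 L^2/B`, `mu = a^2 K L^2/B`, `eta = pi0/(pi0+eps0)`,
#' `zeta = a (pi0+eps0)/v0`, `fstar = f0/fc`.
#'
#' @param p a [dim_params()] object.
#' @return An [rd_params()] object.
#' @export
nondimensionalize <- function(p) {
  if (!inherits(p, "dim_params"))
    stop("nondimensionalize: expected a 'dim_params' object", call. = FALSE)
  rd_params(mu_a  = p$a * p$rho * p$f0 * p$L^2 / p$B,
            mu    = p$a^2 * p$K * p$L^2 / p$B,
            eta   = p$pi0 / (p$pi0 + p$eps0),
            zeta  = p$a * (p$pi0 + p$eps0) / p$v0,
            fstar = p$f0 / p$fc,
            provenance = p$provenance)
}

#' Equilibrium attached motor fraction
#'
#' At the quiescent equilibrium the attached fraction on either filament
#' is `n0 = eta / (eta + (1 - eta) exp(fstar))`, equivalently
#' `pi0/(pi0 + eps0 e^{f*})`.
#'
#' @param eta duty parameter in (0, 1).
#' @param fstar force ratio, >= 0.
#' @return `n0` in (0, 1).
#' @export
equilibrium_attachment <- function(eta, fstar) {
  if (any(eta <= 0) || any(eta >= 1))
    stop("equilibrium_attachment: 'eta' must lie in (0, 1)", call. = FALSE)
  if (any(fstar < 0))
    stop("equilibrium_attachment: 'fstar' must be >= 0", call. = FALSE)
  eta / (eta + (1 - eta) * exp(fstar))
}

#' Squared intrinsic oscillation frequency
#'
#' `omega0^2 = (1 - n0) fstar - 1`, in units of the motor time scale tau.
#' May be non-positive; oscillatory behaviour requires a positive value,
#' which the stability functions enforce.
#'
#' @param n0 equilibrium attached fraction in (0, 1).
#' @param fstar force ratio.
#' @return The (possibly non-positive) squared frequency.
#' @export
intrinsic_frequency_sq <- function(n0, fstar) {
  if (any(n0 <= 0) || any(n0 >= 1))
    stop("intrinsic_frequency_sq: 'n0' must lie in (0, 1)", call. = FALSE)
  (1 - n0) * fstar - 1
}

# zeta_bar = a/(v0 tau_bar) with tau_bar = 1/(pi0 + eps0 e^{f*}).
# From zeta = a/(v0 tau), tau = 1/(pi0+eps0):
#   zeta_bar/zeta = tau/tau_bar = (pi0 + eps0 e^{f*})/(pi0 + eps0)
#                 = eta + (1 - eta) e^{f*},
# using eta = pi0 tau, 1 - eta = eps0 tau. Hence the identity below.
#' Barred motor-friction parameter
#'
#' Rescales the friction parameter to the equilibrium motor time scale:
#' `zeta_bar = zeta (eta + (1 - eta) exp(fstar))`.
#'
#' @param zeta motor friction parameter.
#' @param eta duty parameter in (0, 1).
#' @param fstar force ratio.
#' @return `zeta_bar >= zeta`.
#' @export
friction_bar <- function(zeta, eta, fstar) {
  zeta * (eta + (1 - eta) * exp(fstar))
}

#' Derived motor quantities
#'
#' Convenience wrapper computing `n0`, `omega0^2` and `zeta_bar` for a
#' motor parameter triple.
#'
#' @param eta,zeta,fstar motor parameters.
#' @return A list with elements `n0`, `omega0_sq`, `zeta_bar`.
#' @export
motor_quantities <- function(eta, zeta, fstar) {
  n0 <- equilibrium_attachment(eta, fstar)
  list(n0 = n0,
       omega0_sq = intrinsic_frequency_sq(n0, fstar),
       zeta_bar = friction_bar(zeta, eta, fstar))
}

#' Critical activity of the flagellar Hopf bifurcation
#'
#' The spatially extended system loses stability at
#' `mu_a_crit = (pi^2 + 4 mu) / (8 n0 zeta_bar omega0^2)`. Setting the
#' `pi^2` summand to zero recovers `mu` times the single-element critical
#' ratio `nu_a_crit = 1/(2 zeta_bar n0 omega0^2)`.
#'
#' @param mu shear/bend stiffness ratio.
#' @param eta,zeta,fstar motor parameters.
#' @return `mu_a_crit > 0`.
#' @export
critical_activity <- function(mu, eta, zeta, fstar) {
  mq <- motor_quantities(eta, zeta, fstar)
  if (mq$omega0_sq <= 0)
    stop("critical_activity: below oscillation threshold (omega0^2 <= 0); ",
         "no Hopf bifurcation for these motor parameters", call. = FALSE)
  (pi^2 + 4 * mu) / (8 * mq$n0 * mq$zeta_bar * mq$omega0_sq)
}

#' Single-element critical activity ratio
#'
#' Hopf point of the isolated shearing element,
#' `nu_a_crit = 1/(2 zeta_bar n0 omega0^2)` with `nu_a = mu_a/mu`.
#'
#' @inheritParams critical_activity
#' @export
critical_activity_element <- function(eta, zeta, fstar) {
  mq <- motor_quantities(eta, zeta, fstar)
  if (mq$omega0_sq <= 0)
    stop("critical_activity_element: below oscillation threshold ",
         "(omega0^2 <= 0)", call. = FALSE)
  1 / (2 * mq$zeta_bar * mq$n0 * mq$omega0_sq)
}

#' Relative distance to the Hopf bifurcation
#'
#' `epsilon = (mu_a - mu_a_crit)/mu_a_crit`; negative when subcritical.
#'
#' @param mu_a activity parameter.
#' @inheritParams critical_activity
#' @export
bifurcation_distance <- function(mu_a, mu, eta, zeta, fstar) {
  crit <- critical_activity(mu, eta, zeta, fstar)
  (mu_a - crit) / crit
}

#' Linear growth rate and frequency near onset
#'
#' For relative distance `epsilon` to the bifurcation, linear theory gives
#' growth rate `alpha = epsilon omega0^2 / (2 (1 + epsilon))` and squared
#' frequency
#' `omega^2 = omega0^2 (1 + epsilon - omega0^2 epsilon^2 / 4)/(1 + epsilon)^2`.
#' Both are in units of the equilibrium (barred) motor time scale
#' `tau_bar`; multiply by `zeta_bar/zeta = eta + (1 - eta) exp(fstar)` to
#' convert to the simulation time unit tau (done by
#' [stability_summary()]).
#'
#' @param epsilon relative distance to the bifurcation, > -1.
#' @param omega0_sq squared intrinsic frequency, > 0.
#' @return A list with elements `alpha` and `omega`.
#' @export
linear_growth_and_frequency <- function(epsilon, omega0_sq) {
  if (epsilon <= -1)
    stop("linear_growth_and_frequency: 'epsilon' must exceed -1",
         call. = FALSE)
  if (omega0_sq <= 0)
    stop("linear_growth_and_frequency: below oscillation threshold ",
         "(omega0^2 <= 0)", call. = FALSE)
  alpha <- epsilon * omega0_sq / (2 * (1 + epsilon))
  w2 <- omega0_sq * (1 + epsilon - omega0_sq * epsilon^2 / 4) /
    (1 + epsilon)^2
  if (w2 < 0)
    stop("linear_growth_and_frequency: overdamped regime ",
         "(squared frequency negative at this epsilon)", call. = FALSE)
  list(alpha = alpha, omega = sqrt(w2))
}

#' Linear-stability summary of a parameter set
#'
#' Evaluates the full closed-form chain n0 -> omega0^2 -> zeta_bar ->
#' mu_a_crit -> epsilon -> (alpha, omega) for a nondimensional parameter
#' set.
#'
#' @param params an [rd_params()] object.
#' @return An object of class `rd_stability` with fields `n0`,
#'   `omega0_sq`, `zeta_bar`, `mu_a_crit`, `nu_a_crit`, `epsilon`, and
#'   `alpha`, `omega` converted to the simulation time unit tau (`NA` in
#'   the overdamped regime).
#' @export
stability_summary <- function(params) {
  stopifnot(inherits(params, "rd_params"))
  mq <- motor_quantities(params$eta, params$zeta, params$fstar)
  crit <- critical_activity(params$mu, params$eta, params$zeta, params$fstar)
  eps <- (params$mu_a - crit) / crit
  lin <- tryCatch(linear_growth_and_frequency(eps, mq$omega0_sq),
                  error = function(e) list(alpha = NA_real_,
                                           omega = NA_real_))
  tau_ratio <- mq$zeta_bar / params$zeta   # tau / tau_bar
  lin$alpha <- lin$alpha * tau_ratio
  lin$omega <- lin$omega * tau_ratio
  structure(list(params = params, n0 = mq$n0, omega0_sq = mq$omega0_sq,
                 zeta_bar = mq$zeta_bar, mu_a_crit = crit,
                 nu_a_crit = critical_activity_element(params$eta,
                                                       params$zeta,
                                                       params$fstar),
                 epsilon = eps, alpha = lin$alpha, omega = lin$omega),
            class = "rd_stability")
}

#' @export
print.rd_stability <- function(x, ...) {
  p <- x$params
  cat("Linear stability of the flagellar RD model\n")
  cat(sprintf("  parameters: mu_a = %g, mu = %g, eta = %g, zeta = %g, f* = %g\n",
              p$mu_a, p$mu, p$eta, p$zeta, p$fstar))
  cat(sprintf("  n0 = %.5g   omega0^2 = %.5g   zeta_bar = %.5g\n",
              x$n0, x$omega0_sq, x$zeta_bar))
  cat(sprintf("  mu_a_crit = %.5g   (single element nu_a_crit = %.5g)\n",
              x$mu_a_crit, x$nu_a_crit))
  cat(sprintf("  epsilon = %.4g  (%s)\n", x$epsilon,
              if (x$epsilon > 0) "supercritical: spontaneous oscillations"
              else "subcritical: quiescent"))
  if (is.finite(x$alpha))
    cat(sprintf("  linear growth rate alpha = %.5g, frequency omega = %.5g (1/tau)\n",
                x$alpha, x$omega))
  else
    cat("  linear frequency undefined at this epsilon (overdamped branch)\n")
  invisible(x)
}

#' Standing-wave solution of the linearised model
#'
#' Near onset the shear angle obeys
#' `gamma(s, t) = Re[A exp((alpha + i omega) t) sin(pi s / 2)]` on the
#' nondimensional arclength `s` in `[0, 1]`: growing (or decaying)
#' in-phase oscillations with a quarter-sine spatial envelope, satisfying
#' `gamma(0) = 0` and `gamma_s(1) = 0`.
#'
#' @param s_grid arclength samples in `[0, 1]`.
#' @param t time (tau units); scalar or vector.
#' @param A complex or real amplitude.
#' @param alpha linear growth rate.
#' @param omega linear angular frequency.
#' @return A matrix of `length(t)` rows and `length(s_grid)` columns
#'   (dropped to a vector for scalar `t`).
#' @export
standing_wave_solution <- function(s_grid, t, A = 1, alpha = 0, omega = 1) {
  if (any(s_grid < 0) || any(s_grid > 1))
    stop("standing_wave_solution: 's_grid' must lie in [0, 1]", call. = FALSE)
  out <- outer(t, s_grid, function(tt, ss)
    Re(A * exp((alpha + 1i * omega) * tt) * sin(pi * ss / 2)))
  if (length(t) == 1L) drop(out) else out
}

#' Read/write nondimensional parameter sets as JSON
#'
#' Serialized with keys exactly `mu_a`, `mu`, `eta`, `zeta`, `fstar` plus
#' a `provenance` string.
#'
#' @param params an [rd_params()] object.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "rd_params"))
  jsonlite::write_json(params[c("mu_a", "mu", "eta", "zeta", "fstar",
                                "provenance")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("mu_a", "mu", "eta", "zeta", "fstar")
  if (!all(need %in% names(x)))
    stop("read_params: JSON must contain keys ",
         paste(need, collapse = ", "), call. = FALSE)
  rd_params(x$mu_a, x$mu, x$eta, x$zeta, x$fstar,
            provenance = if (!is.null(x$provenance)) x$provenance else "file")
}
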