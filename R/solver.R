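#' Space-time kymograph container
#'
#' The universal exchange object: a matrix of field samples with rows
#' indexed by time and columns by arclength, plus grid metadata.
#'
#' @param values numeric matrix, `length(times)` rows by
#'   `length(s_grid)` columns.
#' @param times strictly increasing, uniformly spaced sample instants.
#' @param s_grid arclength samples (units of L).
#' @param field_name one of `"shear_angle"`, `"tangent_angle"`,
#'   `"curvature"`, `"n_plus"`, `"n_minus"`.
#' @param metadata free-form list recording parameter provenance.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(values, times, s_grid,
                      field_name = c("shear_angle", "tangent_angle",
                                     "curvature", "n_plus", "n_minus"),
                      metadata = list()) {
  field_name <- match.arg(field_name)
  values <- as.matrix(values)
  if (nrow(values) != length(times) || ncol(values) != length(s_grid))
    stop("kymograph: grid sizes inconsistent with 'values'", call. = FALSE)
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) ||
                     max(abs(dt - dt[1])) > 1e-8 * max(abs(dt))))
    stop("kymograph: 'times' must be strictly increasing and uniform",
         call. = FALSE)
  structure(list(values = values, times = as.numeric(times),
                 s_grid = as.numeric(s_grid), field_name = field_name,
                 metadata = metadata),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph of %s: %d time samples x %d arclength points\n",
              x$field_name, nrow(x$values), length(x$s_grid)))
  cat(sprintf("  t in [%g, %g] (dt = %g), s in [%g, %g]\n",
              x$times[1], x$times[length(x$times)],
              x$times[2] - x$times[1], x$s_grid[1],
              x$s_grid[length(x$s_grid)]))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x$times, x$s_grid, x$values, xlab = "t", ylab = "s",
                  main = x$field_name,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

#' Default small-perturbation initial condition
#'
#' A Gaussian bump of amplitude 0.001 centred at the flagellum midpoint,
#' `gamma(s) = 0.001 exp(-((s - 0.5)/0.1)^2)`, with motors at their
#' equilibrium fraction `n0`.
#'
#' @param m number of equally spaced arclength points (>= 3).
#' @param n0 equilibrium attached fraction.
#' @param amplitude bump amplitude (0.001 by default).
#' @return A list of class `flagellum_state` with `gamma`, `n_plus`,
#'   `n_minus`, `s_grid`.
#' @export
default_initial_condition <- function(m, n0, amplitude = 0.001) {
  if (m < 3) stop("default_initial_condition: m must be >= 3", call. = FALSE)
  s <- seq(0, 1, length.out = m)
  structure(list(gamma = amplitude * exp(-((s - 0.5) / 0.1)^2),
                 n_plus = rep(n0, m), n_minus = rep(n0, m), s_grid = s),
            class = "flagellum_state")
}

#' Flagellum state on the arclength grid
#'
#' @param gamma,n_plus,n_minus numeric vectors of equal length `m >= 3`.
#' @param s_grid optional arclength grid; defaults to `m` equally spaced
#'   points on `[0, 1]`.
#' @export
flagellum_state <- function(gamma, n_plus, n_minus, s_grid = NULL) {
  m <- length(gamma)
  if (m < 3 || length(n_plus) != m || length(n_minus) != m)
    stop("flagellum_state: fields must share length m >= 3", call. = FALSE)
  if (any(n_plus < 0 | n_plus > 1) || any(n_minus < 0 | n_minus > 1))
    stop("flagellum_state: bound fractions must lie in [0, 1]",
         call. = FALSE)
  if (is.null(s_grid)) s_grid <- seq(0, 1, length.out = m)
  structure(list(gamma = gamma, n_plus = n_plus, n_minus = n_minus,
                 s_grid = s_grid),
            class = "flagellum_state")
}

grid_w2 <- function(m, grid_factor) {
  switch(grid_factor, spacing = (m - 1)^2, m2 = m^2,
         stop("grid_factor must be 'spacing' or 'm2'", call. = FALSE))
}

#' Right-hand side of the discretized reaction-diffusion system
#'
#' Method-of-lines derivative of the shear-angle/motor system: basal
#' penalization `gamma_t,0 = -gamma_0`, centred second differences in
#' the interior, a one-sided (ghost-node) stencil at the free tip, and
#' the tug-of-war motor rate equations with the shear rate substituted.
#' This is the reference R implementation; [simulate_rd()] uses an
#' equivalent compiled version by default.
#'
#' @param state a [flagellum_state()].
#' @param params an [rd_params()] object.
#' @param grid_factor `"spacing"` uses `(m-1)^2` as the squared inverse
#'   grid spacing (consistent second-order Laplacian); `"m2"` uses the
#'   `m^2` prefactor variant for exact-replication studies.
#' @param feedback logical; `FALSE` freezes the detachment exponent at
#'   its equilibrium value (no sliding feedback), giving the pure
#'   shear-diffusion limit.
#' @return A list with derivative vectors `gamma`, `n_plus`, `n_minus`.
#' @export
rd_rhs <- function(state, params, grid_factor = c("spacing", "m2"),
                   feedback = TRUE) {
  stopifnot(inherits(state, "flagellum_state"), inherits(params, "rd_params"))
  grid_factor <- match.arg(grid_factor)
  g <- state$gamma; np <- state$n_plus; nm <- state$n_minus
  m <- length(g)
  nbar <- np + nm
  if (any(nbar <= 0))
    stop("rd_rhs: singular mass (n_plus + n_minus = 0 at some node)",
         call. = FALSE)
  ntil <- nm - np
  w2 <- grid_w2(m, grid_factor)
  lap <- numeric(m)
  i <- 2:(m - 1)
  lap[i] <- w2 * (g[i + 1] - 2 * g[i] + g[i - 1])
  lap[m] <- 2 * w2 * (g[m - 1] - g[m])
  gt <- (lap - params$mu * g + params$mu_a * ntil) /
    (params$mu_a * params$zeta * nbar)
  gt[1] <- -g[1]
  fs <- params$fstar; zeta <- params$zeta; eta <- params$eta
  if (feedback) {
    ep <- exp(fs * (1 + zeta * gt)); em <- exp(fs * (1 - zeta * gt))
  } else {
    ep <- em <- rep(exp(fs), m)
  }
  list(gamma = gt,
       n_plus = eta * (1 - np) - (1 - eta) * np * ep,
       n_minus = eta * (1 - nm) - (1 - eta) * nm * em)
}

#' Simulate the flagellar reaction-diffusion system
#'
#' Integrates the discretized shear-angle/motor PDE with a stiff BDF
#' method-of-lines scheme (banded Jacobian, compiled right-hand side),
#' or optionally in residual form with a DAE solver, and returns
#' kymographs of the shear angle and both bound-motor fractions.
#'
#' @param params an [rd_params()] object.
#' @param initial a [flagellum_state()]; defaults to
#'   [default_initial_condition()] on `m` points.
#' @param t_end integration horizon (tau units); fitting-grade runs use
#'   `t_end >= 100`.
#' @param dt_out output sampling interval.
#' @param m number of arclength points when `initial` is `NULL`.
#' @param grid_factor,feedback see [rd_rhs()].
#' @param method `"bdf"` (default, method of lines) or `"daspk"`
#'   (residual form, more robust at very high activity).
#' @param rtol,atol solver tolerances.
#' @param use_compiled logical; set `FALSE` to integrate with the pure-R
#'   right-hand side (slower, for cross-checks).
#' @return An object of class `rd_sim`: list with `gamma`, `n_plus`,
#'   `n_minus` matrices (time by arclength), `times`, `s_grid`,
#'   `params` and solver metadata.
#' @export
simulate_rd <- function(params, initial = NULL, t_end = 100, dt_out = 0.01,
                        m = 101, grid_factor = c("spacing", "m2"),
                        feedback = TRUE, method = c("bdf", "daspk"),
                        rtol = 1e-8, atol = 1e-10, use_compiled = TRUE) {
  stopifnot(inherits(params, "rd_params"))
  grid_factor <- match.arg(grid_factor)
  method <- match.arg(method)
  n0 <- equilibrium_attachment(params$eta, params$fstar)
  if (is.null(initial)) initial <- default_initial_condition(m, n0)
  stopifnot(inherits(initial, "flagellum_state"))
  m <- length(initial$gamma)
  w2 <- grid_w2(m, grid_factor)
  y0 <- as.vector(rbind(initial$gamma, initial$n_plus, initial$n_minus))
  times <- seq(0, t_end, by = dt_out)
  p <- c(params$mu_a, params$mu, params$eta, params$zeta, params$fstar,
         w2, m, as.numeric(feedback))

  if (method == "bdf") {
    if (use_compiled) {
      sol <- deSolve::lsode(y = y0, times = times, func = "rd_derivs",
                            parms = p, dllname = "flagellaRD",
                            initfunc = "rd_init", jactype = "bandnum",
                            bandup = 3, banddown = 5, mf = 25,
                            rtol = rtol, atol = atol, maxsteps = 50000)
    } else {
      fn <- function(t, y, parms) {
        st <- list(gamma = y[seq(1, 3 * m, 3)], n_plus = y[seq(2, 3 * m, 3)],
                   n_minus = y[seq(3, 3 * m, 3)],
                   s_grid = initial$s_grid)
        class(st) <- "flagellum_state"
        d <- rd_rhs(st, params, grid_factor, feedback)
        list(as.vector(rbind(d$gamma, d$n_plus, d$n_minus)))
      }
      sol <- deSolve::lsode(y = y0, times = times, func = fn, parms = NULL,
                            jactype = "bandnum", bandup = 3, banddown = 5,
                            mf = 25, rtol = rtol, atol = atol,
                            maxsteps = 50000)
    }
  } else {
    res <- function(t, y, dy, parms) {
      gam <- y[seq(1, 3 * m, 3)]; np <- y[seq(2, 3 * m, 3)]
      nm <- y[seq(3, 3 * m, 3)]
      st <- structure(list(gamma = gam, n_plus = np, n_minus = nm,
                           s_grid = initial$s_grid),
                      class = "flagellum_state")
      d <- rd_rhs(st, params, grid_factor, feedback)
      list(dy - as.vector(rbind(d$gamma, d$n_plus, d$n_minus)))
    }
    dy0fn <- rd_rhs(initial, params, grid_factor, feedback)
    dy0 <- as.vector(rbind(dy0fn$gamma, dy0fn$n_plus, dy0fn$n_minus))
    sol <- deSolve::daspk(y = y0, dy = dy0, times = times, res = res,
                          parms = NULL, rtol = rtol, atol = atol)
  }
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop(sprintf(paste0("simulate_rd: integrator failure (istate = %d) for ",
                        "mu_a = %g, mu = %g, eta = %g, zeta = %g, f* = %g"),
                 diagn[1], params$mu_a, params$mu, params$eta, params$zeta,
                 params$fstar), call. = FALSE)
  if (nrow(sol) < length(times))
    stop("simulate_rd: integration stopped early at t = ",
         sol[nrow(sol), 1], call. = FALSE)
  y <- unclass(sol)[, -1, drop = FALSE]
  structure(list(gamma = y[, seq(1, 3 * m, 3), drop = FALSE],
                 n_plus = y[, seq(2, 3 * m, 3), drop = FALSE],
                 n_minus = y[, seq(3, 3 * m, 3), drop = FALSE],
                 times = times, s_grid = initial$s_grid, params = params,
                 m = m, grid_factor = grid_factor, feedback = feedback,
                 method = method),
            class = "rd_sim")
}

#' @export
print.rd_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("RD simulation: mu_a = %g, mu = %g, eta = %g, zeta = %g, f* = %g\n",
              p$mu_a, p$mu, p$eta, p$zeta, p$fstar))
  cat(sprintf("  m = %d points, t in [0, %g] tau (%d samples), method %s\n",
              x$m, x$times[length(x$times)], length(x$times), x$method))
  amp <- max(abs(x$gamma[nrow(x$gamma), ]))
  cat(sprintf("  final max |gamma| = %.4g rad\n", amp))
  invisible(x)
}

#' @export
plot.rd_sim <- function(x, ...) {
  plot(as_kymograph(x, "shear_angle"), ...)
  invisible(x)
}

#' Extract a field of an RD simulation as a kymograph
#'
#' @param sim an `rd_sim` object.
#' @param field one of `"shear_angle"`, `"n_plus"`, `"n_minus"`.
#' @param window optional time interval `c(t0, t1)` to extract.
#' @export
as_kymograph <- function(sim, field = c("shear_angle", "n_plus", "n_minus"),
                         window = NULL) {
  stopifnot(inherits(sim, "rd_sim"))
  field <- match.arg(field)
  vals <- switch(field, shear_angle = sim$gamma, n_plus = sim$n_plus,
                 n_minus = sim$n_minus)
  keep <- rep(TRUE, length(sim$times))
  if (!is.null(window))
    keep <- sim$times >= window[1] & sim$times <= window[2]
  kymograph(vals[keep, , drop = FALSE], sim$times[keep], sim$s_grid,
            field_name = if (field == "shear_angle") "shear_angle" else field,
            metadata = list(params = unclass(sim$params)[c("mu_a", "mu",
                                                           "eta", "zeta",
                                                           "fstar")],
                            grid_factor = sim$grid_factor,
                            feedback = sim$feedback))
}

#' Measure the linear growth rate (and frequency) of a simulation
#'
#' From a run started at the default small perturbation, tracks the
#' spatial L2 norm of the shear angle, locates its oscillation envelope
#' peaks inside the linear-growth window (amplitude between
#' `lower_mult` times the initial norm and `saturation_frac` times the
#' maximum), and fits the growth rate by least squares on the log
#' envelope. The frequency follows from the peak spacing (the norm of a
#' standing wave peaks twice per period).
#'
#' @param kym a shear-angle [kymograph()].
#' @param lower_mult,saturation_frac window bounds relative to the
#'   initial norm and the saturation norm.
#' @return A list with `alpha`, `omega`, `n_peaks` and the window used.
#' @export
measure_growth_rate <- function(kym, lower_mult = 10,
                                saturation_frac = 0.1) {
  stopifnot(inherits(kym, "kymograph"))
  nrm <- sqrt(rowMeans(kym$values^2))
  pk <- which(diff(sign(diff(nrm))) < 0) + 1L
  lower <- lower_mult * nrm[1]
  upper <- saturation_frac * max(nrm)
  sel <- pk[nrm[pk] > lower & nrm[pk] < upper]
  if (length(sel) < 4)
    stop("measure_growth_rate: window not found (no identifiable ",
         "linear-growth phase)", call. = FALSE)
  tt <- kym$times[sel]
  fit <- stats::lm.fit(cbind(1, tt), log(nrm[sel]))
  list(alpha = unname(fit$coefficients[2]),
       omega = pi / mean(diff(tt)),
       n_peaks = length(sel),
       window = range(tt))
}

#' Closed-form solution of the no-feedback diffusion limit
#'
#' With the sliding feedback switched off the motors relax to `n0` and
#' the shear angle obeys `gamma_t = D gamma_ss - E gamma` with
#' `D = 1/(2 n0 mu_a zeta)` and `E = mu D` (nondimensional). With
#' `gamma(0) = 0` and `gamma_s(1) = 0` the solution is the series
#' `gamma(s,t) = sum_k c_k exp(-(E + D (k+1/2)^2 pi^2) t)
#' sin((k+1/2) pi s)` where
#' `c_k = 2 integral_0^1 gamma(s,0) sin((k+1/2) pi s) ds`.
#'
#' @param gamma0 function of `s` giving the initial profile (must vanish
#'   at `s = 0`), or a numeric vector on `s_grid`.
#' @param params an [rd_params()] object.
#' @param s_grid arclength evaluation points in `[0, 1]`.
#' @param t time or vector of times.
#' @param k_max series truncation order.
#' @return A list of class `diffusion_solution`: `values` (time by
#'   arclength matrix), `coefficients` `c_k`, per-mode `decay_rates`,
#'   `D`, `E` and a bound `tail_bound` on the truncation error at t = 0.
#' @export
diffusion_closed_form <- function(gamma0, params, s_grid, t, k_max = 400) {
  stopifnot(inherits(params, "rd_params"))
  n0 <- equilibrium_attachment(params$eta, params$fstar)
  D <- 1 / (2 * n0 * params$mu_a * params$zeta)
  E <- params$mu * D
  f <- if (is.function(gamma0)) gamma0 else {
    stats::splinefun(s_grid, gamma0, method = "natural")
  }
  # coefficients by fine trapezoidal quadrature (basis: int sin^2 = 1/2)
  sq <- seq(0, 1, length.out = 2001)
  fv <- f(sq)
  ks <- 0:k_max
  ck <- vapply(ks, function(k) {
    ig <- fv * sin((k + 0.5) * pi * sq)
    2 * sum((ig[-1] + ig[-length(ig)]) / 2) * (sq[2] - sq[1])
  }, numeric(1))
  rates <- E + D * (ks + 0.5)^2 * pi^2
  basis <- sin(outer(s_grid, (ks + 0.5) * pi))   # m x K
  vals <- t(vapply(t, function(tt) {
    as.vector(basis %*% (ck * exp(-rates * tt)))
  }, numeric(length(s_grid))))
  if (length(t) == 1L) vals <- matrix(vals, nrow = 1)
  structure(list(values = vals, times = t, s_grid = s_grid,
                 coefficients = ck, decay_rates = rates, D = D, E = E,
                 tail_bound = abs(ck[length(ck)])),
            class = "diffusion_solution")
}

#' Locate the flagellar Hopf bifurcation numerically
#'
#' Bisects on the activity `mu_a`, classifying growth/decay of the
#' default small perturbation in full simulations; an independent check
#' of the closed-form [critical_activity()].
#'
#' @param mu,eta,zeta,fstar model parameters.
#' @param rel_tol relative bracket width at which to stop.
#' @param t_end classification horizon per candidate.
#' @param m grid resolution used for the classification runs.
#' @return list with `lower`, `upper`, `mu_a_crit` (midpoint).
#' @export
find_rd_hopf <- function(mu, eta, zeta, fstar = 2, rel_tol = 0.005,
                         t_end = 250, m = 101) {
  guess <- critical_activity(mu, eta, zeta, fstar)
  lower <- guess * 0.7; upper <- guess * 1.4
  grows <- function(mu_a) {
    sim <- simulate_rd(rd_params(mu_a, mu, eta, zeta, fstar),
                       t_end = t_end, dt_out = 0.1, m = m)
    nrm <- sqrt(rowMeans(sim$gamma^2))
    n <- length(nrm)
    late <- max(nrm[seq(floor(0.75 * n), n)])
    early <- max(nrm[seq(floor(0.25 * n), floor(0.5 * n))])
    late > 1e-9 && (late > 3 * early || late > 10 * nrm[1])
  }
  if (grows(lower) || !grows(upper))
    stop("find_rd_hopf: initial bracket does not straddle the onset",
         call. = FALSE)
  while ((upper - lower) / lower > rel_tol) {
    mid <- (lower + upper) / 2
    if (grows(mid)) upper <- mid else lower <- mid
  }
  list(lower = lower, upper = upper, mu_a_crit = (lower + upper) / 2)
}

#' Write/read a kymograph as delimited text plus JSON sidecar
#'
#' The matrix is stored with rows as time samples and columns as
#' arclength samples (comma-separated); `<path>.json` records the field
#' name, grid geometry and parameter provenance. The reader accepts
#' comma- or tab-delimited files.
#'
#' @param kym a [kymograph()].
#' @param path CSV path.
#' @export
write_kymograph <- function(kym, path) {
  stopifnot(inherits(kym, "kymograph"))
  utils::write.table(kym$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(field_name = kym$field_name,
                            m = length(kym$s_grid),
                            dt = kym$times[2] - kym$times[1],
                            t0 = kym$times[1],
                            s_grid = kym$s_grid,
                            metadata = kym$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  vals <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(vals) <- NULL
  times <- side$t0 + side$dt * (seq_len(nrow(vals)) - 1)
  kymograph(vals, times, side$s_grid, field_name = side$field_name,
            metadata = as.list(side$metadata))
}
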