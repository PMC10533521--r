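#' Generate an experiment-like synthetic beat record
#'
#' Runs the RD model to its limit cycle, superposes an optional static
#' curvature component (`gamma -> gamma + C s`), converts the
#' saturated window to the requested recording dialect — tangent angle
#' on 19 arclength points every 1 ms, or curvature (finite differences
#' of the angle on the fine grid) on 30 points every 4 ms — downsamples,
#' and finally adds i.i.d. Gaussian measurement noise with the given
#' seed. The physical time scale is chosen so the simulated limit cycle
#' beats at `beat_hz`; all ground truth needed to regenerate the record
#' is returned in the metadata (and can be written to a separate JSON
#' that the fitter never reads).
#'
#' @param params supercritical [rd_params()] (an error is raised for
#'   subcritical parameters unless `allow_decay`).
#' @param dialect recording dialect, see [beat_record()].
#' @param noise_sigma measurement noise standard deviation (rad for
#'   angles, rad per unit arclength for curvature). Default 0.02 rad,
#'   small against O(1) rad beat amplitudes.
#' @param static_C static curvature component (rad per unit arclength).
#' @param n_periods record length in beat periods (>= 20 for
#'   spectral-grade records).
#' @param seed random seed for the noise.
#' @param beat_hz physical beat frequency used to map simulation time to
#'   seconds; defaults to 50 Hz (chlamy dialect) or 20 Hz (bull).
#' @param m fine-grid resolution of the underlying simulation.
#' @param transient_t transient discarded before the record window
#'   (tau units).
#' @param allow_decay permit subcritical parameter sets (decay
#'   fixtures).
#' @return A [beat_record()] whose `metadata$ground_truth` holds the
#'   generating parameters, `epsilon`, the measured period (tau), the
#'   tau-to-seconds factor, `static_C`, `noise_sigma` and `seed`.
#' @export
synthesize_beat_record <- function(params,
                                   dialect = c("chlamy_theta_19pt_1ms",
                                               "bull_curvature_30pt_4ms"),
                                   noise_sigma = 0.02, static_C = 0,
                                   n_periods = 24, seed = 1,
                                   beat_hz = NULL, m = 101,
                                   transient_t = 100,
                                   allow_decay = FALSE) {
  stopifnot(inherits(params, "rd_params"))
  dialect <- match.arg(dialect)
  geom <- dialect_geometry(dialect)
  if (noise_sigma < 0)
    stop("synthesize_beat_record: 'noise_sigma' must be >= 0",
         call. = FALSE)
  eps <- bifurcation_distance(params$mu_a, params$mu, params$eta,
                              params$zeta, params$fstar)
  if (eps <= 0 && !allow_decay)
    stop("synthesize_beat_record: subcritical parameters (epsilon = ",
         signif(eps, 3), "); set allow_decay = TRUE for decay fixtures",
         call. = FALSE)
  if (is.null(beat_hz))
    beat_hz <- if (dialect == "chlamy_theta_19pt_1ms") 50 else 20

  # pilot run through the transient; measure the limit-cycle period
  pilot <- simulate_rd(params, t_end = transient_t, dt_out = 0.01, m = m)
  mid <- ceiling(m / 2)
  keep <- pilot$times >= transient_t / 2
  g <- pilot$gamma[keep, mid]
  tt <- pilot$times[keep]
  g <- g - mean(g)
  up <- which(g[-length(g)] < 0 & g[-1] >= 0)
  if (eps > 0 && length(up) < 3)
    stop("synthesize_beat_record: no sustained oscillation detected ",
         "after the transient", call. = FALSE)
  period_tau <- if (length(up) >= 3) mean(diff(tt[up])) else NA_real_

  if (eps > 0) {
    # continue from the transient's end state for n_periods beats
    end_state <- flagellum_state(pilot$gamma[nrow(pilot$gamma), ],
                                 pmin(pmax(pilot$n_plus[nrow(pilot$n_plus), ], 0), 1),
                                 pmin(pmax(pilot$n_minus[nrow(pilot$n_minus), ], 0), 1),
                                 pilot$s_grid)
    rec_t <- n_periods * period_tau
    sim <- simulate_rd(params, initial = end_state, t_end = rec_t,
                       dt_out = 0.01, m = m)
    gam <- sim$gamma; times_tau <- sim$times
    tau_s <- 1 / (beat_hz * period_tau)
  } else {
    gam <- pilot$gamma; times_tau <- pilot$times
    tau_s <- 1 / (beat_hz * 2 * pi)       # nominal scale for decay fixtures
  }

  theta <- sweep(gam, 2, static_C * pilot$s_grid, "+")

  # dialect field on the fine grid
  if (geom$field == "curvature") {
    h <- pilot$s_grid[2] - pilot$s_grid[1]
    field_fine <- t(apply(theta, 1, function(row) {
      d <- numeric(length(row))
      i <- 2:(length(row) - 1)
      d[i] <- (row[i + 1] - row[i - 1]) / (2 * h)
      d[1] <- (row[2] - row[1]) / h
      d[length(row)] <- (row[length(row)] - row[length(row) - 1]) / h
      d
    }))
  } else {
    field_fine <- theta
  }

  # resample in time at the dialect rate, then in arclength
  dt_tau <- geom$dt_s / tau_s
  t_samp <- seq(0, times_tau[length(times_tau)], by = dt_tau)
  time_interp <- apply(field_fine, 2, function(col)
    stats::approx(times_tau, col, xout = t_samp)$y)
  s_out <- seq(0, 1, length.out = geom$n_s)
  vals <- t(apply(time_interp, 1, function(row)
    stats::splinefun(pilot$s_grid, row, method = "fmm")(s_out)))

  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + stats::rnorm(length(vals), sd = noise_sigma)
  }

  beat_record(vals, dialect = dialect, times_s = t_samp * tau_s,
              s_grid = s_out,
              metadata = list(ground_truth = list(
                params = unclass(params)[c("mu_a", "mu", "eta", "zeta",
                                           "fstar")],
                epsilon = eps, period_tau = period_tau, tau_s = tau_s,
                beat_hz = beat_hz, static_C = static_C,
                noise_sigma = noise_sigma, seed = seed, m = m,
                n_periods = n_periods, transient_t = transient_t)))
}

#' Write the ground truth of a synthetic record
#'
#' Stores the generator's parameters in a separate JSON file (never read
#' by the fitting code) so the record can be regenerated exactly.
#'
#' @param rec a synthetic [beat_record()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(rec, path) {
  stopifnot(inherits(rec, "beat_record"))
  gt <- rec$metadata$ground_truth
  if (is.null(gt))
    stop("write_ground_truth: record carries no ground truth",
         call. = FALSE)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
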