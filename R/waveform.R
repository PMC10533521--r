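#' Fundamental Fourier mode of a beating kymograph
#'
#' Removes the time mean per arclength point, discrete-Fourier
#' transforms each arclength sample over an integer number of estimated
#' periods, and extracts the complex mode at the fundamental frequency,
#' defined as the peak of the spatially averaged power spectrum
#' (zero-frequency bin excluded). The one-sided convention is
#' `gamma(s,t) ~ gamma_bar(s) + mode(s) exp(i omega t) + c.c.`, so a
#' signal `2 A cos(omega t + phi)` has mode magnitude `A`.
#'
#' No spectral window or peak interpolation is applied; the record is
#' truncated to an integer number of estimated periods to limit leakage
#' and the raw periodogram bin is reported.
#'
#' @param kym a [kymograph()] with uniform time sampling.
#' @param min_periods minimum record length in estimated periods; a
#'   shorter record raises an "insufficient record" error.
#' @return An object of class `fourier_mode`: `mode` (complex vector
#'   over `s_grid`), `omega_fund` (rad per time unit), `spectrum`
#'   (data frame `freq`, `power`), `gamma_bar`, `s_grid`,
#'   `record_periods` and `bin_width` (rad per time unit).
#' @export
fundamental_mode <- function(kym, min_periods = 20) {
  stopifnot(inherits(kym, "kymograph"))
  v <- kym$values
  dt <- kym$times[2] - kym$times[1]
  gamma_bar <- colMeans(v)
  x <- sweep(v, 2, gamma_bar)
  if (max(abs(x)) < 1e-10 * (1 + max(abs(gamma_bar))))
    stop("fundamental_mode: field is constant in time ",
         "(no non-DC peak above floor)", call. = FALSE)
  peak_bin <- function(xm) {
    n <- nrow(xm)
    sp <- stats::mvfft(xm)
    pw <- rowMeans(Mod(sp)^2) / n^2
    half <- 2:(floor(n / 2) + 1)       # positive-frequency, non-DC bins
    k <- half[which.max(pw[half])]
    list(k = k, n = n, power = pw, ft = sp)
  }
  p1 <- peak_bin(x)
  # refine the period estimate off the bin grid (parabolic interpolation
  # of log power) before truncating; the reported mode still comes from
  # the raw bin of the truncated record
  delta <- 0
  if (p1$k > 2 && p1$k < floor(p1$n / 2) + 1) {
    side <- p1$power[c(p1$k - 1, p1$k + 1)]
    # only refine when genuine leakage is present; an exactly on-bin
    # tone leaves machine noise in the side bins
    if (min(side) > 1e-8 * p1$power[p1$k]) {
      lp <- log(c(side[1], p1$power[p1$k], side[2]))
      den <- lp[1] - 2 * lp[2] + lp[3]
      if (is.finite(den) && den < 0)
        delta <- max(-0.5, min(0.5, 0.5 * (lp[1] - lp[3]) / den))
    }
  }
  f1 <- (p1$k - 1 + delta) / (p1$n * dt)   # cycles per time unit
  total_t <- p1$n * dt
  periods <- total_t * f1
  if (periods < min_periods)
    stop(sprintf(paste0("fundamental_mode: insufficient record (%.1f ",
                        "estimated periods < %g)"), periods, min_periods),
         call. = FALSE)
  # truncate to an integer number of estimated periods, re-transform
  n_keep <- floor(floor(periods) / f1 / dt)
  p2 <- peak_bin(x[seq_len(n_keep), , drop = FALSE])
  n <- p2$n
  freq <- (seq_len(floor(n / 2) + 1) - 1) / (n * dt)
  omega <- 2 * pi * (p2$k - 1) / (n * dt)
  mode <- p2$ft[p2$k, ] / n            # one-sided complex coefficients
  structure(list(mode = as.complex(mode), omega_fund = omega,
                 spectrum = data.frame(freq = freq,
                                       power = p2$power[seq_along(freq)]),
                 gamma_bar = gamma_bar, s_grid = kym$s_grid,
                 record_periods = n * dt * omega / (2 * pi),
                 bin_width = 2 * pi / (n * dt)),
            class = "fourier_mode")
}

#' @export
print.fourier_mode <- function(x, ...) {
  cat(sprintf("Fundamental Fourier mode: omega = %.5g rad/time (bin width %.3g)\n",
              x$omega_fund, x$bin_width))
  cat(sprintf("  %d arclength points, max |mode| = %.4g rad, %.1f periods\n",
              length(x$mode), max(Mod(x$mode)), x$record_periods))
  invisible(x)
}

#' @export
plot.fourier_mode <- function(x, ...) {
  graphics::plot(x$s_grid, Re(x$mode), type = "l", col = "black",
                 xlab = "s", ylab = "mode (rad)",
                 ylim = range(Re(x$mode), Im(x$mode)), ...)
  graphics::lines(x$s_grid, Im(x$mode), col = "red")
  graphics::legend("topleft", c("Re", "Im"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Optimal phase alignment of two complex modes
#'
#' Returns `phi = Arg(sum_i exp_mode_i * Conj(sim_mode_i))`, the phase
#' that minimizes `sum_i |exp_mode_i - e^{i phi} sim_mode_i|^2`.
#' (Expanding the sum, the phase-dependent term is
#' `-2 Re[e^{-i phi} sum e Conj(s)]`, maximized at `phi = Arg(sum)`.)
#'
#' @param exp_mode,sim_mode complex vectors on the same arclength grid
#'   (or `fourier_mode` objects).
#' @return Phase `phi` in `(-pi, pi]`.
#' @export
optimal_phase <- function(exp_mode, sim_mode) {
  e <- if (inherits(exp_mode, "fourier_mode")) exp_mode$mode else exp_mode
  s <- if (inherits(sim_mode, "fourier_mode")) sim_mode$mode else sim_mode
  if (length(e) != length(s))
    stop("optimal_phase: modes must share the same arclength grid",
         call. = FALSE)
  z <- sum(e * Conj(s))
  if (Mod(z) == 0)
    stop("optimal_phase: undefined phase (a mode is identically zero ",
         "or the modes are orthogonal)", call. = FALSE)
  Arg(z)
}

#' Quality-of-fit score between two fundamental modes
#'
#' After optimal phase alignment, computes
#' `R^2 = 1 - sum_i |e_i - e^{i phi} s_i|^2 / sum_i |e_i|^2`. Equal to
#' one iff the modes coincide after alignment; can be negative for a fit
#' worse than the zero mode.
#'
#' @inheritParams optimal_phase
#' @param align logical; apply phase alignment first (default).
#' @return A list with `R2` and the aligned phase `phi`.
#' @export
r_squared <- function(exp_mode, sim_mode, align = TRUE) {
  e <- if (inherits(exp_mode, "fourier_mode")) exp_mode$mode else exp_mode
  s <- if (inherits(sim_mode, "fourier_mode")) sim_mode$mode else sim_mode
  if (length(e) != length(s))
    stop("r_squared: modes must share the same arclength grid",
         call. = FALSE)
  denom <- sum(Mod(e)^2)
  if (denom == 0)
    stop("r_squared: undefined for a zero experimental mode",
         call. = FALSE)
  phi <- 0
  if (align && sum(Mod(s)^2) > 0 && Mod(sum(e * Conj(s))) > 0)
    phi <- optimal_phase(e, s)
  list(R2 = 1 - sum(Mod(e - exp(1i * phi) * s)^2) / denom, phi = phi)
}

#' Dominant wavenumber of a kymograph
#'
#' Computes the spatial autocorrelation of the (time-mean removed)
#' field, `A(k) = mean_i theta(s_i) theta(s_{i+k})` over valid pairs,
#' averaged over the time samples, and locates its extrema where the
#' lag-derivative changes sign (domain endpoints included). The
#' wavelength is the lag of the maximal positive peak, or twice the lag
#' of the maximal-magnitude valley when no positive peak exists (a beat
#' with less than one full spatial oscillation); `q = 2 pi / lambda`
#' in units of 1/L. The record should span at least 20 beat periods so
#' the time average is representative.
#'
#' @param kym a [kymograph()].
#' @return A list with `q`, `lambda`, `lag` (in arclength units),
#'   `branch` (`"peak"` or `"valley"`) and the autocorrelation
#'   data frame `acf` (columns `lag`, `A`). When no extremum exists
#'   beyond lag zero, `q = 0` with a warning.
#' @export
wavenumber <- function(kym) {
  stopifnot(inherits(kym, "kymograph"))
  v <- sweep(kym$values, 2, colMeans(kym$values))
  m <- ncol(v)
  h <- kym$s_grid[2] - kym$s_grid[1]
  lags <- 1:(m - 1)
  A <- vapply(lags, function(k) {
    i <- seq_len(m - k)
    mean(v[, i] * v[, i + k])
  }, numeric(1))
  dA <- diff(A)
  peaks <- integer(0); valleys <- integer(0)
  if (length(dA)) {
    sign_change <- which(dA[-length(dA)] * dA[-1] < 0 |
                           (dA[-length(dA)] != 0 & dA[-1] == 0)) + 1L
    for (j in sign_change) {
      if (dA[j - 1] > 0) peaks <- c(peaks, j) else valleys <- c(valleys, j)
    }
    # endpoint extremum: rising end is a peak, falling end a valley
    K <- length(A)
    if (dA[length(dA)] > 0) peaks <- c(peaks, K)
    if (dA[length(dA)] < 0) valleys <- c(valleys, K)
  }
  pick_max <- function(idx, val) {
    # maximal value with relative tolerance; ties broken by smallest lag
    best <- max(val)
    idx[which(val >= best * (1 - 1e-8))][1]
  }
  acf_df <- data.frame(lag = lags * h, A = A)
  pos_peaks <- peaks[A[peaks] > 0]
  if (length(pos_peaks)) {
    j <- pick_max(pos_peaks, A[pos_peaks])
    lam <- lags[j] * h
    return(list(q = 2 * pi / lam, lambda = lam, lag = lags[j] * h,
                branch = "peak", acf = acf_df))
  }
  neg_valleys <- valleys[A[valleys] < 0]
  if (length(neg_valleys)) {
    j <- pick_max(neg_valleys, -A[neg_valleys])
    lam <- 2 * lags[j] * h
    return(list(q = 2 * pi / lam, lambda = lam, lag = lags[j] * h,
                branch = "valley", acf = acf_df))
  }
  warning("wavenumber: no extremum beyond lag 0; returning q = 0 (no wave)")
  list(q = 0, lambda = Inf, lag = NA_real_, branch = "none", acf = acf_df)
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

#' Reconstruct the planar centerline from a shear-angle profile
#'
#' Integrates the unit tangent `(cos gamma, sin gamma)` cumulatively
#' along arclength (trapezoidal rule) starting from the origin:
#' `r(s) = integral_0^s (cos gamma, sin gamma) ds'`.
#'
#' @param gamma_profile shear/tangent angle at uniform arclength samples
#'   (rad).
#' @param s_grid arclength samples (units of L); defaults to a uniform
#'   grid on `[0, 1]`.
#' @return Data frame of class `centerline` with columns `s`, `x`, `y`.
#' @export
reconstruct_centerline <- function(gamma_profile, s_grid = NULL) {
  if (is.null(s_grid))
    s_grid <- seq(0, 1, length.out = length(gamma_profile))
  out <- data.frame(s = s_grid,
                    x = cumtrapz(s_grid, cos(gamma_profile)),
                    y = cumtrapz(s_grid, sin(gamma_profile)))
  class(out) <- c("centerline", "data.frame")
  out
}

#' Rebuild a beating pattern from its mean and fundamental mode
#'
#' Samples `gamma_bar(s) + 2 Re[mode(s) exp(i omega t)]` at the given
#' times, inverting the one-sided convention of [fundamental_mode()].
#'
#' @param gamma_bar time-average profile (length of the mode grid), or
#'   0.
#' @param mode a `fourier_mode` object (or complex vector, in which case
#'   `omega` must be supplied).
#' @param times sample instants.
#' @param omega angular frequency; taken from `mode` when absent.
#' @param s_grid arclength grid; taken from `mode` when absent.
#' @return A shear-angle [kymograph()].
#' @export
reconstruct_beat <- function(gamma_bar, mode, times, omega = NULL,
                             s_grid = NULL) {
  if (inherits(mode, "fourier_mode")) {
    if (is.null(omega)) omega <- mode$omega_fund
    if (is.null(s_grid)) s_grid <- mode$s_grid
    mode <- mode$mode
  }
  if (is.null(omega) || is.null(s_grid))
    stop("reconstruct_beat: 'omega' and 's_grid' required with a bare ",
         "complex mode", call. = FALSE)
  if (length(gamma_bar) == 1L) gamma_bar <- rep(gamma_bar, length(mode))
  osc <- 2 * Re(outer(exp(1i * omega * times), mode))
  vals <- sweep(osc, 2, gamma_bar, "+")
  kymograph(vals, times, s_grid, field_name = "shear_angle",
            metadata = list(reconstructed = TRUE, omega = omega))
}

#' Superpose or remove a static curvature component
#'
#' Shifts the field by a linear-in-arclength static shear,
#' `gamma -> gamma - C s` (signed `C`). The time derivative and second
#' space derivative are unchanged, so the oscillatory dynamics are
#' superposed on the static part of the beat.
#'
#' @param kym a [kymograph()].
#' @param C static curvature (rad per unit arclength).
#' @return The shifted kymograph.
#' @export
apply_static_curvature <- function(kym, C) {
  stopifnot(inherits(kym, "kymograph"))
  kym$values <- sweep(kym$values, 2, C * kym$s_grid)
  kym
}

#' Write a fundamental mode as delimited text plus JSON sidecar
#'
#' Columns `s, Re, Im`; the sidecar records `omega_fund`,
#' `record_periods` and `bin_width`.
#'
#' @param mode a `fourier_mode`.
#' @param path CSV path.
#' @export
write_mode <- function(mode, path) {
  stopifnot(inherits(mode, "fourier_mode"))
  utils::write.csv(data.frame(s = mode$s_grid, Re = Re(mode$mode),
                              Im = Im(mode$mode)),
                   path, row.names = FALSE)
  jsonlite::write_json(list(omega_fund = mode$omega_fund,
                            record_periods = mode$record_periods,
                            bin_width = mode$bin_width),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
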