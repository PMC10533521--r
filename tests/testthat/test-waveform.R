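test_that("fundamental mode recovers a constructed amplitude/phase/frequency", {
  s <- seq(0, 1, length.out = 51)
  w <- 2 * pi * 0.5                      # 0.5 cycles per time unit
  tt <- seq(0, 48 - 0.05, by = 0.05)     # exactly 24 periods
  A <- 0.3 * sin(pi * s / 2)
  phi <- 0.8 * s
  gbar <- 0.2 * s
  vals <- t(vapply(tt, function(t1) gbar + 2 * A * cos(w * t1 + phi),
                   numeric(length(s))))
  md <- fundamental_mode(kymograph(vals, tt, s, "shear_angle"))
  expect_equal(md$omega_fund, w, tolerance = md$bin_width / w)
  expect_equal(Mod(md$mode), A, tolerance = 1e-6)
  expect_equal(md$gamma_bar, gbar, tolerance = 1e-10)
  # phases recovered up to the common convention
  expect_equal(Arg(md$mode[-1] * Conj(md$mode[2])),
               unwrap_phase(phi[-1] - phi[2]), tolerance = 1e-6)
})

test_that("fundamental mode rejects constant and too-short records", {
  s <- seq(0, 1, length.out = 11)
  tt <- seq(0, 10, by = 0.1)
  flat <- kymograph(outer(rep(1, length(tt)), s), tt, s, "shear_angle")
  expect_error(fundamental_mode(flat), "constant in time")
  short <- kymograph(outer(sin(2 * pi * 0.2 * tt), sin(pi * s / 2)),
                     tt, s, "shear_angle")
  expect_error(fundamental_mode(short, min_periods = 20),
               "insufficient record")
  expect_s3_class(fundamental_mode(short, min_periods = 1), "fourier_mode")
})

test_that("closed-form phase alignment matches a brute-force scan", {
  e <- c(1 + 0i, 0 + 1i, 0.5 - 0.2i)
  expect_equal(optimal_phase(e, e), 0)
  expect_equal(optimal_phase(e, e * exp(-1i * pi / 3)), pi / 3,
               tolerance = 1e-12)
  set.seed(11)
  for (k in 1:5) {
    a <- complex(real = stats::rnorm(8), imaginary = stats::rnorm(8))
    b <- complex(real = stats::rnorm(8), imaginary = stats::rnorm(8))
    expect_equal(optimal_phase(a, b), brute_force_phase(a, b),
                 tolerance = 2 * pi / 1e4 * 2)
  }
  expect_error(optimal_phase(e, e * 0), "undefined")
})

test_that("the R^2 score matches hand evaluation on toy modes", {
  e <- c(1 + 0i, 0 + 1i)
  s <- c(1 + 0i, 0 + 0i)
  # phase term: sum e conj(s) = 1, phi = 0;
  # R^2 = 1 - (|1-1|^2 + |i-0|^2) / (1 + 1) = 1 - 1/2 = 0.5
  sc <- r_squared(e, s)
  expect_equal(sc$R2, 0.5)
  expect_equal(sc$phi, 0)
  # perfect fit at any relative phase
  expect_equal(r_squared(e, e * exp(1i * 1.3))$R2, 1, tolerance = 1e-12)
  # zero simulated mode scores zero
  expect_equal(r_squared(e, e * 0)$R2, 0)
  # invariant under a common global phase of both modes
  g <- exp(1i * 0.7)
  expect_equal(r_squared(e * g, s * g)$R2, sc$R2, tolerance = 1e-12)
  expect_error(r_squared(e * 0, s), "zero experimental")
})

test_that("wavenumber identifies full, double and half oscillations", {
  s <- seq(0, 1, length.out = 101)
  tt <- seq(0, 20 * 2 * pi, length.out = 2001)[-1]
  mk <- function(f) kymograph(outer(tt, s, f), tt, s, "tangent_angle")
  w1 <- wavenumber(mk(function(t, x) sin(2 * pi * x - t)))
  expect_equal(w1$q, 2 * pi, tolerance = 2 * pi * 0.011)   # one lag bin
  w2 <- wavenumber(mk(function(t, x) sin(4 * pi * x - t)))
  expect_equal(w2$q, 4 * pi, tolerance = 4 * pi * 0.021)
  wh <- wavenumber(mk(function(t, x) sin(pi * x - t)))
  expect_identical(wh$branch, "valley")
  expect_equal(wh$q, pi, tolerance = pi * 0.011)
  # invariance under amplitude scaling and sign flip
  w1b <- wavenumber(mk(function(t, x) -3.7 * sin(2 * pi * x - t)))
  expect_equal(w1b$q, w1$q)
  # featureless field reports no wave
  expect_warning(w0 <- wavenumber(mk(function(t, x) sin(t) + 0 * x)),
                 "no wave")
  expect_equal(w0$q, 0)
})

test_that("centerline reconstruction matches straight lines and circular arcs", {
  m <- 101
  straight <- reconstruct_centerline(rep(0, m))
  expect_equal(straight$x[m], 1)
  expect_equal(max(abs(straight$y)), 0)
  vertical <- reconstruct_centerline(rep(pi / 2, m))
  expect_equal(vertical$y[m], 1)
  expect_equal(max(abs(vertical$x)), 0, tolerance = 1e-15)
  # constant curvature c: arc of radius 1/c
  c0 <- 1.5
  s <- seq(0, 1, length.out = m)
  arc <- reconstruct_centerline(c0 * s)
  expect_equal(arc$x, sin(c0 * s) / c0, tolerance = 1e-4)
  expect_equal(arc$y, (1 - cos(c0 * s)) / c0, tolerance = 1e-4)
  # arclength preservation for a gentle smooth profile
  gentle <- reconstruct_centerline(0.2 * sin(pi * s / 2))
  seg <- sqrt(diff(gentle$x)^2 + diff(gentle$y)^2)
  expect_lt(abs(sum(seg) - 1), 1e-6)
})

test_that("beat reconstruction inverts the mode extraction", {
  s <- seq(0, 1, length.out = 51)
  mode0 <- 0.25 * sin(pi * s / 2) * exp(1i * (0.5 + s))
  w <- 2 * pi * 0.4
  gbar <- 0.1 * s^2
  tt <- seq(0, 25 / 0.4 - 0.05, by = 0.05)   # exactly 25 periods
  kym <- reconstruct_beat(gbar, mode0, tt, omega = w, s_grid = s)
  md <- fundamental_mode(kym)
  expect_equal(md$omega_fund, w, tolerance = md$bin_width / w)
  expect_equal(md$mode, mode0, tolerance = 1e-3)
  expect_equal(md$gamma_bar, gbar, tolerance = 1e-8)
  # zero mode reproduces the static shape
  static <- reconstruct_beat(gbar, mode0 * 0, tt, omega = w, s_grid = s)
  expect_equal(static$values[3, ], gbar)
  # Parseval-style bound: fundamental power never exceeds signal power
  multi <- kym
  multi$values <- multi$values + 0.05 * cos(2 * w * outer(tt, rep(1, 51)))
  md2 <- fundamental_mode(multi)
  rec <- reconstruct_beat(md2$gamma_bar, md2, tt)
  pow <- function(v) mean(sweep(v, 2, colMeans(v))^2)
  expect_lte(pow(rec$values), pow(multi$values) * (1 + 1e-10))
})

test_that("static curvature superposition shifts and restores exactly", {
  s <- seq(0, 1, length.out = 31)
  tt <- 2 * pi * (0:39) / 40             # one exact period, zero mean
  kym <- kymograph(outer(sin(tt), sin(pi * s / 2)), tt, s, "shear_angle")
  expect_equal(apply_static_curvature(kym, 0)$values, kym$values)
  back <- apply_static_curvature(apply_static_curvature(kym, 0.7), -0.7)
  expect_equal(back$values, kym$values, tolerance = 1e-15)
  # removing the generator's C leaves no time-averaged linear trend
  shifted <- apply_static_curvature(kym, -0.7)   # adds +0.7 s
  removed <- apply_static_curvature(shifted, 0.7)
  trend <- stats::coef(stats::lm(colMeans(removed$values) ~ s))[[2]]
  expect_lt(abs(trend), 1e-10)
})

test_that("modes round-trip through delimited text", {
  s <- seq(0, 1, length.out = 21)
  md <- structure(list(mode = complex(real = s, imaginary = rev(s)),
                       omega_fund = 3.2, spectrum = NULL, gamma_bar = 0 * s,
                       s_grid = s, record_periods = 25, bin_width = 0.1),
                  class = "fourier_mode")
  path <- tempfile(fileext = ".csv")
  write_mode(md, path)
  back <- utils::read.csv(path)
  expect_equal(complex(real = back$Re, imaginary = back$Im), md$mode)
})
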