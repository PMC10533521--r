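test_that("the discrete right-hand side vanishes at the homogeneous equilibrium", {
  p <- rd_params(500, 100, 0.14, 0.3, 2)
  n0 <- equilibrium_attachment(0.14, 2)
  m <- 51
  st <- flagellum_state(rep(0, m), rep(n0, m), rep(n0, m))
  d <- rd_rhs(st, p)
  expect_equal(d$gamma, rep(0, m))
  expect_equal(d$n_plus, rep(0, m), tolerance = 1e-14)
  expect_equal(d$n_minus, rep(0, m), tolerance = 1e-14)
})

test_that("the right-hand side satisfies the printed residual equations exactly", {
  set.seed(7)
  p <- rd_params(800, 100, 0.14, 0.3, 2)
  m <- 41
  s <- seq(0, 1, length.out = m)
  st <- flagellum_state(0.3 * sin(2 * pi * s) + 0.1 * s,
                        0.05 + 0.02 * cos(pi * s),
                        0.05 + 0.02 * sin(3 * s))
  for (gf in c("spacing", "m2")) {
    d <- rd_rhs(st, p, grid_factor = gf)
    w2 <- if (gf == "spacing") (m - 1)^2 else m^2
    res <- rd_residual_oracle(st, d, p, w2)
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("without sliding feedback the shear obeys the diffusion limit form", {
  p <- rd_params(800, 100, 0.14, 0.3, 2)
  n0 <- equilibrium_attachment(0.14, 2)
  m <- 41
  s <- seq(0, 1, length.out = m)
  g <- 0.2 * sin(pi * s / 2)
  st <- flagellum_state(g, rep(n0, m), rep(n0, m))
  d <- rd_rhs(st, p, feedback = FALSE)
  w2 <- (m - 1)^2
  lap <- numeric(m)
  lap[2:(m - 1)] <- w2 * diff(diff(g))
  lap[m] <- 2 * w2 * (g[m - 1] - g[m])
  expect_equal(d$gamma[-1], ((lap - 100 * g) / (2 * n0 * 800 * 0.3))[-1],
               tolerance = 1e-12)
  expect_equal(d$n_plus, rep(0, m), tolerance = 1e-14)
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- rd_params(2000, 100, 0.14, 0.3, 2)
  a <- simulate_rd(p, t_end = 2, dt_out = 0.5, m = 31)
  b <- simulate_rd(p, t_end = 2, dt_out = 0.5, m = 31, use_compiled = FALSE)
  expect_equal(a$gamma, b$gamma, tolerance = 1e-7)
  expect_equal(a$n_plus, b$n_plus, tolerance = 1e-7)
})

test_that("the DAE path reproduces the method-of-lines solution", {
  p <- rd_params(2000, 100, 0.14, 0.3, 2)
  # compared while the instability is still amplifying, so solver
  # differences grow with the growth rate; agreement at 1e-3 relative
  a <- simulate_rd(p, t_end = 3, dt_out = 0.5, m = 31)
  b <- simulate_rd(p, t_end = 3, dt_out = 0.5, m = 31, method = "daspk")
  expect_equal(a$gamma, b$gamma, tolerance = 1e-3)
})

test_that("the default initial condition is the printed Gaussian bump", {
  ic <- default_initial_condition(101, 0.05)
  s <- ic$s_grid
  expect_equal(ic$gamma[s == 0.5], 0.001)
  expect_equal(ic$gamma[abs(s - 0.4) < 1e-9], 0.001 / exp(1))
  expect_equal(ic$gamma[abs(s - 0.6) < 1e-9], 0.001 / exp(1))
  expect_equal(max(ic$gamma), 0.001)
  expect_equal(which.max(ic$gamma), 51L)
  expect_equal(ic$n_plus, rep(0.05, 101))
})

test_that("subcritical activity decays to the homogeneous equilibrium", {
  crit <- critical_activity(100, 0.14, 0.3, 2)
  sim <- simulate_rd(rd_params(0.5 * crit, 100, 0.14, 0.3, 2),
                     t_end = 40, dt_out = 0.5)
  nrm <- sqrt(rowMeans(sim$gamma^2))
  expect_lt(nrm[length(nrm)], 0.1 * nrm[1])
  n0 <- equilibrium_attachment(0.14, 2)
  expect_equal(max(abs(sim$n_plus[nrow(sim$n_plus), ] - n0)), 0,
               tolerance = 1e-6)
})

test_that("without motors the only steady state is the straight elastica", {
  # gamma_ss - mu gamma = 0 with gamma(0) = 0, gamma_s(1) = 0 has only
  # the trivial solution; the no-feedback dynamics must relax to it and
  # the shear L2 norm must never grow
  p <- rd_params(500, 50, 0.2, 0.5, 2)
  m <- 61
  s <- seq(0, 1, length.out = m)
  n0 <- equilibrium_attachment(0.2, 2)
  st <- flagellum_state(0.4 * sin(3 * pi * s / 2) + 0.2 * s,
                        rep(n0, m), rep(n0, m))
  sim <- simulate_rd(p, initial = st, t_end = 30, dt_out = 0.25,
                     feedback = FALSE)
  nrm <- sqrt(rowMeans(sim$gamma^2))
  expect_true(all(diff(nrm) <= 1e-10))
  expect_lt(max(abs(sim$gamma[nrow(sim$gamma), ])), 1e-7)
})

test_that("growth-rate measurement recovers a constructed exponential envelope", {
  s <- seq(0, 1, length.out = 101)
  tt <- seq(0, 60, by = 0.02)
  vals <- 1e-4 * exp(0.1 * tt) * sin(5 * tt)
  kym <- kymograph(outer(vals, sin(pi * s / 2)), tt, s, "shear_angle")
  gm <- measure_growth_rate(kym)
  expect_equal(gm$alpha, 0.1, tolerance = 1e-2)
  expect_equal(gm$omega, 5, tolerance = 1e-2)
  # subcritical decay has no growth window
  vals2 <- 1e-4 * exp(-0.05 * tt) * cos(5 * tt)
  kym2 <- kymograph(outer(vals2, sin(pi * s / 2)), tt, s, "shear_angle")
  expect_error(measure_growth_rate(kym2), "window not found")
})

test_that("an eigenfunction of the diffusion limit decays at its closed-form rate", {
  p <- rd_params(1000, 100, 0.14, 0.3, 2)
  n0 <- equilibrium_attachment(0.14, 2)
  D <- 1 / (2 * n0 * 1000 * 0.3); E <- 100 * D
  s <- seq(0, 1, length.out = 101)
  sol <- diffusion_closed_form(function(x) sin(pi * x / 2), p, s,
                               t = c(0, 0.05, 0.1))
  rate <- E + D * pi^2 / 4
  for (j in 1:3)
    expect_equal(sol$values[j, ], exp(-rate * c(0, 0.05, 0.1)[j]) *
                   sin(pi * s / 2), tolerance = 1e-6)
  expect_true(all(diff(sol$decay_rates) > 0))
  expect_equal(sol$D, D)
  expect_equal(sol$E, E)
})

test_that("the no-feedback solver matches the series solution of the curved release", {
  p <- rd_params(1000, 100, 0.14, 0.3, 2)
  n0 <- equilibrium_attachment(0.14, 2)
  m <- 101
  s <- seq(0, 1, length.out = m)
  D <- 1 / (2 * n0 * 1000 * 0.3); E <- 100 * D
  tdec <- 1 / (E + D * pi^2 / 4)
  st <- flagellum_state((1 - cos(2 * pi * s)) / 4, rep(n0, m), rep(n0, m))
  sim <- cached("nofb_curved",
                simulate_rd(p, initial = st, t_end = 5 * tdec,
                            dt_out = 5 * tdec / 25, feedback = FALSE))
  cf <- diffusion_closed_form(function(x) (1 - cos(2 * pi * x)) / 4, p, s,
                              t = sim$times)
  expect_lt(max(abs(sim$gamma - cf$values)), 1e-4)
  # long-time dissipation
  late <- diffusion_closed_form(function(x) (1 - cos(2 * pi * x)) / 4, p, s,
                                t = 20 * tdec)
  expect_lt(max(abs(late$values)), 1e-6 * max(abs(cf$values[1, ])))
})

test_that("halving the grid spacing leaves the beat frequency unchanged to 0.5%", {
  crit <- critical_activity(100, 0.14, 0.3, 2)
  p <- rd_params(1.2 * crit, 100, 0.14, 0.3, 2)
  freq <- vapply(c(51, 101), function(m) {
    sim <- simulate_rd(p, t_end = 100, dt_out = 0.02, m = m)
    keep <- sim$times >= 50
    2 * pi / crossing_period(sim$times[keep],
                             sim$gamma[keep, ceiling(m / 2)])
  }, numeric(1))
  expect_lt(abs(freq[2] / freq[1] - 1), 0.005)
})

test_that("numerical Hopf location brackets the closed-form critical activity", {
  hb <- cached("rd_hopf", find_rd_hopf(100, 0.14, 0.3, 2))
  crit <- critical_activity(100, 0.14, 0.3, 2)
  expect_lt(abs(hb$mu_a_crit / crit - 1), 0.02)
  expect_gt(hb$upper, crit * 0.98)
  expect_lt(hb$lower, crit * 1.02)
})

test_that("kymographs round-trip through delimited text with sidecar", {
  s <- seq(0, 1, length.out = 21)
  tt <- seq(0, 1, by = 0.1)
  kym <- kymograph(outer(tt, s), tt, s, "shear_angle",
                   metadata = list(note = "fixture"))
  path <- tempfile(fileext = ".csv")
  write_kymograph(kym, path)
  back <- read_kymograph(path)
  expect_equal(back$values, kym$values)
  expect_equal(back$times, kym$times)
  expect_equal(back$s_grid, kym$s_grid)
  expect_identical(back$field_name, "shear_angle")
})
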