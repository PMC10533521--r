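test_that("curvature integrates to angle and differentiates back", {
  tt <- seq(0, 0.4, by = 4e-3)
  s <- seq(0, 1, length.out = 30)
  const <- beat_record(matrix(1.3, length(tt), 30),
                       "bull_curvature_30pt_4ms", times_s = tt)
  ang <- curvature_to_angle(const)
  expect_identical(ang$field, "tangent_angle")
  expect_equal(ang$values[1, ], 1.3 * s, tolerance = 1e-12)
  zero <- curvature_to_angle(beat_record(matrix(0, length(tt), 30),
                                         "bull_curvature_30pt_4ms"))
  expect_equal(max(abs(zero$values)), 0)
  # smooth curvature: numerical differentiation recovers input to O(h^2)
  curv <- outer(cos(2 * pi * 5 * tt), sin(2 * pi * s) + 0.5)
  rec <- beat_record(curv, "bull_curvature_30pt_4ms", times_s = tt)
  th <- curvature_to_angle(rec)$values
  h <- s[2] - s[1]
  mid <- 2:29
  dth <- (th[, mid + 1] - th[, mid - 1]) / (2 * h)
  expect_lt(max(abs(dth - curv[, mid])), 12 * h^2)
  expect_error(curvature_to_angle(ang), "does not hold curvature")
})

test_that("relative angle removes rigid rotation and keeps the bend", {
  tt <- seq(0, 0.1, by = 1e-3)
  s <- seq(0, 1, length.out = 19)
  rigid <- beat_record(outer(sin(20 * tt), rep(1, 19)),
                       "chlamy_theta_19pt_1ms", times_s = tt)
  expect_equal(max(abs(to_relative_angle(rigid)$values)), 0)
  bend <- outer(rep(1, length(tt)), 0.5 * s^2)
  both <- beat_record(outer(sin(20 * tt), rep(1, 19)) + bend,
                      "chlamy_theta_19pt_1ms", times_s = tt)
  expect_equal(to_relative_angle(both)$values, bend, tolerance = 1e-12)
  # already relative: unchanged
  rel <- beat_record(bend, "chlamy_theta_19pt_1ms", times_s = tt)
  expect_equal(to_relative_angle(rel)$values, bend)
})

test_that("arclength interpolation is spline-accurate and preserves knots", {
  tt <- seq(0, 0.05, by = 1e-3)
  s19 <- seq(0, 1, length.out = 19)
  prof <- sin(pi * s19 / 2) + 0.3 * sin(2 * pi * s19)
  rec <- beat_record(outer(rep(1, length(tt)), prof),
                     "chlamy_theta_19pt_1ms", times_s = tt)
  kym <- interpolate_arclength(rec, m = 101)
  expect_length(kym$s_grid, 101)
  s101 <- kym$s_grid
  truth <- sin(pi * s101 / 2) + 0.3 * sin(2 * pi * s101)
  expect_lt(max(abs(kym$values[1, ] - truth)), 1e-3 * max(abs(truth)))
  # original knots preserved exactly
  knots <- match(round(s19, 10), round(s101, 10))
  expect_equal(kym$values[1, stats::na.omit(knots)],
               prof[!is.na(knots)], tolerance = 1e-12)
  few <- beat_record(matrix(1, 2, 19), "chlamy_theta_19pt_1ms")
  few$s_grid <- few$s_grid[1:3]; few$values <- few$values[, 1:3]
  expect_error(interpolate_arclength(few), "at least 4")
})

test_that("parameter grids follow the stated steps and counts", {
  g10 <- parameter_grid(10)
  ax <- attr(g10, "axes")
  expect_equal(diff(ax$mu_a)[1], 100)
  expect_equal(diff(ax$eta)[1], 0.04)
  expect_equal(diff(ax$zeta)[1], 0.1)
  g100 <- parameter_grid(100)
  expect_equal(diff(attr(g100, "axes")$mu_a)[1], 1000)
  expect_equal(nrow(g10), length(ax$mu_a) * length(ax$eta) * length(ax$zeta))
  small <- parameter_grid(10, mu_a = seq(100, 300, 100), eta = c(0.1, 0.2),
                          zeta = c(0.3, 0.4))
  expect_equal(nrow(small), 12)
  expect_equal(nrow(parameter_grid(10, mu_a = 500, eta = 0.1, zeta = 0.3)),
               1)
  expect_error(parameter_grid(10, mu_a = numeric(0)), "empty axis")
})

test_that("a noiseless on-grid target is recovered exactly", {
  fx <- fit_fixture()
  fit <- fit_beat(fx$target, fx$grid, mu = 100, sims = fx$sims)
  expect_equal(unname(coef(fit)), c(2500, 0.14, 0.3))
  expect_gt(fit$R2, 0.98)
  # closed-form subcritical candidates are scored 0 and logged
  eps <- mapply(function(ma, et, ze)
    bifurcation_distance(ma, 100, et, ze, 2),
    fit$scores$mu_a, fit$scores$eta, fit$scores$zeta)
  expect_true(any(eps <= 0))
  sub <- fit$scores[eps <= 0, ]
  expect_true(all(sub$reason == "subcritical"))
  expect_true(all(sub$R2 == 0))
  # reported score equals an independent recomputation of the winning mode
  best_mode <- fx$sims[[fit$best_index]]
  direct <- r_squared(fx$target$mode, best_mode$mode)
  expect_equal(fit$R2, direct$R2, tolerance = 1e-12)
  expect_equal(fit$phi, direct$phi, tolerance = 1e-12)
})

test_that("candidate order does not change the fitted parameters", {
  fx <- fit_fixture()
  set.seed(3)
  perm <- sample(nrow(fx$grid))
  gperm <- fx$grid[perm, ]
  sperm <- fx$sims[perm]
  attr(sperm, "reasons") <- attr(fx$sims, "reasons")[perm]
  fit1 <- fit_beat(fx$target, fx$grid, mu = 100, sims = fx$sims)
  fit2 <- fit_beat(fx$target, gperm, mu = 100, sims = sperm)
  expect_equal(coef(fit2), coef(fit1))
  expect_equal(fit2$R2, fit1$R2)
})

test_that("preprocessing commutes with amplitude scaling", {
  fx <- fit_fixture()
  rec <- fx$rec
  scaled <- rec
  scaled$values <- 2.5 * scaled$values
  a <- preprocess_record(scaled)
  b <- preprocess_record(rec)
  expect_equal(a$values, 2.5 * b$values, tolerance = 1e-12)
})

test_that("fit results serialize to JSON plus a score table", {
  fx <- fit_fixture()
  fit <- fit_beat(fx$target, fx$grid, mu = 100, sims = fx$sims)
  path <- tempfile()
  write_fit(fit, path)
  js <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(js$best_params$mu_a, 2500)
  expect_equal(js$grid_size, nrow(fx$grid))
  tab <- utils::read.csv(paste0(path, "_scores.csv"))
  expect_equal(nrow(tab), nrow(fx$grid))
  expect_equal(max(tab$R2), fit$R2, tolerance = 1e-12)
})
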