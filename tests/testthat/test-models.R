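test_that("polynomial fit recovers exact low-order structure", {
  g <- make_argument_grid(10)
  # collinear points, degree 1: exact
  m <- fit_polynomial(g, 2 - 3 * g, degree = 1)
  expect_equal(m$coefficients, c(2, -3), tolerance = 1e-12)
  dev <- fit_deviations(m, g, 2 - 3 * g)
  expect_lt(dev$max_deviation, 1e-12)

  # degree = N - 1 on few points: interpolation (checked against solve())
  g5 <- make_argument_grid(5)
  y5 <- c(0.3, -1.2, 2.5, 0.1, -0.7)
  m5 <- fit_polynomial(g5, y5, degree = 4)
  a_direct <- solve(outer(as.numeric(g5), 0:4, `^`), y5)
  expect_equal(m5$coefficients, as.numeric(a_direct), tolerance = 1e-8)
  expect_lt(fit_deviations(m5, g5, y5)$max_deviation, 1e-8)

  expect_error(fit_polynomial(g5, y5, degree = 5), "over-parameterized")
  expect_error(fit_polynomial(g5, y5, degree = 0), "degree")
})

test_that("polynomial rms deviation is non-increasing in degree", {
  s <- eye_fixture(seed = 2)
  g <- make_argument_grid(60)
  tv <- sample_values(modify_sample(s))
  rms <- vapply(2:12, function(d) {
    fit_deviations(fit_polynomial(g, tv, d), g, tv)$rms_deviation
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-10))
})

test_that("cubic spline interpolates exactly and reproduces cubics", {
  g <- make_argument_grid(12)
  # zero data -> all-zero coefficients
  m0 <- fit_spline(g, rep(0, 12))
  expect_true(all(m0$coefficients == 0))

  # not-a-knot reproduces a cubic polynomial everywhere
  cubic <- function(t) 1 - 2 * t + 3 * t^2 - 4 * t^3
  m <- fit_spline(g, cubic(g), bc = "notaknot")
  tt <- seq(0, 1, length.out = 301)
  expect_lt(max(abs(evaluate_model(m, tt) - cubic(tt))), 1e-9)

  # overlap match: exact at the knots, for arbitrary data
  for (seed in 1:5) {
    s <- eye_fixture(seed)
    tv <- sample_values(modify_sample(s))
    g60 <- make_argument_grid(60)
    ms <- fit_spline(g60, tv)
    expect_lt(
      max(abs(evaluate_model(ms, as.numeric(g60)) - tv)),
      1e-12 * max(1, max(abs(tv)))
    )
    dev <- fit_deviations(ms, g60, tv)
    expect_equal(dev$max_deviation, 0, tolerance = 1e-12)
    expect_equal(dev$rms_deviation, 0, tolerance = 1e-12)
  }
  expect_error(fit_spline(make_argument_grid(3), 1:3), "N >= 4")
  expect_error(fit_spline(c(0, 0.5, 0.5, 1), c(1, 2, 3, 4)), "duplicate")
})

test_that("natural spline agrees with the base-R reference interpolant", {
  g <- make_argument_grid(25)
  set.seed(11)
  y <- as.numeric(stats::filter(rnorm(25), rep(1 / 3, 3), circular = TRUE))
  m <- fit_spline(g, y, bc = "natural")
  ref <- stats::splinefun(as.numeric(g), y, method = "natural")
  tt <- seq(0, 1, length.out = 401)
  expect_lt(max(abs(evaluate_model(m, tt) - ref(tt))), 1e-10)
})

test_that("full-center RBF network interpolates; reduced centers least-squares", {
  g <- make_argument_grid(30)
  bump <- exp(-(as.numeric(g) - 0.5)^2 / (2 * 0.1^2))
  m <- fit_rbf(g, bump)
  expect_lt(
    max(abs(evaluate_model(m, as.numeric(g)) - bump)),
    1e-6 * max(abs(bump))
  )
  # against an independent linear solve of the interpolation system
  A <- exp(-outer(as.numeric(g), m$centers, `-`)^2 / (2 * m$widths[1]^2))
  expect_equal(m$weights, as.numeric(solve(A, bump)), tolerance = 1e-6)

  # zero data -> zero weights
  mz <- fit_rbf(g, rep(0, 30))
  expect_true(all(abs(mz$weights) < 1e-12))
  expect_equal(evaluate_model(mz, c(0.2, 0.7)), c(0, 0))

  # fewer centers: least squares still tracks a smooth target
  mls <- fit_rbf(g, bump, n_centers = 10)
  expect_lt(fit_deviations(mls, g, bump)$rms_deviation, 0.05)
  expect_error(fit_rbf(g, bump, n_centers = 0), "n_centers")
})

test_that("MLP training is seeded-deterministic and fits smooth targets", {
  g <- make_argument_grid(40)
  bump <- sin(pi * as.numeric(g))^3
  m1 <- fit_mlp(g, bump, hidden = c(15), seed = 4, max_epochs = 2000)
  m2 <- fit_mlp(g, bump, hidden = c(15), seed = 4, max_epochs = 2000)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$biases, m2$biases)
  expect_lte(m1$loss_final, m1$loss_initial)

  # beats a degree-3 polynomial on the same data
  rms_mlp <- fit_deviations(m1, g, bump)$rms_deviation
  rms_p3 <- fit_deviations(fit_polynomial(g, bump, 3), g, bump)$rms_deviation
  expect_lt(rms_mlp, rms_p3)

  # constant zero target collapses to the zero function
  mz <- fit_mlp(g, rep(0, 40), seed = 1, max_epochs = 500)
  expect_lt(fit_deviations(mz, g, rep(0, 40))$rms_deviation, 1e-3)

  expect_error(fit_mlp(g, c(bump[-1], NaN)), "non-finite")
  expect_error(fit_mlp(g, bump, hidden = integer(0)), "hidden")
})

test_that("two-hidden-layer MLP trains and counts its parameters", {
  g <- make_argument_grid(30)
  y <- sin(2 * pi * as.numeric(g)) * (1 - as.numeric(g))
  m <- fit_mlp(g, y, hidden = c(6, 5), seed = 2, max_epochs = 1500)
  # 1*6+6 + 6*5+5 + 5*1+1 weights/biases, +1 normalizing coefficient
  expect_equal(model_complexity(m), 12 + 35 + 6 + 1)
  expect_lt(fit_deviations(m, g, y)$rms_deviation, 0.2)
})

test_that("model evaluation respects support, affine postprocessing, linearity", {
  g <- make_argument_grid(20)
  y <- cos(2 * pi * as.numeric(g))
  for (m in list(
    fit_polynomial(g, y, 6), fit_spline(g, y),
    fit_rbf(g, y)
  )) {
    expect_identical(evaluate_model(m, c(-0.5, 1.5, -1e-9)), c(0, 0, 0))
    m2 <- m
    m2$norm_coeff <- 2 * m$norm_coeff
    tt <- seq(0, 1, 0.05)
    expect_equal(evaluate_model(m2, tt), 2 * evaluate_model(m, tt))
    m3 <- m
    m3$offset <- m$offset + 1.5
    expect_equal(
      evaluate_model(m3, tt),
      evaluate_model(m, tt) + m$norm_coeff * 1.5
    )
  }
  # spline at a knot returns norm_coeff * (value + offset)
  ms <- fit_spline(g, y)
  ms$offset <- 0.25
  ms$norm_coeff <- 3
  expect_equal(evaluate_model(ms, as.numeric(g)[5]), 3 * (y[5] + 0.25))
})

test_that("deviation metrics implement max and rms by hand-checked formulas", {
  g <- make_argument_grid(8)
  y <- as.numeric(g)
  m <- fit_polynomial(g, y, 1) # exact line
  # model == values + 1
  m_shift <- m
  m_shift$coefficients[1] <- m_shift$coefficients[1] + 1
  d <- fit_deviations(m_shift, g, y)
  expect_equal(d$max_deviation, 1, tolerance = 1e-10)
  expect_equal(d$rms_deviation, 1, tolerance = 1e-10)
  # residual 2 on half the points, 0 on the other half: max 2, rms sqrt(2)
  y_half <- y - c(rep(2, 4), rep(0, 4))
  d2 <- fit_deviations(m, g, y_half)
  expect_equal(d2$max_deviation, 2, tolerance = 1e-10)
  expect_equal(d2$rms_deviation, sqrt(2), tolerance = 1e-10)
})

test_that("parameter counts follow the family conventions", {
  g <- make_argument_grid(60)
  s <- eye_fixture(1)
  tv <- sample_values(modify_sample(s))
  expect_equal(model_complexity(fit_polynomial(g, tv, 12)), 14)
  expect_equal(model_complexity(fit_spline(g, tv)), 241)
  expect_equal(model_complexity(fit_rbf(g, tv)), 182)
  expect_equal(model_complexity(fit_mlp(g, tv, hidden = c(15), max_epochs = 10)), 47)
})
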