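test_that("model integrals use exact antiderivatives where available", {
  g <- make_argument_grid(10)
  # constant polynomial value 1 -> area 1
  m1 <- fit_polynomial(g, rep(1, 10), 1)
  expect_equal(integral_of(m1), 1, tolerance = 1e-12)
  # spline interpolating t^2 -> integral 1/3 (cubic pieces reproduce t^2)
  g25 <- make_argument_grid(25)
  ms <- fit_spline(g25, as.numeric(g25)^2)
  expect_equal(integral_of(ms), 1 / 3, tolerance = 1e-9)
  # quadrature path (RBF) against dense trapezoid
  s <- eye_fixture(3)
  tv <- sample_values(modify_sample(s))
  mr <- fit_rbf(make_argument_grid(60), tv)
  expect_equal(
    integral_of(mr),
    trapz_quad(function(t) evaluate_model(mr, t), 0, 1),
    tolerance = 1e-7
  )
})

test_that("offset correction zeroes the integral in one exact step", {
  g <- make_argument_grid(10)
  # already zero-integral: untouched
  vals <- as.numeric(g) - 0.5 # odd around midpoint
  m <- fit_polynomial(g, vals, 1)
  oc <- offset_correct(m, g, vals)
  expect_equal(oc$iterations, 0)
  expect_identical(oc$model, m)
  # constant c: one iteration, integral exactly 0
  mc <- fit_polynomial(g, rep(2.5, 10), 1)
  occ <- offset_correct(mc, g, rep(2.5, 10))
  expect_equal(occ$iterations, 1)
  expect_lt(abs(integral_of(occ$model)), 1e-14)
  # tapered bump + spline: exact shift, at most one step
  s <- eye_fixture(4)
  tv <- sample_values(modify_sample(s))
  msp <- fit_spline(make_argument_grid(60), tv)
  ocs <- offset_correct(msp, make_argument_grid(60), tv)
  expect_lte(ocs$iterations, 3)
  expect_lt(abs(integral_of(ocs$model)), 1e-8 * max(abs(tv)))
  expect_true(ocs$converged)
})

test_that("normalization scales to unit energy and is idempotent", {
  g <- make_argument_grid(10)
  # constant value 2: energy 4, Ms = 0.5
  m2 <- fit_polynomial(g, rep(2, 10), 1)
  expect_equal(normalization_coefficient(m2), 0.5, tolerance = 1e-12)
  # doubling a unit-energy model halves Ms
  mn <- normalize_wavelet(fit_spline(g, sin(2 * pi * as.numeric(g))))
  expect_equal(normalization_coefficient(mn), 1, tolerance = 1e-10)
  m_doubled <- mn
  m_doubled$norm_coeff <- 2 * mn$norm_coeff
  expect_equal(normalization_coefficient(m_doubled), 0.5, tolerance = 1e-10)
  # idempotent within quadrature tolerance
  mnn <- normalize_wavelet(mn)
  expect_equal(mnn$norm_coeff / mn$norm_coeff, 1, tolerance = 1e-8)
  # zero model cannot be normalized
  expect_error(
    normalization_coefficient(fit_polynomial(g, rep(0, 10), 1)),
    "zero-energy"
  )
})

test_that("admissibility constant matches the Mexican-hat closed form", {
  cp <- admissibility_constant(mexican_hat)
  expect_equal(cp, (8 / 3) * sqrt(pi), tolerance = 0.02)
  # quadratic scaling in the wavelet amplitude
  cp2 <- admissibility_constant(function(t) 2 * mexican_hat(t))
  expect_equal(cp2 / cp, 4, tolerance = 1e-10)
  # Haar: finite, positive, and stable under grid refinement
  ch1 <- admissibility_constant(haar, support = c(0, 1))
  ch2 <- admissibility_constant(haar, n_fft = 8192, support = c(0, 1))
  expect_gt(ch1, 0)
  expect_lt(abs(ch2 - ch1) / ch1, 0.01)
  # nonzero-mean input is refused
  expect_error(
    admissibility_constant(function(t) exp(-t^2), support = c(-6, 6)),
    "offset correction"
  )
})

test_that("end-to-end synthesis yields admissible wavelets for all families", {
  s <- eye_fixture(1)
  for (kind in c("spline", "polynomial", "rbf", "mlp")) {
    syn <- synthesize_wavelet(s, synthesis_config(kind, seed = 1, max_epochs = 2000))
    g <- glance(syn)
    expect_lte(abs(g$integral), 1e-8)
    expect_lte(abs(g$l2_norm - 1), 1e-8)
    expect_true(g$c_psi > 0 && is.finite(g$c_psi))
    expect_true(g$admissible)
  }
  # interpolation guarantee shows up as zero deviations for the spline
  syn_sp <- synthesize_wavelet(s, synthesis_config("spline"))
  expect_equal(syn_sp$report$fit$max_deviation, 0, tolerance = 1e-12)
  expect_equal(syn_sp$report$fit$rms_deviation, 0, tolerance = 1e-12)
  # degree-12 polynomial: 14 parameters, nonzero deviations
  syn_p <- synthesize_wavelet(s, synthesis_config("polynomial", degree = 12))
  expect_equal(model_complexity(syn_p$model), 14)
  expect_gt(syn_p$report$fit$max_deviation, 0)
  # zero sample cannot be synthesized
  expect_error(
    synthesize_wavelet(wavelet_sample(rep(0, 60), 250)),
    "zero-energy"
  )
})

test_that("synthesis is deterministic given seeds and config", {
  s <- eye_fixture(5)
  cfg <- synthesis_config("mlp", seed = 7, max_epochs = 500)
  s1 <- synthesize_wavelet(s, cfg)
  s2 <- synthesize_wavelet(s, cfg)
  tt <- seq(0, 1, length.out = 101)
  expect_identical(evaluate_model(s1$model, tt), evaluate_model(s2$model, tt))
})
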