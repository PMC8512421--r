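syn_spline <- synthesize_wavelet(eye_fixture(1), synthesis_config("spline"))
wm <- syn_spline$model

test_that("wavelet family members dilate, translate and keep their norm", {
  tt <- seq(-1, 3, by = 0.01)
  # identity scale/shift reduces to the mother wavelet
  expect_equal(wavelet_family_eval(wm, 1, 0, tt), evaluate_model(wm, tt))
  # pure translation
  expect_equal(
    wavelet_family_eval(wm, 1, 10, tt + 10),
    wavelet_family_eval(wm, 1, 0, tt)
  )
  # 1/sqrt(a) preserves the L2 norm under dilation
  e1 <- trapz_quad(function(t) wavelet_family_eval(wm, 1, 0, t)^2, -1, 6)
  e4 <- trapz_quad(function(t) wavelet_family_eval(wm, 4, 0, t)^2, -1, 6)
  expect_equal(e4, e1, tolerance = 1e-6)
  expect_error(wavelet_family_eval(wm, 0, 0, tt), "nonzero")
})

test_that("cwt agrees with the brute-force Riemann oracle", {
  set.seed(7)
  sig <- wavelet_sample(rnorm(64), fs = 64)
  scales <- c(2, 3, 5, 8, 13, 21, 34, 55)
  res <- cwt(sig, wm, scales)
  W_oracle <- brute_cwt(
    sample_values(sig), function(u) evaluate_model(wm, u), scales
  )
  expect_lt(max(abs(res$matrix - W_oracle)) / max(abs(W_oracle)), 1e-8)
  expect_equal(dim(res$matrix), c(8, 64))
  expect_equal(res$scales, scales)
})

test_that("cwt is linear and vanishes on the zero signal", {
  set.seed(8)
  f <- rnorm(50)
  g <- rnorm(50)
  scales <- c(2, 5, 11, 23)
  Wf <- cwt(wavelet_sample(f, 50), wm, scales)$matrix
  Wg <- cwt(wavelet_sample(g, 50), wm, scales)$matrix
  Wfg <- cwt(wavelet_sample(f + g, 50), wm, scales)$matrix
  expect_lt(max(abs(Wfg - (Wf + Wg))), 1e-10)
  W0 <- cwt(wavelet_sample(rep(0, 50), 50), wm, scales)$matrix
  expect_true(all(W0 == 0))
  expect_error(cwt(wavelet_sample(f, 50), wm, c(-1, 2)), "positive")
  expect_error(cwt(wavelet_sample(f, 50), wm, c(2, 2, 3)), "strictly increasing")
})

test_that("delaying the signal shifts coefficient rows accordingly", {
  set.seed(9)
  n <- 80
  m_delay <- 7
  f <- rnorm(n)
  f_delayed <- c(rep(0, m_delay), f[1:(n - m_delay)])
  scales <- c(3, 6, 12)
  W1 <- cwt(wavelet_sample(f, 100), wm, scales)$matrix
  W2 <- cwt(wavelet_sample(f_delayed, 100), wm, scales)$matrix
  for (i in seq_along(scales)) {
    # interior columns: wavelet support fully inside both signals
    valid_b <- 0:(n - 1 - m_delay - ceiling(scales[i]) - 1)
    expect_lt(
      max(abs(W2[i, valid_b + 1 + m_delay] - W1[i, valid_b + 1])),
      1e-10
    )
  }
})

test_that("discrete coefficient energy is unity when signal matches the wavelet", {
  a <- 64
  k <- 0:79
  f <- wavelet_family_eval(wm, a, 0, k)
  res <- cwt(wavelet_sample(f, 250), wm, c(32, 64))
  expect_equal(res$matrix[2, 1], 1, tolerance = 1e-3)
})

test_that("scale-frequency relation is inverse-proportional with constant beta", {
  fm <- frequency_map(250, 250)
  expect_equal(scale_for_frequency(fm, 5), 50)
  expect_equal(scale_for_frequency(fm, 250), 1)
  expect_equal(
    scale_for_frequency(fm, 2.5),
    2 * scale_for_frequency(fm, 5)
  )
  expect_error(scale_for_frequency(fm, 0), "positive")
  expect_error(frequency_map(-1, 250), "positive")
})

test_that("beta calibration tracks the wavelet spectral peak and fs", {
  fm <- estimate_beta(wm, 250)
  # dilating by a moves the spectral peak to beta/a: verify by FFT at a = 40
  a <- 40
  kk <- 0:(40 * 8 - 1)
  dilated <- wavelet_family_eval(wm, a, 0, kk)
  pk <- spectral_peak_hz(dilated, 250, nfft = 16384)
  expect_equal(pk, fm$beta / a, tolerance = 0.15)
  # doubling fs doubles beta
  fm2 <- estimate_beta(wm, 500)
  expect_equal(fm2$beta, 2 * fm$beta)
  # requesting the unit-scale peak frequency returns a = 1
  expect_equal(scale_for_frequency(fm, fm$beta), 1)
  expect_error(estimate_beta(fit_polynomial(
    make_argument_grid(8), rep(0, 8), 1
  ), 250), "flat spectrum|zero")
})

test_that("icwt reconstructs a noise-free artifact up to discretization", {
  sim <- gen_eeg_like_signal(1000, 250, artifact_specs(2.0),
    noise_sd = 0, seed = 2
  )
  res <- cwt(sim$signal, wm, 1:100)
  cp <- admissibility_constant(wm)
  rec <- icwt(res, wm, cp)
  expect_equal(nrow(rec), 1000)
  win <- which(abs(sim$signal$time - 2.0) <= 3 * 0.08)
  r <- stats::cor(sample_values(sim$signal)[win], sample_values(rec)[win])
  expect_gt(r, 0.95)
  # zero coefficients give the zero signal
  res0 <- res
  res0$matrix[] <- 0
  expect_identical(sample_values(icwt(res0, wm, cp)), rep(0, 1000))
  expect_error(icwt(res, wm, -1), "finite and positive")
})

test_that("peak localization recovers embedded artifact positions", {
  fm <- estimate_beta(wm, 250)
  a5 <- scale_for_frequency(fm, 5)
  # single artifact -> exactly one peak near truth
  one <- gen_eeg_like_signal(1000, 250, artifact_specs(2.0),
    noise_sd = 0, seed = 3
  )
  res1 <- cwt(one$signal, wm, 1:100)
  pk1 <- peak_localize(res1, a5, half_window = 25)
  expect_length(pk1, 1)
  expect_lt(abs(pk1 - 2.0 * 250), 0.08 * 250)
  # six artifacts with background noise
  sim <- gen_eeg_like_signal(1000, 250, noise_sd = 5, seed = 4)
  res6 <- cwt(sim$signal, wm, 1:100)
  pk6 <- peak_localize(res6, a5, half_window = 25)
  expect_length(pk6, 6)
  expect_true(all(abs(pk6 - sim$artifacts$center_time * 250) <
    sim$artifacts$half_width * 250))
  # zero signal -> no peaks
  res0 <- cwt(wavelet_sample(rep(0, 200), 250), wm, c(10, 20))
  expect_length(peak_localize(res0, 20), 0)
  expect_error(peak_localize(res6, 1e6), "scale range")
})

test_that("tidiers expose the transform as tables and plots build", {
  res <- cwt(wavelet_sample(sin(1:40 / 3), 100), wm, c(4, 8))
  td <- tidy(res)
  expect_equal(nrow(td), 2 * 40)
  expect_named(td, c("scale", "shift", "time", "coefficient", "boundary"))
  expect_equal(
    td$coefficient[td$scale == 8 & td$shift == 5],
    res$matrix[2, 6]
  )
  gl <- glance(res)
  expect_equal(gl$n_scales, 2)
  p <- ggplot2::ggplot_build(autoplot(res))
  expect_s3_class(autoplot(wm), "ggplot")
  expect_gt(nrow(p$data[[1]]), 0)
})
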