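# Independent oracles kept deliberately naive: they re-derive quantities by
# direct summation/quadrature, not by calling the code paths under test.

# Brute-force Riemann double loop for the CWT (dt = 1 sample).
brute_cwt <- function(values, wavelet_fun, scales) {
  n <- length(values)
  W <- matrix(0, length(scales), n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    for (b in 0:(n - 1)) {
      u <- ((0:(n - 1)) - b) / a
      psi <- ifelse(u >= 0 & u <= 1, wavelet_fun(u), 0)
      W[i, b + 1] <- sum(values * psi) / sqrt(a)
    }
  }
  W
}

# Trapezoid quadrature of f on [lo, hi] with a dense grid.
trapz_quad <- function(f, lo, hi, n = 20001) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}

# Spectral peak (Hz) of a sampled signal by zero-padded FFT.
spectral_peak_hz <- function(values, fs, nfft = 8192) {
  sp <- Mod(stats::fft(c(values, rep(0, nfft - length(values)))))
  k <- 2:(nfft %/% 2)
  (k[which.max(sp[k])] - 1) * fs / nfft
}

eye_fixture <- function(seed = 1) gen_eye_artifact_sample(60, 250, 100, seed = seed)
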