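# Seeded signal generators and closed-form reference wavelets. All generators
# are pure functions of their arguments (including the seed): RNG state is
# local to each call and the caller's .Random.seed is left untouched.

local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a synthetic ocular-artifact fragment
#'
#' Emulates the slow, high-amplitude eye-movement graph element used as the
#' wavelet-synthesis exemplar: a Gaussian-windowed single-cycle slow wave with
#' a dominant frequency near 5 Hz. The default length/rate (60 samples at
#' 250 Hz, a 0.24 s window) matches the exemplar dimensions this kind of
#' analysis uses. The envelope width is duration/6.2, which keeps the fragment
#' endpoints below 1 % of the peak amplitude. The carrier is 4.6 Hz with a
#' seeded jitter of +-0.2 Hz (distinct seeds give distinct, reproducible
#' fragments); the short Gaussian window skews the spectral peak upward to
#' about 5 Hz, within 4-6 Hz at the default geometry.
#'
#' @param n Number of samples, >= 8.
#' @param fs Sampling rate in Hz.
#' @param amplitude Peak amplitude (microvolts).
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A [wavelet_sample()] of length `n`.
#' @export
#' @examples
#' s <- gen_eye_artifact_sample(60, 250, 100, seed = 1)
#' nrow(s)
gen_eye_artifact_sample <- function(n, fs, amplitude = 100, seed = 1) {
  if (n < 8) stop("eye-artifact fragment needs n >= 8 samples", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  f0 <- local_rng(seed, 4.6 + stats::runif(1, -0.2, 0.2))
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  tc <- (n - 1) / (2 * fs)
  sigma <- dur / 6.2
  v <- amplitude * sin(2 * pi * f0 * (t - tc)) * exp(-(t - tc)^2 / (2 * sigma^2))
  wavelet_sample(v, fs, label = sprintf("synthetic eye artifact (%g Hz)", f0))
}

#' Specify embedded artifact ground truth
#'
#' Builds the tibble of burst parameters consumed (and returned as ground
#' truth) by [gen_eeg_like_signal()]. Each row is one graph element: a
#' Gaussian-windowed sinusoidal burst centred at `center_time`, hard-zero
#' outside `center_time +- 3 * half_width`.
#'
#' @param center_time Burst centres in seconds.
#' @param half_width Envelope half-widths in seconds (> 0); the Gaussian
#'   standard deviation is `2/3 * half_width`.
#' @param amplitude Peak amplitudes (microvolts).
#' @param frequency Carrier frequencies in Hz (> 0).
#'
#' @return A tibble with one row per artifact.
#' @export
artifact_specs <- function(center_time, half_width = 0.08, amplitude = 100,
                           frequency = 5) {
  out <- tibble::tibble(
    center_time = as.numeric(center_time),
    half_width = as.numeric(half_width),
    amplitude = as.numeric(amplitude),
    frequency = as.numeric(frequency)
  )
  if (any(out$half_width <= 0)) stop("half_width must be > 0", call. = FALSE)
  if (any(out$frequency <= 0)) stop("frequency must be > 0", call. = FALSE)
  out
}

#' Evenly spaced artifact layout for a signal of given duration
#'
#' @param k Number of artifacts.
#' @param duration Signal duration in seconds.
#' @inheritParams artifact_specs
#' @return A tibble of `k` artifact rows.
#' @export
default_artifact_layout <- function(k = 6, duration = 4, half_width = 0.08,
                                    amplitude = 100, frequency = 5) {
  centers <- duration * (seq_len(k) - 0.5) / k
  artifact_specs(centers, half_width, amplitude, frequency)
}

#' Generate an EEG-like test signal with embedded artifacts
#'
#' Produces band-limited background activity (a seeded sum of sinusoids with
#' random frequencies in 1-30 Hz and random phases, rescaled to standard
#' deviation `noise_sd`) plus Gaussian-windowed sinusoidal bursts at the
#' positions given in `artifacts`. Each burst is exactly zero outside
#' `center +- 3 * half_width`, so localization tests have crisp ground truth.
#' The defaults (1000 samples at 250 Hz, i.e. 4 s, six 5 Hz graph elements)
#' reproduce the dimensions of the analyzed-signal setting this package
#' targets.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param artifacts Tibble from [artifact_specs()]; may have zero rows.
#' @param noise_sd Standard deviation of the background (microvolts).
#' @param seed Integer seed.
#'
#' @return A list with elements `signal` (a [wavelet_sample()]) and
#'   `artifacts` (the ground-truth tibble, unchanged).
#' @export
gen_eeg_like_signal <- function(n = 1000, fs = 250,
                                artifacts = default_artifact_layout(6, n / fs),
                                noise_sd = 5, seed = 1) {
  if (n < 2) stop("signal needs n >= 2 samples", call. = FALSE)
  dur <- n / fs
  if (nrow(artifacts) > 0) {
    if (any(artifacts$center_time < 0 | artifacts$center_time > dur)) {
      stop("artifact centers must lie within [0, n/fs]", call. = FALSE)
    }
    if (nrow(artifacts) > 1) {
      o <- order(artifacts$center_time)
      a <- artifacts[o, ]
      for (i in seq_len(nrow(a) - 1)) {
        lo <- a$center_time[i] + 3 * a$half_width[i]
        hi <- a$center_time[i + 1] - 3 * a$half_width[i + 1]
        if (hi - lo < max(a$half_width[i], a$half_width[i + 1])) {
          stop("artifacts overlap: burst windows must be separated by at least one half_width",
            call. = FALSE
          )
        }
      }
    }
  }
  t <- (seq_len(n) - 1) / fs
  v <- rep(0, n)
  if (noise_sd > 0) {
    k <- 24L
    comps <- local_rng(seed, list(
      f = stats::runif(k, 1, 30),
      ph = stats::runif(k, 0, 2 * pi),
      w = stats::runif(k, 0.5, 1)
    ))
    bg <- rep(0, n)
    for (i in seq_len(k)) {
      bg <- bg + comps$w[i] * sin(2 * pi * comps$f[i] * t + comps$ph[i])
    }
    v <- v + noise_sd * bg / stats::sd(bg)
  }
  for (i in seq_len(nrow(artifacts))) {
    ct <- artifacts$center_time[i]
    hw <- artifacts$half_width[i]
    am <- artifacts$amplitude[i]
    fr <- artifacts$frequency[i]
    inside <- abs(t - ct) <= 3 * hw
    burst <- rep(0, n)
    burst[inside] <- am * sin(2 * pi * fr * (t[inside] - ct)) *
      exp(-(t[inside] - ct)^2 / (2 * (2 / 3 * hw)^2))
    v <- v + burst
  }
  list(
    signal = wavelet_sample(v, fs, label = sprintf(
      "synthetic EEG-like signal (%d artifacts)", nrow(artifacts)
    )),
    artifacts = artifacts
  )
}

#' Generate a piecewise-linear ("broken") fragment
#'
#' A continuous piecewise-linear sequence with zero endpoints and at least
#' three interior slope discontinuities: a triangular-wave template whose knot
#' amplitudes carry seeded jitter. Used to probe fine-structure analysis,
#' where smooth exemplars are inappropriate.
#'
#' @param n Number of samples, >= 4.
#' @param seed Integer seed.
#' @param fs Sampling rate (Hz); nominal, the fragment is usually treated as
#'   normalized amplitude against sample index.
#'
#' @return A [wavelet_sample()] of length `n`.
#' @export
gen_broken_sample <- function(n, seed = 1, fs = 250) {
  if (n < 4) stop("broken fragment needs n >= 4 samples", call. = FALSE)
  n_knots <- min(as.integer(n), 7L)
  kx <- round(seq(1, n, length.out = n_knots))
  kx <- unique(kx)
  ky <- local_rng(seed, {
    j <- seq_along(kx)
    amp <- (-1)^j * (0.6 + 0.4 * stats::runif(length(kx)))
    amp
  })
  ky[1] <- 0
  ky[length(ky)] <- 0
  v <- stats::approx(kx, ky, xout = seq_len(n))$y
  wavelet_sample(v, fs, label = "synthetic broken (piecewise-linear) fragment")
}

#' Concatenate broken fragments separated by zero segments
#'
#' Builds the broken test signal: `gap` zeros, the fragment, `gap` zeros, the
#' fragment, ..., ending with `gap` zeros. Total length is
#' `n_repeats * length(fragment) + (n_repeats + 1) * gap`.
#'
#' @param fragment A [wavelet_sample()].
#' @param n_repeats Number of fragment copies, >= 1.
#' @param gap Number of zero samples between (and around) copies, >= 0.
#'
#' @return A [wavelet_sample()].
#' @export
gen_broken_signal <- function(fragment, n_repeats = 3, gap = 50) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  frag <- sample_values(fragment)
  z <- rep(0, gap)
  v <- z
  for (i in seq_len(n_repeats)) v <- c(v, frag, z)
  wavelet_sample(v, sample_fs(fragment), label = sprintf(
    "broken test signal (%d fragments, gap %d)", n_repeats, gap
  ))
}

#' Mexican hat (Ricker) reference wavelet
#'
#' The closed-form reference wavelet
#' `psi(t) = (2/sqrt(3)) * pi^(-1/4) * (1 - t^2) * exp(-t^2/2)`,
#' which has zero integral and unit L2 norm analytically. Useful as a
#' formalized baseline against which synthesized wavelets are compared, and
#' as a known-answer case for the admissibility constant
#' (`C_psi = (8/3) * sqrt(pi)`).
#'
#' @param t Numeric vector of times (defined on all reals).
#' @return Wavelet amplitudes at `t`.
#' @export
#' @examples
#' mexican_hat(0) # ~0.8673
mexican_hat <- function(t) {
  (2 / sqrt(3)) * pi^(-1 / 4) * (1 - t^2) * exp(-t^2 / 2)
}

#' Haar reference wavelet
#'
#' +1 on [0, 0.5), -1 on [0.5, 1), 0 elsewhere. The natural reference for
#' broken (piecewise) signals.
#'
#' @param t Numeric vector of times.
#' @return Wavelet amplitudes at `t`.
#' @export
haar <- function(t) {
  ifelse(t >= 0 & t < 0.5, 1, ifelse(t >= 0.5 & t < 1, -1, 0))
}
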