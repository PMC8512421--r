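# Forward CWT, scale-frequency mapping, inverse CWT, and scalogram peak
# localization. Time is measured in sample units (dt = 1 sample) and scales
# are dimensionless dilations in the same units: the wavelet family member
# psi_ab occupies [b, b + a] sample indices, a literal dilation/translation of
# the [0,1]-supported mother wavelet. Reported peak positions are corrected by
# the wavelet's energy centroid so they point at the feature, not at the left
# edge of the wavelet support.

# Accept either a fitted model or a plain function on [0,1] (e.g. haar).
as_wavelet_fun <- function(model) {
  if (inherits(model, "wavelet_model")) {
    function(t) evaluate_model(model, t)
  } else if (is.function(model)) {
    function(t) ifelse(t >= 0 & t <= 1, model(t), 0)
  } else {
    stop("`model` must be a wavelet model or a function on [0, 1]", call. = FALSE)
  }
}

wavelet_centroid <- function(model, quad_points = 256) {
  f <- as_wavelet_fun(model)
  gl <- gauss_nodes(quad_points)
  e <- sum(gl$w * f(gl$x)^2)
  if (e <= 0) {
    return(0.5)
  }
  sum(gl$w * gl$x * f(gl$x)^2) / e
}

#' Evaluate a dilated/translated wavelet family member
#'
#' `psi_ab(t) = (1/sqrt(|a|)) * psi((t - b) / a)`; with the unit-support
#' mother wavelet, the member's support is `[b, b + a]`. The `1/sqrt(a)`
#' factor preserves the L2 norm under dilation.
#'
#' @param model A fitted wavelet model (or function on [0, 1]).
#' @param a Scale (nonzero).
#' @param b Shift.
#' @param t Numeric vector of times (same units as `a` and `b`).
#' @return Amplitudes at `t`.
#' @export
wavelet_family_eval <- function(model, a, b, t) {
  if (length(a) != 1 || a == 0) stop("scale `a` must be a single nonzero number", call. = FALSE)
  f <- as_wavelet_fun(model)
  f((t - b) / a) / sqrt(abs(a))
}

#' Continuous wavelet transform
#'
#' Computes the coefficient matrix
#' `W(a, b) = sum_k f(t_k) psi_ab(t_k) dt` (Riemann discretization with
#' `dt = 1` sample; real wavelets, so conjugation is the identity) for every
#' scale in `scales` and every signal sample as shift. The signal is zero-
#' extended beyond its ends; columns where more than half of the wavelet
#' support falls outside the signal are flagged in the `boundary` attribute.
#'
#' @param signal A [wavelet_sample()] of length >= 2.
#' @param model A fitted wavelet model (or a function on [0, 1], e.g.
#'   [haar()]).
#' @param scales Positive, strictly increasing scales in sample units.
#' @return An object of class `cwt_result`: list with `matrix`
#'   (scales x shifts), `scales`, `shifts` (0-based sample indices), `dt`
#'   (seconds per sample), `fs`, `centroid` (wavelet energy centroid on
#'   [0, 1]) and `boundary` (logical matrix).
#' @export
#' @examples
#' sim <- gen_eeg_like_signal(200, 250, artifact_specs(0.4), noise_sd = 0)
#' syn <- synthesize_wavelet(gen_eye_artifact_sample(60, 250), synthesis_config("spline"))
#' res <- cwt(sim$signal, syn$model, scales = 10:60)
cwt <- function(signal, model, scales = 1:100) {
  v <- sample_values(signal)
  n <- length(v)
  if (n < 2) stop("signal must have at least 2 samples", call. = FALSE)
  scales <- as.numeric(scales)
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be strictly increasing", call. = FALSE)
  }
  f <- as_wavelet_fun(model)
  W <- matrix(0, length(scales), n)
  boundary <- matrix(FALSE, length(scales), n)
  shifts <- 0:(n - 1)
  for (si in seq_along(scales)) {
    a <- scales[si]
    m <- floor(a) + 1L
    kern <- f((seq_len(m) - 1) / a) / sqrt(a)
    if (m == 1L) {
      W[si, ] <- v * kern
    } else {
      y <- stats::filter(c(v, rep(0, m - 1)), rev(kern),
        method = "convolution", sides = 1
      )
      W[si, ] <- as.numeric(y[m:(n + m - 1)])
    }
    outside <- pmax(0, shifts + a - (n - 1))
    boundary[si, ] <- outside / a > 0.5
  }
  structure(
    list(
      matrix = W, scales = scales, shifts = shifts,
      dt = 1 / sample_fs(signal), fs = sample_fs(signal),
      centroid = wavelet_centroid(model), boundary = boundary
    ),
    class = "cwt_result"
  )
}

#' @export
print.cwt_result <- function(x, ...) {
  cat(sprintf(
    "<cwt_result> %d scales x %d shifts (fs = %g Hz, scales %g..%g samples)\n",
    length(x$scales), length(x$shifts), x$fs, min(x$scales), max(x$scales)
  ))
  invisible(x)
}

#' Scale-frequency map
#'
#' Holds the wavelet-specific constant `beta` of the relation
#' `a = beta / omega` pairing a dilation `a` (sample units) with a signal
#' frequency (Hz).
#'
#' @param beta Positive constant (Hz x samples).
#' @param fs Sampling rate the calibration refers to.
#' @return A list of class `frequency_map`.
#' @export
frequency_map <- function(beta, fs) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  structure(list(beta = beta, fs = fs), class = "frequency_map")
}

#' Scale matching a target frequency
#'
#' `a = beta / f`: the dilation at which the wavelet's dominant frequency
#' equals the requested signal frequency.
#'
#' @param map A [frequency_map()].
#' @param freq Target frequency in Hz, > 0.
#' @return The scale (sample units).
#' @export
#' @examples
#' scale_for_frequency(frequency_map(250, 250), 5) # 50
scale_for_frequency <- function(map, freq) {
  stopifnot(inherits(map, "frequency_map"))
  if (any(freq <= 0)) stop("frequency must be positive", call. = FALSE)
  map$beta / freq
}

#' Calibrate the scale-frequency constant of a wavelet
#'
#' Finds the spectral-peak frequency of the unit-scale wavelet (cycles per
#' unit support, located by a zero-padded FFT of the densely sampled model)
#' and converts it to `beta = nu_c * fs`, so that
#' `scale_for_frequency(map, f)` returns the dilation at which the dilated
#' wavelet's spectral peak sits at `f` Hz in an `fs`-sampled signal.
#'
#' @param model A fitted wavelet model (or function on [0, 1]).
#' @param fs Sampling rate of the signals to be analyzed (Hz).
#' @param n_fft,pad_factor Spectral grid controls.
#' @return A [frequency_map()].
#' @export
estimate_beta <- function(model, fs, n_fft = 4096, pad_factor = 8) {
  f <- as_wavelet_fun(model)
  dt <- 1 / n_fft
  v <- f((seq_len(n_fft) - 1) * dt)
  npad <- n_fft * pad_factor
  spec <- Mod(stats::fft(c(v, rep(0, npad - n_fft))))
  k <- seq_len(npad %/% 2)
  mag <- spec[k + 1]
  if (max(mag) <= 1e-12 * sqrt(sum(v^2))) {
    stop("flat spectrum: cannot locate a spectral peak", call. = FALSE)
  }
  nu_c <- k[which.max(mag)] / (npad * dt) # cycles per unit support
  frequency_map(beta = nu_c * fs, fs = fs)
}

#' Inverse continuous wavelet transform
#'
#' Reconstructs the signal from its coefficient matrix by discretizing the
#' resolution identity
#' `f(t) = (1/C_psi) * double-integral of W(a,b) psi_ab(t) da db / a^2`,
#' i.e. each coefficient contributes with net weight `a^(-5/2)` (the family's
#' `1/sqrt(a)` combined with `da db / a^2`). The scale measure `da` uses
#' trapezoid weights on the (possibly nonuniform) scale grid; the shift
#' measure is one sample.
#'
#' @param coeffs A `cwt_result` from [cwt()].
#' @param model The same wavelet model used for the forward transform.
#' @param c_psi The admissibility constant of that wavelet (finite, > 0); see
#'   [admissibility_constant()].
#' @return A [wavelet_sample()] on the same time grid as the input signal.
#' @export
icwt <- function(coeffs, model, c_psi) {
  stopifnot(inherits(coeffs, "cwt_result"))
  if (!is.finite(c_psi) || c_psi <= 0) {
    stop("c_psi must be finite and positive", call. = FALSE)
  }
  f <- as_wavelet_fun(model)
  a <- coeffs$scales
  n <- length(coeffs$shifts)
  da <- if (length(a) == 1) {
    1
  } else {
    d <- diff(a)
    c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  }
  out <- numeric(n)
  for (si in seq_along(a)) {
    m <- floor(a[si]) + 1L
    kern <- f((seq_len(m) - 1) / a[si])
    z <- stats::convolve(coeffs$matrix[si, ], rev(kern), type = "open")
    out <- out + a[si]^(-5 / 2) * da[si] * z[seq_len(n)]
  }
  wavelet_sample(out / c_psi, coeffs$fs, label = "icwt reconstruction")
}

#' Localize scalogram peaks at a target scale
#'
#' Finds local maxima of `|W(a, .)|` along the shift axis at the row closest
#' to `expected_scale`, keeps those above half the row maximum, applies
#' non-maximum suppression within `half_window` samples, and corrects the
#' reported positions by the wavelet's energy centroid (`b + a * centroid`)
#' so they point at the detected feature.
#'
#' @param coeffs A `cwt_result`.
#' @param expected_scale Scale at which features are expected (must lie
#'   within the transform's scale range).
#' @param half_window Non-maximum-suppression radius in samples.
#' @return Numeric vector of corrected peak positions (sample indices),
#'   ascending; empty if the row is identically zero.
#' @export
peak_localize <- function(coeffs, expected_scale, half_window = 25) {
  stopifnot(inherits(coeffs, "cwt_result"))
  if (expected_scale < min(coeffs$scales) || expected_scale > max(coeffs$scales)) {
    stop("expected_scale outside the transform's scale range", call. = FALSE)
  }
  si <- which.min(abs(coeffs$scales - expected_scale))
  a <- coeffs$scales[si]
  row <- abs(coeffs$matrix[si, ])
  mx <- max(row)
  if (mx == 0) {
    return(numeric(0))
  }
  thr <- mx / 2
  n <- length(row)
  j <- 2:(n - 1)
  cand <- j[row[j] >= thr & row[j] > row[j - 1] & row[j] >= row[j + 1]]
  if (length(cand) == 0) {
    return(numeric(0))
  }
  kept <- integer(0)
  for (p in cand[order(row[cand], decreasing = TRUE)]) {
    if (all(abs(p - kept) > half_window)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  sort(coeffs$shifts[kept] + a * coeffs$centroid)
}
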