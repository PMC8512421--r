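#' Construct a sampled signal
#'
#' A `wavelet_sample` is a tibble with columns `time` (seconds, starting at 0)
#' and `value` (amplitude, microvolts or normalized units), carrying the
#' sampling rate and a free-text label as attributes. It is the container for
#' both the synthesis exemplar (the "sample" the wavelet is adapted to) and
#' analyzed signals.
#'
#' @param values Numeric vector of amplitudes, length >= 1.
#' @param fs Sampling rate in Hz, > 0.
#' @param label Free-text description of the signal.
#'
#' @return A tibble of class `wavelet_sample` with columns `time` and `value`.
#' @export
#' @examples
#' s <- wavelet_sample(sin(2 * pi * 5 * (0:59) / 250), fs = 250)
#' sample_fs(s)
wavelet_sample <- function(values, fs, label = "") {
  if (!is.numeric(values) || length(values) < 1) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  out <- tibble::tibble(
    time = (seq_along(values) - 1) / fs,
    value = as.numeric(values)
  )
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "label") <- as.character(label)
  class(out) <- c("wavelet_sample", class(out))
  out
}

#' @describeIn wavelet_sample Sampling rate (Hz) of a signal.
#' @param x A `wavelet_sample`.
#' @export
sample_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop("not a wavelet_sample: no `fs` attribute", call. = FALSE)
  fs
}

#' @describeIn wavelet_sample Amplitude vector of a signal.
#' @export
sample_values <- function(x) {
  if (!is.data.frame(x) || is.null(x[["value"]])) {
    stop("expected a wavelet_sample with a `value` column", call. = FALSE)
  }
  x[["value"]]
}

#' @describeIn wavelet_sample Number of samples.
#' @export
sample_length <- function(x) length(sample_values(x))

#' @export
print.wavelet_sample <- function(x, ...) {
  fs <- attr(x, "fs")
  lab <- attr(x, "label")
  n <- nrow(x)
  cat(sprintf(
    "<wavelet_sample> %d samples @ %g Hz (%.4g s)%s\n",
    n, fs, n / fs, if (nzchar(lab)) paste0(" - ", lab) else ""
  ))
  NextMethod()
}

#' Plot a sampled signal
#'
#' @param object A `wavelet_sample`.
#' @param ... Unused.
#' @return A ggplot object (amplitude against time).
#' @export
autoplot.wavelet_sample <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time [s]", y = "amplitude",
      title = attr(object, "label")
    )
}
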