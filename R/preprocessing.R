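# Argument-grid construction and sample modification (tapering) ahead of
# model fitting. Indexing follows the 1-based sample convention k = 1..N.

#' Uniform argument grid on [0, 1]
#'
#' The fitting abscissae for an N-sample fragment: `n` points from 0 to 1 in
#' increments of `1/(n - 1)`.
#'
#' @param n Number of grid points, >= 2.
#' @return Numeric vector of length `n` (class `argument_grid`).
#' @export
#' @examples
#' make_argument_grid(5)
make_argument_grid <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n < 2) {
    stop("argument grid needs n >= 2 points", call. = FALSE)
  }
  g <- seq(0, 1, length.out = as.integer(n))
  class(g) <- c("argument_grid", "numeric")
  g
}

#' Taper specification
#'
#' Describes the window that forces the fragment to zero at its extreme
#' points: an increasing ramp `f1` (0 at k = 1 up to 1 at k = n1), a flat
#' unit section, and a decreasing ramp `f2` (1 at k = n2 down to 0 at k = N).
#' Ramps are linear by default; a raised-cosine option is available.
#'
#' @param n1 Last index of the rising ramp (1-based), >= 1.
#' @param n2 First index of the falling ramp, with `n1 < n2`.
#' @param ramp_kind `"linear"` or `"cosine"`.
#' @return A list of class `taper_spec`.
#' @export
taper_spec <- function(n1, n2, ramp_kind = c("linear", "cosine")) {
  ramp_kind <- match.arg(ramp_kind)
  if (n1 < 1) stop("n1 must be >= 1", call. = FALSE)
  if (n1 >= n2) stop("taper spec requires n1 < n2", call. = FALSE)
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2), ramp_kind = ramp_kind),
    class = "taper_spec"
  )
}

#' Default taper for an N-sample fragment
#'
#' Linear ramps over the outer 10 % of the fragment on each side:
#' `n1 = ceiling(0.1 N)`, `n2 = N - ceiling(0.1 N) + 1`.
#'
#' @param n Fragment length.
#' @return A [taper_spec()].
#' @export
default_taper <- function(n) {
  k <- ceiling(0.1 * n)
  taper_spec(n1 = max(1, k), n2 = min(n, n - k + 1), ramp_kind = "linear")
}

ramp_up <- function(k, n1, kind) {
  if (n1 == 1) {
    return(rep(0, length(k)))
  }
  u <- (k - 1) / (n1 - 1)
  if (kind == "cosine") (1 - cos(pi * u)) / 2 else u
}

ramp_down <- function(k, n2, n, kind) {
  if (n2 == n) {
    return(rep(0, length(k)))
  }
  u <- (n - k) / (n - n2)
  if (kind == "cosine") (1 - cos(pi * u)) / 2 else u
}

#' Taper window weights
#'
#' Evaluates the piecewise window for a fragment of length `n`:
#' `w(k) = f1(k)` for `k in [1, n1]`, 1 for `k in [n1+1, n2-1]`, and
#' `w(k) = f2(k)` for `k in [n2, n]`, with `f1(1) = 0`, `f1(n1) = 1`,
#' `f2(n2) = 1`, `f2(n) = 0`. All weights lie in [0, 1].
#'
#' @param n Fragment length.
#' @param spec A [taper_spec()]; default [default_taper()] for `n`.
#' @return Numeric weight vector of length `n`.
#' @export
#' @examples
#' taper_window(6, taper_spec(2, 5))
taper_window <- function(n, spec = default_taper(n)) {
  stopifnot(inherits(spec, "taper_spec"))
  if (spec$n2 > n) stop("taper spec n2 exceeds fragment length", call. = FALSE)
  k <- seq_len(n)
  w <- rep(1, n)
  up <- k <= spec$n1
  dn <- k >= spec$n2
  w[up] <- ramp_up(k[up], spec$n1, spec$ramp_kind)
  w[dn] <- ramp_down(k[dn], spec$n2, n, spec$ramp_kind)
  # degenerate overlap (n1 >= n2 excluded by the constructor); endpoints exact
  w[1] <- 0
  w[n] <- 0
  w
}

#' Modify (taper) a sample before fitting
#'
#' Multiplies the fragment element-wise by the taper window so the synthesized
#' wavelet is exactly zero at the extreme points of its support.
#'
#' @param sample A [wavelet_sample()].
#' @param spec A [taper_spec()]; defaults to [default_taper()].
#' @return A [wavelet_sample()] with tapered values.
#' @export
modify_sample <- function(sample, spec = default_taper(sample_length(sample))) {
  v <- sample_values(sample)
  w <- taper_window(length(v), spec)
  out <- wavelet_sample(v * w, sample_fs(sample),
    label = paste0(attr(sample, "label"), " [tapered]")
  )
  out
}
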