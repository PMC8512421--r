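# broom-style tidiers and ggplot2 autoplot methods for the package's result
# types.

#' Tidy a fitted wavelet model
#'
#' Returns the model parameters as a long tibble with columns `component`,
#' `index` and `value` (`component` names the parameter group: polynomial
#' coefficient, spline piece coefficient, RBF weight/center/width, MLP layer
#' weight/bias).
#'
#' @param x A `wavelet_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wavelet_model <- function(x, ...) {
  base <- switch(x$kind,
    polynomial = tibble::tibble(
      component = "coefficient",
      index = paste0("a", seq_along(x$coefficients) - 1),
      value = x$coefficients
    ),
    spline = {
      co <- x$coefficients
      tibble::tibble(
        component = "piece_coefficient",
        index = paste0(
          "a", rep(seq_len(nrow(co)) - 1, 4), ",",
          rep(0:3, each = nrow(co))
        ),
        value = as.numeric(co)
      )
    },
    rbf = tibble::tibble(
      component = rep(c("weight", "center", "width"), each = length(x$weights)),
      index = rep(paste0("i", seq_along(x$weights)), 3),
      value = c(x$weights, x$centers, x$widths)
    ),
    mlp = {
      rows <- lapply(seq_along(x$weights), function(l) {
        tibble::tibble(
          component = c(
            rep(sprintf("layer%d_weight", l), length(x$weights[[l]])),
            rep(sprintf("layer%d_bias", l), length(x$biases[[l]]))
          ),
          index = c(
            paste0("w", seq_along(x$weights[[l]])),
            paste0("b", seq_along(x$biases[[l]]))
          ),
          value = c(as.numeric(x$weights[[l]]), x$biases[[l]])
        )
      })
      do.call(rbind, rows)
    }
  )
  rbind(
    base,
    tibble::tibble(
      component = c("offset", "norm_coeff"),
      index = c("", ""),
      value = c(x$offset, x$norm_coeff)
    )
  )
}

#' @describeIn tidy.wavelet_model One-row model summary.
#' @export
glance.wavelet_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    parameter_count = model_complexity(x),
    offset = x$offset,
    norm_coeff = x$norm_coeff,
    n_fit = if (is.null(x$n_fit)) NA_integer_ else x$n_fit
  )
}

#' Tidy a synthesis result
#'
#' @param x A `wavelet_synthesis` from [synthesize_wavelet()].
#' @param ... Unused.
#' @return `tidy()`: the model parameter tibble; `glance()`: a one-row tibble
#'   combining fit deviations, offset and admissibility diagnostics.
#' @export
tidy.wavelet_synthesis <- function(x, ...) tidy(x$model)

#' @rdname tidy.wavelet_synthesis
#' @export
glance.wavelet_synthesis <- function(x, ...) {
  adm <- x$report$admissibility
  tibble::tibble(
    kind = x$model$kind,
    parameter_count = model_complexity(x$model),
    max_deviation = x$report$fit$max_deviation,
    rms_deviation = x$report$fit$rms_deviation,
    offset_iterations = x$report$offset_iterations,
    final_offset = x$report$final_offset,
    norm_coeff = x$report$norm_coeff,
    integral = adm$integral,
    l2_norm = adm$l2_norm,
    c_psi = adm$c_psi,
    admissible = adm$zero_integral_ok && adm$unit_norm_ok && adm$c_psi_finite
  )
}

#' Tidy a CWT coefficient matrix
#'
#' @param x A `cwt_result`.
#' @param ... Unused.
#' @return A long tibble with columns `scale`, `shift`, `time` (seconds),
#'   `coefficient` and `boundary`.
#' @export
tidy.cwt_result <- function(x, ...) {
  tibble::tibble(
    scale = rep(x$scales, times = length(x$shifts)),
    shift = rep(x$shifts, each = length(x$scales)),
    time = rep(x$shifts * x$dt, each = length(x$scales)),
    coefficient = as.numeric(x$matrix),
    boundary = as.logical(x$boundary)
  )
}

#' @describeIn tidy.cwt_result One-row transform summary.
#' @export
glance.cwt_result <- function(x, ...) {
  tibble::tibble(
    n_scales = length(x$scales),
    n_shifts = length(x$shifts),
    fs = x$fs,
    max_abs_coefficient = max(abs(x$matrix))
  )
}

#' Plot a wavelet model on its support
#'
#' @param object A `wavelet_model`.
#' @param n Number of evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wavelet_model <- function(object, n = 512, ...) {
  t <- seq(0, 1, length.out = n)
  df <- tibble::tibble(t = t, psi = evaluate_model(object, t))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$psi)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "t (support)", y = expression(psi(t)),
      title = sprintf("%s wavelet model", object$kind)
    )
}

#' @export
autoplot.wavelet_synthesis <- function(object, ...) autoplot(object$model, ...)

#' Scalogram plot
#'
#' Magnitude image of the coefficient matrix with shift (time) on the
#' horizontal axis and scale ascending bottom-up.
#'
#' @param object A `cwt_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cwt_result <- function(object, ...) {
  df <- tidy(object)
  df$magnitude <- abs(df$coefficient)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$scale,
    fill = .data$magnitude
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time [s]", y = "scale a [samples]", fill = "|W(a,b)|")
}
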