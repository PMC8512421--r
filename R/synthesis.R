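# Admissibility checking, iterative offset correction, normalization, and the
# end-to-end wavelet synthesis orchestrator (grid -> taper -> fit -> integral
# check -> offset loop -> normalize -> admissibility report).

gauss_nodes <- function(n, a = 0, b = 1) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

#' Integral of the un-normalized wavelet model over its support
#'
#' Computes `integral over [0,1] of (raw_model(t) + offset) dt`, the quantity
#' driven to zero by the offset correction. Polynomial and spline families use
#' exact per-piece antiderivatives; RBF and MLP use fixed-order
#' Gauss-Legendre quadrature.
#'
#' @param model A fitted wavelet model.
#' @param quad_points Gauss-Legendre node count for RBF/MLP (default 256).
#' @return Signed area (signal units x unit time).
#' @export
integral_of <- function(model, quad_points = 256) {
  stopifnot(inherits(model, "wavelet_model"))
  raw <- switch(model$kind,
    polynomial = {
      a <- model$coefficients
      sum(a / seq_along(a))
    },
    spline = {
      h <- diff(model$knots)
      co <- model$coefficients
      sum(co[, 1] * h + co[, 2] * h^2 / 2 + co[, 3] * h^3 / 3 +
        co[, 4] * h^4 / 4)
    },
    {
      gl <- gauss_nodes(quad_points)
      sum(gl$w * eval_raw(model, gl$x))
    }
  )
  raw + model$offset
}

# Energy of the full model (norm_coeff applied): integral of psi^2 over [0,1].
# Exact composite quadrature for polynomial/spline (the integrand is a
# polynomial per piece), global Gauss-Legendre for RBF/MLP.
model_energy <- function(model, quad_points = 256) {
  stopifnot(inherits(model, "wavelet_model"))
  e_raw <- switch(model$kind,
    polynomial = {
      gl <- gauss_nodes(max(model$degree + 1, 16))
      sum(gl$w * (eval_raw(model, gl$x) + model$offset)^2)
    },
    spline = {
      gl <- gauss_nodes(4, 0, 1) # degree-6 integrand per piece: exact
      x <- model$knots
      total <- 0
      for (i in seq_len(length(x) - 1)) {
        h <- x[i + 1] - x[i]
        tt <- x[i] + gl$x * h
        total <- total + h * sum(gl$w * (eval_raw(model, tt) + model$offset)^2)
      }
      total
    },
    {
      gl <- gauss_nodes(quad_points)
      sum(gl$w * (eval_raw(model, gl$x) + model$offset)^2)
    }
  )
  model$norm_coeff^2 * e_raw
}

#' Iterative offset correction toward a zero-integral wavelet
#'
#' Displaces the model along the amplitude axis by a constant until the
#' integral over the support is zero within tolerance. The initial (and each
#' subsequent) correction is the current integral divided by the support
#' length, i.e. `offset <- offset - integral`; since the additive constant is
#' exactly representable in every model family, one step suffices in exact
#' arithmetic and the loop guards only against quadrature rounding.
#'
#' @param model A fitted wavelet model.
#' @param grid,values The fitting data (used to scale the tolerance).
#' @param tol Relative zero-integral tolerance (default 1e-8); the absolute
#'   threshold is `tol * max(1, max(abs(values)))`.
#' @param max_iters Iteration cap (default 50).
#' @param quad_points Quadrature order for RBF/MLP integrals.
#' @return A list: `model` (offset-corrected), `iterations`, `converged`.
#' @export
offset_correct <- function(model, grid, values, tol = 1e-8, max_iters = 50,
                           quad_points = 256) {
  thresh <- tol * max(1, max(abs(values)))
  iters <- 0L
  repeat {
    I <- integral_of(model, quad_points)
    if (abs(I) <= thresh || iters >= max_iters) break
    model$offset <- model$offset - I # support length is 1
    iters <- iters + 1L
  }
  list(model = model, iterations = iters, converged = abs(I) <= thresh)
}

#' Normalizing coefficient
#'
#' `Ms = 1 / sqrt(integral of psi^2)` for the model as currently evaluated
#' (offset and any previous normalization included); multiplying the model by
#' `Ms` yields unit L2 norm.
#'
#' @inheritParams offset_correct
#' @return The scalar `Ms`.
#' @export
normalization_coefficient <- function(model, quad_points = 256) {
  e <- model_energy(model, quad_points)
  if (!is.finite(e) || e <= 0) {
    stop("zero-energy model cannot be normalized", call. = FALSE)
  }
  1 / sqrt(e)
}

#' Normalize a wavelet model to unit energy
#'
#' Folds the normalizing coefficient into the model's `norm_coeff`; after the
#' call, `evaluate_model()` has unit L2 norm over [0, 1] within quadrature
#' tolerance. Idempotent: a second call changes `norm_coeff` by a factor of 1.
#'
#' @inheritParams offset_correct
#' @return The normalized model.
#' @export
normalize_wavelet <- function(model, quad_points = 256) {
  ms <- normalization_coefficient(model, quad_points)
  model$norm_coeff <- model$norm_coeff * ms
  model
}

#' Admissibility constant of a wavelet
#'
#' Estimates `C_psi = integral of |psi_hat(omega)|^2 / |omega| d omega` under
#' the Fourier convention `psi_hat(omega) = integral psi(t) exp(-i omega t)
#' dt` (angular frequency): the wavelet is densely sampled on its support,
#' zero-padded, transformed with the FFT, and the spectrum integrated by the
#' trapezoid rule over both signs of omega, excluding the zero bin. Finite
#' `C_psi` requires a zero-integral wavelet, which is enforced as a
#' precondition.
#'
#' @param w A fitted `wavelet_model` (support [0, 1]) or a plain function of
#'   time (e.g. [mexican_hat()]), in which case `support` applies.
#' @param n_fft Number of samples on the support (default 4096).
#' @param pad_factor Zero-padding multiple (default 8).
#' @param support Length-2 support interval for function input
#'   (default `c(-8, 8)`); ignored for models.
#' @param integral_tol Relative bound on the wavelet integral above which the
#'   estimate is refused (`C_psi` diverges for nonzero-mean wavelets).
#' @return The `C_psi` estimate (dimensionless).
#' @export
#' @examples
#' admissibility_constant(mexican_hat) # ~ (8/3) * sqrt(pi) = 4.7276
admissibility_constant <- function(w, n_fft = 4096, pad_factor = 8,
                                   support = NULL, integral_tol = 1e-6) {
  if (inherits(w, "wavelet_model")) {
    support <- c(0, 1)
    f <- function(t) evaluate_model(w, t)
  } else if (is.function(w)) {
    if (is.null(support)) support <- c(-8, 8)
    f <- w
  } else {
    stop("`w` must be a wavelet model or a function", call. = FALSE)
  }
  span <- support[2] - support[1]
  dt <- span / n_fft
  # midpoint sampling: the integral check is O(dt^2) accurate and the
  # half-sample shift only adds linear phase, leaving |psi_hat| unchanged
  t <- support[1] + (seq_len(n_fft) - 0.5) * dt
  v <- f(t)
  scale <- sqrt(sum(v^2) * dt)
  if (scale == 0) stop("wavelet is identically zero", call. = FALSE)
  if (abs(sum(v) * dt) > integral_tol * max(1, scale)) {
    stop(
      "wavelet integral is not zero within tolerance: C_psi diverges; ",
      "run offset correction first",
      call. = FALSE
    )
  }
  npad <- n_fft * pad_factor
  spec <- stats::fft(c(v, rep(0, npad - n_fft))) * dt
  k <- seq_len(npad %/% 2) # positive frequencies, zero bin excluded
  omega <- 2 * pi * k / (npad * dt)
  integrand <- Mod(spec[k + 1])^2 / omega
  d_omega <- omega[2] - omega[1]
  pos <- d_omega * (sum(integrand) - (integrand[1] + integrand[length(k)]) / 2)
  2 * pos # real wavelet: spectrum is even in |.|
}

#' Admissibility report for a wavelet model
#'
#' Checks the two wavelet conditions and the admissibility constant on the
#' final (normalized) model: integral over the support, L2 norm, and the
#' `C_psi` estimate, with pass/fail flags at the given tolerances.
#'
#' @param model A fitted wavelet model.
#' @param zero_tol Relative zero-integral tolerance (default 1e-8).
#' @param norm_tol Unit-norm tolerance (default 1e-8).
#' @param quad_points Quadrature order for RBF/MLP integrals.
#' @param ... Passed to [admissibility_constant()].
#' @return A one-row tibble: `integral`, `l2_norm`, `c_psi`,
#'   `zero_integral_ok`, `unit_norm_ok`, `c_psi_finite`.
#' @export
admissibility_report <- function(model, zero_tol = 1e-8, norm_tol = 1e-8,
                                 quad_points = 256, ...) {
  integral <- model$norm_coeff * integral_of(model, quad_points)
  l2 <- sqrt(model_energy(model, quad_points))
  c_psi <- tryCatch(
    admissibility_constant(model, ...),
    error = function(e) NA_real_
  )
  tibble::tibble(
    integral = integral,
    l2_norm = l2,
    c_psi = c_psi,
    zero_integral_ok = abs(integral) <= zero_tol * max(1, l2),
    unit_norm_ok = abs(l2 - 1) <= norm_tol,
    c_psi_finite = is.finite(c_psi) && c_psi > 0
  )
}

#' Synthesis configuration
#'
#' Collects the tunables of [synthesize_wavelet()]: the model family and its
#' options, the taper, and numerical tolerances.
#'
#' @param model_kind `"polynomial"`, `"spline"`, `"rbf"`, or `"mlp"`.
#' @param degree Polynomial degree (polynomial family).
#' @param bc Spline boundary condition, `"notaknot"` or `"natural"`.
#' @param n_centers RBF center count; `NULL` means one per grid point.
#' @param width_factor RBF width multiplier.
#' @param hidden MLP hidden layer sizes.
#' @param activation MLP activation, `"tanh"` or `"logistic"`.
#' @param seed MLP initialization seed.
#' @param max_epochs MLP training iteration cap.
#' @param taper A [taper_spec()], or `NULL` for [default_taper()].
#' @param zero_integral_tol Relative zero-integral tolerance.
#' @param max_offset_iters Offset-correction iteration cap.
#' @param quad_points Gauss-Legendre order for RBF/MLP quadrature.
#' @return A list of class `synthesis_config`.
#' @export
synthesis_config <- function(model_kind = c("spline", "polynomial", "rbf", "mlp"),
                             degree = 12, bc = "notaknot", n_centers = NULL,
                             width_factor = 1, hidden = c(15),
                             activation = "tanh", seed = 1, max_epochs = 5000,
                             taper = NULL, zero_integral_tol = 1e-8,
                             max_offset_iters = 50, quad_points = 256) {
  model_kind <- match.arg(model_kind)
  stopifnot(zero_integral_tol > 0, max_offset_iters >= 1)
  structure(
    list(
      model_kind = model_kind, degree = degree, bc = bc,
      n_centers = n_centers, width_factor = width_factor, hidden = hidden,
      activation = activation, seed = seed, max_epochs = max_epochs,
      taper = taper, zero_integral_tol = zero_integral_tol,
      max_offset_iters = max_offset_iters, quad_points = quad_points
    ),
    class = "synthesis_config"
  )
}

#' Synthesize a mother wavelet from a signal fragment
#'
#' The end-to-end adapted-wavelet pipeline: build the argument grid, taper the
#' fragment so it vanishes at the support endpoints, fit the chosen model
#' family, record fit deviations (before normalization), correct the offset
#' until the integral is zero, normalize to unit energy, and check
#' admissibility. The result is a valid mother wavelet on [0, 1] adapted to
#' the fragment's shape.
#'
#' @param sample A [wavelet_sample()] of length >= 4 (the exemplar fragment).
#' @param config A [synthesis_config()].
#' @return An object of class `wavelet_synthesis`: a list with `model` (the
#'   normalized wavelet model) and `report` (fit deviations, offset
#'   iterations, final offset, normalizing coefficient, admissibility).
#' @export
#' @examples
#' s <- gen_eye_artifact_sample(60, 250, 100, seed = 1)
#' syn <- synthesize_wavelet(s, synthesis_config("spline"))
#' syn$report$admissibility
synthesize_wavelet <- function(sample, config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  v <- sample_values(sample)
  n <- length(v)
  if (n < 4) stop("sample must have at least 4 points", call. = FALSE)
  grid <- make_argument_grid(n)
  taper <- if (is.null(config$taper)) default_taper(n) else config$taper
  tapered <- modify_sample(sample, taper)
  tv <- sample_values(tapered)
  model <- switch(config$model_kind,
    polynomial = fit_polynomial(grid, tv, degree = config$degree),
    spline = fit_spline(grid, tv, bc = config$bc),
    rbf = fit_rbf(grid, tv,
      n_centers = if (is.null(config$n_centers)) n else config$n_centers,
      width_factor = config$width_factor
    ),
    mlp = fit_mlp(grid, tv,
      hidden = config$hidden, activation = config$activation,
      seed = config$seed, max_epochs = config$max_epochs
    )
  )
  fit <- fit_deviations(model, grid, tv)
  oc <- offset_correct(model, grid, tv,
    tol = config$zero_integral_tol,
    max_iters = config$max_offset_iters,
    quad_points = config$quad_points
  )
  model <- oc$model
  ms <- normalization_coefficient(model, config$quad_points)
  model <- normalize_wavelet(model, config$quad_points)
  # final polish: zero the *normalized* integral at unit scale; the induced
  # energy change is O(integral^2), far below the unit-norm tolerance
  iters <- oc$iterations
  I_un <- integral_of(model, config$quad_points)
  if (abs(model$norm_coeff * I_un) > config$zero_integral_tol) {
    model$offset <- model$offset - I_un
    iters <- iters + 1L
  }
  adm <- admissibility_report(model,
    zero_tol = config$zero_integral_tol,
    quad_points = config$quad_points
  )
  out <- list(
    model = model,
    report = list(
      fit = fit,
      offset_iterations = iters,
      offset_converged = oc$converged,
      final_offset = model$offset,
      norm_coeff = ms,
      admissibility = adm,
      taper = taper,
      config = config
    )
  )
  class(out) <- "wavelet_synthesis"
  out
}

#' @export
print.wavelet_synthesis <- function(x, ...) {
  cat(sprintf(
    "<wavelet_synthesis: %s>\n  parameters: %d\n  deviations (max/rms): %.4g / %.4g\n  offset: %.6g (%d iteration(s))\n  norm coeff: %.6g\n  integral: %.3g | L2 norm: %.8f | C_psi: %.4g\n",
    x$model$kind, model_complexity(x$model),
    x$report$fit$max_deviation, x$report$fit$rms_deviation,
    x$report$final_offset, x$report$offset_iterations,
    x$report$norm_coeff,
    x$report$admissibility$integral, x$report$admissibility$l2_norm,
    x$report$admissibility$c_psi
  ))
  invisible(x)
}
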