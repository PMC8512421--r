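# Serialization: signals as commented CSV, wavelet models as schema-versioned
# JSON, coefficient matrices as CSV (first row shifts, first column scales).

MODEL_SCHEMA_VERSION <- "1.0"

#' Read a signal from CSV
#'
#' Accepts one-column (`value`) or two-column (`time,value`) CSV with the
#' sampling rate in a header comment of the form `# fs=<Hz>`. If the file has
#' no `fs` comment, the rate must be supplied.
#'
#' @param path File path.
#' @param fs Sampling rate override (Hz); required when absent from the file.
#' @return A [wavelet_sample()].
#' @export
read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty signal file: ", path, call. = FALSE)
  comment <- grepl("^\\s*#", lines)
  fs_line <- grep("^\\s*#\\s*fs\\s*=", lines, value = TRUE)
  if (length(fs_line) > 0) {
    fs <- as.numeric(sub("^\\s*#\\s*fs\\s*=\\s*", "", fs_line[1]))
  }
  if (is.null(fs) || !is.finite(fs)) {
    stop("sampling rate missing: no `# fs=<Hz>` header and no `fs` argument",
      call. = FALSE
    )
  }
  label_line <- grep("^\\s*#\\s*label\\s*=", lines, value = TRUE)
  label <- if (length(label_line) > 0) {
    sub("^\\s*#\\s*label\\s*=\\s*", "", label_line[1])
  } else {
    ""
  }
  body_idx <- which(!comment & nzchar(trimws(lines)))
  if (length(body_idx) == 0) stop("no data rows in ", path, call. = FALSE)
  body <- lines[body_idx]
  has_header <- grepl("[A-Za-z]", body[1])
  first_data <- if (has_header) 2L else 1L
  if (length(body) < first_data) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(body[first_data:length(body)], ",")
  ncol <- length(parts[[1]])
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)) || length(v) != ncol, logical(1)))
  if (length(bad) > 0) {
    stop(sprintf(
      "non-numeric or ragged row at line %d of %s",
      body_idx[first_data - 1 + bad[1]], path
    ), call. = FALSE)
  }
  m <- do.call(rbind, vals)
  values <- if (ncol >= 2) m[, 2] else m[, 1]
  wavelet_sample(values, fs, label = label)
}

#' Write a signal to CSV
#'
#' Two-column `time,value` CSV with `# fs=` (and `# label=`) header comments,
#' round-trippable through [read_signal_csv()].
#'
#' @param sample A [wavelet_sample()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sample, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", sample_fs(sample)), con)
  lab <- attr(sample, "label")
  if (!is.null(lab) && nzchar(lab)) writeLines(paste0("# label=", lab), con)
  writeLines("time,value", con)
  writeLines(sprintf("%.17g,%.17g", sample$time, sample$value), con)
  invisible(path)
}

model_parameters <- function(model) {
  switch(model$kind,
    polynomial = list(
      degree = model$degree,
      coefficients = model$coefficients,
      condition_number = model$condition_number,
      condition_warning = model$condition_warning
    ),
    spline = list(
      knots = model$knots,
      coefficients = model$coefficients,
      bc = model$bc
    ),
    rbf = list(
      centers = model$centers,
      weights = model$weights,
      widths = model$widths,
      bias = model$bias
    ),
    mlp = list(
      layer_sizes = model$layer_sizes,
      weights = model$weights,
      biases = model$biases,
      activation = model$activation,
      seed = model$seed,
      loss_initial = model$loss_initial,
      loss_final = model$loss_final
    )
  )
}

#' Save a wavelet model as JSON
#'
#' Writes a schema-versioned, human-readable document with a `kind`
#' discriminator, the kind-specific parameters, the additive offset and the
#' normalizing coefficient, plus free-form provenance. Numbers are written at
#' full precision so that a save/load round trip reproduces
#' [evaluate_model()] output bit-exactly.
#'
#' @param model A fitted wavelet model.
#' @param path Output file path.
#' @param provenance Optional named list (e.g. source label, seeds).
#' @return `path`, invisibly.
#' @export
save_model_json <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "wavelet_model"))
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    kind = model$kind,
    offset = model$offset,
    norm_coeff = model$norm_coeff,
    n_fit = model$n_fit,
    parameters = model_parameters(model),
    provenance = provenance
  )
  # digits = I(17): significant digits, enough for binary64 round trips
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = I(17), pretty = TRUE
  )
  invisible(path)
}

require_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop(sprintf("malformed model document: missing key `%s` in %s", key, where),
      call. = FALSE
    )
  }
  x[[key]]
}

#' Load a wavelet model from JSON
#'
#' Inverse of [save_model_json()]; rejects unknown schema versions and
#' documents with missing keys, naming the offending key.
#'
#' @param path File path.
#' @return A `wavelet_model`.
#' @export
load_model_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ver <- require_key(doc, "schema_version", "document")
  if (!identical(ver, MODEL_SCHEMA_VERSION)) {
    stop("unknown model schema_version: ", ver, call. = FALSE)
  }
  kind <- require_key(doc, "kind", "document")
  if (!kind %in% c("polynomial", "spline", "rbf", "mlp")) {
    stop("unknown model kind: ", kind, call. = FALSE)
  }
  offset <- require_key(doc, "offset", "document")
  norm_coeff <- require_key(doc, "norm_coeff", "document")
  p <- require_key(doc, "parameters", "document")
  fields <- switch(kind,
    polynomial = list(
      coefficients = as.numeric(require_key(p, "coefficients", "parameters")),
      degree = as.integer(require_key(p, "degree", "parameters")),
      condition_number = p$condition_number,
      condition_warning = isTRUE(p$condition_warning)
    ),
    spline = list(
      knots = as.numeric(require_key(p, "knots", "parameters")),
      coefficients = {
        co <- require_key(p, "coefficients", "parameters")
        matrix(as.numeric(co), nrow = nrow(co), ncol = ncol(co))
      },
      bc = require_key(p, "bc", "parameters")
    ),
    rbf = list(
      centers = as.numeric(require_key(p, "centers", "parameters")),
      weights = as.numeric(require_key(p, "weights", "parameters")),
      widths = as.numeric(require_key(p, "widths", "parameters")),
      bias = require_key(p, "bias", "parameters")
    ),
    mlp = {
      ws <- require_key(p, "weights", "parameters")
      bs <- require_key(p, "biases", "parameters")
      list(
        layer_sizes = as.integer(require_key(p, "layer_sizes", "parameters")),
        weights = lapply(ws, function(w) {
          if (is.matrix(w)) w else matrix(as.numeric(w), nrow = 1)
        }),
        biases = lapply(bs, as.numeric),
        activation = require_key(p, "activation", "parameters"),
        seed = p$seed,
        loss_initial = p$loss_initial,
        loss_final = p$loss_final
      )
    }
  )
  fields$n_fit <- doc$n_fit
  m <- new_wavelet_model(kind, fields)
  m$offset <- offset
  m$norm_coeff <- norm_coeff
  m
}

#' Export a coefficient matrix to CSV
#'
#' Layout: comment header (`# fs=`, `# centroid=`), then the shift indices as
#' the first row (leading cell empty) and each subsequent row a scale followed
#' by its coefficients — readable back with [read_cwt_csv()].
#'
#' @param coeffs A `cwt_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cwt_csv <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "cwt_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", coeffs$fs), con)
  writeLines(sprintf("# centroid=%.17g", coeffs$centroid), con)
  writeLines(paste(c("", coeffs$shifts), collapse = ","), con)
  body <- cbind(coeffs$scales, coeffs$matrix)
  utils::write.table(body, con,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a coefficient matrix from CSV
#'
#' @param path File written by [write_cwt_csv()].
#' @return A `cwt_result` (the `boundary` flags are not stored in the CSV and
#'   are returned as all-`FALSE`).
#' @export
read_cwt_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", grep("^#\\s*fs=", lines, value = TRUE)[1]))
  centroid <- as.numeric(sub(
    "^#\\s*centroid\\s*=\\s*", "",
    grep("^#\\s*centroid=", lines, value = TRUE)[1]
  ))
  body <- lines[!grepl("^#", lines)]
  first <- strsplit(body[1], ",")[[1]]
  shifts <- as.numeric(first[-1])
  rows <- strsplit(body[-1], ",")
  m <- do.call(rbind, lapply(rows, as.numeric))
  structure(
    list(
      matrix = m[, -1, drop = FALSE], scales = m[, 1], shifts = shifts,
      dt = 1 / fs, fs = fs,
      centroid = if (is.finite(centroid)) centroid else 0.5,
      boundary = matrix(FALSE, nrow(m), length(shifts))
    ),
    class = "cwt_result"
  )
}
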