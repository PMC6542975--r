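#' Moisture content relative to solid content
#'
#' Dry-basis-like moisture `M = (m_t - s * m_o) / (s * m_o)` in grams of water
#' per gram of solids, where `m_o` is the initial sample weight, `m_t` the
#' weight at time t, and `s` the initial solid fraction (default 0.13, the
#' conventional assumption for onion bulbs).  `M` is strictly increasing in
#' `m_t` and strictly decreasing in `s`.
#'
#' @param m_t current weight in g, > 0 (vectorised).
#' @param m_o initial weight in g, > 0.
#' @param s initial solid fraction in (0, 1).
#' @return moisture content in g/g.  Weights below the bone-dry estimate
#'   `s * m_o` yield a negative value with a warning.
#' @examples
#' moisture_from_weight(90, 96)
#' @export
moisture_from_weight <- function(m_t, m_o, s = 0.13) {
  if (any(m_o <= 0) || any(m_t <= 0)) stop("weights must be > 0", call. = FALSE)
  if (s <= 0 || s >= 1) stop("solid fraction s must lie in (0, 1)", call. = FALSE)
  M <- (m_t - s * m_o) / (s * m_o)
  if (any(M < 0)) {
    warning("weight below the bone-dry estimate s * m_o: negative moisture content")
  }
  M
}

#' Impedance per unit weight
#'
#' Normalises an impedance magnitude by the sample mass, `Zpu = |Z| /
#' (weight_g / 1000)` in ohm/kg, compensating for size differences between
#' samples.
#'
#' @param z_mod impedance modulus in ohm.
#' @param weight_g sample weight in g, > 0.
#' @return impedance per unit weight in ohm/kg.
#' @examples
#' impedance_per_unit_weight(2500, 80)
#' @export
impedance_per_unit_weight <- function(z_mod, weight_g) {
  if (any(weight_g <= 0)) stop("weight_g must be > 0", call. = FALSE)
  z_mod / (weight_g / 1000)
}

#' Polynomial moisture calibration
#'
#' Ordinary least-squares polynomial regression of moisture content on an
#' impedance predictor (|Z| at a spot frequency, or impedance per unit
#' weight), with the usual performance indices: `SSE = sum((M - Mhat)^2)`,
#' `R^2 = 1 - SSE / sum((M - mean(M))^2)` and `RMSE = sqrt(SSE / N)`.
#'
#' @param moisture moisture contents in g/g (response).
#' @param predictor impedance predictor values (same length).
#' @param degree polynomial degree, 1 or 2.
#' @param predictor_type `"impedance_at_frequency"` or
#'   `"impedance_per_unit_weight"` (bookkeeping only).
#' @param frequency_hz spot frequency of the predictor, if applicable.
#' @return an object of class `moisture_calibration`: `coefficients` ordered
#'   high-to-low degree, `sse`, `r_squared`, `rmse`, `predictor_range`, `n`.
#' @examples
#' z <- c(20, 60, 110, 150, 190)
#' M <- -2e-4 * z + 7.3
#' fit_calibration(M, z, degree = 1)
#' @export
fit_calibration <- function(moisture, predictor, degree = 1,
                            predictor_type = c("impedance_at_frequency",
                                               "impedance_per_unit_weight"),
                            frequency_hz = NA_real_) {
  predictor_type <- match.arg(predictor_type)
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2", call. = FALSE)
  n <- length(moisture)
  if (length(predictor) != n) {
    stop("moisture and predictor must have equal length", call. = FALSE)
  }
  if (n < degree + 2) {
    stop(sprintf("need at least %d points for a degree-%d calibration",
                 degree + 2, degree), call. = FALSE)
  }
  if (length(unique(predictor)) < degree + 1) {
    stop("rank-deficient design: predictor values are (nearly) constant",
         call. = FALSE)
  }
  dat <- data.frame(M = moisture, x = predictor)
  form <- if (degree == 1) M ~ x else M ~ x + I(x^2)
  fit <- stats::lm(form, data = dat)
  co <- stats::coef(fit)
  if (any(!is.finite(co))) {
    stop("rank-deficient design: calibration fit failed", call. = FALSE)
  }
  coefficients <- rev(unname(co))  # high -> low degree
  fitted_vals <- stats::fitted(fit)
  sse <- sum((moisture - fitted_vals)^2)
  tss <- sum((moisture - mean(moisture))^2)
  structure(list(
    predictor = predictor_type,
    frequency_hz = frequency_hz,
    degree = degree,
    coefficients = coefficients,
    sse = sse,
    r_squared = if (tss > 0) 1 - sse / tss else NA_real_,
    rmse = sqrt(sse / n),
    predictor_range = range(predictor),
    n = n
  ), class = "moisture_calibration")
}

#' Construct a calibration from known coefficients
#'
#' Wraps published polynomial coefficients (ordered high-to-low degree) as a
#' `moisture_calibration` usable with [predict_moisture()], without fit
#' statistics.
#'
#' @param coefficients numeric vector, high-to-low degree (length = degree+1).
#' @inheritParams fit_calibration
#' @export
moisture_calibration <- function(coefficients,
                                 predictor_type = c("impedance_at_frequency",
                                                    "impedance_per_unit_weight"),
                                 frequency_hz = NA_real_) {
  predictor_type <- match.arg(predictor_type)
  degree <- length(coefficients) - 1L
  if (!degree %in% c(1L, 2L)) stop("coefficients must have length 2 or 3", call. = FALSE)
  structure(list(predictor = predictor_type, frequency_hz = frequency_hz,
                 degree = degree, coefficients = as.numeric(coefficients),
                 sse = NA_real_, r_squared = NA_real_, rmse = NA_real_,
                 predictor_range = c(NA_real_, NA_real_), n = NA_integer_),
            class = "moisture_calibration")
}

#' @export
print.moisture_calibration <- function(x, ...) {
  terms <- rev(seq_along(x$coefficients)) - 1L
  poly <- paste(sprintf("%+.6g*x^%d", x$coefficients, terms), collapse = " ")
  cat(sprintf("moisture calibration (degree %d, %s%s)\n  M(x) = %s\n",
              x$degree, x$predictor,
              if (is.finite(x$frequency_hz)) sprintf(" @ %g Hz", x$frequency_hz) else "",
              poly))
  if (is.finite(x$sse)) {
    cat(sprintf("  SSE = %.6g, R^2 = %.6g, RMSE = %.6g (n = %d)\n",
                x$sse, x$r_squared, x$rmse, x$n))
  }
  invisible(x)
}

#' Predict moisture content from a calibration
#'
#' Evaluates the calibration polynomial (coefficients ordered high-to-low) at
#' the given predictor value(s).  Extrapolation beyond the calibration's
#' stored predictor range is permitted; the result then carries the attribute
#' `extrapolated = TRUE`.
#'
#' @param calibration a `moisture_calibration`.
#' @param predictor_value predictor value(s) (ohm or ohm/kg).
#' @return predicted moisture in g/g.
#' @examples
#' eq6 <- moisture_calibration(c(-0.0002442, 0.03636, 5.346),
#'                             "impedance_per_unit_weight", 10000)
#' predict_moisture(eq6, 0)
#' @export
predict_moisture <- function(calibration, predictor_value) {
  co <- calibration$coefficients
  M <- rep(0, length(predictor_value))
  for (c_i in co) M <- M * predictor_value + c_i
  rng <- calibration$predictor_range
  if (all(is.finite(rng)) &&
      any(predictor_value < rng[1] | predictor_value > rng[2])) {
    attr(M, "extrapolated") <- TRUE
  }
  M
}

#' Per-frequency moisture calibrations over a drying dataset
#'
#' For each requested spot frequency, regresses the moisture content of every
#' (sample, day) record — computed from the drying weights via
#' [moisture_from_weight()] — on the impedance magnitude |Z| at that
#' frequency, pooled over all samples and days.  Frequencies are matched to
#' the spectra's grid by nearest point within 1% relative tolerance.
#'
#' @param dataset a `drying_dataset` (see [simulate_drying()]) or any list
#'   with a `records` data frame (`day`, `sample_id`, `weight_g`) and a
#'   `spectra` list keyed by `record_key(sample_id, day)`.
#' @param frequencies spot frequencies in Hz.
#' @param degree polynomial degree (the per-frequency sweep uses 1).
#' @param s initial solid fraction for the moisture computation; defaults to
#'   the dataset's configured value, else 0.13.
#' @return list of `moisture_calibration` objects sorted by `r_squared`
#'   descending; `as.data.frame()` gives a summary table.
#' @export
calibration_sweep <- function(dataset, frequencies, degree = 1, s = NULL) {
  if (is.null(s)) {
    s <- if (!is.null(dataset$config$solid_fraction)) dataset$config$solid_fraction else 0.13
  }
  rec <- dataset$records
  m_o <- tapply(rec$weight_g, rec$sample_id, function(w) w[1])
  ## weight at the earliest day per sample
  first_day <- tapply(rec$day, rec$sample_id, min)
  for (sid in names(m_o)) {
    m_o[[sid]] <- rec$weight_g[rec$sample_id == sid & rec$day == first_day[[sid]]][1]
  }
  M <- moisture_from_weight(rec$weight_g, unname(m_o[rec$sample_id]), s)

  keys <- record_key(rec$sample_id, rec$day)
  grid <- dataset$spectra[[keys[1]]]$frequency_hz
  cals <- lapply(frequencies, function(f) {
    idx <- which.min(abs(grid - f))
    if (abs(grid[idx] - f) > 0.01 * f) {
      stop(sprintf("frequency %g Hz not present in the spectra grid (nearest: %g Hz)",
                   f, grid[idx]), call. = FALSE)
    }
    zmod <- vapply(keys, function(k) {
      sp <- dataset$spectra[[k]]
      sqrt(sp$re_ohm[idx]^2 + sp$im_ohm[idx]^2)
    }, numeric(1))
    fit_calibration(M, unname(zmod), degree = degree,
                    predictor_type = "impedance_at_frequency",
                    frequency_hz = grid[idx])
  })
  cals[order(vapply(cals, `[[`, numeric(1), "r_squared"), decreasing = TRUE)]
}

#' Summary table for a list of calibrations
#'
#' @param calibrations list of `moisture_calibration` objects.
#' @return data frame with one row per calibration.
#' @export
calibration_table <- function(calibrations) {
  do.call(rbind, lapply(calibrations, function(cal) {
    data.frame(frequency_hz = cal$frequency_hz, degree = cal$degree,
               slope = cal$coefficients[1],
               intercept = cal$coefficients[length(cal$coefficients)],
               sse = cal$sse, r_squared = cal$r_squared, rmse = cal$rmse,
               n = cal$n)
  }))
}

#' Serialise / deserialise calibrations as JSON
#'
#' @param calibration a `moisture_calibration`.
#' @param path JSON file path.
#' @param metadata optional named list merged into the JSON object.
#' @export
write_calibration <- function(calibration, path, metadata = NULL) {
  obj <- unclass(calibration)
  if (!is.null(metadata)) obj <- c(obj, metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(predictor = obj$predictor,
                 frequency_hz = as.numeric(obj$frequency_hz %||% NA_real_),
                 degree = as.integer(obj$degree),
                 coefficients = as.numeric(obj$coefficients),
                 sse = as.numeric(obj$sse %||% NA_real_),
                 r_squared = as.numeric(obj$r_squared %||% NA_real_),
                 rmse = as.numeric(obj$rmse %||% NA_real_),
                 predictor_range = as.numeric(obj$predictor_range %||% c(NA_real_, NA_real_)),
                 n = as.integer(obj$n %||% NA_integer_)),
            class = "moisture_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
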