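#' Fitting options
#'
#' Options for the complex nonlinear least-squares fit of [fit_model()].
#'
#' @param weighting `"modulus"` (default) divides each real/imaginary residual
#'   by the measured |Z| at that frequency, making the objective scale-free
#'   across spectra spanning orders of magnitude; `"unit"` uses raw ohm
#'   residuals.
#' @param max_iterations simplex iteration cap per Nelder-Mead pass.
#' @param xtol_rel relative improvement threshold between successive simplex
#'   passes; a fresh pass is started from the current best vertex until the
#'   objective improves by less than this fraction.
#' @param ftol_rel relative convergence tolerance of each simplex pass.
#' @param n_restarts number of additional jittered starting points (log-uniform
#'   factor in \[0.2, 5\] around the initial point), guarding against local
#'   minima of the multi-modal CNLS surface.
#' @param seed integer seed making the restart jitter reproducible.
#' @return a list of class `fit_options`.
#' @export
fit_options <- function(weighting = c("modulus", "unit"),
                        max_iterations = 10000,
                        xtol_rel = 1e-10, ftol_rel = 1e-10,
                        n_restarts = 4, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(max_iterations >= 1, xtol_rel > 0, ftol_rel > 0, n_restarts >= 0)
  structure(list(weighting = weighting,
                 max_iterations = as.integer(max_iterations),
                 xtol_rel = xtol_rel, ftol_rel = ftol_rel,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "fit_options")
}

#' Stacked real/imaginary residual vector
#'
#' Residuals between the model spectrum of `circuit` at `params` and the
#' measured spectrum, interleaved per frequency as (Re_1, Im_1, Re_2, Im_2,
#' ...).  Under modulus weighting each pair is divided by the measured |Z| at
#' that frequency.
#'
#' @param circuit a [circuit_model].
#' @param params named parameter vector.
#' @param spectrum measured [impedance_spectrum()].
#' @param weighting `"modulus"` or `"unit"`.
#' @return numeric vector of length `2 * nrow(spectrum)`.
#' @export
residual_vector <- function(circuit, params, spectrum,
                            weighting = c("modulus", "unit")) {
  weighting <- match.arg(weighting)
  if (nrow(spectrum) == 0) stop("spectrum is empty", call. = FALSE)
  model <- evaluate_circuit(circuit, params, spectrum$frequency_hz)
  dre <- model$re_ohm - spectrum$re_ohm
  dim_ <- model$im_ohm - spectrum$im_ohm
  if (weighting == "modulus") {
    zmod <- spectrum_modulus(spectrum)
    if (any(zmod == 0)) {
      stop("modulus weighting undefined: measured |Z| = 0 at some point",
           call. = FALSE)
    }
    dre <- dre / zmod
    dim_ <- dim_ / zmod
  }
  as.numeric(rbind(dre, dim_))
}

## parameter transform: log10 for R/C/P scale parameters, identity for CPE
## exponents (names ending in ".n"), which are clipped into (0, 1].
is_exponent_param <- function(param_names) grepl("(^|\\.)n$", param_names)

transform_params <- function(values, expo) {
  out <- values
  out[!expo] <- log10(values[!expo])
  out
}

untransform_params <- function(theta, expo, lower, upper) {
  out <- theta
  out[!expo] <- 10^pmin(pmax(theta[!expo], log10(lower[!expo])),
                        log10(upper[!expo]))
  out[expo] <- pmin(pmax(theta[expo], lower[expo]), upper[expo])
  out
}

#' Fit an equivalent circuit to a measured spectrum
#'
#' Minimises the sum of squared [residual_vector()] entries by Nelder-Mead
#' simplex.  Resistances, capacitances and CPE pre-exponential factors are
#' optimised as log10 values (guaranteeing positivity and respecting the
#' model's bounds); CPE exponents are optimised directly and clipped into
#' (0, 1].  The search runs from the initial point plus `n_restarts` jittered
#' copies; within each start, fresh simplex passes are launched from the best
#' vertex until the objective stops improving, which restores the precision a
#' single collapsing simplex loses.  Deterministic given `options$seed`.
#'
#' @param circuit a [circuit_model], built-in name, or expression string.
#' @param spectrum measured [impedance_spectrum()]; must provide at least as
#'   many data values (2 per frequency) as free parameters.
#' @param options a [fit_options()] list.
#' @param init named initial parameter vector; default `NULL` derives starting
#'   values from the spectrum geometry via [estimate_initial()].
#' @return an object of class `fit_result`: optimised `parameters`, the final
#'   `objective`, [goodness_of_fit()] `metrics`, a `converged` flag, the total
#'   Nelder-Mead iteration count and an evaluation `trace` of the running best
#'   objective.
#' @examples
#' truth <- builtin_model("simplified_hayden")
#' s <- evaluate_circuit(truth, frequencies = 10^seq(log10(500), 4, length.out = 27))
#' fit <- fit_model(truth, s, fit_options(n_restarts = 0))
#' fit$parameters
#' @export
fit_model <- function(circuit, spectrum, options = fit_options(), init = NULL) {
  circuit <- as_circuit_model(circuit)
  pnames <- names(circuit$parameters)
  k <- length(pnames)
  if (2 * nrow(spectrum) < k) {
    stop(sprintf("spectrum provides %d values for %d free parameters",
                 2 * nrow(spectrum), k), call. = FALSE)
  }
  if (is.null(init)) {
    init <- estimate_initial(circuit, spectrum)
  } else {
    init <- unlist(init)[pnames]
    if (any(is.na(init))) stop("init must name every circuit parameter", call. = FALSE)
  }
  expo <- is_exponent_param(pnames)
  lower <- circuit$lower[pnames]
  upper <- circuit$upper[pnames]
  init <- pmin(pmax(init, lower), upper)

  best_trace <- numeric(0)
  n_evals <- 0L
  objective_fn <- function(theta) {
    p <- untransform_params(theta, expo, lower, upper)
    names(p) <- pnames
    val <- tryCatch(sum(residual_vector(circuit, p, spectrum, options$weighting)^2),
                    error = function(e) Inf)
    if (!is.finite(val)) val <- 1e300
    n_evals <<- n_evals + 1L
    best_trace <<- c(best_trace,
                     if (length(best_trace) == 0) val else min(val, best_trace[length(best_trace)]))
    val
  }

  theta0 <- transform_params(init, expo)
  f0 <- objective_fn(theta0)
  if (f0 >= 1e300) {
    stop("objective is non-finite at the initial point", call. = FALSE)
  }

  starts <- list(theta0)
  if (options$n_restarts > 0) {
    with_local_seed(options$seed, {
      for (r in seq_len(options$n_restarts)) {
        th <- theta0
        th[!expo] <- th[!expo] + stats::runif(sum(!expo), log10(0.2), log10(5))
        th[expo] <- pmin(pmax(th[expo] * stats::runif(sum(expo), 0.6, 1.2), 0.05), 1)
        starts[[r + 1L]] <- th
      }
    })
  }

  best <- NULL
  for (th in starts) {
    res <- run_simplex(objective_fn, th, options)
    if (is.null(best) || res$value < best$value) best <- res
  }
  total_iter <- n_evals

  params <- untransform_params(best$theta, expo, lower, upper)
  names(params) <- pnames
  fitted <- evaluate_circuit(circuit, params, spectrum$frequency_hz)
  ## percentage metrics are undefined when a measured component is exactly 0
  ## (e.g. a purely resistive spectrum); keep the fit, drop the metrics
  metrics <- tryCatch(goodness_of_fit(fitted, spectrum), error = function(e) NULL)
  structure(list(
    model_name = circuit$name,
    expression = circuit$expression,
    parameters = params,
    objective = best$value,
    metrics = metrics,
    converged = best$converged,
    n_iterations = total_iter,
    weighting = options$weighting,
    seed = options$seed,
    trace = best_trace
  ), class = "fit_result")
}

## repeated Nelder-Mead passes from the current best point; optim's simplex
## collapses near the optimum, a fresh simplex there recovers precision.
run_simplex <- function(fn, theta, options, max_passes = 25L) {
  value <- fn(theta)
  converged <- FALSE
  for (pass in seq_len(max_passes)) {
    res <- if (length(theta) == 1) {
      ## one-dimensional Nelder-Mead is unreliable; optim itself recommends
      ## Brent in 1-D, bracket generously around the current point
      o <- stats::optim(theta, fn, method = "Brent",
                        lower = theta - 6, upper = theta + 6,
                        control = list(maxit = options$max_iterations))
      list(par = o$par, value = o$value, convergence = o$convergence)
    } else {
      stats::optim(theta, fn, method = "Nelder-Mead",
                   control = list(maxit = options$max_iterations,
                                  reltol = options$ftol_rel))
    }
    improvement <- value - res$value
    if (res$value < value) {
      theta <- res$par
      value <- res$value
    }
    converged <- res$convergence == 0
    if (converged && improvement <= options$xtol_rel * (abs(value) + 1e-300)) break
  }
  list(theta = theta, value = value, converged = converged)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit of '%s' (%s weighting): objective %.6g, %s after %d iterations\n",
              x$model_name, x$weighting, x$objective,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  print(x$parameters)
  if (!is.null(x$metrics)) {
    cat(sprintf("  MAE%%: real %.4g imag %.4g | RMSE%%: real %.4g imag %.4g\n",
                x$metrics$mae_real_pct, x$metrics$mae_imag_pct,
                x$metrics$rmse_real_pct, x$metrics$rmse_imag_pct))
  }
  invisible(x)
}

#' Percentage-error goodness-of-fit metrics
#'
#' Mean absolute and root-mean-squared percentage errors of the real and
#' imaginary parts, each relative to the measured component at that frequency:
#' `mae_real_pct = (100/N) sum |Re_fit - Re_meas| / |Re_meas|` and
#' `rmse_real_pct = 100 sqrt((1/N) sum ((Re_fit - Re_meas)/Re_meas)^2)`,
#' analogously for the imaginary part.  All four are zero iff the spectra
#' coincide, and are invariant under a common rescaling of both spectra.
#'
#' @param fitted model [impedance_spectrum()].
#' @param measured measured [impedance_spectrum()] on the identical frequency
#'   grid.
#' @return a list of class `fit_metrics` with `mae_real_pct`, `mae_imag_pct`,
#'   `rmse_real_pct`, `rmse_imag_pct`.
#' @export
goodness_of_fit <- function(fitted, measured) {
  if (nrow(fitted) != nrow(measured) ||
      any(abs(fitted$frequency_hz - measured$frequency_hz) >
          1e-9 * measured$frequency_hz)) {
    stop("frequency grids of fitted and measured spectra do not match",
         call. = FALSE)
  }
  if (any(measured$re_ohm == 0) || any(measured$im_ohm == 0)) {
    stop("relative error undefined: measured component is zero at some point",
         call. = FALSE)
  }
  rel_re <- (fitted$re_ohm - measured$re_ohm) / measured$re_ohm
  rel_im <- (fitted$im_ohm - measured$im_ohm) / measured$im_ohm
  structure(list(
    mae_real_pct = 100 * mean(abs(rel_re)),
    mae_imag_pct = 100 * mean(abs(rel_im)),
    rmse_real_pct = 100 * sqrt(mean(rel_re^2)),
    rmse_imag_pct = 100 * sqrt(mean(rel_im^2))
  ), class = "fit_metrics")
}

#' Geometry-based initial parameter estimates
#'
#' Scales the model's default parameters to the measured spectrum: all
#' resistances are multiplied by the ratio of measured to modelled real part
#' at the lowest frequency (the low-frequency plateau), then capacitances and
#' CPE factors are rescaled so the model's -Im(Z) peak frequency moves onto
#' the measured one (via the single-relaxation relation `omega_peak ~ 1/(RC)`;
#' for a CPE the time-constant enters as `(R P)^(1/n)` so P is scaled by the
#' peak-frequency ratio to the power n).
#'
#' @param circuit a [circuit_model].
#' @param spectrum measured [impedance_spectrum()].
#' @return named initial parameter vector within the model's bounds.
#' @export
estimate_initial <- function(circuit, spectrum) {
  pnames <- names(circuit$parameters)
  init <- circuit$parameters
  is_n <- is_exponent_param(pnames)
  is_res <- grepl("^R", pnames)
  is_cap <- grepl("^C", pnames) & !grepl("^CPE", pnames)
  is_cpe_p <- grepl("(^|\\.)P$", pnames)

  model0 <- evaluate_circuit(circuit, init, spectrum$frequency_hz)
  r_lf_meas <- spectrum$re_ohm[1]
  r_lf_model <- model0$re_ohm[1]
  if (is.finite(r_lf_meas) && r_lf_meas > 0 && r_lf_model > 0) {
    scale_r <- r_lf_meas / r_lf_model
    init[is_res] <- init[is_res] * scale_r
  }
  model1 <- evaluate_circuit(circuit, pmin(pmax(init, circuit$lower), circuit$upper),
                             spectrum$frequency_hz)
  f_pk_meas <- spectrum$frequency_hz[which.max(-spectrum$im_ohm)]
  f_pk_model <- model1$frequency_hz[which.max(-model1$im_ohm)]
  if (f_pk_meas > 0 && f_pk_model > 0) {
    ratio <- f_pk_model / f_pk_meas
    init[is_cap] <- init[is_cap] * ratio
    n_mean <- if (any(is_n)) mean(init[is_n]) else 1
    init[is_cpe_p] <- init[is_cpe_p] * ratio^n_mean
  }
  pmin(pmax(init, circuit$lower), circuit$upper)
}

#' Fit and rank several circuit models on one spectrum
#'
#' Fits each requested model to the spectrum and tabulates its
#' [goodness_of_fit()] metrics, sorted by `mae_real_pct` ascending (best model
#' first).  A model whose fit fails is kept as a row with `NA` metrics and the
#' error message; it does not abort the comparison.
#'
#' @param spectrum measured [impedance_spectrum()].
#' @param model_names character vector of built-in names (or expression
#'   strings); defaults to all built-ins.
#' @param options a [fit_options()] list.
#' @return a data frame of class `model_comparison` with columns `model`,
#'   `mae_real_pct`, `mae_imag_pct`, `rmse_real_pct`, `rmse_imag_pct`,
#'   `objective`, `converged`, `error`, plus the fit objects in
#'   `attr(, "fits")`.
#' @export
compare_models <- function(spectrum, model_names = builtin_model_names(),
                           options = fit_options()) {
  rows <- vector("list", length(model_names))
  fits <- stats::setNames(vector("list", length(model_names)), model_names)
  for (i in seq_along(model_names)) {
    nm <- model_names[[i]]
    fit <- tryCatch(fit_model(as_circuit_model(nm), spectrum, options),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(model = nm, mae_real_pct = NA_real_,
                              mae_imag_pct = NA_real_, rmse_real_pct = NA_real_,
                              rmse_imag_pct = NA_real_, objective = NA_real_,
                              converged = NA, error = conditionMessage(fit))
    } else {
      fits[[nm]] <- fit
      m <- fit$metrics
      if (is.null(m)) {
        m <- list(mae_real_pct = NA_real_, mae_imag_pct = NA_real_,
                  rmse_real_pct = NA_real_, rmse_imag_pct = NA_real_)
      }
      rows[[i]] <- data.frame(model = nm, mae_real_pct = m$mae_real_pct,
                              mae_imag_pct = m$mae_imag_pct,
                              rmse_real_pct = m$rmse_real_pct,
                              rmse_imag_pct = m$rmse_imag_pct,
                              objective = fit$objective,
                              converged = fit$converged, error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mae_real_pct, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", "data.frame")
  out
}

## run code with a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
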