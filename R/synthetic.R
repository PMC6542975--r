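#' Drying-simulation configuration
#'
#' Configures the synthetic drying experiment: a cohort of bulb samples
#' weighed daily while their impedance spectra are recorded on a fixed
#' frequency grid.  Defaults emulate the study design the package targets:
#' 10 samples of 75-96 g initial weight, 21 daily measurements, 27
#' log-spaced spot frequencies between 0.5 and 10 kHz, 13% initial solid
#' fraction, 1% relative daily water loss, and 0.05% multiplicative
#' measurement noise (an LCR-meter accuracy class).
#'
#' Circuit parameters are tied to moisture through a per-parameter power law
#' `value(M) = base * (M / M0)^b` with `M0 = (1 - s)/s` (the day-0 moisture).
#' Default exponents: resistances `b = -1` (electrolyte resistivity grows as
#' water leaves), capacitances and CPE factors `b = -0.5` (membrane
#' capacitance rises with dehydration-induced membrane disruption), CPE
#' exponents constant.  So every |Z| rises monotonically as M falls.
#'
#' @param n_samples number of samples.
#' @param n_days number of daily measurements (day 0 .. n_days-1).
#' @param initial_weight_range_g (low, high) initial weight range in g.
#' @param solid_fraction initial solid fraction s in (0, 1).
#' @param drying_rate_per_day relative daily water loss in (0, 1).
#' @param truth_circuit built-in name, expression, or [circuit_model] used as
#'   ground truth.
#' @param moisture_to_param_map named list, one entry per circuit parameter,
#'   each `list(base =, exponent =)`; `NULL` builds the default map from the
#'   truth circuit's parameters with the exponents above.
#' @param frequencies measurement grid in Hz, strictly increasing within
#'   \[500, 10000\]; `NULL` gives 27 log-spaced points.
#' @param noise_sd_rel relative s.d. of the multiplicative Gaussian noise
#'   applied independently to Re and Im of each point.
#' @param seed integer master seed.
#' @return a list of class `drying_sim_config`.
#' @export
drying_sim_config <- function(n_samples = 10, n_days = 21,
                              initial_weight_range_g = c(75, 96),
                              solid_fraction = 0.13,
                              drying_rate_per_day = 0.01,
                              truth_circuit = "cpe_modified",
                              moisture_to_param_map = NULL,
                              frequencies = NULL,
                              noise_sd_rel = 5e-4,
                              seed = 1L) {
  stopifnot(n_samples >= 1, n_days >= 1,
            length(initial_weight_range_g) == 2,
            initial_weight_range_g[1] > 0,
            initial_weight_range_g[2] >= initial_weight_range_g[1],
            solid_fraction > 0, solid_fraction < 1,
            drying_rate_per_day >= 0, drying_rate_per_day < 1,
            noise_sd_rel >= 0)
  circuit <- as_circuit_model(truth_circuit)
  if (is.null(frequencies)) {
    ## 27 spot frequencies: log-spaced over 0.5-10 kHz, guaranteed to contain
    ## the four conventionally analysed points 0.5, 1.1, 5 and 10 kHz
    frequencies <- sort(c(10^seq(log10(500), log10(10000), length.out = 25),
                          1100, 5000))
  }
  if (any(diff(frequencies) <= 0) ||
      frequencies[1] < 500 - 1e-9 || frequencies[length(frequencies)] > 10000 + 1e-9) {
    stop("frequencies must be strictly increasing within [500, 10000] Hz",
         call. = FALSE)
  }
  if (is.null(moisture_to_param_map)) {
    moisture_to_param_map <- default_param_map(circuit)
  } else {
    missing_p <- setdiff(names(circuit$parameters), names(moisture_to_param_map))
    if (length(missing_p) > 0) {
      stop(sprintf("moisture_to_param_map misses parameter(s): %s",
                   paste(missing_p, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(
    n_samples = as.integer(n_samples), n_days = as.integer(n_days),
    initial_weight_range_g = as.numeric(initial_weight_range_g),
    solid_fraction = solid_fraction,
    drying_rate_per_day = drying_rate_per_day,
    truth_circuit = circuit,
    moisture_to_param_map = moisture_to_param_map,
    frequencies = as.numeric(frequencies),
    noise_sd_rel = noise_sd_rel,
    seed = as.integer(seed)
  ), class = "drying_sim_config")
}

default_param_map <- function(circuit) {
  pnames <- names(circuit$parameters)
  expo <- ifelse(is_exponent_param(pnames), 0,
                 ifelse(grepl("^R", pnames), -1, -0.5))
  stats::setNames(lapply(seq_along(pnames), function(i) {
    list(base = unname(circuit$parameters[i]), exponent = expo[i])
  }), pnames)
}

#' Per-day weight and moisture trajectory of one sample
#'
#' Geometric drying law: the water mass decays by a constant relative rate
#' per day, `w(t) = w(0) * (1 - rate)^t`, while the solid mass `s * m_o`
#' stays fixed; the weight is their sum and the moisture content
#' `M = water / solid` follows [moisture_from_weight()] exactly.  M is
#' strictly decreasing in t whenever the rate is positive and never drops
#' below 0.
#'
#' @param config a [drying_sim_config()].
#' @param m_o initial sample weight in g.
#' @return data frame with columns `day`, `weight_g`, `M`.
#' @export
moisture_trajectory <- function(config, m_o) {
  s <- config$solid_fraction
  solid <- s * m_o
  water0 <- (1 - s) * m_o
  t <- 0:(config$n_days - 1L)
  water <- water0 * (1 - config$drying_rate_per_day)^t
  data.frame(day = t, weight_g = solid + water, M = water / solid)
}

#' Synthetic spectrum at a given moisture content
#'
#' Maps moisture to circuit parameters through the config's power-law map,
#' evaluates the truth circuit on the config frequency grid, and applies
#' multiplicative Gaussian noise of relative s.d. `noise_sd_rel`
#' independently to the real and imaginary part of every point.
#' Deterministic given `seed`; with `noise_sd_rel = 0` the result equals
#' [evaluate_circuit()] exactly.
#'
#' @param config a [drying_sim_config()].
#' @param M moisture content in g/g, > 0.
#' @param seed integer seed for the noise draw (`NULL` = use the current RNG
#'   stream).
#' @param label label for the spectrum.
#' @return an [impedance_spectrum()]; the true parameters are attached as
#'   `attr(, "true_parameters")`.
#' @export
spectrum_for_moisture <- function(config, M, seed = NULL, label = "") {
  if (M <= 0) stop("M must be > 0", call. = FALSE)
  circuit <- config$truth_circuit
  M0 <- (1 - config$solid_fraction) / config$solid_fraction
  params <- vapply(names(circuit$parameters), function(pn) {
    m <- config$moisture_to_param_map[[pn]]
    m$base * (M / M0)^m$exponent
  }, numeric(1))
  out_of_bounds <- params < circuit$lower | params > circuit$upper
  if (any(out_of_bounds)) {
    stop(sprintf("moisture_to_param_map yields out-of-bounds parameter(s): %s",
                 paste(names(params)[out_of_bounds], collapse = ", ")),
         call. = FALSE)
  }
  spec <- evaluate_circuit(circuit, params, config$frequencies, label = label)
  if (config$noise_sd_rel > 0) {
    draw <- function() {
      n <- nrow(spec)
      re <- spec$re_ohm * (1 + stats::rnorm(n, 0, config$noise_sd_rel))
      im <- spec$im_ohm * (1 + stats::rnorm(n, 0, config$noise_sd_rel))
      impedance_spectrum(spec$frequency_hz, re, im, label = label)
    }
    spec <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  }
  attr(spec, "true_parameters") <- params
  spec
}

#' Key identifying a (sample, day) record
#'
#' @param sample_id sample identifier(s).
#' @param day day number(s).
#' @export
record_key <- function(sample_id, day) sprintf("%s_day%02d", sample_id, day)

#' Simulate a full drying experiment
#'
#' Draws an initial weight per sample, runs its [moisture_trajectory()], and
#' generates one noisy [spectrum_for_moisture()] per (sample, day).  The
#' whole dataset — including the per-record ground-truth circuit parameters
#' and moisture values — is reproducible byte-for-byte from the config seed.
#'
#' @param config a [drying_sim_config()].
#' @return an object of class `drying_dataset`: `records` (data frame `day`,
#'   `sample_id`, `weight_g`), `spectra` (list keyed by [record_key()]),
#'   `truth` (data frame with the true `M` and circuit parameters per
#'   record), and the `config`.
#' @examples
#' ds <- simulate_drying(drying_sim_config(n_samples = 2, n_days = 3))
#' nrow(ds$records)
#' @export
simulate_drying <- function(config) {
  stopifnot(inherits(config, "drying_sim_config"))
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  with_local_seed(config$seed, {
    m_o <- stats::runif(config$n_samples,
                        config$initial_weight_range_g[1],
                        config$initial_weight_range_g[2])
    noise_seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, config$n_samples * config$n_days),
      nrow = config$n_samples)

    records <- list()
    truth <- list()
    spectra <- list()
    for (i in seq_len(config$n_samples)) {
      traj <- moisture_trajectory(config, m_o[i])
      for (d in seq_len(config$n_days)) {
        key <- record_key(sample_ids[i], traj$day[d])
        spec <- spectrum_for_moisture(config, traj$M[d],
                                      seed = noise_seeds[i, d], label = key)
        spectra[[key]] <- spec
        records[[key]] <- data.frame(day = traj$day[d],
                                     sample_id = sample_ids[i],
                                     weight_g = traj$weight_g[d])
        truth[[key]] <- cbind(
          data.frame(sample_id = sample_ids[i], day = traj$day[d], M = traj$M[d]),
          as.data.frame(as.list(attr(spec, "true_parameters"))))
      }
    }
    structure(list(
      records = do.call(rbind, c(records, make.row.names = FALSE)),
      spectra = spectra,
      truth = do.call(rbind, c(truth, make.row.names = FALSE)),
      config = config
    ), class = "drying_dataset")
  })
}

#' @export
print.drying_dataset <- function(x, ...) {
  cat(sprintf("drying dataset: %d samples x %d days = %d records, %d-point spectra (%s truth circuit, seed %d)\n",
              x$config$n_samples, x$config$n_days, nrow(x$records),
              length(x$config$frequencies), x$config$truth_circuit$name,
              x$config$seed))
  invisible(x)
}

#' Write / read a drying dataset as plain-text files
#'
#' `write_drying_dataset()` writes a drying log CSV (`day, sample_id,
#' weight_g, spectrum_file`), one spectrum CSV per record, and `truth.json`
#' with the ground-truth table and run metadata.  `read_drying_log()` loads
#' the log plus all referenced spectra back into a dataset usable with
#' [calibration_sweep()].
#'
#' @param dataset a `drying_dataset`.
#' @param dir output directory (created if absent).
#' @param metadata optional named character vector recorded in the files.
#' @return the log file path, invisibly.
#' @export
write_drying_dataset <- function(dataset, dir, metadata = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- dataset$records
  keys <- record_key(rec$sample_id, rec$day)
  files <- paste0("spectrum_", keys, ".csv")
  for (j in seq_along(keys)) {
    write_spectrum(dataset$spectra[[keys[j]]], file.path(dir, files[j]),
                   metadata = metadata)
  }
  log_path <- file.path(dir, "drying_log.csv")
  lines <- c(
    if (!is.null(metadata)) sprintf("# %s=%s", names(metadata), metadata),
    "day,sample_id,weight_g,spectrum_file",
    sprintf("%d,%s,%.17g,%s", rec$day, rec$sample_id, rec$weight_g, files)
  )
  writeLines(lines, log_path)
  truth_obj <- list(truth = dataset$truth,
                    solid_fraction = dataset$config$solid_fraction,
                    seed = dataset$config$seed)
  if (!is.null(metadata)) truth_obj <- c(truth_obj, as.list(metadata))
  jsonlite::write_json(truth_obj, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(log_path)
}

#' @rdname write_drying_dataset
#' @param path path to a drying log CSV.
#' @param s solid fraction recorded with the dataset (used by
#'   [calibration_sweep()]).
#' @export
read_drying_log <- function(path, s = 0.13) {
  if (!file.exists(path)) {
    stop(sprintf("drying log not found: %s", path), call. = FALSE)
  }
  rec <- utils::read.csv(path, comment.char = "#")
  need <- c("day", "sample_id", "weight_g")
  if (!all(need %in% names(rec))) {
    stop(sprintf("drying log %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  spectra <- list()
  if ("spectrum_file" %in% names(rec)) {
    keys <- record_key(rec$sample_id, rec$day)
    for (j in seq_along(keys)) {
      spectra[[keys[j]]] <- read_spectrum(file.path(dirname(path),
                                                    rec$spectrum_file[j]))
    }
  }
  structure(list(records = rec[order(rec$sample_id, rec$day), need],
                 spectra = spectra,
                 truth = NULL,
                 config = list(solid_fraction = s)),
            class = "drying_dataset")
}
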