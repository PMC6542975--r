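#' Impedance spectrum objects
#'
#' An `impedance_spectrum` is a data frame with one row per measured
#' frequency and columns `frequency_hz`, `re_ohm` and `im_ohm`, sorted by
#' strictly increasing frequency.  The imaginary part is stored *signed*:
#' capacitive (non-inductive) tissue has `im_ohm <= 0`, and the classical
#' reactance magnitude X of the Z = R - jX convention equals `-im_ohm`.
#' Phase is derived, in degrees, via [cartesian_to_polar()].
#'
#' @param frequency_hz numeric vector of positive frequencies in Hz.
#' @param re_ohm numeric vector, real part of the impedance in ohm.
#' @param im_ohm numeric vector, signed imaginary part in ohm.
#' @param label free-text label (sample id, day, ...).
#' @return an object of class `impedance_spectrum`.
#' @examples
#' s <- impedance_spectrum(c(100, 1000), c(900, 600), c(-50, -200))
#' spectrum_modulus(s)
#' @export
impedance_spectrum <- function(frequency_hz, re_ohm, im_ohm, label = "") {
  if (length(frequency_hz) != length(re_ohm) ||
      length(frequency_hz) != length(im_ohm)) {
    stop("frequency_hz, re_ohm and im_ohm must have equal length", call. = FALSE)
  }
  validate_frequencies(frequency_hz)
  ord <- order(frequency_hz)
  out <- data.frame(
    frequency_hz = as.numeric(frequency_hz[ord]),
    re_ohm = as.numeric(re_ohm[ord]),
    im_ohm = as.numeric(im_ohm[ord])
  )
  attr(out, "label") <- as.character(label)[1]
  class(out) <- c("impedance_spectrum", "data.frame")
  out
}

validate_frequencies <- function(frequency_hz) {
  bad <- which(!is.finite(frequency_hz) | frequency_hz <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive or non-finite frequency at row(s) %s (values: %s)",
                 paste(bad, collapse = ", "),
                 paste(signif(frequency_hz[bad], 6), collapse = ", ")),
         call. = FALSE)
  }
  dup <- duplicated(frequency_hz)
  if (any(dup)) {
    stop(sprintf("duplicate frequency value(s): %s Hz",
                 paste(unique(frequency_hz[dup]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("impedance spectrum%s: %d points, %.6g-%.6g Hz\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              nrow(x), min(x$frequency_hz), max(x$frequency_hz)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Complex impedance, modulus and phase of a spectrum
#'
#' @param spectrum an [impedance_spectrum()].
#' @return `spectrum_complex()` a complex vector, `spectrum_modulus()` |Z| in
#'   ohm, `spectrum_phase()` the phase angle in degrees (`atan2(Im, Re)`).
#' @export
spectrum_complex <- function(spectrum) {
  complex(real = spectrum$re_ohm, imaginary = spectrum$im_ohm)
}

#' @rdname spectrum_complex
#' @export
spectrum_modulus <- function(spectrum) {
  sqrt(spectrum$re_ohm^2 + spectrum$im_ohm^2)
}

#' @rdname spectrum_complex
#' @export
spectrum_phase <- function(spectrum) {
  cartesian_to_polar(spectrum$re_ohm, spectrum$im_ohm)$theta_deg
}

#' Polar/cartesian impedance conversions
#'
#' Converts between the polar representation (|Z|, theta) reported by LCR
#' meters and the cartesian real/imaginary parts used for circuit fitting:
#' R = |Z| cos(theta), X_signed = |Z| sin(theta).  `X_signed` is the signed
#' imaginary part Im(Z); the reactance magnitude of the Z = R - jX convention
#' is its negative for capacitive points.
#'
#' @param z_mod impedance modulus in ohm, must be >= 0.
#' @param theta_deg phase angle in degrees.
#' @return `polar_to_cartesian()` returns a list with `re_ohm` and `im_ohm`;
#'   `cartesian_to_polar()` returns a list with `z_mod` and `theta_deg`.
#' @examples
#' polar_to_cartesian(141.4214, -45)
#' cartesian_to_polar(600, -200)
#' @export
polar_to_cartesian <- function(z_mod, theta_deg) {
  if (any(!is.finite(z_mod)) || any(z_mod < 0)) {
    stop("z_mod must be finite and non-negative", call. = FALSE)
  }
  th <- theta_deg * pi / 180
  list(re_ohm = z_mod * cos(th), im_ohm = z_mod * sin(th))
}

#' @rdname polar_to_cartesian
#' @param re_ohm real part in ohm.
#' @param im_ohm signed imaginary part in ohm.
#' @export
cartesian_to_polar <- function(re_ohm, im_ohm) {
  list(z_mod = sqrt(re_ohm^2 + im_ohm^2),
       theta_deg = atan2(im_ohm, re_ohm) * 180 / pi)
}

spectrum_csv_columns <- c("frequency_hz", "re_ohm", "im_ohm", "z_mod_ohm", "phase_deg")

#' Read an impedance spectrum from CSV
#'
#' The file must have a header row and contain `frequency_hz` together with
#' either the cartesian pair (`re_ohm`, `im_ohm`) or the polar pair
#' (`z_mod_ohm`, `phase_deg`); files written by [write_spectrum()] carry all
#' five columns, in which case the cartesian pair is used.  Rows are sorted by
#' frequency on read.
#'
#' @param path path to a comma-separated file (UTF-8, `.` decimal separator).
#' @param label optional label; defaults to the file name.
#' @return an [impedance_spectrum()].
#' @export
read_spectrum <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("spectrum file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#", check.names = TRUE)
  cols <- names(tab)
  if (!"frequency_hz" %in% cols) {
    stop(sprintf("unknown column set in %s: expected 'frequency_hz' plus (re_ohm, im_ohm) or (z_mod_ohm, phase_deg); found: %s",
                 path, paste(cols, collapse = ", ")), call. = FALSE)
  }
  if (all(c("re_ohm", "im_ohm") %in% cols)) {
    re <- tab$re_ohm
    im <- tab$im_ohm
  } else if (all(c("z_mod_ohm", "phase_deg") %in% cols)) {
    cart <- polar_to_cartesian(tab$z_mod_ohm, tab$phase_deg)
    re <- cart$re_ohm
    im <- cart$im_ohm
  } else {
    stop(sprintf("unknown column set in %s: expected 'frequency_hz' plus (re_ohm, im_ohm) or (z_mod_ohm, phase_deg); found: %s",
                 path, paste(cols, collapse = ", ")), call. = FALSE)
  }
  impedance_spectrum(tab$frequency_hz, re, im,
                     label = if (is.null(label)) basename(path) else label)
}

#' Write an impedance spectrum to CSV
#'
#' Emits all five columns (`frequency_hz, re_ohm, im_ohm, z_mod_ohm,
#' phase_deg`) at full double precision so that
#' `read_spectrum(write_spectrum(s))` round-trips exactly.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param path output file path.
#' @param metadata optional named character vector written as `# key=value`
#'   comment lines before the header.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, metadata = NULL) {
  pol <- cartesian_to_polar(spectrum$re_ohm, spectrum$im_ohm)
  body <- sprintf("%.17g,%.17g,%.17g,%.17g,%.17g",
                  spectrum$frequency_hz, spectrum$re_ohm, spectrum$im_ohm,
                  pol$z_mod, pol$theta_deg)
  lines <- c(
    if (!is.null(metadata)) sprintf("# %s=%s", names(metadata), metadata),
    paste(spectrum_csv_columns, collapse = ","),
    body
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write spectrum to %s", path), call. = FALSE)
  invisible(path)
}
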