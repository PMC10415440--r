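# Multi-peak fat spectrum: frequencies (Hz relative to water) and relative
# amplitudes summing to one. Negative frequencies are upfield of water.

#' Proton gyromagnetic ratio used for ppm to Hz conversion
#'
#' 42.58 MHz/T, so that the Larmor frequency at 1.5 T is 63.87 MHz.
#' @keywords internal
GYROMAGNETIC_MHZ_PER_T <- 42.58

#' Construct a multi-peak fat spectrum
#'
#' A fat spectrum is the set of spectral resonances of triglyceride protons,
#' each described by its chemical-shift frequency relative to water (Hz) and
#' its relative amplitude. The amplitudes must sum to one: they partition the
#' total fat signal across peaks.
#'
#' @param peak_frequencies_hz Numeric vector of peak frequencies in Hz
#'   relative to water. Negative values are upfield of water (the main
#'   methylene peak is at about -217 Hz at 1.5 T).
#' @param relative_amplitudes Numeric vector of positive relative amplitudes,
#'   same length, summing to 1 (within 1e-9).
#' @return An object of class `fat_spectrum`.
#' @export
#' @examples
#' sp <- fat_spectrum(-217, 1)
#' fat_modulation(2.3e-3, sp)
fat_spectrum <- function(peak_frequencies_hz, relative_amplitudes) {
  f <- as.numeric(peak_frequencies_hz)
  a <- as.numeric(relative_amplitudes)
  if (length(f) < 1L || length(f) != length(a)) {
    stop("peak frequencies and amplitudes must be non-empty vectors of equal length")
  }
  if (any(!is.finite(f)) || any(!is.finite(a))) {
    stop("fat spectrum values must be finite")
  }
  if (any(a <= 0)) stop("all relative amplitudes must be positive")
  if (abs(sum(a) - 1) > 1e-9) {
    stop(sprintf("relative amplitudes must sum to 1 (got %.12f)", sum(a)))
  }
  structure(list(peak_frequencies_hz = f, relative_amplitudes = a),
            class = "fat_spectrum")
}

#' @export
print.fat_spectrum <- function(x, ...) {
  cat(sprintf("Fat spectrum: %d peak(s)\n", length(x$peak_frequencies_hz)))
  print(data.frame(frequency_hz = x$peak_frequencies_hz,
                   amplitude = x$relative_amplitudes), row.names = FALSE)
  invisible(x)
}

is_fat_spectrum <- function(x) inherits(x, "fat_spectrum")

#' Default six-peak liver fat spectrum
#'
#' Returns the standard six-peak spectral model of liver triglyceride,
#' with chemical shifts expressed in ppm relative to water and converted to Hz
#' at the requested field strength. The ppm offsets and relative amplitudes
#' are the widely used published liver model (main methylene peak at
#' -3.40 ppm carrying ~69% of the fat signal); they are shipped as a JSON
#' config (`inst/extdata/liver_spectrum_6peak.json`) and can be overridden by
#' supplying any other file of the same schema to [read_fat_spectrum()].
#'
#' @param field_strength_t Main magnetic field in tesla (default 1.5).
#' @return A [fat_spectrum] with frequencies in Hz at `field_strength_t`.
#' @export
#' @examples
#' default_liver_spectrum(1.5)
default_liver_spectrum <- function(field_strength_t = 1.5) {
  if (!is.numeric(field_strength_t) || length(field_strength_t) != 1L ||
      field_strength_t <= 0) {
    stop("field_strength_t must be a positive scalar")
  }
  path <- system.file("extdata", "liver_spectrum_6peak.json", package = "wfsep")
  read_fat_spectrum(path, field_strength_t = field_strength_t)
}

#' Read a fat spectrum definition from a JSON config
#'
#' The schema has either `peak_frequencies_hz` (used verbatim) or
#' `peak_offsets_ppm` (converted to Hz at `field_strength_t`), plus
#' `relative_amplitudes`. Amplitudes are normalized to sum exactly 1.
#'
#' @param path Path to a JSON file.
#' @param field_strength_t Field strength in tesla, required when the file
#'   specifies ppm offsets.
#' @return A [fat_spectrum].
#' @export
read_fat_spectrum <- function(path, field_strength_t = 1.5) {
  if (!file.exists(path)) stop("fat spectrum config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$peak_offsets_ppm)) {
    freq <- ppm_to_hz(cfg$peak_offsets_ppm, field_strength_t)
  } else if (!is.null(cfg$peak_frequencies_hz)) {
    freq <- as.numeric(cfg$peak_frequencies_hz)
  } else {
    stop("spectrum config must define peak_offsets_ppm or peak_frequencies_hz")
  }
  amp <- as.numeric(cfg$relative_amplitudes)
  if (is.null(cfg$relative_amplitudes) || length(amp) != length(freq)) {
    stop("spectrum config must define relative_amplitudes matching the peaks")
  }
  fat_spectrum(freq, amp / sum(amp))
}

#' Convert a chemical-shift offset in ppm to Hz
#'
#' @param ppm Offset in parts per million relative to the water resonance.
#' @param field_strength_t Field strength in tesla.
#' @return Frequency offset in Hz.
#' @export
ppm_to_hz <- function(ppm, field_strength_t) {
  as.numeric(ppm) * GYROMAGNETIC_MHZ_PER_T * field_strength_t
}

#' Complex fat modulation factor at one echo time
#'
#' Evaluates the bracketed spectral sum of the CSE signal model for a unit
#' fat signal: `sum_p alpha_p * exp(1i * 2 * pi * f_p * te)`. Its magnitude
#' is at most 1, with equality when all peaks are in phase.
#'
#' @param te_s Echo time in seconds (scalar or vector, >= 0).
#' @param spectrum A [fat_spectrum].
#' @return Complex vector, one value per echo time.
#' @export
fat_modulation <- function(te_s, spectrum) {
  if (!is_fat_spectrum(spectrum)) {
    spectrum <- do.call(fat_spectrum, unclass(spectrum))  # re-validate
  }
  te_s <- as.numeric(te_s)
  if (any(te_s < 0)) stop("echo times must be non-negative")
  ph <- outer(te_s, spectrum$peak_frequencies_hz) * (2i * pi)
  as.vector(exp(ph) %*% spectrum$relative_amplitudes)
}
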