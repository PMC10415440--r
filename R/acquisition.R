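# Acquisition parameters of a multi-echo gradient-echo protocol.
# SI units internally (seconds); milliseconds are accepted only at
# CLI/config boundaries and converted immediately there.

#' Multi-echo gradient-echo acquisition parameters
#'
#' Describes a uniformly spaced echo train: `TE_n = te1_s + (n - 1) * delta_te_s`.
#' The defaults are a typical 1.5 T abdominal protocol with TE1 = 1.29 ms and
#' echo spacing 2.1 ms.
#'
#' @param te1_s First echo time in seconds (> 0).
#' @param delta_te_s Echo spacing in seconds (> 0).
#' @param n_echoes Number of echoes (integer >= 1).
#' @param field_strength_t Main field strength in tesla (default 1.5).
#' @return An object of class `acq_params`.
#' @export
#' @examples
#' acq <- acq_params(n_echoes = 6)
#' echo_times(acq)
acq_params <- function(te1_s = 1.29e-3, delta_te_s = 2.1e-3, n_echoes = 6,
                       field_strength_t = 1.5) {
  n_echoes <- as.integer(n_echoes)
  if (!is.finite(te1_s) || te1_s <= 0) stop("te1_s must be > 0")
  if (!is.finite(delta_te_s) || delta_te_s <= 0) stop("delta_te_s must be > 0")
  if (is.na(n_echoes) || n_echoes < 1L) stop("n_echoes must be a positive integer")
  if (!is.finite(field_strength_t) || field_strength_t <= 0) {
    stop("field_strength_t must be > 0")
  }
  structure(list(te1_s = te1_s, delta_te_s = delta_te_s, n_echoes = n_echoes,
                 field_strength_t = field_strength_t),
            class = "acq_params")
}

#' Echo times of an acquisition
#'
#' @param acq An [acq_params] object.
#' @return Numeric vector of `n_echoes` strictly increasing echo times (s).
#' @export
echo_times <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  acq$te1_s + (seq_len(acq$n_echoes) - 1) * acq$delta_te_s
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("CSE-MRI acquisition: %d echoes, TE1 = %.3f ms, dTE = %.3f ms, B0 = %.2g T\n",
              x$n_echoes, 1e3 * x$te1_s, 1e3 * x$delta_te_s, x$field_strength_t))
  invisible(x)
}
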