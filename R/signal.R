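# Forward CSE-MRI signal model: the complex signal at the n-th echo is
#   I_n = exp(-R2* TE_n) * exp(j 2 pi df TE_n) * (PW + PF * c(TE_n))
# where c(TE) is the multi-peak fat modulation factor.

#' Construct a multi-echo complex image series
#'
#' @param data Complex array of shape `(n_echoes, H, W)`.
#' @param echo_times_s Strictly increasing echo times, one per leading slice.
#' @param acquisition The generating [acq_params]; echo times must match.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(data, echo_times_s, acquisition) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-D array (n_echoes, H, W)")
  }
  data <- array(as.complex(data), dim(data))
  echo_times_s <- as.numeric(echo_times_s)
  if (dim(data)[1] != length(echo_times_s)) {
    stop("leading dimension of data must equal the number of echo times")
  }
  if (length(echo_times_s) > 1 && any(diff(echo_times_s) <= 0)) {
    stop("echo times must be strictly increasing")
  }
  stopifnot(inherits(acquisition, "acq_params"))
  if (!isTRUE(all.equal(echo_times_s, echo_times(acquisition), tolerance = 1e-12))) {
    stop("echo_times_s inconsistent with the acquisition parameters")
  }
  structure(list(data = data, echo_times_s = echo_times_s,
                 acquisition = acquisition),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("Echo series: %d echoes of %dx%d (TE %.2f-%.2f ms)\n",
              dm[1], dm[2], dm[3], 1e3 * min(x$echo_times_s),
              1e3 * max(x$echo_times_s)))
  invisible(x)
}

#' Simulate the multi-echo CSE-MRI signal from parameter maps
#'
#' Applies the voxel-wise forward model at every echo time: exponential R2*
#' decay, off-resonance phase accrual, and the water plus spectrally
#' modulated fat composition. Voxels outside the mask are exactly zero.
#'
#' @param maps A [parameter_maps] object (ground truth or estimates).
#' @param acq An [acq_params] object.
#' @param spectrum A [fat_spectrum].
#' @return An [echo_series] of shape `(n_echoes, H, W)`.
#' @export
#' @examples
#' maps <- parameter_maps(water = matrix(1 + 0i, 4, 4), fat = matrix(0i, 4, 4),
#'                        r2star_per_s = matrix(30, 4, 4),
#'                        fieldmap_hz = matrix(0, 4, 4))
#' sig <- simulate_signal(maps, acq_params(n_echoes = 3), default_liver_spectrum())
simulate_signal <- function(maps, acq, spectrum) {
  stopifnot(inherits(maps, "parameter_maps"), inherits(acq, "acq_params"))
  te <- echo_times(acq)
  cmod <- fat_modulation(te, spectrum)
  dm <- dim(maps$water)
  out <- array(0i, c(length(te), dm[1], dm[2]))
  base <- complex(real = -maps$r2star_per_s, imaginary = 2 * pi * maps$fieldmap_hz)
  for (n in seq_along(te)) {
    sl <- exp(base * te[n]) * (maps$water + maps$fat * cmod[n])
    sl[!maps$mask] <- 0 + 0i
    out[n, , ] <- sl
  }
  echo_series(out, te, acq)
}

#' Pack a complex echo series into a real channel stack
#'
#' Interleaves real and imaginary parts per echo into channels ordered
#' `[Re(e1), Im(e1), Re(e2), Im(e2), ...]`, the input layout of the
#' water-fat separation networks.
#'
#' @param echoes An [echo_series].
#' @return Real array of shape `(H, W, 2 * n_echoes)`.
#' @seealso [unpack_input()]
#' @export
pack_input <- function(echoes) {
  stopifnot(inherits(echoes, "echo_series"))
  dm <- dim(echoes$data)
  ne <- dm[1]
  out <- array(0, c(dm[2], dm[3], 2L * ne))
  for (n in seq_len(ne)) {
    out[, , 2L * n - 1L] <- Re(echoes$data[n, , ])
    out[, , 2L * n] <- Im(echoes$data[n, , ])
  }
  out
}

#' Unpack a real channel stack into a complex echo series
#'
#' Inverse of [pack_input()].
#'
#' @param x Real array `(H, W, 2 * n_echoes)`.
#' @param acq The [acq_params] describing the echo train.
#' @return An [echo_series].
#' @export
unpack_input <- function(x, acq) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3] %% 2L == 0L)
  ne <- dim(x)[3] %/% 2L
  if (ne != acq$n_echoes) stop("channel count inconsistent with acquisition")
  dat <- array(0i, c(ne, dim(x)[1], dim(x)[2]))
  for (n in seq_len(ne)) {
    dat[n, , ] <- complex(real = x[, , 2L * n - 1L], imaginary = x[, , 2L * n])
  }
  echo_series(dat, echo_times(acq), acq)
}
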