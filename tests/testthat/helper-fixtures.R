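# Shared fixtures: random parameter maps and an independent scalar-loop
# implementation of the forward signal model (used as an oracle; kept
# deliberately naive and separate from the package's vectorized path).

random_maps <- function(n = 8, seed = 1, r2_max = 150, df_max = 100,
                        mask = NULL) {
  set.seed(seed)
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  parameter_maps(
    water = matrix(complex(real = runif(n * n), imaginary = runif(n * n, -0.3, 0.3)), n, n),
    fat = matrix(complex(real = runif(n * n), imaginary = runif(n * n, -0.3, 0.3)), n, n),
    r2star_per_s = matrix(runif(n * n, 0, r2_max), n, n),
    fieldmap_hz = matrix(runif(n * n, -df_max, df_max), n, n),
    mask = mask)
}

# scalar-loop forward model oracle: one voxel, one echo at a time
oracle_signal <- function(maps, acq, spectrum) {
  te <- echo_times(acq)
  dm <- dim(maps$water)
  out <- array(0i, c(length(te), dm[1], dm[2]))
  for (k in seq_along(te)) {
    cm <- 0i
    for (p in seq_along(spectrum$peak_frequencies_hz)) {
      cm <- cm + spectrum$relative_amplitudes[p] *
        exp(2i * pi * spectrum$peak_frequencies_hz[p] * te[k])
    }
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
      if (!maps$mask[i, j]) next
      out[k, i, j] <- exp(-maps$r2star_per_s[i, j] * te[k]) *
        exp(2i * pi * maps$fieldmap_hz[i, j] * te[k]) *
        (maps$water[i, j] + maps$fat[i, j] * cm)
    }
  }
  out
}

single_voxel_signal <- function(pw, pf, r2s, df, acq, spectrum) {
  maps <- parameter_maps(matrix(pw, 1, 1), matrix(pf, 1, 1),
                         matrix(r2s, 1, 1), matrix(df, 1, 1))
  simulate_signal(maps, acq, spectrum)$data[, 1, 1]
}

tiny_net_config <- function(size = 32, n_echoes = 2) {
  network_config(input_size = size, n_echoes = n_echoes,
                 encoder_filters = c(3L, 4L, 6L, 8L),
                 bottleneck_filters = 16L)
}
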