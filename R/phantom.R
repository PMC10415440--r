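# Seeded synthetic abdominal phantom: piecewise-constant elliptical
# water/fat compartments inside a body ellipse, smooth polynomial
# off-resonance field, circular complex Gaussian noise. Stands in for
# in-vivo CSE-MRI slices at desk scale.

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic phantom configuration
#'
#' Describes the simulated 2-D abdominal slice: image size, number of
#' internal tissue compartments, the PDFF and R2* ranges the compartments are
#' drawn from, the peak off-resonance amplitude, and the noise level.
#' Defaults emulate a 1.5 T liver protocol: compartment PDFF spanning
#' 4-36%, R2* in 10-150 1/s, a smooth field within +/-100 Hz, SNR 50.
#'
#' @param image_size Pixels per side; >= 16 and divisible by 16 (the
#'   networks pool four times).
#' @param n_regions Number of internal elliptical compartments (2-8).
#' @param pdff_range Two fractions in `[0, 1]`: compartment PDFF is drawn
#'   uniformly from this range.
#' @param r2star_range_per_s Two non-negative rates (1/s), upper <= 200.
#' @param fieldmap_amplitude_hz Peak |off-resonance| in Hz (<= 400).
#' @param noise_snr Signal-to-noise ratio (> 0), or `NULL` for noiseless.
#' @param seed Integer seed controlling the generated anatomy.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64, n_regions = 5,
                           pdff_range = c(0.04, 0.36),
                           r2star_range_per_s = c(10, 150),
                           fieldmap_amplitude_hz = 100,
                           noise_snr = 50, seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 16L || image_size %% 16L != 0L) {
    stop("image_size must be >= 16 and divisible by 16")
  }
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 1L) stop("n_regions must be >= 1")
  pdff_range <- sort(as.numeric(pdff_range))
  if (length(pdff_range) != 2 || pdff_range[1] < 0 || pdff_range[2] > 1) {
    stop("pdff_range must lie within [0, 1]")
  }
  r2star_range_per_s <- sort(as.numeric(r2star_range_per_s))
  if (length(r2star_range_per_s) != 2 || r2star_range_per_s[1] < 0) {
    stop("r2star_range_per_s must be non-negative")
  }
  if (!is.finite(fieldmap_amplitude_hz) || fieldmap_amplitude_hz < 0 ||
      fieldmap_amplitude_hz > 400) {
    stop("fieldmap_amplitude_hz must be in [0, 400]")
  }
  if (!is.null(noise_snr) && (!is.finite(noise_snr) || noise_snr <= 0) &&
      !identical(noise_snr, Inf)) {
    stop("noise_snr must be > 0 (or NULL for noiseless)")
  }
  structure(list(image_size = image_size, n_regions = n_regions,
                 pdff_range = pdff_range,
                 r2star_range_per_s = r2star_range_per_s,
                 fieldmap_amplitude_hz = fieldmap_amplitude_hz,
                 noise_snr = noise_snr, seed = as.integer(seed)),
            class = "phantom_config")
}

# ellipse interior on normalized [-1,1]^2 coordinates
ellipse_mask <- function(size, cx, cy, ax, ay, theta = 0) {
  u <- seq(-1, 1, length.out = size)
  X <- matrix(u, size, size)          # varies along rows
  Y <- matrix(u, size, size, byrow = TRUE)
  xr <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  yr <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  (xr / ax)^2 + (yr / ay)^2 <= 1
}

# smooth low-order 2-D polynomial field, rescaled to a peak amplitude;
# draws from the current RNG stream
random_fieldmap <- function(size, amplitude_hz) {
  if (amplitude_hz == 0) return(matrix(0, size, size))
  u <- seq(-1, 1, length.out = size)
  X <- matrix(u, size, size)
  Y <- matrix(u, size, size, byrow = TRUE)
  co <- stats::rnorm(6)
  f <- co[1] + co[2] * X + co[3] * Y + co[4] * X^2 + co[5] * X * Y + co[6] * Y^2
  peak <- amplitude_hz * stats::runif(1, 0.6, 1)
  f * (peak / max(abs(f)))
}

#' Generate ground-truth parameter maps for a synthetic abdominal slice
#'
#' Builds a body ellipse containing `n_regions` internal elliptical
#' compartments (a dominant liver-like region plus smaller analogues). Each
#' compartment has constant PDFF and R2* drawn uniformly from the configured
#' ranges and a constant signal intensity; water and fat share a common
#' random initial phase per slice. The off-resonance field is a smooth
#' low-order 2-D polynomial bounded by `fieldmap_amplitude_hz`. Output is
#' deterministic given `config$seed`.
#'
#' @param config A [phantom_config].
#' @return Ground-truth [parameter_maps]; the mask is the body ellipse.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    n <- config$image_size
    body <- ellipse_mask(n, stats::runif(1, -0.05, 0.05),
                         stats::runif(1, -0.05, 0.05),
                         stats::runif(1, 0.80, 0.92),
                         stats::runif(1, 0.62, 0.75),
                         stats::runif(1, -0.15, 0.15))
    pdff_m <- matrix(0, n, n)
    r2s_m <- matrix(0, n, n)
    int_m <- matrix(0, n, n)
    draw <- function(rng) stats::runif(1, rng[1], rng[2])
    # base body tissue
    pdff_m[body] <- draw(config$pdff_range)
    r2s_m[body] <- draw(config$r2star_range_per_s)
    int_m[body] <- stats::runif(1, 0.55, 0.8)
    # compartments: first is a large liver-like region, the rest smaller
    for (k in seq_len(config$n_regions)) {
      if (k == 1L) {
        e <- ellipse_mask(n, stats::runif(1, -0.4, -0.15), stats::runif(1, -0.35, -0.1),
                          stats::runif(1, 0.35, 0.5), stats::runif(1, 0.28, 0.4),
                          stats::runif(1, -0.3, 0.3))
      } else {
        e <- ellipse_mask(n, stats::runif(1, -0.5, 0.6), stats::runif(1, -0.4, 0.55),
                          stats::runif(1, 0.08, 0.25), stats::runif(1, 0.08, 0.22),
                          stats::runif(1, 0, pi))
      }
      e <- e & body
      pdff_m[e] <- draw(config$pdff_range)
      r2s_m[e] <- draw(config$r2star_range_per_s)
      int_m[e] <- stats::runif(1, 0.7, 1.0)
    }
    phi0 <- stats::runif(1, -pi, pi)
    phase <- exp(1i * phi0)
    water <- matrix(0i, n, n)
    fat <- matrix(0i, n, n)
    water[body] <- (1 - pdff_m[body]) * int_m[body] * phase
    fat[body] <- pdff_m[body] * int_m[body] * phase
    df <- random_fieldmap(n, config$fieldmap_amplitude_hz)
    parameter_maps(water = water, fat = fat, r2star_per_s = r2s_m,
                   fieldmap_hz = df, mask = body)
  })
}

#' Add circular complex Gaussian noise to an echo series
#'
#' The noise standard deviation per real/imaginary component is the mean
#' foreground magnitude of the first echo divided by `snr` (so the magnitude
#' noise is Rician, the standard MRI model). Noise covers the whole field of
#' view, including the background.
#'
#' @param echoes An [echo_series].
#' @param snr Signal-to-noise ratio (> 0); `Inf` or `NULL` returns the input
#'   unchanged.
#' @param seed Integer seed for the noise field.
#' @return A noisy [echo_series].
#' @export
add_noise <- function(echoes, snr, seed = 1L) {
  stopifnot(inherits(echoes, "echo_series"))
  if (is.null(snr) || identical(snr, Inf)) return(echoes)
  if (!is.finite(snr) || snr <= 0) stop("snr must be > 0")
  mag1 <- Mod(echoes$data[1, , ])
  fg <- mag1 > 0
  if (!any(fg)) return(echoes)
  sigma <- mean(mag1[fg]) / snr
  with_seed(seed, {
    nz <- length(echoes$data)
    noise <- complex(real = stats::rnorm(nz, sd = sigma),
                     imaginary = stats::rnorm(nz, sd = sigma))
    out <- echoes
    out$data <- echoes$data + array(noise, dim(echoes$data))
    out
  })
}

fftshift_idx <- function(n) ((seq_len(n) - 1 + ceiling(n / 2)) %% n) + 1
ifftshift_idx <- function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) + 1

#' Resize a complex image by centered k-space cropping
#'
#' Takes the 2-D discrete Fourier transform, keeps the centered
#' `target[1] x target[2]` block of spatial frequencies, and inverse
#' transforms. The result is normalized so the image mean (DC component) is
#' preserved: a constant image stays at the same constant.
#'
#' @param image Complex (or numeric) matrix.
#' @param target Integer vector `c(H, W)`, each no larger than the source.
#' @return Complex matrix of shape `target`.
#' @export
kspace_resize <- function(image, target) {
  if (!is.matrix(image)) stop("image must be a matrix")
  target <- as.integer(target)
  if (length(target) != 2 || any(is.na(target)) || any(target < 1)) {
    stop("target must be two positive integers")
  }
  src <- dim(image)
  if (any(target > src)) stop("target dimensions must not exceed the source")
  k <- stats::fft(matrix(as.complex(image), src[1], src[2]))
  ks <- k[fftshift_idx(src[1]), fftshift_idx(src[2]), drop = FALSE]
  r0 <- floor(src[1] / 2) - floor(target[1] / 2)
  c0 <- floor(src[2] / 2) - floor(target[2] / 2)
  kc <- ks[r0 + seq_len(target[1]), c0 + seq_len(target[2]), drop = FALSE]
  kc <- kc[ifftshift_idx(target[1]), ifftshift_idx(target[2]), drop = FALSE]
  stats::fft(kc, inverse = TRUE) / prod(src)
}

#' Foreground mask by thresholding the mean-magnitude image
#'
#' The mask keeps pixels whose magnitude, averaged over all echoes, exceeds
#' `threshold_fraction` times the maximum of that mean image — the standard
#' noisy-background removal step before training and evaluation.
#'
#' @param echoes An [echo_series].
#' @param threshold_fraction Fraction of the peak mean magnitude in (0, 1).
#' @return Logical matrix `(H, W)`.
#' @export
threshold_mask <- function(echoes, threshold_fraction = 0.05) {
  stopifnot(inherits(echoes, "echo_series"))
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)")
  }
  m <- Mod(echoes$data)
  meanmag <- apply(m, c(2, 3), mean)
  meanmag > threshold_fraction * max(meanmag)
}

#' Generate a seeded multi-subject phantom dataset
#'
#' Each simulated subject has one anatomy (one [generate_phantom] draw); its
#' slices share that anatomy but re-draw the smooth off-resonance field and
#' the noise realization, mimicking neighbouring slices of one scan. Used to
#' build training/validation/test sets with subject-level (never
#' slice-level) splits.
#'
#' @param n_subjects Number of subjects.
#' @param slices_per_subject Slices per subject.
#' @param config A [phantom_config] template (its seed is re-derived per
#'   subject from `seed`).
#' @param acq An [acq_params].
#' @param spectrum A [fat_spectrum].
#' @param seed Master seed.
#' @return List of records, each with `maps`, `echoes` (noisy per
#'   `config$noise_snr`), `subject` and `slice` indices.
#' @export
phantom_dataset <- function(n_subjects, slices_per_subject, config, acq,
                            spectrum, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  out <- vector("list", n_subjects * slices_per_subject)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    sub_seed <- (seed * 1009L + s * 7919L) %% .Machine$integer.max
    cfg <- config
    cfg$seed <- sub_seed
    maps <- generate_phantom(cfg)
    for (sl in seq_len(slices_per_subject)) {
      m <- maps
      if (sl > 1L) {  # re-draw the field for this slice
        m$fieldmap_hz <- with_seed(sub_seed + sl, {
          f <- random_fieldmap(config$image_size, config$fieldmap_amplitude_hz)
          f[!m$mask] <- 0
          f
        })
      }
      ech <- simulate_signal(m, acq, spectrum)
      ech <- add_noise(ech, config$noise_snr, seed = sub_seed + 100000L + sl)
      i <- i + 1L
      out[[i]] <- list(maps = m, echoes = ech, subject = s, slice = sl)
    }
  }
  out
}
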