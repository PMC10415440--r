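# Synthetic phantom generator and preprocessing.

test_that("phantom generation is deterministic given the seed", {
  cfg <- phantom_config(image_size = 32, seed = 5)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$water, b$water)
  expect_identical(a$fat, b$fat)
  expect_identical(a$r2star_per_s, b$r2star_per_s)
  expect_identical(a$fieldmap_hz, b$fieldmap_hz)
  expect_identical(a$mask, b$mask)
  # a different seed yields a different phantom
  c2 <- generate_phantom(phantom_config(image_size = 32, seed = 6))
  expect_false(identical(a$water, c2$water))
})

test_that("degenerate PDFF range forces a constant compartment PDFF", {
  cfg <- phantom_config(image_size = 32, pdff_range = c(0.3, 0.3), seed = 2)
  maps <- generate_phantom(cfg)
  pd <- pdff(maps)
  expect_true(all(abs(pd$values[maps$mask] - 0.30) < 1e-12))
})

test_that("fieldmap stays within the configured amplitude over many seeds", {
  for (seed in 1:100) {
    cfg <- phantom_config(image_size = 16, fieldmap_amplitude_hz = 400,
                          seed = seed)
    maps <- generate_phantom(cfg)
    expect_lte(max(abs(maps$fieldmap_hz)), 400)
  }
})

test_that("generated PDFF spans the configured range across seeds", {
  lo <- 1; hi <- 0
  for (seed in 1:50) {
    cfg <- phantom_config(image_size = 16, seed = seed)
    pd <- pdff(generate_phantom(cfg))
    lo <- min(lo, min(pd$values[pd$mask]))
    hi <- max(hi, max(pd$values[pd$mask]))
  }
  expect_lt(lo, 0.04 + 0.03)
  expect_gt(hi, 0.36 - 0.03)
})

test_that("phantom background is zero outside the body ellipse", {
  maps <- generate_phantom(phantom_config(image_size = 32, seed = 3))
  expect_true(any(!maps$mask))
  expect_true(all(Mod(maps$water[!maps$mask]) == 0))
  expect_true(all(Mod(maps$fat[!maps$mask]) == 0))
})

test_that("added complex noise has the nominal sigma and is seeded", {
  sp <- default_liver_spectrum(1.5)
  acq <- acq_params(n_echoes = 3)
  n <- 256
  maps <- parameter_maps(matrix(1 + 0i, n, n), matrix(0i, n, n),
                         matrix(0, n, n), matrix(0, n, n))
  clean <- simulate_signal(maps, acq, sp)
  noisy <- add_noise(clean, snr = 50, seed = 7)
  resid <- Re(noisy$data[1, , ] - clean$data[1, , ])
  # mean first-echo magnitude is 1, so sigma = 1/50 = 0.02
  expect_lt(abs(stats::sd(resid) - 0.02) / 0.02, 0.05)
  # seeding: same seed reproduces, different seed does not
  expect_identical(add_noise(clean, 50, seed = 7)$data, noisy$data)
  expect_false(identical(add_noise(clean, 50, seed = 8)$data, noisy$data))
  # noiseless limit passes through unchanged
  expect_identical(add_noise(clean, Inf)$data, clean$data)
  expect_identical(add_noise(clean, NULL)$data, clean$data)
  expect_error(add_noise(clean, -2), "snr")
})

test_that("noise averages out over repeated draws", {
  sp <- default_liver_spectrum(1.5)
  acq <- acq_params(n_echoes = 3)
  n <- 8
  maps <- parameter_maps(matrix(0.7 + 0i, n, n), matrix(0.2 + 0i, n, n),
                         matrix(30, n, n), matrix(10, n, n))
  clean <- simulate_signal(maps, acq, sp)
  acc <- array(0i, dim(clean$data))
  n_draws <- 1000
  for (k in seq_len(n_draws)) acc <- acc + add_noise(clean, 25, seed = k)$data
  avg <- acc / n_draws
  sigma <- mean(Mod(clean$data[1, , ])) / 25
  se <- sigma / sqrt(n_draws)
  # single-voxel mean within 3 standard errors (seeded, deterministic)
  expect_lt(abs(Re(avg[1, 4, 4] - clean$data[1, 4, 4])), 3 * se)
  expect_lt(abs(Im(avg[2, 5, 3] - clean$data[2, 5, 3])), 3 * se)
  # grand mean deviation shrinks by the extra voxel averaging
  nvox <- length(avg)
  expect_lt(abs(mean(Re(avg - clean$data))), 3 * se / sqrt(nvox) * 2)
})

test_that("k-space resize crops to the target and preserves the mean", {
  set.seed(11)
  x <- matrix(complex(real = rnorm(232 * 230), imaginary = rnorm(232 * 230)),
              232, 230)
  y <- kspace_resize(x, c(192, 192))
  expect_equal(dim(y), c(192L, 192L))
  # identity when the target equals the source
  expect_lt(max(Mod(kspace_resize(x, dim(x)) - x)), 1e-10)
  # constant image stays at the same constant (DC preservation)
  cimg <- matrix(2.7 + 0i, 40, 36)
  expect_lt(max(Mod(kspace_resize(cimg, c(24, 16)) - 2.7)), 1e-9)
  # idempotent once at the target size
  y2 <- kspace_resize(y, c(192, 192))
  expect_lt(max(Mod(y2 - y)), 1e-10)
  expect_error(kspace_resize(y, c(200, 200)), "exceed")
})

test_that("threshold mask separates foreground from background", {
  sp <- default_liver_spectrum(1.5)
  acq <- acq_params(n_echoes = 3)
  maps <- generate_phantom(phantom_config(image_size = 32, seed = 4))
  clean <- simulate_signal(maps, acq, sp)
  mk <- threshold_mask(clean, 0.05)
  expect_identical(mk, maps$mask)
  # all-zero image gives an empty mask
  zero <- simulate_signal(parameter_maps(matrix(0i, 8, 8), matrix(0i, 8, 8),
                                         matrix(0, 8, 8), matrix(0, 8, 8)),
                          acq, sp)
  expect_false(any(threshold_mask(zero, 0.05)))
  # two-level image: only the bright region survives a 5% threshold
  w <- matrix(0.01 + 0i, 16, 16); w[5:12, 5:12] <- 1 + 0i
  lv <- simulate_signal(parameter_maps(w, matrix(0i, 16, 16),
                                       matrix(0, 16, 16), matrix(0, 16, 16)),
                        acq, sp)
  mk2 <- threshold_mask(lv, 0.05)
  expect_identical(mk2, Mod(w) > 0.5)
  expect_error(threshold_mask(clean, 1.5), "threshold_fraction")
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(image_size = 20), "divisible by 16")
  expect_error(phantom_config(pdff_range = c(-0.1, 0.5)), "pdff_range")
  expect_error(phantom_config(fieldmap_amplitude_hz = 500), "fieldmap")
  expect_error(phantom_config(noise_snr = -1), "noise_snr")
})

test_that("multi-subject datasets share anatomy within a subject", {
  sp <- default_liver_spectrum(1.5)
  acq <- acq_params(n_echoes = 3)
  cfg <- phantom_config(image_size = 32)
  ds <- phantom_dataset(2, 3, cfg, acq, sp, seed = 21)
  expect_length(ds, 6)
  subj <- vapply(ds, `[[`, numeric(1), "subject")
  expect_equal(sort(unique(subj)), c(1, 2))
  s1 <- ds[subj == 1]
  # same anatomy (water/fat) across slices of one subject
  expect_identical(s1[[1]]$maps$water, s1[[2]]$maps$water)
  # but per-slice fieldmaps differ
  expect_false(identical(s1[[1]]$maps$fieldmap_hz, s1[[2]]$maps$fieldmap_hz))
  # reproducible end to end
  ds2 <- phantom_dataset(2, 3, cfg, acq, sp, seed = 21)
  expect_identical(ds[[4]]$echoes$data, ds2[[4]]$echoes$data)
})
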