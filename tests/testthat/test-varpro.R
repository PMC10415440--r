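# Voxel-wise VARPRO water-fat fit.

sp6 <- default_liver_spectrum(1.5)
acq6 <- acq_params(n_echoes = 6)

test_that("projected residual is zero at the true parameters", {
  truth <- list(pw = 0.7 + 0.2i, pf = 0.25 - 0.1i, r2s = 60, df = 35)
  sig <- single_voxel_signal(truth$pw, truth$pf, truth$r2s, truth$df,
                             acq6, sp6)
  v <- varpro_residual(truth$df, truth$r2s, sig, acq6, sp6)
  expect_lt(v$residual, 1e-12)
  expect_lt(Mod(v$pw - truth$pw), 1e-10)
  expect_lt(Mod(v$pf - truth$pf), 1e-10)
})

test_that("zero signal yields zero residual and amplitudes", {
  v <- varpro_residual(10, 40, rep(0i, 6), acq6, sp6)
  expect_equal(v$residual, 0)
  expect_equal(v$pw, 0 + 0i)
  expect_equal(v$pf, 0 + 0i)
})

test_that("degenerate spectra that cannot separate water and fat are flagged", {
  sp0 <- fat_spectrum(0, 1)   # fat indistinguishable from water
  sig <- single_voxel_signal(1 + 0i, 0i, 30, 0, acq6, sp0)
  expect_error(varpro_residual(0, 30, sig, acq6, sp0), "rank-deficient")
})

test_that("residual profile matches a dense brute-force least squares", {
  truth <- list(pw = 0.6 + 0.1i, pf = 0.35 + 0.05i, r2s = 45, df = -60)
  sig <- single_voxel_signal(truth$pw, truth$pf, truth$r2s, truth$df,
                             acq6, sp6)
  te <- echo_times(acq6)
  cmod <- fat_modulation(te, sp6)
  # brute force: explicit complex normal equations per candidate
  brute <- function(df, r2s) {
    A <- cbind(exp((-r2s + 2i * pi * df) * te),
               exp((-r2s + 2i * pi * df) * te) * cmod)
    x <- solve(Conj(t(A)) %*% A, Conj(t(A)) %*% sig)
    sqrt(sum(Mod(sig - A %*% x)^2))
  }
  for (df in seq(-100, 100, by = 1)) {
    got <- varpro_residual(df, 45, sig, acq6, sp6)$residual
    expect_lt(abs(got - brute(df, 45)), 1e-10)
  }
})

test_that("noiseless 6-echo voxels are recovered to 1e-6 relative", {
  cases <- list(
    list(pw = 0.7 + 0.2i, pf = 0.25 - 0.05i, r2s = 60, df = 40),
    list(pw = 0.2 + 0.0i, pf = 0.75 + 0.3i, r2s = 140, df = -210),
    list(pw = 0.9 - 0.1i, pf = 0.08 + 0.02i, r2s = 15, df = 190))
  for (cs in cases) {
    sig <- single_voxel_signal(cs$pw, cs$pf, cs$r2s, cs$df, acq6, sp6)
    f <- fit_voxel(sig, acq6, sp6)
    expect_lt(abs(f$fieldmap_hz - cs$df) / abs(cs$df), 1e-6)
    expect_lt(abs(f$r2star_per_s - cs$r2s) / cs$r2s, 1e-6)
    expect_lt(Mod(f$pw - cs$pw) / Mod(cs$pw), 1e-6)
    expect_lt(Mod(f$pf - cs$pf) / Mod(cs$pf), 1e-6)
  }
})

test_that("pure-water voxel fits to PDFF zero", {
  sig <- single_voxel_signal(0.9 + 0.3i, 0i, 70, 20, acq6, sp6)
  f <- fit_voxel(sig, acq6, sp6)
  pd <- Mod(f$pf) / (Mod(f$pw) + Mod(f$pf))
  expect_lt(pd, 1e-8)
})

test_that("returned residual is no worse than the residual at truth", {
  for (seed in 1:5) {
    set.seed(seed)
    pw <- complex(real = runif(1, 0.2, 1), imaginary = runif(1, -0.2, 0.2))
    pf <- complex(real = runif(1, 0, 0.6), imaginary = runif(1, -0.2, 0.2))
    r2s <- runif(1, 5, 180)
    df <- runif(1, -350, 350)
    sig <- single_voxel_signal(pw, pf, r2s, df, acq6, sp6)
    f <- fit_voxel(sig, acq6, sp6)
    at_truth <- varpro_residual(df, r2s, sig, acq6, sp6)$residual
    expect_lte(f$residual, at_truth + 1e-7)
  }
})

test_that("single-peak fat at zero fieldmap has a swap minimum but truth wins", {
  sp1 <- fat_spectrum(-217, 1)
  truth <- list(pw = 0.3 + 0i, pf = 0.7 + 0i, r2s = 40, df = 0)
  acq3 <- acq_params(n_echoes = 3)
  for (acq in list(acq3, acq6)) {
    sig <- single_voxel_signal(truth$pw, truth$pf, truth$r2s, truth$df,
                               acq, sp1)
    # landscape scan: residual minimized over a coarse R2* grid per
    # fieldmap candidate
    dfs <- seq(-300, 300, by = 5)
    prof <- vapply(dfs, function(df) {
      min(vapply(c(10, 40, 80, 120), function(r2) {
        varpro_residual(df, r2, sig, acq, sp1)$residual
      }, numeric(1)))
    }, numeric(1))
    # bimodal: a deep second basin near the fat peak frequency, well
    # below the ridge separating it from the true basin
    swap_min <- min(prof[abs(dfs - (-217)) < 40])
    ridge <- max(prof[dfs > -160 & dfs < -60])
    expect_lt(swap_min, 0.4 * ridge)
    expect_lt(min(prof[abs(dfs) < 30]), 1e-12)
    # multi-start with a symmetric search range still lands on the truth
    f <- fit_voxel(sig, acq, sp1, fit_config())
    pd <- Mod(f$pf) / (Mod(f$pw) + Mod(f$pf))
    expect_lt(abs(pd - 0.7), 1e-6)
  }
})

test_that("noiseless 16x16 phantom image fit recovers PDFF to 1e-6 RMS", {
  cfg <- phantom_config(image_size = 16, noise_snr = NULL, seed = 9)
  maps <- generate_phantom(cfg)
  sig <- simulate_signal(maps, acq6, sp6)
  fit <- fit_image(sig, sp6, fit_config(), mask = maps$mask)
  pd_est <- pdff(fit)$values
  pd_true <- pdff(maps)$values
  rms <- sqrt(mean((pd_est[maps$mask] - pd_true[maps$mask])^2))
  expect_lt(rms, 1e-6)
  expect_s3_class(fit, "wf_fit")
  expect_equal(fit$n_voxels, sum(maps$mask))
})

test_that("empty mask produces all-zero maps", {
  sp <- default_liver_spectrum(1.5)
  maps <- random_maps(4, 2)
  sig <- simulate_signal(maps, acq6, sp)
  fit <- fit_image(sig, sp, mask = matrix(FALSE, 4, 4))
  expect_true(all(Mod(fit$maps$water) == 0))
  expect_true(all(fit$maps$r2star_per_s == 0))
  expect_equal(fit$n_voxels, 0L)
})

test_that("PDFF RMSE decreases with SNR", {
  cfg0 <- phantom_config(image_size = 16, seed = 31)
  maps <- generate_phantom(cfg0)
  clean <- simulate_signal(maps, acq6, sp6)
  pd_true <- pdff(maps)$values
  rmse <- vapply(c(10, 25, 50, 100), function(snr) {
    errs <- vapply(1:2, function(k) {
      noisy <- add_noise(clean, snr, seed = 1000 + k)
      fit <- fit_image(noisy, sp6, fit_config(), mask = maps$mask)
      pd <- pdff(fit)$values
      sqrt(mean((pd[maps$mask] - pd_true[maps$mask])^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("wf_fit methods expose maps, residuals and summaries", {
  cfg <- phantom_config(image_size = 16, noise_snr = 50, seed = 12)
  maps <- generate_phantom(cfg)
  sig <- add_noise(simulate_signal(maps, acq6, sp6), 50, seed = 3)
  fit <- fit_image(sig, sp6, mask = maps$mask)
  co <- coef(fit)
  expect_named(co, c("water", "fat", "r2star_per_s", "fieldmap_hz"))
  expect_equal(dim(residuals(fit)), c(16L, 16L))
  expect_output(print(fit), "VARPRO")
  expect_output(print(summary(fit)), "pdff")
})
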