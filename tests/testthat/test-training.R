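# Training pipeline: labels, loss, schedule, determinism, learning.

test_that("label normalization follows the 200 / 400 constants", {
  tcfg <- train_config()
  n <- 4
  maps <- parameter_maps(matrix(0.5 + 0i, n, n), matrix(0.25 + 0i, n, n),
                         matrix(200, n, n), matrix(-400, n, n))
  lab <- make_labels(maps, tcfg, scale = 1)
  expect_equal(unique(lab$labels[3, ]), 1)      # R2* = 200 -> 1
  expect_equal(unique(lab$labels[4, ]), -1)     # -400 Hz -> -1
  expect_equal(lab$n_clipped, 0)
  # clipping above the normalization constant is counted
  maps2 <- parameter_maps(matrix(0.5 + 0i, n, n), matrix(0i, n, n),
                          matrix(250, n, n), matrix(0, n, n))
  lab2 <- make_labels(maps2, tcfg, scale = 1)
  expect_equal(lab2$n_clipped, n * n)
  expect_true(all(lab2$labels[3, ] <= 1))
})

test_that("denormalization inverts the label map for in-range values", {
  tcfg <- train_config()
  set.seed(3)
  n <- 8
  maps <- parameter_maps(
    water = matrix(complex(real = runif(n * n, 0.1, 1)), n, n),
    fat = matrix(complex(real = runif(n * n, 0, 0.5)), n, n),
    r2star_per_s = matrix(runif(n * n, 0, 200), n, n),
    fieldmap_hz = matrix(runif(n * n, -400, 400), n, n))
  lab <- make_labels(maps, tcfg)
  back <- denormalize_labels(lab$labels, c(n, n), tcfg, lab$mask,
                             scale = lab$scale)
  expect_equal(Mod(back$water), Mod(maps$water), tolerance = 1e-12)
  expect_equal(Mod(back$fat), Mod(maps$fat), tolerance = 1e-12)
  expect_equal(back$r2star_per_s, maps$r2star_per_s, tolerance = 1e-12)
  expect_equal(back$fieldmap_hz, maps$fieldmap_hz, tolerance = 1e-12)
})

test_that("masked MAE agrees with an elementwise loop", {
  set.seed(4)
  pred <- matrix(rnorm(4 * 50), 4, 50)
  lab <- matrix(rnorm(4 * 50), 4, 50)
  mask <- runif(50) > 0.3
  got <- mae_loss(pred, lab, mask)
  acc <- 0; nn <- 0
  for (j in which(mask)) for (i in 1:4) {
    acc <- acc + abs(pred[i, j] - lab[i, j]); nn <- nn + 1
  }
  expect_equal(got, acc / nn, tolerance = 1e-10)
  expect_equal(mae_loss(lab, lab, mask), 0)
  expect_equal(mae_loss(lab + 0.1, lab, rep(TRUE, 50)), 0.1, tolerance = 1e-9)
  expect_error(mae_loss(pred, lab, rep(FALSE, 50)), "empty")
})

test_that("the cosine schedule matches its closed form", {
  lr0 <- 5e-4
  epochs <- 120
  for (e in c(0, 1, 30, 60, 119, 120)) {
    expect_equal(cosine_lr(e, epochs, lr0),
                 lr0 * 0.5 * (1 + cos(pi * e / epochs)), tolerance = 1e-9)
  }
  expect_equal(cosine_lr(0, epochs, lr0), lr0)
  expect_equal(cosine_lr(epochs, epochs, lr0), 0, tolerance = 1e-20)
})

test_that("training is deterministic given the seed", {
  sp <- default_liver_spectrum(1.5)
  acq <- acq_params(n_echoes = 2)
  cfg <- phantom_config(image_size = 32, seed = 1)
  ds <- phantom_dataset(2, 2, cfg, acq, sp, seed = 6)
  run <- function() {
    arch <- build_mdwf_net(tiny_net_config(32, n_echoes = 2), seed = 11)
    tcfg <- desk_train_config(epochs = 2, batch_size = 2, seed = 30,
                              val_fraction = 0)
    train_network(arch, ds, tcfg)$history$train_mae
  }
  expect_identical(run(), run())
})

test_that("learning reduces the loss on a small phantom set", {
  sp <- default_liver_spectrum(1.5)
  acq <- acq_params(n_echoes = 3)
  cfg <- phantom_config(image_size = 32, seed = 2)
  ds <- phantom_dataset(6, 3, cfg, acq, sp, seed = 8)
  ncfg <- network_config(input_size = 32, n_echoes = 3,
                         encoder_filters = c(4, 8, 12, 16),
                         bottleneck_filters = 32)
  arch <- build_mdwf_net(ncfg, seed = 14)
  tcfg <- desk_train_config(epochs = 10, batch_size = 2, seed = 15,
                            initial_lr = 2e-3)
  net <- train_network(arch, ds, tcfg)
  h <- net$history
  expect_lt(h$train_mae[nrow(h)], 0.5 * h$train_mae[1])
  # learning rate recorded per epoch follows the schedule
  expect_equal(h$lr, cosine_lr(h$epoch - 1, tcfg$epochs, tcfg$initial_lr),
               tolerance = 1e-12)
  # validation split is at subject level
  expect_true(length(net$val_subjects) >= 1)
})

test_that("prediction denormalizes and beats an untrained network after training", {
  sp <- default_liver_spectrum(1.5)
  acq <- acq_params(n_echoes = 3)
  cfg <- phantom_config(image_size = 32, seed = 3)
  ds <- phantom_dataset(8, 3, cfg, acq, sp, seed = 9)
  ncfg <- network_config(input_size = 32, n_echoes = 3,
                         encoder_filters = c(4, 8, 12, 16),
                         bottleneck_filters = 32)
  arch <- build_mdwf_net(ncfg, seed = 16)
  tcfg <- desk_train_config(epochs = 14, batch_size = 2, seed = 17)
  net <- train_network(arch, ds, tcfg)
  # masked label MAE (the training objective) on the training slices must
  # improve on an untrained network of the same architecture; held-out
  # improvement at realistic dataset sizes is exercised by the
  # desk-preset end-to-end test
  slices <- lapply(ds, wfsep:::prepare_slice, tcfg = tcfg)
  mae_trained <- wfsep:::evaluate_mae(net$arch, slices)
  mae_untrained <- wfsep:::evaluate_mae(build_mdwf_net(ncfg, seed = 99),
                                        slices)
  expect_lt(mae_trained, mae_untrained)
  test_ds <- phantom_dataset(2, 1, cfg, acq, sp, seed = 555)
  # outputs respect the physical ranges after denormalization
  p <- predict_maps(net, test_ds[[1]]$echoes)
  expect_true(all(p$maps$r2star_per_s >= 0 & p$maps$r2star_per_s <= 200))
  expect_true(all(abs(p$maps$fieldmap_hz) <= 400))
  expect_true(all(p$pdff$values >= 0 & p$pdff$values <= 1))
  # an all-zero input stays finite under the zero-signal convention
  zero <- simulate_signal(parameter_maps(matrix(0i, 32, 32),
                                         matrix(0i, 32, 32),
                                         matrix(0, 32, 32),
                                         matrix(0, 32, 32)), acq, sp)
  pz <- predict_maps(net, zero)
  expect_true(all(is.finite(pz$pdff$values)))
})

test_that("training aborts cleanly on mismatched slice dimensions", {
  sp <- default_liver_spectrum(1.5)
  acq <- acq_params(n_echoes = 2)
  ds <- phantom_dataset(1, 1, phantom_config(image_size = 16), acq, sp, 1)
  arch <- build_mdwf_net(tiny_net_config(32, n_echoes = 2), seed = 1)
  expect_error(train_network(arch, ds, desk_train_config(epochs = 1)),
               "input size")
})
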