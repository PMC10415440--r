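# Training pipeline: label normalization (R2*/200, fieldmap/400, water/fat
# magnitudes by a per-volume scale), magnitude-threshold masking, masked
# mean-absolute-error loss, Adam with a cosine-decayed learning rate.

#' Training configuration
#'
#' Full-scale defaults follow the reference recipe: 120 epochs, batch size
#' 32, initial learning rate 5e-4 decayed to zero on a cosine schedule,
#' labels normalized by 200 1/s (R2*) and 400 Hz (fieldmap). The desk
#' preset ([desk_train_config()]) shrinks epochs and batch size for CPU
#' training on 64x64 phantoms.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Slices per batch (>= 1).
#' @param initial_lr Initial learning rate (> 0); decays to 0 with
#'   `lr(e) = initial_lr * 0.5 * (1 + cos(pi * e / epochs))`.
#' @param r2star_norm_per_s R2* normalization constant (1/s).
#' @param fieldmap_norm_hz Fieldmap normalization constant (Hz). Signed
#'   division is used, so normalized fieldmap labels lie in `[-1, 1]`.
#' @param mask_threshold Fraction for [threshold_mask()].
#' @param val_fraction Fraction of subjects held out for validation during
#'   training (subject-level split, never slice-level).
#' @param seed Seed for shuffling and the subject split.
#' @param desk_preset Marker that this is the reduced CPU preset.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 120L, batch_size = 32L, initial_lr = 5e-4,
                         r2star_norm_per_s = 200, fieldmap_norm_hz = 400,
                         mask_threshold = 0.05, val_fraction = 0.2,
                         seed = 1L, desk_preset = FALSE) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1")
  if (is.na(batch_size) || batch_size < 1L) stop("batch_size must be >= 1")
  if (!is.finite(initial_lr) || initial_lr <= 0) stop("initial_lr must be > 0")
  if (val_fraction < 0 || val_fraction >= 1) stop("val_fraction must be in [0, 1)")
  structure(list(epochs = epochs, batch_size = batch_size,
                 initial_lr = initial_lr,
                 r2star_norm_per_s = r2star_norm_per_s,
                 fieldmap_norm_hz = fieldmap_norm_hz,
                 mask_threshold = mask_threshold,
                 val_fraction = val_fraction,
                 seed = as.integer(seed), desk_preset = isTRUE(desk_preset)),
            class = "train_config")
}

#' @rdname train_config
#' @export
desk_train_config <- function(epochs = 15L, batch_size = 4L,
                              initial_lr = 2e-3, ...) {
  train_config(epochs = epochs, batch_size = batch_size,
               initial_lr = initial_lr, desk_preset = TRUE, ...)
}

#' Cosine learning-rate schedule
#'
#' @param epoch Zero-based epoch index.
#' @param epochs Total number of epochs.
#' @param initial_lr Initial learning rate.
#' @return `initial_lr * 0.5 * (1 + cos(pi * epoch / epochs))`.
#' @export
cosine_lr <- function(epoch, epochs, initial_lr) {
  initial_lr * 0.5 * (1 + cos(pi * epoch / epochs))
}

#' Build normalized training labels from ground-truth maps
#'
#' Labels are the 4-channel target `[ |PW|/s, |PF|/s, R2*/200, fieldmap/400 ]`
#' where `s` is a per-volume magnitude scale (by default the maximum
#' water/fat magnitude inside the mask). R2* values above the normalization
#' constant are clipped, and the clip count is recorded. Values outside the
#' mask are zeroed.
#'
#' @param maps Ground-truth [parameter_maps].
#' @param config A [train_config].
#' @param mask Logical matrix; defaults to the maps' own mask.
#' @param scale Per-volume water/fat magnitude scale; default
#'   `max(|PW|, |PF|)` inside the mask.
#' @return List with `labels` (a `4 x (H*W)` channels-first matrix),
#'   `mask` (logical vector, column-major), `scale`, and `n_clipped`.
#' @export
make_labels <- function(maps, config = train_config(), mask = NULL,
                        scale = NULL) {
  stopifnot(inherits(maps, "parameter_maps"), inherits(config, "train_config"))
  if (is.null(mask)) mask <- maps$mask
  aw <- Mod(maps$water)
  af <- Mod(maps$fat)
  if (is.null(scale)) {
    scale <- max(aw[mask], af[mask], 0)
    if (scale == 0) scale <- 1
  }
  r2n <- maps$r2star_per_s / config$r2star_norm_per_s
  n_clipped <- sum(r2n[mask] > 1)
  r2n <- pmin(r2n, 1)
  dfn <- maps$fieldmap_hz / config$fieldmap_norm_hz
  lab <- rbind(as.vector(aw / scale), as.vector(af / scale),
               as.vector(r2n), as.vector(dfn))
  lab[, !as.vector(mask)] <- 0
  list(labels = lab, mask = as.vector(mask), scale = scale,
       n_clipped = n_clipped)
}

#' Invert the label normalization
#'
#' Maps a 4-channel label (or prediction) matrix back to [parameter_maps]
#' with real non-negative water/fat magnitudes (the phase is not part of
#' the label space), R2* in 1/s and fieldmap in Hz.
#'
#' @param labels `4 x (H*W)` matrix as produced by [make_labels()] or a
#'   network prediction.
#' @param dim_hw Image dimensions `c(H, W)`.
#' @param config A [train_config].
#' @param mask Logical matrix or vector.
#' @param scale The per-volume water/fat magnitude scale.
#' @return A [parameter_maps] object.
#' @export
denormalize_labels <- function(labels, dim_hw, config, mask, scale = 1) {
  mk <- matrix(as.logical(mask), dim_hw[1], dim_hw[2])
  parameter_maps(
    water = matrix(complex(real = pmax(labels[1, ], 0) * scale, imaginary = 0),
                   dim_hw[1], dim_hw[2]),
    fat = matrix(complex(real = pmax(labels[2, ], 0) * scale, imaginary = 0),
                 dim_hw[1], dim_hw[2]),
    r2star_per_s = matrix(pmax(labels[3, ], 0) * config$r2star_norm_per_s,
                          dim_hw[1], dim_hw[2]),
    fieldmap_hz = matrix(labels[4, ] * config$fieldmap_norm_hz,
                         dim_hw[1], dim_hw[2]),
    mask = mk)
}

#' Masked mean absolute error
#'
#' Mean absolute deviation over in-mask pixels across all four output
#' channels; zero iff prediction equals the label inside the mask.
#'
#' @param pred,labels `4 x (H*W*N)` matrices.
#' @param mask Logical vector of length `H*W*N`.
#' @return Non-negative scalar.
#' @export
mae_loss <- function(pred, labels, mask) {
  stopifnot(identical(dim(pred), dim(labels)), length(mask) == ncol(pred))
  if (!any(mask)) stop("mask is empty: loss undefined")
  d <- abs(pred[, mask, drop = FALSE] - labels[, mask, drop = FALSE])
  mean(d)
}

# per-slice training tensors from phantom_dataset records
prepare_slice <- function(rec, tcfg) {
  ech <- rec$echoes
  msk <- threshold_mask(ech, tcfg$mask_threshold)
  packed <- pack_input(ech)
  dm <- dim(packed)
  x <- t(matrix(packed, dm[1] * dm[2], dm[3]))   # channels-first
  mag <- sqrt(colSums(x^2))                       # per-pixel overall magnitude
  s <- stats::quantile(mag[as.vector(msk)], 0.99, names = FALSE)
  if (!is.finite(s) || s <= 0) s <- 1
  x <- x / s
  lab <- make_labels(rec$maps, tcfg, mask = msk, scale = s)
  list(x = x, y = lab$labels, mask = lab$mask, subject = rec$subject,
       scale = s, n_clipped = lab$n_clipped, dim = dim(msk))
}

#' Train a water-fat separation network
#'
#' Runs masked-MAE training with Adam and a cosine learning-rate decay on a
#' phantom dataset (the output of [phantom_dataset()]). Inputs are scaled
#' per slice by the 99th-percentile in-mask magnitude; water/fat labels
#' share that scale so predictions are in input units. The validation split
#' is at subject level. Training is deterministic given the configuration
#' seed and the architecture's init seed.
#'
#' @param arch A `wf_net_arch` from [build_mdwf_net()] or [build_unet()].
#' @param dataset List of records with `maps`, `echoes`, `subject`.
#' @param config A [train_config].
#' @param verbose Print per-epoch progress.
#' @return An object of class `wf_net`: the trained architecture, the
#'   configuration, and a history data frame (epoch, lr, train_mae,
#'   val_mae).
#' @export
train_network <- function(arch, dataset, config = desk_train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(arch, "wf_net_arch"), inherits(config, "train_config"))
  slices <- lapply(dataset, prepare_slice, tcfg = config)
  sz <- arch$config$input_size
  ok <- vapply(slices, function(s) identical(s$dim, c(sz, sz)), logical(1))
  if (!all(ok)) stop("slice dimensions do not match the network input size")
  subjects <- vapply(slices, `[[`, numeric(1), "subject")
  with_seed(config$seed, {
    subj <- unique(subjects)
    n_val <- if (config$val_fraction > 0 && length(subj) > 1L) {
      max(1L, round(config$val_fraction * length(subj)))
    } else 0L
    val_subj <- if (n_val > 0) sample(subj, n_val) else numeric(0)
    itrain <- which(!(subjects %in% val_subj))
    ival <- which(subjects %in% val_subj)
    if (length(itrain) == 0L) stop("no training slices after the subject split")
    st <- adam_state(arch$graph)
    hist <- data.frame(epoch = integer(0), lr = numeric(0),
                       train_mae = numeric(0), val_mae = numeric(0))
    for (ep in seq_len(config$epochs)) {
      lr <- cosine_lr(ep - 1L, config$epochs, config$initial_lr)
      ord <- sample(itrain)
      ep_loss <- 0
      ep_n <- 0L
      for (b0 in seq(1L, length(ord), by = config$batch_size)) {
        ib <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        xb <- do.call(cbind, lapply(slices[ib], `[[`, "x"))
        yb <- do.call(cbind, lapply(slices[ib], `[[`, "y"))
        mb <- unlist(lapply(slices[ib], `[[`, "mask"))
        fw <- arch_forward(arch, xb, length(ib), training = TRUE)
        nin <- sum(mb)
        dif <- fw$pred - yb
        dif[, !mb] <- 0
        loss <- sum(abs(dif)) / (4 * nin)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        }
        arch_backward(arch, fw$fw, sign(dif) / (4 * nin))
        st <- adam_step(arch$graph, st, lr)
        ep_loss <- ep_loss + loss * length(ib)
        ep_n <- ep_n + length(ib)
      }
      val_mae <- NA_real_
      if (length(ival) > 0L) {
        val_mae <- evaluate_mae(arch, slices[ival])
      }
      hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                     train_mae = ep_loss / ep_n,
                                     val_mae = val_mae))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  train MAE %.5f  val MAE %s",
                        ep, lr, ep_loss / ep_n,
                        ifelse(is.na(val_mae), "-", sprintf("%.5f", val_mae))))
      }
    }
    structure(list(arch = arch, config = config, history = hist,
                   val_subjects = val_subj),
              class = "wf_net")
  })
}

# mean masked MAE over prepared slices (inference mode, batched)
evaluate_mae <- function(arch, slices, batch = 8L) {
  tot <- 0
  n <- 0L
  for (b0 in seq(1L, length(slices), by = batch)) {
    sl <- slices[b0:min(b0 + batch - 1L, length(slices))]
    xb <- do.call(cbind, lapply(sl, `[[`, "x"))
    yb <- do.call(cbind, lapply(sl, `[[`, "y"))
    mb <- unlist(lapply(sl, `[[`, "mask"))
    fw <- arch_forward(arch, xb, length(sl), training = FALSE)
    tot <- tot + mae_loss(fw$pred, yb, mb) * sum(mb)
    n <- n + sum(mb)
  }
  tot / n
}

#' @export
print.wf_net <- function(x, ...) {
  print(x$arch)
  h <- x$history
  if (nrow(h) > 0) {
    cat(sprintf("  trained %d epochs: train MAE %.5f -> %.5f",
                nrow(h), h$train_mae[1], h$train_mae[nrow(h)]))
    if (!is.na(h$val_mae[nrow(h)])) {
      cat(sprintf(" (val %.5f)", h$val_mae[nrow(h)]))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
plot.wf_net <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_mae, type = "b", pch = 16,
                 xlab = "epoch", ylab = "masked MAE",
                 ylim = range(c(h$train_mae, h$val_mae), na.rm = TRUE), ...)
  if (any(!is.na(h$val_mae))) {
    graphics::lines(h$epoch, h$val_mae, type = "b", col = 2, pch = 1)
    graphics::legend("topright", c("train", "validation"), col = c(1, 2),
                     pch = c(16, 1), bty = "n")
  }
  invisible(x)
}

#' Predict parameter maps from an echo series with a trained network
#'
#' Packs and normalizes the input like the training pipeline, runs the
#' network in inference mode, and denormalizes the outputs (water/fat by
#' the input magnitude scale, R2* by 200 1/s, fieldmap by 400 Hz); the
#' PDFF map follows from the predicted magnitudes. An untrained
#' architecture may also be passed (used for baseline comparisons).
#'
#' @param object A trained `wf_net` (or, for `predict_maps()`, also a bare
#'   `wf_net_arch`).
#' @param echoes An [echo_series] matching the configured size/echo count.
#' @param ... Unused.
#' @return List with `maps` ([parameter_maps]), `pdff` ([pdff_map]) and
#'   `mask`.
#' @export
predict.wf_net <- function(object, echoes, ...) {
  predict_maps(object, echoes)
}

#' @rdname predict.wf_net
#' @param model A `wf_net` or `wf_net_arch`.
#' @param config A [train_config] (taken from the trained model when
#'   available).
#' @export
predict_maps <- function(model, echoes, config = NULL) {
  if (inherits(model, "wf_net")) {
    arch <- model$arch
    if (is.null(config)) config <- model$config
  } else {
    arch <- model
    if (is.null(config)) config <- train_config()
  }
  stopifnot(inherits(arch, "wf_net_arch"), inherits(echoes, "echo_series"))
  dm <- dim(echoes$data)
  if (dm[1] != arch$config$n_echoes) {
    stop("echo count does not match the network configuration")
  }
  if (dm[2] != arch$config$input_size || dm[3] != arch$config$input_size) {
    stop("image size does not match the network configuration")
  }
  sl <- prepare_slice(list(echoes = echoes,
                           maps = parameter_maps(
                             water = matrix(0i, dm[2], dm[3]),
                             fat = matrix(0i, dm[2], dm[3]),
                             r2star_per_s = matrix(0, dm[2], dm[3]),
                             fieldmap_hz = matrix(0, dm[2], dm[3])),
                           subject = 0), config)
  fw <- arch_forward(arch, sl$x, 1L, training = FALSE)
  pred <- fw$pred
  pred[, !sl$mask] <- 0
  maps <- denormalize_labels(pred, dm[2:3], config, sl$mask, scale = sl$scale)
  list(maps = maps, pdff = pdff(maps),
       mask = matrix(sl$mask, dm[2], dm[3]))
}
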