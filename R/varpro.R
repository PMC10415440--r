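# Voxel-independent VARPRO water-fat fit. For fixed nonlinear parameters
# (fieldmap df, R2*) the linear complex amplitudes (PW, PF) are eliminated
# by linear least squares; the nonlinear pair is found by a multi-start
# bounded quasi-Newton search of the projected residual. No spatial
# regularization: multi-start over the fieldmap range handles the
# water-fat swap ambiguity at desk scale.

#' Configuration of the voxel-wise VARPRO fit
#'
#' @param fieldmap_search_range_hz Two finite bounds on the off-resonance
#'   search (default +/-400 Hz, the label normalization range).
#' @param n_initializations Size of the fieldmap screening grid (>= 1).
#' @param r2star_bounds_per_s `c(0, upper)` bounds on R2* (default 200 1/s).
#' @param convergence_tol Convergence tolerance on the squared residual.
#' @param max_iterations Iteration cap per local refinement.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(fieldmap_search_range_hz = c(-400, 400),
                       n_initializations = 17L,
                       r2star_bounds_per_s = c(0, 200),
                       convergence_tol = 1e-14,
                       max_iterations = 200L) {
  fieldmap_search_range_hz <- sort(as.numeric(fieldmap_search_range_hz))
  if (length(fieldmap_search_range_hz) != 2 ||
      any(!is.finite(fieldmap_search_range_hz))) {
    stop("fieldmap_search_range_hz must be two finite values")
  }
  n_initializations <- as.integer(n_initializations)
  if (is.na(n_initializations) || n_initializations < 1L) {
    stop("n_initializations must be >= 1")
  }
  r2star_bounds_per_s <- sort(as.numeric(r2star_bounds_per_s))
  if (r2star_bounds_per_s[1] < 0) stop("r2star bounds must be non-negative")
  if (!is.finite(convergence_tol) || convergence_tol <= 0) {
    stop("convergence_tol must be > 0")
  }
  structure(list(fieldmap_search_range_hz = fieldmap_search_range_hz,
                 n_initializations = n_initializations,
                 r2star_bounds_per_s = r2star_bounds_per_s,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations)),
            class = "fit_config")
}

# squared VARPRO residual and its gradient in (df, r2s) for one voxel.
# te: echo times; cmod: fat modulation at te; sig: complex signal vector.
varpro_rss <- function(df_hz, r2s, sig, te, cmod, want_grad = FALSE) {
  phi <- exp(complex(real = -r2s * te, imaginary = 2 * pi * df_hz * te))
  A <- cbind(phi, phi * cmod)
  Ah <- Conj(t(A))
  M <- Ah %*% A
  detM <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  scale <- Mod(M[1, 1] * M[2, 2])
  if (Mod(detM) <= 1e-12 * max(scale, .Machine$double.xmin)) {
    stop("rank-deficient water-fat design: echo train cannot separate water and fat")
  }
  b <- Ah %*% sig
  x <- c(M[2, 2] * b[1] - M[1, 2] * b[2],
         -M[2, 1] * b[1] + M[1, 1] * b[2]) / detM
  r <- sig - as.vector(A %*% x)
  rss <- sum(Mod(r)^2)
  out <- list(rss = rss, pw = x[1], pf = x[2], residual = sqrt(rss))
  if (want_grad) {
    ax <- as.vector(A %*% x)
    # d(rss)/d(theta) = -2 Re( r^H dA x ); dA/d(df) = i 2 pi te * A,
    # dA/d(r2s) = -te * A (both columns share the exponential factor)
    inner <- Conj(r) * ax
    out$grad <- c(df = -2 * sum(Re(2i * pi * te * inner)),
                  r2s = -2 * sum(Re(-te * inner)))
  }
  out
}

#' VARPRO projected residual at candidate nonlinear parameters
#'
#' For a fixed candidate pair (fieldmap, R2*) the complex water and fat
#' amplitudes minimizing the model misfit are obtained in closed form by
#' linear least squares on the demodulated signal; the returned residual is
#' the norm of the remaining misfit.
#'
#' @param candidate_fieldmap_hz Candidate off-resonance (Hz).
#' @param candidate_r2star_per_s Candidate R2* (1/s).
#' @param signal Complex signal vector, one value per echo (length >= 3).
#' @param acq An [acq_params] matching the signal length.
#' @param spectrum A [fat_spectrum].
#' @return List with `residual` (norm), `pw`, `pf` (complex amplitudes).
#' @export
varpro_residual <- function(candidate_fieldmap_hz, candidate_r2star_per_s,
                            signal, acq, spectrum) {
  stopifnot(inherits(acq, "acq_params"))
  signal <- as.complex(signal)
  if (length(signal) != acq$n_echoes) {
    stop("signal length must equal the number of echoes")
  }
  if (acq$n_echoes < 3L) stop("at least 3 echoes are required")
  te <- echo_times(acq)
  cmod <- fat_modulation(te, spectrum)
  v <- varpro_rss(candidate_fieldmap_hz, candidate_r2star_per_s, signal, te, cmod)
  list(residual = v$residual, pw = v$pw, pf = v$pf)
}

# vectorized screening of the rss over a (df grid x r2s grid); returns matrix
screen_rss <- function(sig, te, cmod, df_grid, r2s_grid) {
  s2 <- sum(Mod(sig)^2)
  out <- matrix(NA_real_, length(df_grid), length(r2s_grid))
  for (j in seq_along(r2s_grid)) {
    w <- exp(-2 * r2s_grid[j] * te)
    m11 <- sum(w)
    m12 <- sum(w * cmod)
    m22 <- sum(w * Mod(cmod)^2)
    detM <- m11 * m22 - Mod(m12)^2
    if (Mod(detM) <= 1e-12 * Mod(m11 * m22)) { out[, j] <- Inf; next }
    # b depends on df: b = A^H sig with A columns sharing exp factor
    dem <- exp(complex(real = -r2s_grid[j] * te, imaginary = 0)) * sig
    E <- exp(outer(te, df_grid) * (-2i * pi))   # conj(phase) per df
    b1 <- as.vector(t(E) %*% dem)
    b2 <- as.vector(t(E) %*% (dem * Conj(cmod)))
    x1 <- (m22 * b1 - m12 * b2) / detM
    x2 <- (-Conj(m12) * b1 + m11 * b2) / detM
    out[, j] <- s2 - Re(Conj(x1) * b1 + Conj(x2) * b2)
  }
  out
}

#' Fit a single voxel by multi-start VARPRO least squares
#'
#' Screens the projected residual over a fieldmap grid spanning the search
#' range (crossed with a coarse R2* grid), then refines the best distinct
#' local minima with bounded quasi-Newton iterations using the analytic
#' VARPRO gradient, and returns the global best. Deterministic given the
#' configuration.
#'
#' @param signal Complex vector of echo signals (length >= 3).
#' @param acq An [acq_params].
#' @param spectrum A [fat_spectrum].
#' @param config A [fit_config].
#' @return List with `pw`, `pf` (complex), `r2star_per_s`, `fieldmap_hz`,
#'   `residual`, and `converged` (FALSE when every refinement hit the
#'   iteration cap).
#' @export
fit_voxel <- function(signal, acq, spectrum, config = fit_config()) {
  stopifnot(inherits(acq, "acq_params"), inherits(config, "fit_config"))
  signal <- as.complex(signal)
  if (acq$n_echoes < 3L) stop("at least 3 echoes are required")
  if (length(signal) != acq$n_echoes) {
    stop("signal length must equal the number of echoes")
  }
  if (all(Mod(signal) == 0)) {
    return(list(pw = 0 + 0i, pf = 0 + 0i, r2star_per_s = 0, fieldmap_hz = 0,
                residual = 0, converged = TRUE))
  }
  te <- echo_times(acq)
  cmod <- fat_modulation(te, spectrum)
  rng <- config$fieldmap_search_range_hz
  df_grid <- if (config$n_initializations == 1L) mean(rng) else
    seq(rng[1], rng[2], length.out = config$n_initializations)
  r2b <- config$r2star_bounds_per_s
  r2s_grid <- unique(pmin(pmax(c(0.05, 0.4) * r2b[2] + r2b[1], r2b[1]), r2b[2]))
  rssmat <- screen_rss(signal, te, cmod, df_grid, r2s_grid)
  prof <- apply(rssmat, 1, min)              # best rss per df candidate
  # distinct local minima of the df profile (plus global), up to 4 starts
  is_lmin <- vapply(seq_along(prof), function(i) {
    (i == 1 || prof[i] <= prof[i - 1]) &&
      (i == length(prof) || prof[i] <= prof[i + 1])
  }, logical(1))
  starts <- order(prof)[order(prof) %in% which(is_lmin)]
  starts <- utils::head(unique(c(starts, which.min(prof))), 4L)
  s2 <- sum(Mod(signal)^2)
  # Newton polish on the squared residual using the analytic gradient and
  # a finite-difference Hessian; pushes the local solution to machine
  # precision even when strong decay flattens the landscape
  polish <- function(p) {
    for (it in 1:4) {
      g <- varpro_rss(p[1], p[2], signal, te, cmod, want_grad = TRUE)$grad
      h <- c(1e-3, 1e-3)
      H <- matrix(0, 2, 2)
      for (k in 1:2) {
        pp <- p; pp[k] <- p[k] + h[k]
        pm <- p; pm[k] <- p[k] - h[k]
        gp <- varpro_rss(pp[1], pp[2], signal, te, cmod, want_grad = TRUE)$grad
        gm <- varpro_rss(pm[1], pm[2], signal, te, cmod, want_grad = TRUE)$grad
        H[, k] <- (gp - gm) / (2 * h[k])
      }
      H <- (H + t(H)) / 2
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      cand <- p - step
      cand[1] <- min(max(cand[1], rng[1]), rng[2])
      cand[2] <- min(max(cand[2], r2b[1]), r2b[2])
      if (varpro_rss(cand[1], cand[2], signal, te, cmod)$rss <=
          varpro_rss(p[1], p[2], signal, te, cmod)$rss) p <- cand else break
    }
    p
  }
  sols <- list()
  any_conv <- FALSE
  best_rss <- Inf
  for (i in starts) {
    j <- which.min(rssmat[i, ])
    p0 <- c(df_grid[i], r2s_grid[j])
    opt <- stats::optim(
      p0,
      fn = function(p) varpro_rss(p[1], p[2], signal, te, cmod)$rss,
      gr = function(p) varpro_rss(p[1], p[2], signal, te, cmod,
                                  want_grad = TRUE)$grad,
      method = "L-BFGS-B",
      lower = c(rng[1], r2b[1]), upper = c(rng[2], r2b[2]),
      control = list(maxit = config$max_iterations,
                     factr = max(config$convergence_tol / .Machine$double.eps, 1),
                     pgtol = 0))
    if (opt$convergence == 0L) any_conv <- TRUE
    par <- polish(opt$par)
    rss <- varpro_rss(par[1], par[2], signal, te, cmod)$rss
    sols[[length(sols) + 1L]] <- list(par = par, rss = rss)
    best_rss <- min(best_rss, rss)
    # a residual at numerical zero cannot be beaten by another start
    if (best_rss <= config$convergence_tol * s2) break
  }
  # With a uniform echo train the fieldmap is identifiable only modulo
  # 1/delta_TE: shifting df by the alias period rotates water/fat by a
  # global phase and leaves the fit residual unchanged. Explicitly refine
  # the aliases of the current best and break the exact tie toward the
  # smallest off-resonance magnitude (the convention absent spatial
  # information).
  best0 <- sols[[which.min(vapply(sols, `[[`, numeric(1), "rss"))]]
  period <- 1 / acq$delta_te_s
  for (sh in c(-period, period)) {
    cand <- best0$par[1] + sh
    if (cand >= rng[1] && cand <= rng[2]) {
      par <- polish(c(cand, best0$par[2]))
      sols[[length(sols) + 1L]] <- list(
        par = par, rss = varpro_rss(par[1], par[2], signal, te, cmod)$rss)
    }
  }
  best_rss <- min(vapply(sols, `[[`, numeric(1), "rss"))
  tol_tie <- best_rss * 1e-6 + max(config$convergence_tol, 1e-12) * s2
  tied <- Filter(function(s) s$rss <= best_rss + tol_tie, sols)
  best <- tied[[which.min(vapply(tied, function(s) abs(s$par[1]), numeric(1)))]]
  v <- varpro_rss(best$par[1], best$par[2], signal, te, cmod)
  list(pw = v$pw, pf = v$pf, r2star_per_s = best$par[2],
       fieldmap_hz = best$par[1], residual = v$residual,
       converged = any_conv)
}

#' Fit every in-mask voxel of an echo series
#'
#' Applies [fit_voxel()] independently to each voxel inside the mask;
#' voxels outside the mask are zero in the returned maps. Works for any
#' echo count >= 3 (the 6-echo protocol is the reference configuration).
#'
#' @param echoes An [echo_series].
#' @param spectrum A [fat_spectrum].
#' @param config A [fit_config].
#' @param mask Logical matrix `(H, W)`; default keeps voxels with nonzero
#'   mean magnitude via [threshold_mask()].
#' @return An object of class `wf_fit` holding the estimated
#'   [parameter_maps], the per-voxel `residual` map, and a QC count of
#'   voxels whose refinements all hit the iteration cap.
#' @export
fit_image <- function(echoes, spectrum, config = fit_config(), mask = NULL) {
  stopifnot(inherits(echoes, "echo_series"))
  dm <- dim(echoes$data)[2:3]
  if (is.null(mask)) mask <- threshold_mask(echoes)
  if (!is.matrix(mask) || !identical(dim(mask), dm)) {
    stop("mask shape must match the echo series")
  }
  water <- matrix(0i, dm[1], dm[2])
  fat <- matrix(0i, dm[1], dm[2])
  r2s <- matrix(0, dm[1], dm[2])
  dfm <- matrix(0, dm[1], dm[2])
  resid <- matrix(0, dm[1], dm[2])
  n_flag <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    f <- fit_voxel(echoes$data[, i, j], echoes$acquisition, spectrum, config)
    water[i, j] <- f$pw
    fat[i, j] <- f$pf
    r2s[i, j] <- f$r2star_per_s
    dfm[i, j] <- f$fieldmap_hz
    resid[i, j] <- f$residual
    if (!f$converged) n_flag <- n_flag + 1L
  }
  maps <- parameter_maps(water, fat, r2s, dfm, mask)
  structure(list(maps = maps, residual = resid, n_not_converged = n_flag,
                 n_voxels = nrow(idx), config = config,
                 acquisition = echoes$acquisition),
            class = "wf_fit")
}

#' @export
print.wf_fit <- function(x, ...) {
  cat(sprintf("VARPRO water-fat fit: %d voxels, %d echoes\n",
              x$n_voxels, x$acquisition$n_echoes))
  cat(sprintf("  residual (in-mask): median %.3g, max %.3g; %d voxel(s) flagged\n",
              stats::median(x$residual[x$maps$mask]),
              max(x$residual[x$maps$mask]), x$n_not_converged))
  invisible(x)
}

#' @export
summary.wf_fit <- function(object, ...) {
  m <- object$maps
  pd <- pdff(m)
  out <- list(
    n_voxels = object$n_voxels,
    n_not_converged = object$n_not_converged,
    pdff = summary(pd$values[m$mask]),
    r2star_per_s = summary(m$r2star_per_s[m$mask]),
    fieldmap_hz = summary(m$fieldmap_hz[m$mask]),
    residual = summary(object$residual[m$mask]))
  class(out) <- "summary.wf_fit"
  out
}

#' @export
print.summary.wf_fit <- function(x, ...) {
  cat(sprintf("VARPRO fit over %d voxels (%d flagged not converged)\n",
              x$n_voxels, x$n_not_converged))
  for (nm in c("pdff", "r2star_per_s", "fieldmap_hz", "residual")) {
    cat("  ", nm, ":\n", sep = "")
    print(x[[nm]])
  }
  invisible(x)
}

#' @export
coef.wf_fit <- function(object, ...) {
  m <- object$maps
  list(water = m$water, fat = m$fat, r2star_per_s = m$r2star_per_s,
       fieldmap_hz = m$fieldmap_hz)
}

#' @export
residuals.wf_fit <- function(object, ...) object$residual

#' @rdname pdff
#' @export
pdff.wf_fit <- function(x, ...) pdff(x$maps)
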