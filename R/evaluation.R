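# Agreement statistics between PDFF estimation methods: co-localized ROI
# summaries, ordinary least-squares regression, Bland-Altman limits of
# agreement, and one-way ANOVA with Tukey HSD post hoc comparisons of ROI
# standard deviations (a blurring surrogate).

#' Define a region of interest
#'
#' @param pixel_mask Logical matrix marking the ROI pixels.
#' @param label ROI name (e.g. `"RHL"`, `"LHL"`).
#' @param slice_index Slice the ROI belongs to.
#' @return An object of class `roi`.
#' @export
roi <- function(pixel_mask, label = "ROI", slice_index = 1L) {
  stopifnot(is.matrix(pixel_mask))
  pixel_mask <- matrix(as.logical(pixel_mask), nrow(pixel_mask), ncol(pixel_mask))
  if (!any(pixel_mask)) stop("ROI mask is empty")
  structure(list(label = label, slice_index = as.integer(slice_index),
                 pixel_mask = pixel_mask),
            class = "roi")
}

#' Circular ROI helper
#'
#' @param dim_hw Image dimensions `c(H, W)`.
#' @param center `c(row, col)` center.
#' @param radius Radius in pixels.
#' @inheritParams roi
#' @return An [roi].
#' @export
roi_circle <- function(dim_hw, center, radius, label = "ROI",
                       slice_index = 1L) {
  rr <- matrix(seq_len(dim_hw[1]), dim_hw[1], dim_hw[2])
  cc <- matrix(seq_len(dim_hw[2]), dim_hw[1], dim_hw[2], byrow = TRUE)
  roi((rr - center[1])^2 + (cc - center[2])^2 <= radius^2, label, slice_index)
}

#' ROI mean and standard deviation of a PDFF map
#'
#' @param map A `pdff_map` (or plain matrix).
#' @param x An [roi].
#' @return List with `mean` and `std` (sample standard deviation, n - 1
#'   denominator) over ROI pixels inside the map's mask.
#' @export
roi_stats <- function(map, x) {
  stopifnot(inherits(x, "roi"))
  if (inherits(map, "pdff_map")) {
    vals <- map$values
    keep <- x$pixel_mask & map$mask
  } else {
    vals <- map
    keep <- x$pixel_mask
  }
  if (!identical(dim(vals), dim(x$pixel_mask))) {
    stop("ROI dimensions do not match the map")
  }
  if (!any(keep)) stop("ROI does not intersect the map mask")
  v <- vals[keep]
  list(mean = mean(v), std = stats::sd(v), n = length(v))
}

#' Ordinary least-squares regression of test on reference values
#'
#' Fits `y = intercept + slope * x` by least squares and reports the
#' squared Pearson correlation.
#'
#' @param x Reference values (length >= 3).
#' @param y Test values, same length.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
ls_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired values are required")
  if (stats::sd(x) == 0) stop("reference values have zero variance")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(x, y)^2)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the differences `y - x`; the limits of agreement
#' are `bias +/- 1.96` sample standard deviations of the differences.
#'
#' @param x Reference values (length >= 3).
#' @param y Test values, same length.
#' @return List with `bias`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired values are required")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' One-way ANOVA with Tukey HSD post hoc on ROI standard deviations
#'
#' Compares the distributions of ROI standard deviations between methods:
#' one-way ANOVA followed by all-pairs Tukey honest significant
#' difference comparisons. Degenerate input with zero total variance
#' returns p = 1 for every pair with a flag.
#'
#' @param groups Named list of numeric vectors (one per method, each
#'   length >= 2).
#' @param alpha Significance level (default 0.05).
#' @return List with `anova_p`, a data frame `pairs` (comparison,
#'   difference, p, significant), and `degenerate`.
#' @export
anova_posthoc_std <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 values")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                levels = names(groups))
  if (stats::var(vals) == 0) {
    cmb <- utils::combn(names(groups), 2)
    pairs <- data.frame(comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
                        difference = 0, p = 1, significant = FALSE)
    return(list(anova_p = 1, pairs = pairs, degenerate = TRUE, alpha = alpha))
  }
  fit <- stats::aov(vals ~ grp)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$grp
  pairs <- data.frame(comparison = rownames(tk),
                      difference = tk[, "diff"],
                      p = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(anova_p = anova_p, pairs = pairs, degenerate = FALSE, alpha = alpha)
}

#' Per-output mean absolute error between two sets of parameter maps
#'
#' @param pred,ref [parameter_maps] of identical shape.
#' @param mask Logical matrix; defaults to the intersection of both masks.
#' @return Named list of in-mask MAEs for water and fat magnitudes, R2*
#'   (1/s), fieldmap (Hz) and PDFF.
#' @export
mae_map <- function(pred, ref, mask = NULL) {
  stopifnot(inherits(pred, "parameter_maps"), inherits(ref, "parameter_maps"))
  if (!identical(dim(pred$water), dim(ref$water))) {
    stop("map shapes do not match")
  }
  if (is.null(mask)) mask <- pred$mask & ref$mask
  if (!any(mask)) stop("empty mask")
  pp <- pdff(pred)$values
  pr <- pdff(ref)$values
  list(water = mean(abs(Mod(pred$water)[mask] - Mod(ref$water)[mask])),
       fat = mean(abs(Mod(pred$fat)[mask] - Mod(ref$fat)[mask])),
       r2star_per_s = mean(abs(pred$r2star_per_s[mask] - ref$r2star_per_s[mask])),
       fieldmap_hz = mean(abs(pred$fieldmap_hz[mask] - ref$fieldmap_hz[mask])),
       pdff = mean(abs(pp[mask] - pr[mask])))
}

#' Full agreement report between a test and a reference method
#'
#' Reproduces the ROI-level protocol: co-localized ROI means and standard
#' deviations per method, least-squares regression and Bland-Altman
#' analysis of the mean PDFF values (reported in percent), and an ANOVA
#' post hoc (Tukey HSD) comparison of the ROI standard deviations, with
#' both ROIs pooled.
#'
#' @param reference_means,test_means ROI mean PDFF fractions (reference
#'   and test method), equal length >= 3.
#' @param reference_stds,test_stds ROI standard deviations per method.
#' @param alpha Significance level.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(reference_means, test_means,
                             reference_stds, test_stds, alpha = 0.05) {
  reg <- ls_regression(reference_means, test_means)
  ba <- bland_altman(100 * reference_means, 100 * test_means)
  an <- anova_posthoc_std(list(reference = reference_stds, test = test_stds),
                          alpha = alpha)
  structure(list(
    n = length(reference_means),
    roi_means = data.frame(reference = reference_means, test = test_means),
    roi_stds = data.frame(reference = reference_stds, test = test_stds),
    regression = reg, bland_altman_percent = ba, anova = an, alpha = alpha),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("PDFF agreement over %d ROI measurements\n", x$n))
  cat(sprintf("  regression: slope %.3f, intercept %.4f, R^2 %.3f\n",
              x$regression$slope, x$regression$intercept,
              x$regression$r_squared))
  cat(sprintf("  Bland-Altman: bias %.2f%%, LoA [%.2f%%, %.2f%%]\n",
              x$bland_altman_percent$bias, x$bland_altman_percent$loa_low,
              x$bland_altman_percent$loa_high))
  cat(sprintf("  ANOVA on ROI STDs: p = %.4f (%s at alpha = %.2f)\n",
              x$anova$anova_p,
              ifelse(any(x$anova$pairs$significant), "significant",
                     "not significant"), x$alpha))
  invisible(x)
}
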