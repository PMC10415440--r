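# Per-voxel parameter maps: complex water and fat signals, R2* decay,
# off-resonance field, and the foreground mask. The PDFF map derives from
# the water/fat magnitudes.

#' Construct per-voxel water-fat parameter maps
#'
#' Holds the four unknowns of the voxel-wise CSE-MRI signal model on a 2-D
#' grid: complex water signal `water` (PW), complex fat signal `fat` (PF),
#' transverse relaxation rate `r2star_per_s` (R2*, 1/s, non-negative) and the
#' off-resonance field `fieldmap_hz` (Hz), plus a logical foreground `mask`.
#' All arrays share one shape; values outside the mask are forced to zero.
#'
#' @param water,fat Complex (or numeric) matrices, same shape.
#' @param r2star_per_s Numeric matrix, >= 0 inside the mask.
#' @param fieldmap_hz Numeric matrix.
#' @param mask Logical matrix; defaults to all `TRUE`.
#' @return An object of class `parameter_maps`.
#' @export
parameter_maps <- function(water, fat, r2star_per_s, fieldmap_hz, mask = NULL) {
  water <- as_complex_matrix(water)
  fat <- as_complex_matrix(fat)
  dm <- dim(water)
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  r2star_per_s <- as_numeric_matrix(r2star_per_s)
  fieldmap_hz <- as_numeric_matrix(fieldmap_hz)
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  shapes <- list(fat, r2star_per_s, fieldmap_hz, mask)
  if (!all(vapply(shapes, function(a) identical(dim(a), dm), logical(1)))) {
    stop("all parameter map arrays must share one shape")
  }
  if (any(r2star_per_s[mask] < 0)) stop("r2star_per_s must be non-negative inside the mask")
  if (anyNA(mask)) stop("mask must not contain NA")
  # zero outside mask (contract: background carries no signal)
  water[!mask] <- 0 + 0i
  fat[!mask] <- 0 + 0i
  r2star_per_s[!mask] <- 0
  fieldmap_hz[!mask] <- 0
  structure(list(water = water, fat = fat, r2star_per_s = r2star_per_s,
                 fieldmap_hz = fieldmap_hz, mask = mask),
            class = "parameter_maps")
}

as_complex_matrix <- function(x) {
  if (!is.matrix(x)) stop("parameter maps must be matrices")
  matrix(as.complex(x), nrow(x), ncol(x))
}

as_numeric_matrix <- function(x) {
  if (!is.matrix(x)) stop("parameter maps must be matrices")
  if (is.complex(x)) stop("r2star/fieldmap maps must be real-valued")
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' @export
print.parameter_maps <- function(x, ...) {
  dm <- dim(x$water)
  cat(sprintf("Water-fat parameter maps %dx%d (%d in-mask voxels)\n",
              dm[1], dm[2], sum(x$mask)))
  if (any(x$mask)) {
    pd <- pdff(x)
    cat(sprintf("  PDFF in-mask: %.3f - %.3f (median %.3f)\n",
                min(pd$values[x$mask]), max(pd$values[x$mask]),
                stats::median(pd$values[x$mask])))
    cat(sprintf("  R2* in-mask (1/s): %.1f - %.1f; |fieldmap| max %.1f Hz\n",
                min(x$r2star_per_s[x$mask]), max(x$r2star_per_s[x$mask]),
                max(abs(x$fieldmap_hz[x$mask]))))
  }
  invisible(x)
}

#' Proton density fat fraction
#'
#' `PDFF = |PF| / (|PW| + |PF|)`, computed voxel-wise from the water and fat
#' magnitudes. Voxels with zero total signal (`|PW| + |PF| = 0`) get PDFF 0;
#' such voxels are background by construction and flagged outside the mask of
#' the returned map.
#'
#' @param x A [parameter_maps] object (or an object with a `pdff` method).
#' @param ... Passed to methods.
#' @return An object of class `pdff_map` with fields `values` (matrix in
#'   `[0, 1]`) and `mask`.
#' @export
pdff <- function(x, ...) UseMethod("pdff")

#' @rdname pdff
#' @export
pdff.parameter_maps <- function(x, ...) {
  aw <- Mod(x$water)
  af <- Mod(x$fat)
  tot <- aw + af
  vals <- matrix(0, nrow(aw), ncol(aw))
  nz <- tot > 0
  vals[nz] <- af[nz] / tot[nz]
  mask <- x$mask & nz
  structure(list(values = vals, mask = mask), class = "pdff_map")
}

#' @export
print.pdff_map <- function(x, ...) {
  cat(sprintf("PDFF map %dx%d", nrow(x$values), ncol(x$values)))
  if (any(x$mask)) {
    v <- x$values[x$mask]
    cat(sprintf(": in-mask mean %.3f (range %.3f - %.3f)", mean(v), min(v), max(v)))
  }
  cat("\n")
  invisible(x)
}
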