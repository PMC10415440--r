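# Persistence: complex echo series as paired real/imaginary NIfTI volumes
# with a JSON sidecar carrying echo times and acquisition parameters;
# parameter maps as one NIfTI per component; ROI sets as run-length-encoded
# JSON; dataset directories with a manifest.

ECHO_SCHEMA_VERSION <- "1.0"

#' Write / read a complex echo series
#'
#' `write_echoes()` stores the series in a directory as `echoes_real.nii` and
#' `echoes_imag.nii` (H x W x n_echoes volumes) plus a sidecar
#' `echoes.json` with the schema version, echo times (s) and acquisition
#' parameters. `read_echoes()` restores it losslessly. A directory holding
#' only the real volume is accepted with a warning (imaginary part
#' zero-filled), supporting magnitude-only legacy exports.
#'
#' @param echoes An [echo_series].
#' @param path Directory (created if needed).
#' @return `write_echoes()`: the directory, invisibly. `read_echoes()`: an
#'   [echo_series].
#' @export
write_echoes <- function(echoes, path) {
  stopifnot(inherits(echoes, "echo_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(echoes$data)
  vol <- function(part) {
    a <- array(0, c(dm[2], dm[3], dm[1]))
    for (n in seq_len(dm[1])) a[, , n] <- part(echoes$data[n, , ])
    a
  }
  RNifti::writeNifti(RNifti::asNifti(vol(Re)), file.path(path, "echoes_real.nii"))
  RNifti::writeNifti(RNifti::asNifti(vol(Im)), file.path(path, "echoes_imag.nii"))
  acq <- echoes$acquisition
  side <- list(schema_version = ECHO_SCHEMA_VERSION,
               echo_times_s = echoes$echo_times_s,
               acquisition = list(te1_s = acq$te1_s, delta_te_s = acq$delta_te_s,
                                  n_echoes = acq$n_echoes,
                                  field_strength_t = acq$field_strength_t))
  jsonlite::write_json(side, file.path(path, "echoes.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_echoes
#' @export
read_echoes <- function(path) {
  side_path <- file.path(path, "echoes.json")
  if (!file.exists(side_path)) {
    stop("missing metadata sidecar: ", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  for (field in c("echo_times_s", "acquisition")) {
    if (is.null(side[[field]])) {
      stop("echo sidecar is missing required field: ", field)
    }
  }
  for (field in c("te1_s", "delta_te_s", "n_echoes", "field_strength_t")) {
    if (is.null(side$acquisition[[field]])) {
      stop("echo sidecar acquisition block is missing field: ", field)
    }
  }
  acq <- acq_params(side$acquisition$te1_s, side$acquisition$delta_te_s,
                    side$acquisition$n_echoes,
                    side$acquisition$field_strength_t)
  re_path <- file.path(path, "echoes_real.nii")
  if (!file.exists(re_path)) stop("missing volume: ", re_path)
  re <- as.array(RNifti::readNifti(re_path))
  im_path <- file.path(path, "echoes_imag.nii")
  if (file.exists(im_path)) {
    im <- as.array(RNifti::readNifti(im_path))
  } else {
    warning("no imaginary volume found; zero-filling the imaginary channel")
    im <- array(0, dim(re))
  }
  if (length(dim(re)) == 2L) {
    re <- array(re, c(dim(re), 1L))
    im <- array(im, c(dim(im), 1L))
  }
  dm <- dim(re)
  dat <- array(0i, c(dm[3], dm[1], dm[2]))
  for (n in seq_len(dm[3])) {
    dat[n, , ] <- complex(real = re[, , n], imaginary = im[, , n])
  }
  echo_series(dat, as.numeric(side$echo_times_s), acq)
}

#' Write / read parameter maps
#'
#' Each component is stored as its own NIfTI volume (`water_real.nii`,
#' `water_imag.nii`, `fat_real.nii`, `fat_imag.nii`, `r2star.nii`,
#' `fieldmap.nii`, `mask.nii`) in the given directory.
#'
#' @param maps A [parameter_maps] object.
#' @param path Directory (created if needed).
#' @return `write_maps()`: the directory, invisibly. `read_maps()`: a
#'   [parameter_maps].
#' @export
write_maps <- function(maps, path) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) RNifti::writeNifti(RNifti::asNifti(x),
                                          file.path(path, f))
  wr(Re(maps$water), "water_real.nii"); wr(Im(maps$water), "water_imag.nii")
  wr(Re(maps$fat), "fat_real.nii"); wr(Im(maps$fat), "fat_imag.nii")
  wr(maps$r2star_per_s, "r2star.nii")
  wr(maps$fieldmap_hz, "fieldmap.nii")
  wr(maps$mask * 1, "mask.nii")
  invisible(path)
}

#' @rdname write_maps
#' @export
read_maps <- function(path) {
  rd <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("missing map volume: ", p)
    m <- as.array(RNifti::readNifti(p))
    matrix(m, dim(m)[1], dim(m)[2])
  }
  parameter_maps(
    water = matrix(complex(real = rd("water_real.nii"),
                           imaginary = rd("water_imag.nii")),
                   nrow(rd("mask.nii")), ncol(rd("mask.nii"))),
    fat = matrix(complex(real = rd("fat_real.nii"),
                         imaginary = rd("fat_imag.nii")),
                 nrow(rd("mask.nii")), ncol(rd("mask.nii"))),
    r2star_per_s = rd("r2star.nii"),
    fieldmap_hz = rd("fieldmap.nii"),
    mask = rd("mask.nii") > 0.5)
}

#' Write / read ROI definitions as JSON
#'
#' ROIs are stored with their label, slice index, image dimensions and a
#' run-length encoding of the column-major pixel mask.
#'
#' @param rois List of [roi] objects.
#' @param path JSON file path.
#' @return `write_rois()`: the path, invisibly. `read_rois()`: a list of
#'   [roi] objects.
#' @export
write_rois <- function(rois, path) {
  enc <- lapply(rois, function(r) {
    rl <- rle(as.vector(r$pixel_mask))
    list(label = r$label, slice_index = r$slice_index,
         dim = dim(r$pixel_mask),
         rle_lengths = rl$lengths, rle_values = rl$values)
  })
  jsonlite::write_json(list(schema_version = "1.0", rois = enc), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rois)) stop("not an ROI file: ", path)
  lapply(seq_len(nrow(obj$rois)), function(i) {
    rec <- obj$rois[i, ]
    m <- matrix(inverse.rle(structure(
      list(lengths = rec$rle_lengths[[1]], values = rec$rle_values[[1]]),
      class = "rle")), rec$dim[[1]][1], rec$dim[[1]][2])
    roi(m, rec$label, rec$slice_index)
  })
}

#' Write a phantom dataset to a directory with a manifest
#'
#' Each record of a [phantom_dataset()] is stored in `slice_<k>/` (echo
#' series plus ground-truth maps); `manifest.json` records the schema
#' version, generation seed, phantom configuration and per-slice paths.
#'
#' @param records Output of [phantom_dataset()].
#' @param path Dataset directory.
#' @param config The generating [phantom_config].
#' @param seed The master seed used.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(records, path, config, seed) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  slices <- vector("list", length(records))
  for (k in seq_along(records)) {
    sub <- sprintf("slice_%03d", k)
    write_echoes(records[[k]]$echoes, file.path(path, sub, "echoes"))
    write_maps(records[[k]]$maps, file.path(path, sub, "maps"))
    slices[[k]] <- list(path = sub, subject = records[[k]]$subject,
                        slice = records[[k]]$slice)
  }
  jsonlite::write_json(
    list(schema_version = "1.0", seed = seed,
         config = unclass(config), slices = slices),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom dataset directory
#'
#' @param path Dataset directory containing `manifest.json`.
#' @return List of records (`maps`, `echoes`, `subject`, `slice`).
#' @export
read_dataset <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("missing dataset manifest: ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  lapply(man$slices, function(sl) {
    list(maps = read_maps(file.path(path, sl$path, "maps")),
         echoes = read_echoes(file.path(path, sl$path, "echoes")),
         subject = sl$subject, slice = sl$slice)
  })
}
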