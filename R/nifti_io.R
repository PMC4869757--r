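# NIfTI reading/writing for grid-aware containers. 4D series carry their
# frame timing in a YAML sidecar (<file>.timing.yaml) because the NIfTI
# header has no reliable per-frame timing fields.

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".timing.yaml")
}

grid_to_affine <- function(grid) {
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  aff
}

affine_to_grid <- function(aff, shape) {
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0)) stop("degenerate affine: zero-length axis")
  offdiag <- rot - diag(diag(rot))
  if (max(abs(offdiag)) > 1e-4 * max(spacing))
    stop("oblique affines are not supported: grid axes must be axis-aligned")
  if (any(diag(rot) < 0))
    stop("axis-flipping affines are not supported")
  image_grid(shape, diag(rot), aff[1:3, 4])
}

#' Read a NIfTI volume as a parametric map or dynamic series
#'
#' 3D files become a [parametric_map]; 4D files become a [dynamic_series] and
#' require a timing sidecar (`<file>.timing.yaml` with `frame_starts` and
#' `frame_durations` in seconds). Unit and name are taken from the sidecar
#' when present, otherwise the unit defaults to "unknown".
#'
#' @param path path to a NIfTI-1/2 file (.nii or .nii.gz).
#' @return A `parametric_map` (3D) or `dynamic_series` (4D).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header in ", path,
                                           ": ", conditionMessage(e)))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # strip RNifti metadata
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L))
    stop("expected a 3D or 4D volume, got ", nd, "D")
  aff <- RNifti::xform(img)
  grid <- affine_to_grid(unclass(aff), dim(arr)[1:3])
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  unit <- if (!is.null(meta$unit)) meta$unit else "unknown"
  name <- if (!is.null(meta$name)) meta$name else
    sub("\\.nii(\\.gz)?$", "", basename(path))
  if (nd == 3L)
    return(parametric_map(grid, arr, unit = unit, name = name))
  if (is.null(meta$frame_starts) || is.null(meta$frame_durations))
    stop("4D volume ", path, " has no timing metadata: expected sidecar ",
         side, " with frame_starts and frame_durations (seconds)")
  dynamic_series(grid, arr,
                 frame_starts = as.numeric(meta$frame_starts),
                 frame_durations = as.numeric(meta$frame_durations),
                 unit = unit, name = name)
}

#' Write a parametric map or dynamic series as NIfTI
#'
#' The grid is stored in the sform affine; unit, name and (for series) frame
#' timing go to a YAML sidecar next to the file.
#'
#' @param x a `parametric_map` or `dynamic_series`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  UseMethod("write_volume")
}

write_nifti_array <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(grid_to_affine(grid), code = 2L))
  RNifti::writeNifti(img, path)
}

#' @export
write_volume.parametric_map <- function(x, path) {
  write_nifti_array(x$values, x$grid, path)
  yaml::write_yaml(list(unit = x$unit, name = x$name), sidecar_path(path))
  invisible(path)
}

#' @export
write_volume.dynamic_series <- function(x, path) {
  write_nifti_array(x$frames, x$grid, path)
  yaml::write_yaml(list(unit = x$unit, name = x$name,
                        frame_starts = as.numeric(x$frame_starts),
                        frame_durations = as.numeric(x$frame_durations)),
                   sidecar_path(path))
  invisible(path)
}

#' @export
write_volume.roi_mask <- function(x, path) {
  write_nifti_array(array(as.double(x$membership), dim(x$membership)),
                    x$grid, path)
  yaml::write_yaml(list(unit = "binary", name = x$label), sidecar_path(path))
  invisible(path)
}

#' Read a NIfTI mask file written by [write_volume]
#'
#' @param path path to the mask volume; voxels > 0.5 become members.
#' @param label ROI label; defaults to the stored name.
#' @return An `roi_mask`.
#' @export
read_mask <- function(path, label = NULL) {
  m <- read_volume(path)
  if (!inherits(m, "parametric_map")) stop("mask file must be 3D")
  roi_mask(m$grid, m$values > 0.5,
           label = if (is.null(label)) m$name else label)
}
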