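#' Regular 3D image grid
#'
#' Defines the sampling lattice shared by all maps, series and masks: the
#' number of voxels per axis, the voxel spacing in mm and the world position
#' (in mm) of the *center* of voxel index (0,0,0). Grids are axis-aligned;
#' oblique acquisitions are not represented.
#'
#' @param shape integer triple, voxels per axis (all >= 1).
#' @param spacing positive real triple, mm per voxel.
#' @param origin real triple, mm; world coordinate of the first voxel center.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 40), c(2.8, 2.8, 2.0))
#' @export
image_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("shape, spacing and origin must each have length 3")
  if (any(!is.finite(shape)) || any(shape < 1L))
    stop("all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be > 0")
  if (any(!is.finite(origin)))
    stop("origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> shape %s, spacing %s mm, origin %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Compare two grids for equality
#'
#' Two grids are equal iff shape matches exactly and spacing and origin agree
#' within `tol` mm per component.
#'
#' @param a,b `image_grid` objects.
#' @param tol absolute tolerance in mm.
#' @return logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "image_grid"), inherits(b, "image_grid"))
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' World coordinates of all voxel centers of a grid
#'
#' @param grid an `image_grid`.
#' @return n-voxel x 3 matrix of world coordinates (mm), voxels in R's
#'   column-major array order.
#' @export
grid_coordinates <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape) - 1L
  sweep(sweep(idx, 2L, grid$spacing, `*`), 2L, grid$origin, `+`)
}

#' Parametric map: one scalar per grid voxel with a physical unit
#'
#' Non-finite values (`NA`/`NaN`) mark *invalid* voxels, e.g. outside the
#' interpolation field of view or where a per-voxel computation had no
#' physical solution.
#'
#' @param grid an `image_grid`.
#' @param values numeric array with dim equal to `grid$shape`.
#' @param unit non-empty unit label (e.g. "kBq/mL", "SUV", "TBR", "mm^2/s",
#'   "1/min", "dimensionless").
#' @param name modality / parameter label.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(grid, values, unit, name = "") {
  stopifnot(inherits(grid, "image_grid"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values dim must equal grid shape")
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop("unit label must be a non-empty string")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, unit = unit, name = name),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<parametric_map> '%s' [%s] on %s grid; %d/%d valid voxels",
              x$name, x$unit, paste(x$grid$shape, collapse = "x"),
              length(v), length(x$values)))
  if (length(v)) cat(sprintf("; range %.4g..%.4g", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Time-stamped dynamic series on one grid
#'
#' @param grid an `image_grid`.
#' @param frames 4D numeric array (x, y, z, t) of per-frame volumes.
#' @param frame_starts frame start times, seconds, sorted ascending.
#' @param frame_durations positive frame durations, seconds.
#' @param unit unit label.
#' @param name series label.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(grid, frames, frame_starts, frame_durations,
                           unit, name = "") {
  stopifnot(inherits(grid, "image_grid"))
  frames <- as.array(frames)
  if (length(dim(frames)) != 4L)
    stop("frames must be a 4D array (x, y, z, t)")
  if (!identical(as.integer(dim(frames)[1:3]), grid$shape))
    stop("frame volumes must match grid shape")
  nt <- dim(frames)[4L]
  frame_starts <- as.numeric(frame_starts)
  frame_durations <- as.numeric(frame_durations)
  if (length(frame_durations) == 1L)
    frame_durations <- rep(frame_durations, nt)
  if (length(frame_starts) != nt || length(frame_durations) != nt)
    stop("frame timing length must equal the number of frames")
  if (any(frame_durations <= 0)) stop("frame durations must be positive")
  if (is.unsorted(frame_starts, strictly = FALSE))
    stop("frames must be sorted by start time")
  if (nt > 1L) {
    overlap <- frame_starts[-1L] - (frame_starts[-nt] + frame_durations[-nt])
    if (any(overlap < -1e-9)) stop("frames must not overlap in time")
  }
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop("unit label must be a non-empty string")
  storage.mode(frames) <- "double"
  structure(list(grid = grid, frames = frames, frame_starts = frame_starts,
                 frame_durations = frame_durations, unit = unit, name = name),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  nt <- dim(x$frames)[4L]
  cat(sprintf(
    "<dynamic_series> '%s' [%s]: %d frames on %s grid, t = %.1f..%.1f s\n",
    x$name, x$unit, nt, paste(x$grid$shape, collapse = "x"),
    x$frame_starts[1L], x$frame_starts[nt] + x$frame_durations[nt]))
  invisible(x)
}

#' Number of frames in a dynamic series
#' @param series a `dynamic_series`.
#' @return integer frame count.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  dim(series$frames)[4L]
}

#' Region-of-interest mask on a grid
#'
#' @param grid an `image_grid`.
#' @param membership logical array matching `grid$shape`, at least one `TRUE`.
#' @param label one of "GTV", "background-muscle", "carotid" (or another
#'   descriptive label).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(grid, membership, label = "GTV") {
  stopifnot(inherits(grid, "image_grid"))
  membership <- as.array(membership)
  if (!identical(as.integer(dim(membership)), grid$shape))
    stop("mask dim must equal grid shape")
  storage.mode(membership) <- "logical"
  if (anyNA(membership)) stop("mask membership must not contain NA")
  if (!any(membership)) stop("mask must contain at least one voxel")
  structure(list(grid = grid, membership = membership, label = label),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels (%.1f cm^3) on %s grid\n",
              x$label, sum(x$membership),
              sum(x$membership) * prod(x$grid$spacing) / 1000,
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Voxel volume of a grid in cubic millimetres
#' @param grid an `image_grid`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)
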