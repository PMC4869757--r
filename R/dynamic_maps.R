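# Collapse dynamic series into wash-in summary maps and compute ADC from a
# two-b-value diffusion acquisition.

#' Time window for wash-in integration
#'
#' @param start,end window bounds in seconds, `0 <= start < end`. The default
#'   (0, 240) s covers the first four minutes after injection.
#' @return An object of class `integration_window`.
#' @export
integration_window <- function(start = 0, end = 240) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    stop("window must satisfy 0 <= start < end")
  structure(list(start = start, end = end), class = "integration_window")
}

#' Time-averaged activity map over a window (rectangle method)
#'
#' Each frame contributes its value times the length of its overlap with the
#' window (piecewise-constant-over-frame convention); the sum is divided by
#' the window length. Applied to an early dynamic FMISO series with the
#' default 0-4 min window this yields the mean wash-in activity map; applied
#' to a baseline-subtracted DCE series it yields the mean signal-enhancement
#' map.
#'
#' @param series a `dynamic_series`.
#' @param window an [integration_window]; default 0-240 s.
#' @return A `parametric_map` in the series' unit.
#' @export
mean_activity_map <- function(series, window = integration_window()) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(window, "integration_window"))
  s <- series$frame_starts
  e <- series$frame_starts + series$frame_durations
  ov <- pmax(0, pmin(e, window$end) - pmax(s, window$start))
  wlen <- window$end - window$start

  # coverage check: union of frame overlaps must cover the window up to a
  # gap smaller than one frame duration
  gap_tol <- max(series$frame_durations[ov > 0], 0)
  covered <- sum(ov)  # frames are non-overlapping, so overlaps do not double-count
  if (wlen - covered > gap_tol - 1e-9) {
    # report the first uncovered interval
    pts <- sort(unique(c(window$start, window$end,
                         pmax(pmin(s, window$end), window$start),
                         pmax(pmin(e, window$end), window$start))))
    miss <- NULL
    for (i in seq_len(length(pts) - 1L)) {
      mid <- (pts[i] + pts[i + 1L]) / 2
      if (!any(s <= mid & e > mid)) { miss <- c(pts[i], pts[i + 1L]); break }
    }
    stop(sprintf(
      "frames cover only %.1f of %.1f s of the window (gap tolerance %.1f s); missing interval approx. [%.1f, %.1f] s",
      covered, wlen, gap_tol,
      if (is.null(miss)) NA_real_ else miss[1],
      if (is.null(miss)) NA_real_ else miss[2]))
  }

  nt <- dim(series$frames)[4L]
  nv <- prod(series$grid$shape)
  vals <- matrix(series$frames, nrow = nv, ncol = nt) %*% ov / wlen
  parametric_map(series$grid, array(vals, series$grid$shape),
                 unit = series$unit,
                 name = paste0("mean(", series$name, ")"))
}

#' Baseline-subtracted signal enhancement series
#'
#' Subtracts from every frame the per-voxel mean of the first
#' `n_baseline_frames` frames (the pre-injection signal).
#'
#' @param series a `dynamic_series`.
#' @param n_baseline_frames number of pre-injection frames, `>= 1` and less
#'   than the frame count.
#' @return A `dynamic_series` with unit "signal-difference".
#' @export
signal_enhancement_series <- function(series, n_baseline_frames) {
  stopifnot(inherits(series, "dynamic_series"))
  nt <- dim(series$frames)[4L]
  n_baseline_frames <- as.integer(n_baseline_frames)
  if (is.na(n_baseline_frames) || n_baseline_frames < 1L ||
      n_baseline_frames >= nt)
    stop("n_baseline_frames must be in [1, frame count)")
  nv <- prod(series$grid$shape)
  fm <- matrix(series$frames, nrow = nv, ncol = nt)
  base <- rowMeans(fm[, seq_len(n_baseline_frames), drop = FALSE])
  enh <- fm - base
  dynamic_series(series$grid, array(enh, dim(series$frames)),
                 series$frame_starts, series$frame_durations,
                 unit = "signal-difference",
                 name = paste0("enhancement(", series$name, ")"))
}

#' ADC map from a two-b-value diffusion acquisition
#'
#' Monoexponential model `S(b) = S0 * exp(-b * ADC)`:
#' `ADC = ln(S(b1)/S(b2)) / (b2 - b1)`. Voxels with non-positive signal or
#' `S(b2) > S(b1)` (negative ADC) are flagged invalid; equal signals give
#' ADC = 0.
#'
#' @param s_low,s_high `parametric_map`s acquired at the lower/higher b-value.
#' @param b_values numeric pair (b1, b2) in s/mm^2 with `b2 > b1 >= 0`.
#' @return A `parametric_map` in mm^2/s.
#' @export
adc_from_two_b <- function(s_low, s_high, b_values = c(50, 800)) {
  stopifnot(inherits(s_low, "parametric_map"),
            inherits(s_high, "parametric_map"))
  if (!grids_equal(s_low$grid, s_high$grid))
    stop("the two diffusion-weighted maps must share one grid")
  b_values <- as.numeric(b_values)
  if (length(b_values) != 2L || b_values[1] < 0 ||
      b_values[2] <= b_values[1])
    stop("b_values must satisfy b2 > b1 >= 0")
  lo <- s_low$values; hi <- s_high$values
  adc <- log(lo / hi) / (b_values[2] - b_values[1])
  bad <- !is.finite(lo) | !is.finite(hi) | lo <= 0 | hi <= 0 | hi > lo
  adc[bad] <- NA_real_
  parametric_map(s_low$grid, adc, unit = "mm^2/s", name = "ADC")
}
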