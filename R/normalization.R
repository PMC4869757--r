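# SUV and tumor-to-background normalization of PET activity maps. Both are
# strictly monotone per-voxel transforms, so downstream rank correlations
# are invariant to them.

#' Tracer injection record
#'
#' @param injected_activity_MBq injected activity in MBq, decay-corrected to
#'   scan start by the caller.
#' @param body_weight_kg patient body weight in kg.
#' @return An object of class `injection_record`.
#' @export
injection_record <- function(injected_activity_MBq, body_weight_kg) {
  if (!is.finite(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("injected activity must be > 0")
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be > 0")
  structure(list(injected_activity_MBq = injected_activity_MBq,
                 body_weight_kg = body_weight_kg),
            class = "injection_record")
}

#' Convert an activity map to standardized uptake values
#'
#' `SUV = activity [kBq/mL] / (injected activity [kBq] / body weight [g])`,
#' assuming 1 g/mL tissue density. No decay arithmetic is performed here;
#' the injected activity is taken as already decay-corrected to scan start.
#'
#' @param activity a `parametric_map` with unit "kBq/mL".
#' @param injection an [injection_record].
#' @return A `parametric_map` in SUV.
#' @export
to_suv <- function(activity, injection) {
  stopifnot(inherits(activity, "parametric_map"),
            inherits(injection, "injection_record"))
  if (activity$unit != "kBq/mL")
    stop("to_suv expects activity in kBq/mL, got '", activity$unit, "'")
  denom <- injection$injected_activity_MBq * 1000 /
    (injection$body_weight_kg * 1000)  # kBq per g
  parametric_map(activity$grid, activity$values / denom,
                 unit = "SUV", name = paste0(activity$name, "-SUV"))
}

#' Convert an activity map to tumor-to-background ratio
#'
#' Every voxel is divided by the mean (or, optionally, median) activity over
#' the background-muscle ROI.
#'
#' @param activity a `parametric_map`.
#' @param background an `roi_mask` (deep neck muscle) on the activity grid.
#' @param stat background statistic, "mean" (default) or "median".
#' @return A `parametric_map` in TBR.
#' @export
to_tbr <- function(activity, background, stat = c("mean", "median")) {
  stopifnot(inherits(activity, "parametric_map"),
            inherits(background, "roi_mask"))
  stat <- match.arg(stat)
  if (!grids_equal(activity$grid, background$grid))
    stop("background mask must be on the activity grid")
  bgvals <- activity$values[background$membership]
  bgvals <- bgvals[is.finite(bgvals)]
  if (length(bgvals) == 0L) stop("background ROI has no valid voxels")
  bg <- if (stat == "mean") mean(bgvals) else stats::median(bgvals)
  if (!is.finite(bg) || bg <= 0)
    stop("background level must be > 0, got ", signif(bg, 4))
  parametric_map(activity$grid, activity$values / bg,
                 unit = "TBR", name = paste0(activity$name, "-TBR"))
}
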