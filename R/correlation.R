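# Paired sampling within the GTV at voxel and regional (3x3x4-block) level,
# tie-corrected Spearman coefficients, per-patient correlation matrices and
# cohort summaries with the <10-subregion exclusion rule.

#' Spearman rank correlation coefficient (tie-corrected)
#'
#' Pearson correlation of the average-ranked data (ties receive the mean of
#' the ranks they occupy).
#'
#' @param x,y numeric vectors of equal length `>= 2`, finite, each with at
#'   least two distinct values.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 paired samples")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  stats::cor(rx, ry)
}

#' Paired voxel samples of two maps within the GTV
#'
#' @param map_a,map_b `parametric_map`s on the GTV grid.
#' @param gtv an `roi_mask`.
#' @return An object of class `sample_set`: paired vectors `x`/`y`, sample
#'   count `n`, dropped-voxel count `n_dropped` (GTV voxels invalid in
#'   either map), `level = "voxel"` and the two map names.
#' @export
voxel_samples <- function(map_a, map_b, gtv) {
  stopifnot(inherits(map_a, "parametric_map"),
            inherits(map_b, "parametric_map"),
            inherits(gtv, "roi_mask"))
  if (!grids_equal(map_a$grid, gtv$grid) ||
      !grids_equal(map_b$grid, gtv$grid))
    stop("maps and GTV mask must share one grid (resample upstream)")
  a <- map_a$values[gtv$membership]
  b <- map_b$values[gtv$membership]
  keep <- is.finite(a) & is.finite(b)
  n <- sum(keep)
  if (n < 2L)
    stop("fewer than 2 valid paired samples in the GTV (",
         sum(!keep), " voxels dropped)")
  structure(list(x = a[keep], y = b[keep], n = n,
                 n_dropped = sum(!keep), level = "voxel",
                 labels = c(map_a$name, map_b$name)),
            class = "sample_set")
}

#' Sub-region specification for regional analysis
#'
#' Blocks of `block_shape` voxels tile the GTV bounding box anchored at its
#' minimal corner; a block is kept when at least `min_gtv_fraction` of its
#' voxels belong to the GTV.
#'
#' @param block_shape voxel-count triple; default `c(3, 3, 4)`, which on the
#'   2.8 x 2.8 x 2.0 mm PET grid spans 8.4 x 8.4 x 8 mm^3.
#' @param min_gtv_fraction required GTV occupancy in `(0, 1]`; default 0.5.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(block_shape = c(3L, 3L, 4L), min_gtv_fraction = 0.5) {
  block_shape <- as.integer(block_shape)
  if (length(block_shape) != 3L || any(block_shape < 1L))
    stop("block_shape must be three integers >= 1")
  if (!is.finite(min_gtv_fraction) || min_gtv_fraction <= 0 ||
      min_gtv_fraction > 1)
    stop("min_gtv_fraction must be in (0, 1]")
  structure(list(block_shape = block_shape,
                 min_gtv_fraction = min_gtv_fraction),
            class = "region_spec")
}

#' Partition a GTV into non-overlapping sub-region blocks
#'
#' Tiles the GTV bounding box with blocks of `spec$block_shape` anchored at
#' the box's minimal corner. A block is kept iff the fraction of its voxels
#' inside the GTV is at least `spec$min_gtv_fraction`; each kept region
#' contains only its GTV voxels.
#'
#' @param gtv an `roi_mask`.
#' @param spec a [region_spec].
#' @return List of integer vectors of linear voxel indices (possibly empty
#'   when no block qualifies). The physical block extent in mm is attached
#'   as attribute `block_extent_mm`.
#' @export
partition_regions <- function(gtv, spec = region_spec()) {
  stopifnot(inherits(gtv, "roi_mask"), inherits(spec, "region_spec"))
  bs <- spec$block_shape
  shape <- gtv$grid$shape
  idx <- which(gtv$membership, arr.ind = TRUE)
  lo <- apply(idx, 2L, min)
  hi <- apply(idx, 2L, max)
  nb <- ceiling((hi - lo + 1L) / bs)
  blocksize <- prod(bs)

  regions <- list()
  for (k in seq_len(nb[3]) - 1L) for (j in seq_len(nb[2]) - 1L)
    for (i in seq_len(nb[1]) - 1L) {
      r1 <- lo + c(i, j, k) * bs
      r2 <- pmin(r1 + bs - 1L, shape)
      xs <- r1[1]:r2[1]; ys <- r1[2]:r2[2]; zs <- r1[3]:r2[3]
      sub <- gtv$membership[xs, ys, zs, drop = FALSE]
      if (sum(sub) / blocksize >= spec$min_gtv_fraction) {
        g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
        lin <- g[, 1] + shape[1] * (g[, 2] - 1L + shape[2] * (g[, 3] - 1L))
        regions[[length(regions) + 1L]] <- sort(lin[as.vector(sub)])
      }
    }
  attr(regions, "block_extent_mm") <- bs * gtv$grid$spacing
  attr(regions, "spec") <- spec
  regions
}

#' Paired regional samples of two maps
#'
#' One paired sample per region: the mean of each map over the region's GTV
#' voxels (invalid voxels excluded from the mean). Regions with no valid
#' voxel in either map are dropped and counted.
#'
#' @param map_a,map_b `parametric_map`s on one grid.
#' @param regions list of linear voxel-index vectors from
#'   [partition_regions].
#' @return A `sample_set` with `level = "regional"`.
#' @export
regional_samples <- function(map_a, map_b, regions) {
  stopifnot(inherits(map_a, "parametric_map"),
            inherits(map_b, "parametric_map"))
  if (!grids_equal(map_a$grid, map_b$grid))
    stop("maps must share one grid")
  if (length(regions) == 0L) stop("regions must be non-empty")
  va <- as.vector(map_a$values); vb <- as.vector(map_b$values)
  mean_valid <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)])
    else NA_real_
  xa <- vapply(regions, function(r) mean_valid(va[r]), numeric(1))
  xb <- vapply(regions, function(r) mean_valid(vb[r]), numeric(1))
  keep <- is.finite(xa) & is.finite(xb)
  n <- sum(keep)
  if (n < 2L) stop("fewer than 2 valid regional samples")
  structure(list(x = xa[keep], y = xb[keep], n = n,
                 n_dropped = sum(!keep), level = "regional",
                 labels = c(map_a$name, map_b$name)),
            class = "sample_set")
}

#' Per-patient pairwise Spearman correlation matrix
#'
#' Computes all pairwise coefficients among the maps available for one
#' patient, at voxel or regional level, within the GTV. At the regional
#' level the exclusion rule applies: a patient whose GTV yields fewer than
#' `min_regions` sub-regions is excluded (flag set, no coefficients
#' reported). Pairs whose sampling fails (e.g. too few valid samples) are
#' recorded as `NA` with a note rather than aborting the patient.
#'
#' @param maps named list of `parametric_map`s on the GTV grid (>= 2).
#' @param gtv an `roi_mask`.
#' @param level "voxel" or "regional".
#' @param spec a [region_spec] (regional level).
#' @param patient patient identifier string.
#' @param min_regions minimum sub-region count for regional analysis
#'   (default 10).
#' @return An object of class `correlation_result`: `patient`, `level`,
#'   symmetric coefficient matrix `r` with unit diagonal, matrix `n` of
#'   per-pair sample counts, `excluded` flag + `reason`, and `notes`.
#' @export
patient_correlation_matrix <- function(maps, gtv,
                                       level = c("voxel", "regional"),
                                       spec = region_spec(),
                                       patient = "", min_regions = 10L) {
  level <- match.arg(level)
  if (!is.list(maps) || length(maps) < 2L || is.null(names(maps)) ||
      any(!nzchar(names(maps))))
    stop("maps must be a named list of at least 2 parametric maps")
  labs <- names(maps)
  k <- length(labs)
  r <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  diag(r) <- 1
  nmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  notes <- character()

  regions <- NULL
  if (level == "regional") {
    regions <- partition_regions(gtv, spec)
    if (length(regions) < min_regions) {
      return(structure(list(patient = patient, level = level,
                            r = NULL, n = NULL, excluded = TRUE,
                            reason = sprintf(
                              "only %d sub-regions (minimum %d)",
                              length(regions), min_regions),
                            n_regions = length(regions), notes = notes),
                       class = "correlation_result"))
    }
  }

  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    res <- tryCatch({
      ss <- if (level == "voxel")
        voxel_samples(maps[[i]], maps[[j]], gtv)
      else
        regional_samples(maps[[i]], maps[[j]], regions)
      list(r = spearman_cor(ss$x, ss$y), n = ss$n)
    }, error = function(e) {
      notes <<- c(notes, sprintf("%s/%s: %s", labs[i], labs[j],
                                 conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      r[i, j] <- r[j, i] <- res$r
      nmat[i, j] <- nmat[j, i] <- res$n
    }
  }
  structure(list(patient = patient, level = level, r = r, n = nmat,
                 excluded = FALSE, reason = NULL,
                 n_regions = if (is.null(regions)) NA_integer_
                             else length(regions),
                 notes = notes),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> patient '%s', %s level", x$patient,
              x$level))
  if (x$excluded) cat(" [EXCLUDED: ", x$reason, "]", sep = "")
  cat("\n")
  if (!is.null(x$r)) print(round(x$r, 3))
  invisible(x)
}

#' Cohort summary of per-patient correlation results
#'
#' Per modality pair and level: the median coefficient over contributing
#' patients, the (min, max) range and the patient count N. Excluded results
#' contribute nothing; pairs with zero contributors are absent from the
#' table, not reported as zero.
#'
#' @param results list of `correlation_result`s (possibly mixed levels).
#' @return data.frame with columns `pair`, `map_a`, `map_b`, `level`,
#'   `median_r`, `min_r`, `max_r`, `n_patients`.
#' @export
cohort_summary <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  rows <- list()
  for (res in results) {
    if (!inherits(res, "correlation_result")) stop("not a correlation_result")
    if (res$excluded || is.null(res$r)) next
    labs <- rownames(res$r)
    k <- length(labs)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (!is.finite(res$r[i, j])) next
      ab <- sort(c(labs[i], labs[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(ab, collapse = "/"), map_a = ab[1], map_b = ab[2],
        level = res$level, patient = res$patient, r = res$r[i, j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pair = character(), map_a = character(),
                      map_b = character(), level = character(),
                      median_r = numeric(), min_r = numeric(),
                      max_r = numeric(), n_patients = integer()))
  long <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(long, list(long$pair, long$level), drop = TRUE),
    function(d) data.frame(
      pair = d$pair[1], map_a = d$map_a[1], map_b = d$map_b[1],
      level = d$level[1], median_r = stats::median(d$r),
      min_r = min(d$r), max_r = max(d$r), n_patients = nrow(d),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(agg$level, agg$pair), ]
}

#' Square median-coefficient matrix (voxel upper, regional lower triangle)
#'
#' Arranges a [cohort_summary] table as one square matrix over all modality
#' labels: voxel-level medians above the diagonal, regional-level medians
#' below, `NA` where a pair has no contributors.
#'
#' @param summary data.frame from [cohort_summary].
#' @return numeric matrix with unit diagonal.
#' @export
correlation_matrix_table <- function(summary) {
  labs <- sort(unique(c(summary$map_a, summary$map_b)))
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  diag(m) <- 1
  for (row in seq_len(nrow(summary))) {
    i <- match(summary$map_a[row], labs)
    j <- match(summary$map_b[row], labs)
    lo <- min(i, j); hi <- max(i, j)
    if (summary$level[row] == "voxel") m[lo, hi] <- summary$median_r[row]
    else m[hi, lo] <- summary$median_r[row]
  }
  m
}
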