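# Extended Tofts compartmental model: forward convolution, voxel-wise and
# regional Levenberg-Marquardt parameter estimation.
#
# C_t(t) = v_p C_p(t) + Ktrans \int_0^t C_p(u) exp(-k_ep (t - u)) du,
# k_ep = Ktrans / v_e. The convolution is evaluated on a refined internal
# time grid with the exponential kernel integrated analytically per step
# (C_p taken linear within each step), which is stable for any k_ep.

#' Extended Tofts parameter triple with fit diagnostics
#'
#' @param ktrans volume transfer constant, 1/min, `>= 0`.
#' @param ve extravascular-extracellular volume fraction in `[0, 1]`.
#' @param vp plasma volume fraction in `[0, 1]`; `ve + vp <= 1`.
#' @param rss residual sum of squares of the fit (NA when not fitted).
#' @param converged logical convergence flag.
#' @param n_iter iteration count.
#' @return An object of class `tofts_params`.
#' @export
tofts_params <- function(ktrans, ve, vp, rss = NA_real_,
                         converged = NA, n_iter = NA_integer_) {
  if (!is.finite(ktrans) || ktrans < 0) stop("ktrans must be >= 0")
  if (!is.finite(ve) || ve < 0 || ve > 1) stop("ve must be in [0, 1]")
  if (!is.finite(vp) || vp < 0 || vp > 1) stop("vp must be in [0, 1]")
  if (ve + vp > 1 + 1e-12) stop("ve + vp must be <= 1")
  structure(list(ktrans = ktrans, ve = ve, vp = vp, rss = rss,
                 converged = converged, n_iter = n_iter),
            class = "tofts_params")
}

#' @export
print.tofts_params <- function(x, ...) {
  cat(sprintf(
    "<tofts_params> Ktrans %.4g 1/min, ve %.4g, vp %.4g (rss %.4g, converged %s)\n",
    x$ktrans, x$ve, x$vp, x$rss, x$converged))
  invisible(x)
}

# Refined internal time grid in minutes: a uniform grid at (median sampling
# interval)/refine, augmented with the output times and the bolus arrival so
# the kink at t0 and every sample point are hit exactly.
tofts_time_grid <- function(times_s, aif, refine) {
  tmax <- max(times_s)
  dt <- if (length(times_s) > 1L) min(diff(times_s)) else tmax
  h <- max(dt / refine, 1e-6)
  tg <- sort(unique(c(seq(0, tmax, by = h), tmax, times_s,
                      aif$params["t0"])))
  tg <- tg[tg >= 0 & tg <= tmax + 1e-12]
  tg / 60
}

# Batch forward model: ktrans/ve/vp are equal-length vectors (one entry per
# voxel); returns an n_voxel x n_time matrix of tissue concentrations.
tofts_forward_batch <- function(ktrans, ve, vp, aif, times_s, refine = 10) {
  nvox <- length(ktrans)
  stopifnot(length(ve) == nvox, length(vp) == nvox)
  if (any(ktrans > 0 & ve <= 0))
    stop("ktrans > 0 requires ve > 0 (k_ep undefined)")
  tg <- tofts_time_grid(times_s, aif, refine)   # minutes
  cp <- aif_eval(aif, tg * 60)
  m <- length(tg)
  kep <- ifelse(ktrans > 0, ktrans / ve, 0)

  I <- matrix(0, nvox, m)  # running convolution integral per voxel
  if (m > 1L) {
    acc <- numeric(nvox)
    for (n in seq_len(m - 1L)) {
      h <- tg[n + 1L] - tg[n]
      a <- cp[n]
      b <- (cp[n + 1L] - cp[n]) / h
      kh <- kep * h
      E <- exp(-kh)
      small <- kh < 1e-6
      G1 <- ifelse(small, h * (1 - kh / 2 + kh^2 / 6), (1 - E) / kep)
      G2 <- ifelse(small, h^2 * (0.5 - kh / 6 + kh^2 / 24), (h - G1) / kep)
      acc <- acc * E + a * G1 + b * G2
      I[, n + 1L] <- acc
    }
  }
  idx <- match(round(times_s / 60, 10), round(tg, 10))
  if (anyNA(idx)) stop("internal error: output times missing from time grid")
  ct <- vp %o% cp[idx] + ktrans * I[, idx, drop = FALSE]
  pmax(ct, 0)
}

#' Extended Tofts forward model
#'
#' Evaluates the tissue concentration curve for one parameter triple.
#'
#' @param params a [tofts_params] (or list with ktrans, ve, vp).
#' @param aif an [aif_model].
#' @param times_s sample times in seconds, sorted ascending, `>= 0`.
#' @param refine internal time-grid refinement factor (default 10).
#' @return Nonnegative concentration vector, one entry per time.
#' @export
tofts_forward <- function(params, aif, times_s, refine = 10) {
  stopifnot(inherits(aif, "aif_model"))
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s)) stop("times must be sorted ascending")
  if (any(times_s < 0)) stop("times must be >= 0")
  as.numeric(tofts_forward_batch(params$ktrans, params$ve, params$vp,
                                 aif, times_s, refine))
}

# smooth reparameterization in the better-conditioned (Ktrans, k_ep) pair:
# ktrans = exp(q1), k_ep = ktrans + exp(q2) (so ve = ktrans/k_ep < 1),
# vp = plogis(q3) * (1 - ve)  =>  all bounds and ve + vp <= 1 structural
tofts_pack <- function(ktrans, ve, vp) {
  kt <- max(ktrans, 1e-8)
  ve <- min(max(ve, 1e-6), 1 - 1e-6)
  dk <- kt * (1 - ve) / ve  # k_ep - ktrans
  c(log(kt), log(max(dk, 1e-10)),
    stats::qlogis(min(max(vp / (1 - ve), 1e-8), 1 - 1e-8)))
}

tofts_unpack <- function(q) {
  kt <- exp(q[1])
  kep <- kt + exp(q[2])
  ve <- kt / kep
  list(ktrans = kt, ve = ve, vp = stats::plogis(q[3]) * (1 - ve))
}

#' Fit the extended Tofts model to one enhancement curve
#'
#' Minimizes `sum((curve - scale * tofts_forward)^2)` by Levenberg-Marquardt
#' with bounds enforced through a smooth reparameterization in the
#' better-conditioned `(Ktrans, k_ep)` pair (log for `ktrans` and for
#' `k_ep - ktrans`, logistic for `vp/(1-ve)`), so `ktrans >= 0`,
#' `0 <= ve, vp <= 1` and `ve + vp <= 1` hold structurally. A small
#' multistart is attempted when the residual exceeds a noise-scaled
#' threshold. An all-zero curve short-circuits to the null model.
#'
#' @param curve baseline-subtracted enhancement values (length >= 10).
#' @param times_s sample times in seconds.
#' @param aif an [aif_model].
#' @param scale global enhancement-per-concentration factor, `> 0`.
#' @param init initial (ktrans, ve, vp); default (0.1, 0.2, 0.02).
#' @param refine forward-model time refinement factor.
#' @param multistart_rss_frac multistart is triggered when
#'   `sqrt(rss/n) > multistart_rss_frac * max(|curve|)`.
#' @return A [tofts_params] with rss, converged flag and iteration count;
#'   `NULL` if the curve contains non-finite values (invalid voxel).
#' @export
fit_tofts_voxel <- function(curve, times_s, aif, scale = 1,
                            init = c(0.1, 0.2, 0.02), refine = 10,
                            multistart_rss_frac = 0.05) {
  curve <- as.numeric(curve); times_s <- as.numeric(times_s)
  if (length(curve) != length(times_s) || length(curve) < 10L)
    stop("curve and times must have equal length >= 10")
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  if (any(!is.finite(curve))) return(NULL)
  if (max(abs(curve)) < 1e-12)
    return(tofts_params(0, init[2], 0, rss = 0, converged = TRUE,
                        n_iter = 0L))

  resid_fn <- function(q) {
    p <- tofts_unpack(q)
    curve - scale * as.numeric(
      tofts_forward_batch(p$ktrans, p$ve, p$vp, aif, times_s, refine))
  }
  run <- function(q0) tryCatch(
    minpack.lm::nls.lm(q0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)

  best <- run(tofts_pack(init[1], init[2], init[3]))
  thr <- (multistart_rss_frac * max(abs(curve)))^2 * length(curve)
  if (is.null(best) || best$deviance > thr) {
    for (st in list(c(0.02, 0.4, 0.01), c(0.4, 0.1, 0.05))) {
      alt <- run(tofts_pack(st[1], st[2], st[3]))
      if (!is.null(alt) && (is.null(best) || alt$deviance < best$deviance))
        best <- alt
    }
  }
  if (is.null(best)) stop("Tofts fit failed from all starting points")
  p <- tofts_unpack(best$par)
  tofts_params(p$ktrans, p$ve, p$vp, rss = best$deviance,
               converged = best$info %in% 1:4, n_iter = best$niter)
}

#' Fit extended Tofts parameter maps voxel-by-voxel
#'
#' Computes the baseline-subtracted enhancement, then fits every voxel inside
#' the mask independently. Voxels outside the mask, and voxels with
#' non-finite curves, are invalid in the returned maps.
#'
#' @param series a DCE `dynamic_series` on the mask grid (raw signal).
#' @param mask an `roi_mask`.
#' @param aif an [aif_model].
#' @param config list: `n_baseline_frames` (required), `scale` (default 1),
#'   `init`, `refine` (default 10).
#' @return list with `parametric_map`s `ktrans` (1/min), `ve`, `vp`,
#'   `rss`, and `diagnostics` (n_fitted, n_invalid, frac_nonconverged).
#'   A warning is emitted when more than half the fitted voxels fail to
#'   converge.
#' @export
fit_tofts_map <- function(series, mask, aif, config) {
  stopifnot(inherits(series, "dynamic_series"), inherits(mask, "roi_mask"))
  if (!grids_equal(series$grid, mask$grid))
    stop("series and mask must share one grid")
  if (is.null(config$n_baseline_frames))
    stop("config$n_baseline_frames is required")
  scale <- if (is.null(config$scale)) 1 else config$scale
  init <- if (is.null(config$init)) c(0.1, 0.2, 0.02) else config$init
  refine <- if (is.null(config$refine)) 10 else config$refine

  enh <- signal_enhancement_series(series, config$n_baseline_frames)
  nv <- prod(series$grid$shape)
  nt <- dim(series$frames)[4L]
  fm <- matrix(enh$frames, nrow = nv, ncol = nt)
  idx <- which(as.vector(mask$membership))

  shape <- series$grid$shape
  empty <- array(NA_real_, shape)
  out <- list(ktrans = empty, ve = empty, vp = empty, rss = empty)
  n_invalid <- 0L; n_nonconv <- 0L
  for (i in idx) {
    fit <- fit_tofts_voxel(fm[i, ], enh$frame_starts, aif, scale = scale,
                           init = init, refine = refine)
    if (is.null(fit)) { n_invalid <- n_invalid + 1L; next }
    out$ktrans[i] <- fit$ktrans
    out$ve[i] <- fit$ve
    out$vp[i] <- fit$vp
    out$rss[i] <- fit$rss
    if (!isTRUE(fit$converged)) n_nonconv <- n_nonconv + 1L
  }
  n_fitted <- length(idx) - n_invalid
  frac_nonconv <- if (n_fitted > 0) n_nonconv / n_fitted else 0
  if (frac_nonconv > 0.5)
    warning(sprintf("Tofts map fit: %.0f%% of voxels did not converge",
                    100 * frac_nonconv))
  g <- series$grid
  list(ktrans = parametric_map(g, out$ktrans, "1/min", "Ktrans"),
       ve = parametric_map(g, out$ve, "dimensionless", "ve"),
       vp = parametric_map(g, out$vp, "dimensionless", "vp"),
       rss = parametric_map(g, out$rss, "a.u.^2", "rss"),
       diagnostics = list(n_fitted = n_fitted, n_invalid = n_invalid,
                          frac_nonconverged = frac_nonconv))
}

#' Fit the extended Tofts model per region
#'
#' For each block the enhancement curves of its voxels are averaged, then a
#' single fit is performed (the regional-level analysis of the pipeline).
#'
#' @param series a DCE `dynamic_series` (raw signal).
#' @param blocks list of voxel index vectors (linear indices into the grid),
#'   non-overlapping; e.g. from [partition_regions].
#' @param aif an [aif_model].
#' @param config as for [fit_tofts_map].
#' @return list of [tofts_params], one per block (NULL for skipped blocks);
#'   empty blocks are skipped with a warning.
#' @export
fit_tofts_regional <- function(series, blocks, aif, config) {
  stopifnot(inherits(series, "dynamic_series"))
  if (is.null(config$n_baseline_frames))
    stop("config$n_baseline_frames is required")
  if (length(blocks) > 1L) {
    all_idx <- unlist(blocks)
    if (anyDuplicated(all_idx)) stop("blocks must be non-overlapping")
  }
  scale <- if (is.null(config$scale)) 1 else config$scale
  init <- if (is.null(config$init)) c(0.1, 0.2, 0.02) else config$init
  refine <- if (is.null(config$refine)) 10 else config$refine

  enh <- signal_enhancement_series(series, config$n_baseline_frames)
  nv <- prod(series$grid$shape)
  nt <- dim(series$frames)[4L]
  fm <- matrix(enh$frames, nrow = nv, ncol = nt)

  lapply(blocks, function(b) {
    if (length(b) == 0L) {
      warning("empty block skipped in regional Tofts fit")
      return(NULL)
    }
    curve <- colMeans(fm[b, , drop = FALSE])
    fit_tofts_voxel(curve, enh$frame_starts, aif, scale = scale,
                    init = init, refine = refine)
  })
}
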