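# Multi-modal phantom generation with known ground truth. Latent Gaussian
# copula design: jointly Gaussian smooth random fields with a matched
# Pearson correlation (rho_P = 2 sin(pi rho_S / 6)) give exact control of
# the population Spearman between modalities; strictly monotone marginal
# transforms to modality-plausible ranges leave that rank correlation
# untouched; modality noise is added after the transform.

modality_ranges <- list(
  fdg       = c(1, 15),          # SUV
  fmiso     = c(0.8, 3),         # TBR
  adc       = c(0.6e-3, 2.0e-3), # mm^2/s
  perfusion = c(0.2, 1),         # a.u. wash-in surrogate
  ktrans    = c(0.01, 0.6),      # 1/min
  ve        = c(0.05, 0.6),
  vp        = c(0.01, 0.1))

#' Default inter-modality target Spearman matrix
#'
#' Modalities: fdg, fmiso, adc, perfusion (FMISO wash-in surrogate), and the
#' Tofts truth maps ktrans, ve, vp. The strongest entries are set at the
#' scale of the cohort medians the pipeline is designed to resolve (e.g.
#' FDG/FMISO 0.56, FDG/perfusion 0.55, ADC/FDG -0.39); the remaining
#' entries are plausible weak couplings chosen once so the matched Pearson
#' matrix is positive definite.
#'
#' @return symmetric 7 x 7 matrix with unit diagonal.
#' @export
default_target_spearman <- function() {
  labs <- c("fdg", "fmiso", "adc", "perfusion", "ktrans", "ve", "vp")
  S <- diag(7)
  dimnames(S) <- list(labs, labs)
  set2 <- function(a, b, v) { S[a, b] <<- v; S[b, a] <<- v }
  set2("fdg", "fmiso", 0.56);  set2("fdg", "adc", -0.39)
  set2("fdg", "perfusion", 0.55); set2("fdg", "ktrans", 0.2)
  set2("fdg", "ve", 0.1);      set2("fdg", "vp", 0.2)
  set2("fmiso", "adc", -0.2);  set2("fmiso", "perfusion", 0.45)
  set2("fmiso", "ktrans", 0.1); set2("fmiso", "ve", 0.1)
  set2("fmiso", "vp", 0.1)
  set2("adc", "perfusion", -0.2); set2("adc", "ktrans", -0.1)
  set2("adc", "ve", 0.2);      set2("adc", "vp", -0.1)
  set2("perfusion", "ktrans", 0.5); set2("perfusion", "ve", 0.2)
  set2("perfusion", "vp", 0.4)
  set2("ktrans", "ve", 0.3);   set2("ktrans", "vp", 0.3)
  set2("ve", "vp", 0.2)
  S
}

check_spearman_matrix <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("target_spearman must be a square matrix")
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S)))
    stop("target_spearman needs identical row and column names")
  if (max(abs(S - t(S))) > 1e-12) stop("target_spearman must be symmetric")
  if (any(abs(diag(S) - 1) > 1e-12))
    stop("target_spearman must have unit diagonal")
  if (any(S < -1 - 1e-12 | S > 1 + 1e-12))
    stop("target_spearman entries must be in [-1, 1]")
  P <- 2 * sin(pi * S / 6)
  diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    labs <- rownames(S)
    # name pairs whose removal restores positive semi-definiteness
    fixes <- character()
    for (i in seq_len(nrow(S) - 1L)) for (j in (i + 1L):nrow(S)) {
      P2 <- P; P2[i, j] <- P2[j, i] <- 0
      if (min(eigen(P2, symmetric = TRUE,
                    only.values = TRUE)$values) >= -1e-10)
        fixes <- c(fixes, paste(labs[i], labs[j], sep = "/"))
    }
    stop("matched Pearson matrix is not positive semi-definite",
         if (length(fixes))
           paste0("; offending pair(s): ", paste(fixes, collapse = ", "))
         else "; no single pair is responsible")
  }
  P
}

# separable Gaussian smoothing with edge renormalization; the SAME linear
# operator is applied to every field, which preserves their pointwise
# cross-correlation
gauss_smooth <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    K <- max(1L, ceiling(4 * s))
    w <- exp(-((-K:K)^2) / (2 * s^2))
    arr <- apply_along_axis(arr, ax, function(m) {
      n <- nrow(m)
      acc <- matrix(0, n, ncol(m))
      norm <- numeric(n)
      for (k in -K:K) {
        to <- max(1L, 1L - k):min(n, n - k)
        acc[to, ] <- acc[to, ] + w[k + K + 1L] * m[to + k, , drop = FALSE]
        norm[to] <- norm[to] + w[k + K + 1L]
      }
      acc / norm
    })
  }
  arr
}

#' Generate correlated smooth Gaussian latent fields
#'
#' Draws jointly Gaussian white-noise fields with Pearson correlation
#' `rho_P = 2 sin(pi rho_S / 6)` (the Gaussian-copula match for a target
#' population Spearman `rho_S`), smooths all fields with one shared Gaussian
#' kernel, and standardizes each field. Smoothing with a shared kernel
#' preserves the pointwise cross-correlation of jointly stationary fields,
#' so the population Spearman between any two returned fields equals the
#' target.
#'
#' @param target_spearman named symmetric matrix with unit diagonal, entries
#'   in `[-1, 1]`; the matched Pearson matrix must be positive
#'   semi-definite.
#' @param grid an `image_grid`.
#' @param smoothness_fwhm Gaussian smoothing FWHM in mm (0 disables).
#' @param seed integer RNG seed.
#' @return named list of standardized (dimensionless) `parametric_map`s.
#' @export
make_correlated_fields <- function(target_spearman, grid,
                                   smoothness_fwhm = 4, seed = 1L) {
  stopifnot(inherits(grid, "image_grid"))
  P <- check_spearman_matrix(target_spearman)
  labs <- rownames(target_spearman)
  k <- length(labs)
  set.seed(as.integer(seed))
  nv <- prod(grid$shape)
  Z <- matrix(stats::rnorm(nv * k), nv, k)
  # eigendecomposition square root (chol fails for singular, e.g. rho = 1)
  ed <- eigen(P, symmetric = TRUE)
  A <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), k) %*% t(ed$vectors)
  X <- Z %*% A
  sigma_vox <- (smoothness_fwhm / 2.3548) / grid$spacing
  out <- list()
  for (i in seq_len(k)) {
    f <- gauss_smooth(array(X[, i], grid$shape), sigma_vox)
    f <- (f - mean(f)) / stats::sd(f)
    out[[labs[i]]] <- parametric_map(grid, f, "dimensionless", labs[i])
  }
  out
}

apply_noise <- function(values, model, exclude = NULL) {
  if (is.null(model) || identical(model$type, "none")) return(values)
  n <- length(values)
  out <- switch(
    model$type,
    gaussian = values + stats::rnorm(n, sd = model$sd),
    rician = {
      n1 <- stats::rnorm(n, sd = model$sigma)
      n2 <- stats::rnorm(n, sd = model$sigma)
      sqrt((values + n1)^2 + n2^2)
    },
    scaled_poisson = {
      # variance proportional to the local mean, factor f: x + N(0, sqrt(f x))
      values + stats::rnorm(n, sd = sqrt(pmax(model$factor * values, 0)))
    },
    stop("unknown noise model type: ", model$type))
  array(out, dim(values))
}

#' Phantom configuration
#'
#' All knobs of the synthetic multi-modal phantom. The defaults are the
#' study conditions the package emulates: a PET/MR grid of 2.8 x 2.8 x 2.0
#' mm voxels, an ellipsoidal GTV of about 32 cm^3 (the cohort median
#' scale), DCE at 2.9 s temporal resolution over 4.3 min driven by
#' ground-truth extended Tofts maps, FMISO wash-in over 0-4 min, and the
#' [default_target_spearman] inter-modality structure.
#'
#' @param grid `image_grid`; default 24^3 voxels at 2.8 x 2.8 x 2.0 mm.
#' @param gtv_semiaxes_mm ellipsoid semi-axes in mm; default (22, 22, 16).
#' @param gtv_center_mm ellipsoid center in mm; default the grid center.
#' @param target_spearman symmetric target matrix over modality labels.
#' @param smoothness_fwhm latent-field smoothing FWHM, mm.
#' @param noise named list of per-modality noise models, each
#'   `list(type = "gaussian", sd = )`, `list(type = "rician", sigma = )`,
#'   `list(type = "scaled_poisson", factor = )` or `list(type = "none")`.
#'   Recognized names: fdg, fmiso, adc, dce, washin.
#' @param seed integer seed; fixed seed + config gives bit-identical output.
#' @param dce_time_step,dce_duration DCE frame spacing / total duration, s.
#' @param dce_baseline_frames pre-injection DCE frames.
#' @param dce_scale global enhancement-per-concentration factor, a.u./mM.
#' @param dce_baseline_value flat pre-injection DCE signal, a.u.
#' @param washin_time_step,washin_duration FMISO wash-in frame spacing /
#'   duration, s (duration >= 240).
#' @param washin_tau wash-in saturation time constant, s.
#' @param aif an [aif_model] driving the DCE simulation.
#' @param injection an [injection_record] (for the SUV path).
#' @param fmiso_background_kBq_mL muscle background activity, kBq/mL.
#' @param b_values,dw_s0 diffusion-weighted simulation settings.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = image_grid(c(24, 24, 24),
                                             c(2.8, 2.8, 2.0)),
                           gtv_semiaxes_mm = c(22, 22, 16),
                           gtv_center_mm = NULL,
                           target_spearman = default_target_spearman(),
                           smoothness_fwhm = 4,
                           noise = list(
                             fdg = list(type = "gaussian", sd = 1.0),
                             fmiso = list(type = "gaussian", sd = 0.1),
                             adc = list(type = "rician", sigma = 0.03e-3),
                             dce = list(type = "gaussian", sd = 1.0),
                             washin = list(type = "gaussian", sd = 0.02)),
                           seed = 1L,
                           dce_time_step = 2.9, dce_duration = 258,
                           dce_baseline_frames = 5,
                           dce_scale = 50, dce_baseline_value = 100,
                           washin_time_step = 10, washin_duration = 240,
                           washin_tau = 60,
                           aif = aif_model(),
                           injection = injection_record(350, 70),
                           fmiso_background_kBq_mL = 2,
                           b_values = c(50, 800), dw_s0 = 1000) {
  stopifnot(inherits(grid, "image_grid"), inherits(aif, "aif_model"),
            inherits(injection, "injection_record"))
  check_spearman_matrix(target_spearman)
  if (is.null(gtv_center_mm))
    gtv_center_mm <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  if (washin_duration < 240)
    stop("washin_duration must be >= 240 s (the 0-4 min window)")
  if (dce_baseline_frames * dce_time_step > aif$params["t0"] + 1e-9)
    stop("baseline frames must precede the bolus arrival t0")
  structure(list(grid = grid, gtv_semiaxes_mm = gtv_semiaxes_mm,
                 gtv_center_mm = gtv_center_mm,
                 target_spearman = target_spearman,
                 smoothness_fwhm = smoothness_fwhm, noise = noise,
                 seed = as.integer(seed),
                 dce_time_step = dce_time_step, dce_duration = dce_duration,
                 dce_baseline_frames = dce_baseline_frames,
                 dce_scale = dce_scale,
                 dce_baseline_value = dce_baseline_value,
                 washin_time_step = washin_time_step,
                 washin_duration = washin_duration, washin_tau = washin_tau,
                 aif = aif, injection = injection,
                 fmiso_background_kBq_mL = fmiso_background_kBq_mL,
                 b_values = b_values, dw_s0 = dw_s0),
            class = "phantom_config")
}

ellipsoid_mask_array <- function(grid, center_mm, semiaxes_mm) {
  w <- grid_coordinates(grid)
  d <- sweep(w, 2L, center_mm, `-`)
  d <- sweep(d, 2L, semiaxes_mm, `/`)
  array(rowSums(d^2) <= 1, grid$shape)
}

# monotone marginal transform of a standardized latent field into a
# modality-plausible range: probit map onto (lo, hi)
latent_to_range <- function(z, range) {
  range[1] + (range[2] - range[1]) * stats::pnorm(z)
}

#' Simulate a DCE-MRI series from extended Tofts truth maps
#'
#' Per voxel: `signal(t) = baseline + scale * C_t(t) + noise`, with `C_t`
#' the extended Tofts forward model driven by the AIF. Frame times are
#' multiples of `time_step`; the frame count is `floor(duration/step) + 1`.
#'
#' @param ktrans,ve,vp `parametric_map`s on one grid (1/min and fractions);
#'   `ve + vp <= 1` and nonnegativity are enforced per voxel.
#' @param aif an [aif_model].
#' @param time_step,duration frame spacing / total duration, s.
#' @param baseline_frames pre-injection frame count; these frames must end
#'   before the bolus arrival.
#' @param noise_sigma Gaussian signal noise SD (0 = noiseless).
#' @param scale enhancement per unit concentration, a.u./mM.
#' @param baseline_value flat pre-injection signal, a.u.
#' @param mask optional `roi_mask`: only its voxels are simulated
#'   kinetically, the rest stay at baseline (a phantom economy, not an
#'   acquisition feature).
#' @param refine forward-model time refinement factor.
#' @return A `dynamic_series` in a.u.
#' @export
simulate_dce_series <- function(ktrans, ve, vp, aif,
                                time_step = 2.9, duration = 258,
                                baseline_frames = 5, noise_sigma = 0,
                                scale = 50, baseline_value = 100,
                                mask = NULL, refine = 5) {
  stopifnot(inherits(ktrans, "parametric_map"),
            inherits(ve, "parametric_map"),
            inherits(vp, "parametric_map"),
            inherits(aif, "aif_model"))
  if (!grids_equal(ktrans$grid, ve$grid) ||
      !grids_equal(ktrans$grid, vp$grid))
    stop("parameter maps must share one grid")
  if (time_step <= 0) stop("time_step must be > 0")
  if (baseline_frames * time_step > aif$params["t0"] + 1e-9)
    stop("baseline frames must precede the bolus arrival")
  kt <- as.vector(ktrans$values); vev <- as.vector(ve$values)
  vpv <- as.vector(vp$values)
  sel <- if (is.null(mask)) rep(TRUE, length(kt))
         else as.vector(mask$membership)
  bad <- which(sel & (!is.finite(kt) | !is.finite(vev) | !is.finite(vpv) |
                        kt < 0 | vev < 0 | vpv < 0 | vev + vpv > 1))
  if (length(bad))
    stop("non-physical Tofts parameters at voxel index ", bad[1],
         " (and ", length(bad) - 1L, " more)")

  nt <- floor(duration / time_step) + 1L
  times <- (seq_len(nt) - 1L) * time_step
  nv <- length(kt)
  fm <- matrix(baseline_value, nv, nt)
  idx <- which(sel)
  if (length(idx)) {
    ct <- tofts_forward_batch(kt[idx], vev[idx], vpv[idx], aif, times,
                              refine = refine)
    fm[idx, ] <- baseline_value + scale * ct
  }
  if (noise_sigma > 0)
    fm <- fm + stats::rnorm(length(fm), sd = noise_sigma)
  dynamic_series(ktrans$grid, array(fm, c(ktrans$grid$shape, nt)),
                 frame_starts = times, frame_durations = time_step,
                 unit = "a.u.", name = "DCE")
}

#' Simulate an early FMISO wash-in PET series
#'
#' Per voxel the activity rises as `P * (1 - exp(-t/tau))`, with `P` the
#' perfusion surrogate; each frame holds the value at its mid-time. The
#' 0-4 min mean of this curve is `P` times a voxel-independent factor, so
#' the wash-in mean map inherits the surrogate's rank order exactly in the
#' noiseless case.
#'
#' @param perfusion a `parametric_map` (nonnegative surrogate).
#' @param time_step,duration frame spacing / duration, s; duration >= 240.
#' @param tau saturation time constant, s.
#' @param noise a noise model list (see [phantom_config]), default none.
#' @return A `dynamic_series` in kBq/mL.
#' @export
simulate_fmiso_washin <- function(perfusion, time_step = 10, duration = 240,
                                  tau = 60, noise = list(type = "none")) {
  stopifnot(inherits(perfusion, "parametric_map"))
  if (duration < 240) stop("duration must cover the 0-4 min window")
  if (time_step <= 0 || tau <= 0) stop("time_step and tau must be > 0")
  nt <- as.integer(floor(duration / time_step))
  starts <- (seq_len(nt) - 1L) * time_step
  mid <- starts + time_step / 2
  p <- as.vector(perfusion$values)
  fm <- p %o% (1 - exp(-mid / tau))
  fm <- apply_noise(fm, noise)
  dynamic_series(perfusion$grid, array(fm, c(perfusion$grid$shape, nt)),
                 frame_starts = starts, frame_durations = time_step,
                 unit = "kBq/mL", name = "FMISO-washin")
}

#' Simulate a two-b-value diffusion-weighted signal pair
#'
#' `S(b) = s0 * exp(-b * ADC)` per voxel.
#'
#' @param adc a `parametric_map` in mm^2/s, values `>= 0`.
#' @param b_values pair (b1, b2) in s/mm^2, `b2 > b1 >= 0`.
#' @param s0 signal at b = 0.
#' @return list of two `parametric_map`s, `s_low` and `s_high`.
#' @export
simulate_dw_signals <- function(adc, b_values = c(50, 800), s0 = 1000) {
  stopifnot(inherits(adc, "parametric_map"))
  if (b_values[1] < 0 || b_values[2] <= b_values[1])
    stop("b_values must satisfy b2 > b1 >= 0")
  if (any(adc$values[is.finite(adc$values)] < 0))
    stop("adc values must be >= 0")
  g <- adc$grid
  list(s_low = parametric_map(g, s0 * exp(-b_values[1] * adc$values),
                              "a.u.", "DW-low-b"),
       s_high = parametric_map(g, s0 * exp(-b_values[2] * adc$values),
                               "a.u.", "DW-high-b"))
}

#' Generate one multi-modal phantom dataset
#'
#' Latent correlated fields are transformed through strictly monotone
#' marginal maps to modality-plausible ranges (preserving the target
#' Spearman structure exactly), modality noise is added after the
#' transform, and the dynamic DCE and FMISO wash-in series are generated
#' from the truth maps. Carotid voxels carry an essentially pure-plasma DCE
#' signal (vp near 1) for AIF estimation; muscle voxels carry the flat
#' FMISO background used by the TBR normalization.
#'
#' @param config a [phantom_config].
#' @return An object of class `phantom_dataset`: named `maps` (fdg, fmiso
#'   in kBq/mL; adc in mm^2/s), `truth` (noise-free latent fields and
#'   transformed truth maps, incl. ktrans/ve/vp and the perfusion
#'   surrogate), `dce_series`, `fmiso_washin_series`, `masks` (gtv, muscle,
#'   carotid), the `injection` record, the `config`, and `warnings`
#'   (e.g. a GTV too small to hold one full block).
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$grid
  fields <- make_correlated_fields(config$target_spearman, g,
                                   config$smoothness_fwhm, config$seed)
  labs <- names(fields)

  gtv_arr <- ellipsoid_mask_array(g, config$gtv_center_mm,
                                  config$gtv_semiaxes_mm)
  if (!any(gtv_arr)) stop("GTV ellipsoid contains no voxels on this grid")
  extent <- (g$shape - 1) * g$spacing
  muscle_arr <- ellipsoid_mask_array(g, g$origin + 0.10 * extent,
                                     c(6, 6, 6)) & !gtv_arr
  carotid_arr <- ellipsoid_mask_array(
    g, g$origin + c(0.92, 0.5, 0.5) * extent,
    c(3, 3, 0.45 * extent[3])) & !gtv_arr & !muscle_arr
  if (!any(muscle_arr) || !any(carotid_arr))
    stop("grid too small to place background-muscle and carotid ROIs")
  masks <- list(gtv = roi_mask(g, gtv_arr, "GTV"),
                muscle = roi_mask(g, muscle_arr, "background-muscle"),
                carotid = roi_mask(g, carotid_arr, "carotid"))

  warnings <- character()
  full_blocks <- partition_regions(masks$gtv,
                                   region_spec(min_gtv_fraction = 1))
  if (length(full_blocks) == 0L) {
    warnings <- c(warnings, "GTV contains no full 3x3x4 block")
    warning("phantom GTV too small to contain one full 3x3x4 block")
  }

  # truth maps: monotone transforms of the latent fields
  truth <- list(fields = fields)
  for (lab in labs) {
    rg <- modality_ranges[[lab]]
    if (is.null(rg)) rg <- c(0, 1)
    unit <- switch(lab, fdg = "SUV", fmiso = "TBR", adc = "mm^2/s",
                   ktrans = "1/min", perfusion = "a.u.", "dimensionless")
    truth[[lab]] <- parametric_map(
      g, latent_to_range(fields[[lab]]$values, rg), unit, lab)
  }

  # carotid voxels: pure-plasma DCE behaviour for AIF extraction
  if (all(c("ktrans", "ve", "vp") %in% labs)) {
    truth$ktrans$values[carotid_arr] <- 0
    truth$ve$values[carotid_arr] <- 0.05
    truth$vp$values[carotid_arr] <- 0.95
  }

  inj <- config$injection
  dose_kBq_per_g <- inj$injected_activity_MBq * 1000 /
    (inj$body_weight_kg * 1000)
  noise <- config$noise

  fdg_act <- truth$fdg$values * dose_kBq_per_g
  fdg_act <- apply_noise(fdg_act, noise$fdg)
  bg <- config$fmiso_background_kBq_mL
  fmiso_act <- truth$fmiso$values * bg
  fmiso_act[muscle_arr] <- bg
  fmiso_act <- apply_noise(fmiso_act, noise$fmiso)
  adc_vals <- apply_noise(truth$adc$values, noise$adc)

  maps <- list(
    fdg = parametric_map(g, fdg_act, "kBq/mL", "FDG"),
    fmiso = parametric_map(g, fmiso_act, "kBq/mL", "FMISO"),
    adc = parametric_map(g, adc_vals, "mm^2/s", "ADC"))

  dce_sigma <- if (!is.null(noise$dce) &&
                     identical(noise$dce$type, "gaussian"))
    noise$dce$sd else 0
  dce <- simulate_dce_series(
    truth$ktrans, truth$ve, truth$vp, config$aif,
    time_step = config$dce_time_step, duration = config$dce_duration,
    baseline_frames = config$dce_baseline_frames,
    noise_sigma = dce_sigma, scale = config$dce_scale,
    baseline_value = config$dce_baseline_value,
    mask = roi_mask(g, gtv_arr | carotid_arr, "dce-sim"))

  washin <- simulate_fmiso_washin(
    truth$perfusion, time_step = config$washin_time_step,
    duration = config$washin_duration, tau = config$washin_tau,
    noise = if (is.null(noise$washin)) list(type = "none")
            else noise$washin)

  structure(list(maps = maps, truth = truth, dce_series = dce,
                 fmiso_washin_series = washin, masks = masks,
                 injection = inj, config = config, warnings = warnings),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<phantom_dataset> seed %d: GTV %.1f cm^3, %d maps, DCE %d frames, wash-in %d frames\n",
    x$config$seed,
    sum(x$masks$gtv$membership) * voxel_volume(x$config$grid) / 1000,
    length(x$maps), n_frames(x$dce_series), n_frames(x$fmiso_washin_series)))
  if (length(x$warnings)) cat(" warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}
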