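times_43min <- seq(0, 258, by = 2.9)  # the DCE sampling used throughout

test_that("tofts_forward reduces to its degenerate limits", {
  aif <- aif_model()
  expect_equal(tofts_forward(list(ktrans = 0, ve = 0.2, vp = 0),
                             aif, times_43min),
               rep(0, length(times_43min)))
  cp <- aif_eval(aif, times_43min)
  expect_lt(max(abs(tofts_forward(list(ktrans = 0, ve = 0.2, vp = 0.05),
                                  aif, times_43min) - 0.05 * cp)), 1e-12)
  expect_error(tofts_forward(list(ktrans = 0.1, ve = 0, vp = 0),
                             aif, times_43min), "k_ep")
})

test_that("tofts_forward matches the constant-AIF closed form", {
  caif <- aif_model(a1 = 1, t0 = 0, form = "constant")
  ct <- tofts_forward(list(ktrans = 0.25, ve = 0.3, vp = 0.05), caif, 180)
  expect_equal(ct, 0.05 + 0.3 * (1 - exp(-2.5 * 0.25 / 0.25)),
               tolerance = 1e-4)
  expect_equal(ct, 0.32537, tolerance = 1e-4)

  # parameter sweep: relative error well below 0.1 %
  worst <- 0
  for (a in c(0.01, 0.25, 0.6)) for (b in c(0.05, 0.3, 0.6))
    for (cc in c(0.01, 0.05, 0.1)) {
      got <- tofts_forward(list(ktrans = a, ve = b, vp = cc), caif,
                           times_43min, refine = 10)
      ex <- cc + b * (1 - exp(-a * (times_43min / 60) / b))
      worst <- max(worst, max(abs(got[-1] - ex[-1]) / abs(ex[-1])))
    }
  expect_lt(worst, 1e-3)
})

test_that("early-time uptake is non-decreasing in Ktrans", {
  aif <- aif_model()
  t_early <- c(60, 90, 120)
  prev <- rep(-Inf, length(t_early))
  for (a in seq(0.02, 0.6, length.out = 8)) {
    ct <- tofts_forward(list(ktrans = a, ve = 0.3, vp = 0.03), aif, t_early)
    expect_true(all(ct >= prev - 1e-12))
    prev <- ct
  }
})

test_that("fit_tofts_voxel recovers noiseless parameters and handles null data", {
  aif <- aif_model()
  for (tr in list(c(0.05, 0.15, 0.02), c(0.25, 0.30, 0.05),
                  c(0.5, 0.55, 0.09))) {
    curve <- 40 * tofts_forward(list(ktrans = tr[1], ve = tr[2],
                                     vp = tr[3]), aif, times_43min)
    fit <- fit_tofts_voxel(curve, times_43min, aif, scale = 40)
    expect_true(fit$converged)
    expect_lt(max(abs(c(fit$ktrans, fit$ve, fit$vp) - tr) / tr), 0.01)
  }
  z <- fit_tofts_voxel(rep(0, length(times_43min)), times_43min, aif)
  expect_lte(z$ktrans, 1e-6)
  expect_lte(z$vp, 1e-6)
  expect_true(z$converged)
  expect_null(fit_tofts_voxel(c(NA, rep(1, length(times_43min) - 1)),
                              times_43min, aif))
})

test_that("Ktrans is robust to 5% curve noise (Monte-Carlo)", {
  aif <- aif_model()
  truth <- c(0.25, 0.30, 0.05)
  clean <- 40 * tofts_forward(list(ktrans = truth[1], ve = truth[2],
                                   vp = truth[3]), aif, times_43min)
  set.seed(2024)
  errs <- replicate(100, {
    noisy <- clean + rnorm(length(clean), sd = 0.05 * max(clean))
    f <- fit_tofts_voxel(noisy, times_43min, aif, scale = 40)
    abs(f$ktrans - truth[1]) / truth[1]
  })
  expect_lt(median(errs), 0.10)
})

test_that("fit_aif recovers a known input function and is shift-equivariant", {
  truth <- aif_model(a1 = 3, m1 = 2, a2 = 1, m2 = 0.05, r = 15, t0 = 30)
  curve <- aif_eval(truth, times_43min)
  fit <- fit_aif(curve, times_43min)
  expect_true(fit$fit$converged)
  expect_lt(max(abs(fit$params - truth$params) / abs(truth$params)), 0.01)

  shifted <- aif_model(a1 = 3, m1 = 2, a2 = 1, m2 = 0.05, r = 15, t0 = 35)
  fit2 <- fit_aif(aif_eval(shifted, times_43min), times_43min)
  expect_lt(abs((fit2$params["t0"] - fit$params["t0"]) - 5), 2.9)

  expect_error(fit_aif(rep(0, length(times_43min)), times_43min),
               "no detectable bolus")
})

test_that("map-level fits are independent per voxel and honor tiny masks", {
  aif <- aif_model()
  g <- pet_grid(c(3, 3, 1))
  set.seed(9)
  kt <- array(runif(9, 0.05, 0.4), g$shape)
  ve <- array(runif(9, 0.1, 0.5), g$shape)
  vp <- array(runif(9, 0.01, 0.08), g$shape)
  dce <- simulate_dce_series(
    parametric_map(g, kt, "1/min"), parametric_map(g, ve, "dimensionless"),
    parametric_map(g, vp, "dimensionless"), aif,
    baseline_frames = 5, noise_sigma = 0, scale = 40)
  cfg <- list(n_baseline_frames = 5, scale = 40)

  one <- box_mask(g, c(2, 2, 1), c(2, 2, 1))
  fm1 <- fit_tofts_map(dce, one, aif, cfg)
  expect_equal(sum(is.finite(fm1$ktrans$values)), 1L)
  expect_equal(fm1$ktrans$values[2, 2, 1], kt[2, 2, 1], tolerance = 1e-3)

  all_m <- roi_mask(g, array(TRUE, g$shape), "all")
  fm <- fit_tofts_map(dce, all_m, aif, cfg)
  expect_lt(max(abs(fm$ktrans$values - kt) / kt), 0.01)
  expect_equal(fm$diagnostics$n_invalid, 0L)
})

test_that("regional fits equal the voxel fit on homogeneous blocks and keep order", {
  aif <- aif_model()
  g <- pet_grid(c(4, 4, 2))
  kt <- constant_map(g, 0.2, "1/min"); ve <- constant_map(g, 0.35)
  vp <- constant_map(g, 0.04)
  dce <- simulate_dce_series(kt, ve, vp, aif, baseline_frames = 5,
                             noise_sigma = 0, scale = 40)
  blocks <- list(1:8, 9:16, 25:32)
  cfg <- list(n_baseline_frames = 5, scale = 40)
  fits <- fit_tofts_regional(dce, blocks, aif, cfg)
  for (f in fits) {
    expect_equal(f$ktrans, 0.2, tolerance = 1e-4)
    expect_equal(f$ve, 0.35, tolerance = 1e-4)
  }
  rev_fits <- fit_tofts_regional(dce, rev(blocks), aif, cfg)
  expect_equal(vapply(rev_fits, `[[`, numeric(1), "ktrans"),
               rev(vapply(fits, `[[`, numeric(1), "ktrans")))
  expect_error(fit_tofts_regional(dce, list(1:8, 5:12), aif, cfg),
               "non-overlapping")
})

test_that("regional parameters on a smooth phantom respect block value ranges", {
  cfg <- small_phantom_config(seed = 21)
  ph <- make_phantom(cfg)
  regions <- partition_regions(ph$masks$gtv)
  regions <- regions[1:min(4, length(regions))]
  fits <- fit_tofts_regional(
    ph$dce_series, regions, ph$config$aif,
    list(n_baseline_frames = cfg$dce_baseline_frames,
         scale = cfg$dce_scale))
  kt_truth <- as.vector(ph$truth$ktrans$values)
  for (i in seq_along(regions)) {
    rng <- range(kt_truth[regions[[i]]])
    # block-mean curve fit stays within (slightly padded) block truth range
    pad <- 0.1 * diff(rng) + 0.01
    expect_gte(fits[[i]]$ktrans, rng[1] - pad)
    expect_lte(fits[[i]]$ktrans, rng[2] + pad)
  }
})

test_that("DESPOT1 recovers T1 and M0 from noiseless dual-angle signals", {
  g <- pet_grid(c(5, 5, 2))
  t1 <- array(seq(200, 3000, length.out = prod(g$shape)), g$shape)
  m0 <- array(5000, g$shape)
  s1 <- parametric_map(g, spgr_signal(m0, t1, 2, 4.04), "a.u.")
  s2 <- parametric_map(g, spgr_signal(m0, t1, 12, 4.04), "a.u.")
  fit <- t1_from_dual_flip(s1, s2, c(2, 12), 4.04)
  expect_true(all(fit$valid))
  expect_lt(max(abs(fit$t1$values - t1)), 0.1)
  expect_lt(max(abs(fit$m0$values - m0) / m0), 1e-6)

  # global scaling leaves T1 unchanged, scales M0
  fit3 <- t1_from_dual_flip(
    parametric_map(g, 3 * s1$values, "a.u."),
    parametric_map(g, 3 * s2$values, "a.u."), c(2, 12), 4.04)
  expect_lt(max(abs(fit3$t1$values - fit$t1$values)), 1e-6)
  expect_lt(max(abs(fit3$m0$values - 3 * fit$m0$values) / fit3$m0$values),
            1e-9)

  # nonphysical branch: signals implying E1 >= 1 are invalid
  bad <- t1_from_dual_flip(constant_map(g, 10), constant_map(g, 300),
                           c(2, 12), 4.04)
  expect_true(all(!bad$valid))
})

test_that("enhancement-to-concentration inverts the SPGR forward model", {
  g <- pet_grid(c(3, 3, 1))
  t1 <- array(seq(400, 1600, length.out = 9), g$shape)
  m0 <- array(4000, g$shape)
  tr <- 2.86; flip <- 12; rlx <- 3.6
  t1map <- t1_from_dual_flip(
    parametric_map(g, spgr_signal(m0, t1, 2, tr), "a.u."),
    parametric_map(g, spgr_signal(m0, t1, 12, tr), "a.u."), c(2, 12), tr)

  conc_t <- seq(0, 1.2, length.out = 10)  # mM over frames
  nv <- prod(g$shape)
  sig <- vapply(conc_t, function(cc) {
    r1 <- 1000 / t1 + rlx * cc
    as.vector(spgr_signal(m0, 1000 / r1, flip, tr))
  }, numeric(nv))
  s0 <- sig[, 1]
  enh <- series_from_matrix(g, sig - s0, dt = 2.9, unit = "signal-difference")
  conc <- enhancement_to_concentration(enh, t1map, rlx, tr, flip)
  got <- matrix(conc$frames, nv, 10)
  expect_lt(max(abs(sweep(got, 2, conc_t))), 1e-6)
  # zero enhancement -> zero concentration
  expect_lt(max(abs(got[, 1])), 1e-9)

  # linear regime: doubling relaxivity halves the recovered concentration
  small <- series_from_matrix(g, cbind(sig[, 2] - s0), dt = 2.9,
                              unit = "signal-difference")
  c1 <- enhancement_to_concentration(small, t1map, rlx, tr, flip)
  c2 <- enhancement_to_concentration(small, t1map, 2 * rlx, tr, flip)
  expect_equal(as.vector(c1$frames), 2 * as.vector(c2$frames),
               tolerance = 1e-9)
})
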