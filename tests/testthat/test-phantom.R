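two_field_matrix <- function(r) {
  m <- matrix(c(1, r, r, 1), 2)
  dimnames(m) <- list(c("a", "b"), c("a", "b"))
  m
}

test_that("correlated fields hit independence and comonotone limits", {
  g <- image_grid(c(18, 18, 16), c(2.8, 2.8, 2.0))
  set.seed(1)
  rs <- vapply(1:20, function(s) {
    f <- make_correlated_fields(two_field_matrix(0), g,
                                smoothness_fwhm = 2, seed = 1000 + s)
    spearman_cor(as.vector(f$a$values), as.vector(f$b$values))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)

  f1 <- make_correlated_fields(two_field_matrix(1), g,
                               smoothness_fwhm = 2, seed = 3)
  expect_equal(spearman_cor(as.vector(f1$a$values),
                            as.vector(f1$b$values)), 1)
})

test_that("copula calibration: mean sample Spearman matches the target", {
  g <- image_grid(c(18, 18, 16), c(2.8, 2.8, 2.0))  # 5184 voxels
  for (target in c(0.56, -0.8)) {
    rs <- vapply(1:20, function(s) {
      f <- make_correlated_fields(two_field_matrix(target), g,
                                  smoothness_fwhm = 2, seed = 500 + s)
      spearman_cor(as.vector(f$a$values), as.vector(f$b$values))
    }, numeric(1))
    expect_lt(abs(mean(rs) - target), 0.03)
  }
})

test_that("a non-PSD target matrix is refused naming the offending pair", {
  bad <- matrix(c(1, 0.9, 0.9,
                  0.9, 1, -0.9,
                  0.9, -0.9, 1), 3, byrow = TRUE)
  dimnames(bad) <- list(c("x", "y", "z"), c("x", "y", "z"))
  g <- pet_grid(c(6, 6, 6))
  expect_error(make_correlated_fields(bad, g, 2, 1),
               "positive semi-definite.*pair")
})

test_that("monotone marginal transforms leave pairwise Spearman unchanged", {
  cfg <- small_phantom_config(seed = 41)
  ph <- make_phantom(cfg)
  gtv <- ph$masks$gtv$membership
  for (pr in list(c("fdg", "fmiso"), c("adc", "perfusion"),
                  c("fmiso", "adc"))) {
    lat <- spearman_cor(ph$truth$fields[[pr[1]]]$values[gtv],
                        ph$truth$fields[[pr[2]]]$values[gtv])
    mapped <- spearman_cor(ph$truth[[pr[1]]]$values[gtv],
                           ph$truth[[pr[2]]]$values[gtv])
    expect_identical(lat, mapped)
  }
})

test_that("noiseless measured maps inherit the latent Spearman exactly", {
  cfg <- small_phantom_config(seed = 42)  # noise = list(): noiseless
  ph <- make_phantom(cfg)
  gtv <- ph$masks$gtv
  ss <- voxel_samples(ph$maps$fdg, ph$maps$fmiso, gtv)
  lat <- voxel_samples(ph$truth$fields$fdg, ph$truth$fields$fmiso, gtv)
  expect_identical(spearman_cor(ss$x, ss$y), spearman_cor(lat$x, lat$y))
})

test_that("phantoms are bit-identical for a fixed seed and differ across seeds", {
  cfg <- small_phantom_config(seed = 77,
                              noise = list(fdg = list(type = "gaussian",
                                                      sd = 1)))
  ph1 <- make_phantom(cfg)
  ph2 <- make_phantom(cfg)
  expect_identical(ph1$maps$fdg$values, ph2$maps$fdg$values)
  expect_identical(ph1$dce_series$frames, ph2$dce_series$frames)
  ph3 <- make_phantom(small_phantom_config(
    seed = 78, noise = list(fdg = list(type = "gaussian", sd = 1))))
  expect_false(identical(ph1$maps$fdg$values, ph3$maps$fdg$values))
})

test_that("GTV geometry matches the analytic ellipsoid volume", {
  cfg <- phantom_config(gtv_semiaxes_mm = c(20, 20, 16), seed = 1,
                        noise = list())
  ph <- make_phantom(cfg)
  vox_cm3 <- sum(ph$masks$gtv$membership) *
    voxel_volume(cfg$grid) / 1000
  analytic_cm3 <- 4 / 3 * pi * 20 * 20 * 16 / 1000
  expect_lt(abs(vox_cm3 - analytic_cm3) / analytic_cm3, 0.10)
  # physicality of the generated Tofts truth
  expect_true(all(ph$truth$ve$values + ph$truth$vp$values <= 1))
  expect_true(all(ph$truth$ktrans$values >= 0))
})

test_that("an undersized GTV is flagged for missing a full block", {
  expect_warning(
    ph <- make_phantom(phantom_config(
      grid = image_grid(c(10, 10, 10), c(2.8, 2.8, 2.0)),
      gtv_semiaxes_mm = c(3, 3, 3), seed = 1, noise = list())),
    "full 3x3x4 block")
  expect_true(any(grepl("full 3x3x4 block", ph$warnings)))
})

test_that("simulate_dce_series matches its spec'd frame count and limits", {
  g <- pet_grid(c(2, 2, 1))
  aif <- aif_model()
  kt0 <- constant_map(g, 0, "1/min"); ve0 <- constant_map(g, 0.2)
  vp0 <- constant_map(g, 0)
  s <- simulate_dce_series(kt0, ve0, vp0, aif, time_step = 2.9,
                           duration = 258, baseline_frames = 5,
                           noise_sigma = 0, baseline_value = 100)
  expect_equal(n_frames(s), 89L)  # floor(258/2.9) + 1
  expect_equal(max(abs(s$frames - 100)), 0)  # no exchange -> flat baseline

  # a single voxel reproduces the forward model plus baseline exactly
  g1 <- image_grid(c(1, 1, 1), c(1, 1, 1))
  s1 <- simulate_dce_series(constant_map(g1, 0.25, "1/min"),
                            constant_map(g1, 0.3), constant_map(g1, 0.05),
                            aif, baseline_frames = 5, noise_sigma = 0,
                            scale = 50, baseline_value = 100, refine = 5)
  expected <- 100 + 50 * tofts_forward(
    list(ktrans = 0.25, ve = 0.3, vp = 0.05), aif, s1$frame_starts,
    refine = 5)
  expect_equal(as.vector(s1$frames), expected, tolerance = 1e-12)

  # nonphysical parameters are rejected with a voxel index
  expect_error(simulate_dce_series(constant_map(g, 0.2, "1/min"),
                                   constant_map(g, 0.7),
                                   constant_map(g, 0.4), aif,
                                   baseline_frames = 5),
               "voxel index")
})

test_that("FMISO wash-in is linear in the perfusion surrogate", {
  g <- image_grid(c(2, 1, 1), c(1, 1, 1))
  p <- parametric_map(g, array(c(1, 2), g$shape), "a.u.", "perfusion")
  s <- simulate_fmiso_washin(p, time_step = 10, duration = 240, tau = 60)
  af <- mean_activity_map(s)
  expect_equal(af$values[2, 1, 1] / af$values[1, 1, 1], 2)

  z <- simulate_fmiso_washin(constant_map(g, 0), time_step = 10,
                             duration = 240)
  expect_equal(max(abs(mean_activity_map(z)$values)), 0)
  expect_error(simulate_fmiso_washin(p, duration = 180), "0-4 min")
})

test_that("simulate_dw_signals matches hand-evaluated exponentials", {
  g <- image_grid(c(1, 1, 1), c(1, 1, 1))
  dw <- simulate_dw_signals(constant_map(g, 1.0e-3, unit = "mm^2/s"),
                            c(50, 800), s0 = 1000)
  expect_lt(abs(dw$s_low$values[1] - 951.2), 0.1)
  expect_lt(abs(dw$s_high$values[1] - 449.3), 0.1)
  flat <- simulate_dw_signals(constant_map(g, 0, unit = "mm^2/s"),
                              c(50, 800), s0 = 1000)
  expect_equal(as.vector(flat$s_low$values), 1000)
  expect_equal(as.vector(flat$s_high$values), 1000)
})
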