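test_that("spearman_cor reproduces hand-computed values incl. ties", {
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 1, 2)), -0.5)
  # ranks (1.5, 1.5, 3) vs (1, 2, 3): r = 1.5/sqrt(3)
  expect_equal(spearman_cor(c(1, 1, 2), c(1, 2, 3)), 1.5 / sqrt(3))
  expect_equal(spearman_cor(1:5, 1:5), 1)
  x <- rnorm(20)
  expect_equal(spearman_cor(x, exp(x)), 1)  # monotone invariance
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, c(1, NA, 3)), "finite")
  expect_error(spearman_cor(1:4, 1:3), "equal length")
})

test_that("spearman_cor agrees with independent oracles on random tie-laden data", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, sd = 0.01 * (rep %% 2))
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_cor(x, y),
                 suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
  # tie-free small n: the classical 1 - 6*sum(d^2)/(n(n^2-1)) definition
  for (rep in 1:100) {
    n <- sample(3:7, 1)
    x <- sample(100, n); y <- sample(100, n)
    d <- rank(x) - rank(y)
    expect_equal(spearman_cor(x, y), 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
                 tolerance = 1e-12)
  }
})

test_that("spearman_cor is antisymmetric and monotone-invariant", {
  set.seed(12)
  for (rep in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(spearman_cor(x, -y), -spearman_cor(x, y), tolerance = 1e-12)
    expect_equal(spearman_cor(x^3, exp(y)), spearman_cor(x, y),
                 tolerance = 1e-12)
  }
})

test_that("voxel_samples counts GTV voxels and reports drops", {
  g <- pet_grid(c(10, 10, 4))
  gtv <- box_mask(g, c(1, 1, 1), c(10, 10, 1))  # 100 voxels
  set.seed(4)
  a <- parametric_map(g, array(rnorm(prod(g$shape)), g$shape), "SUV", "A")
  b <- parametric_map(g, array(rnorm(prod(g$shape)), g$shape), "TBR", "B")
  ss <- voxel_samples(a, b, gtv)
  expect_equal(ss$n, 100L)
  expect_equal(ss$n_dropped, 0L)

  a2 <- a
  a2$values[1:10, 1, 1] <- NA  # 10 invalid GTV voxels
  ss2 <- voxel_samples(a2, b, gtv)
  expect_equal(ss2$n, 90L)
  expect_equal(ss2$n_dropped, 10L)

  a3 <- a; a3$values[, , 1] <- NA
  expect_error(voxel_samples(a3, b, gtv), "fewer than 2")
})

test_that("partition_regions tiles the bounding box with the documented geometry", {
  g <- pet_grid(c(20, 20, 20))
  # GTV exactly one aligned 3x3x4 block
  one <- box_mask(g, c(5, 5, 5), c(7, 7, 8))
  r1 <- partition_regions(one)
  expect_length(r1, 1L)
  expect_length(r1[[1]], 36L)
  expect_equal(attr(r1, "block_extent_mm"), c(8.4, 8.4, 8.0))

  # a 6x6x8 aligned box -> 2x2x2 = 8 regions
  box <- box_mask(g, c(3, 3, 3), c(8, 8, 10))
  r8 <- partition_regions(box)
  expect_length(r8, 8L)
  expect_true(all(lengths(r8) == 36L))
  # regions partition the GTV exactly
  expect_setequal(unlist(r8), which(box$membership))

  # occupancy rule: a half-filled boundary block passes at 0.5, not at 0.8
  part <- box_mask(g, c(5, 5, 5), c(7, 7, 6))  # 3x3x2 = half of a block
  expect_length(partition_regions(part, region_spec()), 1L)
  expect_length(partition_regions(part,
                                  region_spec(min_gtv_fraction = 0.8)), 0L)
})

test_that("regional_samples averages GTV voxels per region", {
  g <- pet_grid(c(6, 6, 4))
  gtv <- box_mask(g, c(1, 1, 1), c(3, 3, 4))
  regions <- partition_regions(gtv)
  expect_length(regions, 1L)
  vals <- array(0, g$shape); vals[1:3, 1:3, 1:4] <- 1:36
  a <- parametric_map(g, vals, "SUV", "A")
  b <- constant_map(g, 2, unit = "TBR", name = "B")
  # need two regions for a correlation, so test the sample values directly
  xa <- mean(vals[1:3, 1:3, 1:4])
  expect_equal(xa, 18.5)
  two <- box_mask(g, c(1, 1, 1), c(6, 3, 4))
  rg2 <- partition_regions(two)
  expect_length(rg2, 2L)
  ss <- regional_samples(a, parametric_map(g, vals * 2, "a.u.", "B"), rg2)
  expect_equal(ss$level, "regional")
  expect_equal(sort(ss$x), c(0, 18.5))
  expect_equal(ss$y, 2 * ss$x)

  # invalid voxels are excluded from the regional mean
  vals_na <- vals; vals_na[1, 1, 1] <- NA
  ssn <- regional_samples(parametric_map(g, vals_na, "SUV"), a, rg2)
  expect_equal(sort(ssn$x)[2], mean((1:36)[-1]))
})

test_that("block-constant maps give identical voxel and regional Spearman", {
  g <- pet_grid(c(6, 6, 8))
  gtv <- box_mask(g, c(1, 1, 1), c(6, 6, 8))
  regions <- partition_regions(gtv)
  expect_length(regions, 8L)
  set.seed(8)
  av <- array(NA_real_, g$shape); bv <- array(NA_real_, g$shape)
  for (i in seq_along(regions)) {
    av[regions[[i]]] <- rnorm(1)
    bv[regions[[i]]] <- rnorm(1)
  }
  a <- parametric_map(g, av, "SUV", "A"); b <- parametric_map(g, bv, "TBR", "B")
  r_reg <- with(regional_samples(a, b, regions), spearman_cor(x, y))
  one_per_block <- vapply(regions, `[`, numeric(1), 1)
  r_vox <- spearman_cor(av[one_per_block], bv[one_per_block])
  expect_equal(r_reg, r_vox)
})

test_that("patient_correlation_matrix applies the sub-region exclusion rule", {
  g <- pet_grid(c(12, 12, 8))
  # 9x9x4-voxel GTV -> 3x3x1 = 9 full blocks: below the minimum of 10
  gtv9 <- box_mask(g, c(2, 2, 2), c(10, 10, 5))
  expect_length(partition_regions(gtv9), 9L)
  set.seed(5)
  maps <- list(
    A = parametric_map(g, array(rnorm(prod(g$shape)), g$shape), "SUV", "A"),
    B = parametric_map(g, array(rnorm(prod(g$shape)), g$shape), "TBR", "B"))
  reg <- patient_correlation_matrix(maps, gtv9, "regional", patient = "p1")
  expect_true(reg$excluded)
  expect_null(reg$r)
  expect_match(reg$reason, "9 sub-regions")
  vox <- patient_correlation_matrix(maps, gtv9, "voxel", patient = "p1")
  expect_false(vox$excluded)
  expect_equal(vox$n["A", "B"], sum(gtv9$membership))

  # identical maps -> off-diagonal 1
  dup <- patient_correlation_matrix(list(A = maps$A, A2 = maps$A), gtv9,
                                    "voxel")
  expect_equal(dup$r["A", "A2"], 1)
})

test_that("cohort_summary computes order statistics and honors exclusions", {
  g <- pet_grid(c(12, 12, 8))
  gtv <- box_mask(g, c(2, 2, 2), c(10, 10, 5))
  mk_res <- function(pid, r, level = "voxel", excluded = FALSE) {
    if (excluded)
      return(structure(list(patient = pid, level = level, r = NULL,
                            n = NULL, excluded = TRUE, reason = "few",
                            n_regions = 9, notes = character()),
                       class = "correlation_result"))
    m <- matrix(c(1, r, r, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
    structure(list(patient = pid, level = level, r = m,
                   n = matrix(100, 2, 2, dimnames = dimnames(m)),
                   excluded = FALSE, reason = NULL, n_regions = NA,
                   notes = character()),
              class = "correlation_result")
  }
  res <- list(mk_res("p1", 0.2), mk_res("p2", 0.5), mk_res("p3", 0.9),
              mk_res("p1", 0.3, "regional"),
              mk_res("p2", NA, "regional", excluded = TRUE))
  sm <- cohort_summary(res)
  vox <- sm[sm$level == "voxel", ]
  expect_equal(vox$median_r, 0.5)
  expect_equal(c(vox$min_r, vox$max_r), c(0.2, 0.9))
  expect_equal(vox$n_patients, 3L)
  reg <- sm[sm$level == "regional", ]
  expect_equal(reg$n_patients, 1L)  # excluded patient contributes nothing
  expect_equal(reg$median_r, 0.3)

  # single patient: median is that patient's r, degenerate range
  sm1 <- cohort_summary(list(mk_res("p1", 0.42)))
  expect_equal(sm1$median_r, 0.42)
  expect_equal(sm1$min_r, sm1$max_r)

  mat <- correlation_matrix_table(sm)
  expect_equal(mat["A", "B"], 0.5)   # voxel upper triangle
  expect_equal(mat["B", "A"], 0.3)   # regional lower triangle
})
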