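# Grid-to-grid resampling with separable B-spline interpolation.
# Degree 0 = nearest neighbour, 1 = trilinear, 3 = cubic B-spline with the
# standard recursive prefilter (pole sqrt(3)-2), which reproduces cubic
# polynomials exactly inside the field of view.

# Recursive cubic B-spline prefilter along the first dimension of a matrix
# (one column per line). Lines are first extended by polynomial (Lagrange)
# extrapolation so that boundary effects of the recursive filter decay below
# 1e-12 inside the field of view; this keeps interpolation exact for
# polynomial fields up to degree 3 right up to the FOV edge.
bspline3_prefilter_lines <- function(s, pad = 22L) {
  n <- nrow(s)
  if (n == 1L) return(s)
  k <- min(n, 4L)  # extrapolation order: cubic where the line allows
  nodes <- seq_len(k) - 1
  lagrange_w <- function(x) {
    vapply(seq_len(k), function(j) {
      others <- nodes[-j]
      prod((x - others) / (nodes[j] - others))
    }, numeric(1))
  }
  wr <- t(vapply(seq_len(pad), function(d) lagrange_w(k - 1 + d), numeric(k)))
  left <- wr %*% s[seq(k, 1L), , drop = FALSE]          # mirror node order
  right <- wr %*% s[seq(n - k + 1L, n), , drop = FALSE]
  sp <- rbind(left[seq(pad, 1L), , drop = FALSE], s, right)
  np <- nrow(sp)

  z <- sqrt(3) - 2
  sp <- sp * 6
  horizon <- min(np, ceiling(log(1e-14) / log(abs(z))))
  cp <- matrix(0, np, ncol(sp))
  zi <- z^(seq_len(horizon) - 1L)
  cp[1L, ] <- colSums(zi * sp[seq_len(horizon), , drop = FALSE])
  for (i in 2:np) cp[i, ] <- sp[i, ] + z * cp[i - 1L, ]
  cm <- matrix(0, np, ncol(sp))
  cm[np, ] <- (z / (z * z - 1)) * (cp[np, ] + z * cp[np - 1L, ])
  for (i in (np - 1L):1L) cm[i, ] <- z * (cm[i + 1L, ] - cp[i, ])
  # keep 2 extra coefficients per side: the cubic support of positions at
  # the FOV edge reaches one node beyond the grid
  cm[(pad - 2L) + seq_len(n + 4L), , drop = FALSE]
}

apply_along_axis <- function(arr, axis, fn) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- fn(m)
  a <- array(m, dim = c(nrow(m), d[perm][-1L]))
  aperm(a, order(perm))
}

# Returns coefficients on an array expanded by 2 voxels per side per axis;
# source voxel i (0-based) maps to expanded index i + 2.
bspline3_prefilter <- function(arr) {
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    if (n == 1L) {
      # a single node: constant extension, coefficient equals the value
      arr <- apply_along_axis(arr, ax, function(m)
        m[rep(1L, 5L), , drop = FALSE])
    } else {
      arr <- apply_along_axis(arr, ax, bspline3_prefilter_lines)
    }
  }
  arr
}

# mirror-reflect indices into 1..n (0-based input)
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- i %% p
  i[i < 0L] <- i[i < 0L] + p
  i[i >= n] <- p - i[i >= n]
  i + 1L
}

bspline3_weights <- function(t) {
  # nodes floor-1 .. floor+2; t = fractional part in [0,1)
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

#' Resample a parametric map onto another grid
#'
#' Values are interpolated at the target voxel centers in world coordinates
#' using separable B-spline interpolation of the requested degree (0 =
#' nearest neighbour, 1 = trilinear, 3 = cubic with prefiltering, the
#' default). Target voxels whose interpolation support falls outside the
#' source field of view, or touches invalid (non-finite) source voxels, are
#' flagged invalid (`NA`) rather than extrapolated.
#'
#' @param map a `parametric_map`.
#' @param target target `image_grid` sharing the source's world frame.
#' @param order spline degree: 0, 1 or 3 (default 3).
#' @return A `parametric_map` on `target`.
#' @export
resample_to_grid <- function(map, target, order = 3L) {
  stopifnot(inherits(map, "parametric_map"), inherits(target, "image_grid"))
  order <- as.integer(order)
  if (!order %in% c(0L, 1L, 3L)) stop("order must be 0, 1 or 3")
  src <- map$grid
  if (grids_equal(src, target))
    return(parametric_map(target, map$values, map$unit, map$name))

  # continuous source indices (0-based) of the target voxel centers
  w <- grid_coordinates(target)
  cont <- sweep(sweep(w, 2L, src$origin, `-`), 2L, src$spacing, `/`)
  n <- src$shape
  eps <- 1e-9
  inside <- cont[, 1] >= -eps & cont[, 1] <= n[1] - 1 + eps &
            cont[, 2] >= -eps & cont[, 2] <= n[2] - 1 + eps &
            cont[, 3] >= -eps & cont[, 3] <= n[3] - 1 + eps

  vals <- map$values
  invalid_src <- !is.finite(vals)
  any_invalid <- any(invalid_src)
  work <- vals
  # invalid voxels never contribute to a reported value (their support is
  # flagged below); fill them smoothly so the recursive prefilter is not
  # perturbed by arbitrary hole values
  if (any_invalid) work <- fill_invalid_voxels(work)

  out <- rep(NA_real_, nrow(cont))
  if (any(inside)) {
    ci <- cont[inside, , drop = FALSE]
    if (order == 0L) {
      ii <- round(ci)
      lin <- 1L + ii[, 1] + n[1] * (ii[, 2] + n[2] * ii[, 3])
      v <- vals[lin]  # nearest neighbour: propagate NA directly
    } else if (order == 1L) {
      v <- interp_separable(work, ci, n, degree = 1L)
      if (any_invalid) {
        bad <- interp_support_touches(invalid_src, ci, n, radius = 1L)
        v[bad] <- NA_real_
      }
    } else {
      coef <- bspline3_prefilter(work)
      v <- interp_separable(coef, ci, n, degree = 3L)
      if (any_invalid) {
        bad <- interp_support_touches(invalid_src, ci, n, radius = 2L)
        v[bad] <- NA_real_
      }
    }
    out[inside] <- v
  }
  parametric_map(target, array(out, target$shape), map$unit, map$name)
}

interp_separable <- function(coef, ci, n, degree) {
  fl <- floor(ci)
  t <- ci - fl
  if (degree == 1L) {
    offs <- 0:1
    wx <- cbind(1 - t[, 1], t[, 1])
    wy <- cbind(1 - t[, 2], t[, 2])
    wz <- cbind(1 - t[, 3], t[, 3])
    index1 <- function(i, ax) mirror_index(i, n[ax])
    dims <- n
  } else {
    # coef is the guard-cell-expanded coefficient array: source node i
    # (0-based) sits at expanded 1-based index i + 3
    offs <- -1:2
    wx <- bspline3_weights(t[, 1])
    wy <- bspline3_weights(t[, 2])
    wz <- bspline3_weights(t[, 3])
    index1 <- function(i, ax) i + 3L
    dims <- n + 4L
  }
  acc <- numeric(nrow(ci))
  for (a in seq_along(offs)) {
    ia <- index1(fl[, 1] + offs[a], 1L)
    for (b in seq_along(offs)) {
      ib <- index1(fl[, 2] + offs[b], 2L)
      wab <- wx[, a] * wy[, b]
      for (cc in seq_along(offs)) {
        ic <- index1(fl[, 3] + offs[cc], 3L)
        lin <- ia + dims[1] * (ib - 1L + dims[2] * (ic - 1L))
        acc <- acc + wab * wz[, cc] * coef[lin]
      }
    }
  }
  acc
}

# Iterative 6-neighbour mean fill of non-finite voxels (plain diffusion
# inpainting; exact for locally linear fields).
fill_invalid_voxels <- function(v) {
  d <- dim(v)
  shift_sum <- function(x) {
    s <- array(0, d); cnt <- array(0, d)
    add <- function(sl_to, sl_from) {
      xs <- x[sl_from$i, sl_from$j, sl_from$k, drop = FALSE]
      ok <- is.finite(xs)
      xs[!ok] <- 0
      s[sl_to$i, sl_to$j, sl_to$k] <<-
        s[sl_to$i, sl_to$j, sl_to$k] + xs
      cnt[sl_to$i, sl_to$j, sl_to$k] <<-
        cnt[sl_to$i, sl_to$j, sl_to$k] + ok
    }
    full <- function(n) seq_len(n)
    if (d[1] > 1L) {
      add(list(i = 1:(d[1] - 1), j = full(d[2]), k = full(d[3])),
          list(i = 2:d[1], j = full(d[2]), k = full(d[3])))
      add(list(i = 2:d[1], j = full(d[2]), k = full(d[3])),
          list(i = 1:(d[1] - 1), j = full(d[2]), k = full(d[3])))
    }
    if (d[2] > 1L) {
      add(list(i = full(d[1]), j = 1:(d[2] - 1), k = full(d[3])),
          list(i = full(d[1]), j = 2:d[2], k = full(d[3])))
      add(list(i = full(d[1]), j = 2:d[2], k = full(d[3])),
          list(i = full(d[1]), j = 1:(d[2] - 1), k = full(d[3])))
    }
    if (d[3] > 1L) {
      add(list(i = full(d[1]), j = full(d[2]), k = 1:(d[3] - 1)),
          list(i = full(d[1]), j = full(d[2]), k = 2:d[3]))
      add(list(i = full(d[1]), j = full(d[2]), k = 2:d[3]),
          list(i = full(d[1]), j = full(d[2]), k = 1:(d[3] - 1)))
    }
    list(sum = s, count = cnt)
  }
  for (iter in seq_len(sum(!is.finite(v)) + length(v))) {
    hole <- !is.finite(v)
    if (!any(hole)) break
    ns <- shift_sum(v)
    fixable <- hole & ns$count > 0
    if (!any(fixable)) { v[hole] <- 0; break }
    v[fixable] <- ns$sum[fixable] / ns$count[fixable]
  }
  v
}

# TRUE where the (2*radius+1)^3 index box around each continuous position
# contains an invalid source voxel; conservative support test.
interp_support_touches <- function(invalid, ci, n, radius) {
  fl <- floor(ci)
  touched <- rep(FALSE, nrow(ci))
  for (a in (-radius + 1L):radius) {
    ia <- pmin(pmax(fl[, 1] + a, 0L), n[1] - 1L)
    for (b in (-radius + 1L):radius) {
      ib <- pmin(pmax(fl[, 2] + b, 0L), n[2] - 1L)
      for (cc in (-radius + 1L):radius) {
        ic <- pmin(pmax(fl[, 3] + cc, 0L), n[3] - 1L)
        lin <- 1L + ia + n[1] * (ib + n[2] * ic)
        touched <- touched | invalid[lin]
      }
    }
  }
  touched
}
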