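# Arterial input function: functional form, evaluation and per-patient
# fitting from a carotid signal-time curve.

#' Arterial input function model
#'
#' One parametric family is implemented: a biexponential decay modulated by a
#' saturating bolus-rise factor (a Parker-like shape),
#' \deqn{C_p(t) = (a_1 e^{-m_1 \tau} + a_2 e^{-m_2 \tau})(1 - e^{-r \tau}),
#'   \quad \tau = (t - t_0)/60,}
#' and zero before the bolus arrival `t0`. Amplitudes are in concentration
#' units (mM for contrast agent; arbitrary units when the fit target is raw
#' enhancement), rates in 1/min, `t0` in seconds. Both form labels accepted
#' by the constructor select this family.
#'
#' @param a1,a2 amplitudes, `>= 0`.
#' @param m1,m2 decay rates in 1/min (fast and slow component, `m1 > m2`).
#' @param r bolus rise rate in 1/min, `> 0`.
#' @param t0 bolus arrival time in seconds.
#' @param form form label, `"biexp_bolus"` (default) or `"parker_like"`;
#'   `"constant"` gives the degenerate plateau `C_p(t) = a1` for `t >= t0`,
#'   for which the model has a closed-form solution (used in validation).
#' @return An object of class `aif_model`.
#' @export
aif_model <- function(a1 = 3.0, m1 = 2.0, a2 = 1.0, m2 = 0.05,
                      r = 15, t0 = 30,
                      form = c("biexp_bolus", "parker_like", "constant")) {
  form <- match.arg(form)
  p <- c(a1 = a1, m1 = m1, a2 = a2, m2 = m2, r = r, t0 = t0)
  if (any(!is.finite(p))) stop("AIF parameters must be finite")
  if (a1 < 0 || a2 < 0) stop("AIF amplitudes must be >= 0")
  if (form != "constant") {
    if (r <= 0) stop("bolus rise rate must be > 0")
    if (m1 <= m2) stop("decay rates must satisfy m1 > m2")
  }
  structure(list(form = form, params = p), class = "aif_model")
}

#' @export
print.aif_model <- function(x, ...) {
  cat(sprintf(
    "<aif_model> %s: a=(%.3g, %.3g), m=(%.3g, %.3g) 1/min, rise %.3g 1/min, t0 %.2f s\n",
    x$form, x$params["a1"], x$params["a2"], x$params["m1"], x$params["m2"],
    x$params["r"], x$params["t0"]))
  invisible(x)
}

#' Evaluate an AIF at given times
#'
#' @param aif an `aif_model`.
#' @param times_s times in seconds.
#' @return Nonnegative concentration vector, zero before bolus arrival.
#' @export
aif_eval <- function(aif, times_s) {
  stopifnot(inherits(aif, "aif_model"))
  p <- aif$params
  tau <- (times_s - p["t0"]) / 60  # minutes since bolus arrival
  out <- numeric(length(tau))
  if (aif$form == "constant") {
    out[tau >= 0] <- p["a1"]
    return(out)
  }
  pos <- tau > 0
  tp <- tau[pos]
  out[pos] <- (p["a1"] * exp(-p["m1"] * tp) + p["a2"] * exp(-p["m2"] * tp)) *
    (1 - exp(-p["r"] * tp))
  pmax(out, 0)
}

#' Fit an AIF to a carotid signal-time curve
#'
#' Least-squares fit (Levenberg-Marquardt) of the [aif_model] family to a
#' measured carotid curve. The curve must contain at least 3 pre-bolus
#' points, and the peak must exceed the pre-bolus level by more than 3
#' pre-bolus standard deviations, otherwise a no-bolus error asks for a
#' manual bolus-arrival time.
#'
#' @param curve concentration or baseline-subtracted enhancement values.
#' @param times_s sample times in seconds, sorted ascending.
#' @param form AIF form label (see [aif_model]).
#' @return An `aif_model` with attached `fit` diagnostics (rss, n_iter,
#'   converged, residuals).
#' @export
fit_aif <- function(curve, times_s, form = c("biexp_bolus", "parker_like")) {
  form <- match.arg(form)
  curve <- as.numeric(curve); times_s <- as.numeric(times_s)
  if (length(curve) != length(times_s) || length(curve) < 8L)
    stop("curve and times must have equal length >= 8")
  if (is.unsorted(times_s, strictly = TRUE)) stop("times must be ascending")
  if (any(!is.finite(curve))) stop("curve contains non-finite values")

  # bolus detection
  base3 <- curve[1:3]
  peak_i <- which.max(curve)
  peak <- curve[peak_i]
  rise <- peak - mean(base3)
  if (!(rise > max(3 * stats::sd(base3), 1e-12)))
    stop("no detectable bolus in carotid curve (peak <= 3 x pre-bolus sd); ",
         "supply t0 manually")
  thr <- mean(base3) + 0.1 * rise
  above <- which(curve > thr & seq_along(curve) <= peak_i)
  t0_init <- if (length(above)) {
    i <- min(above)
    if (i > 1L) times_s[i - 1L] else times_s[1L]
  } else times_s[1L]
  n_pre <- sum(times_s < t0_init)
  if (n_pre < 3L)
    stop("need >= 3 pre-bolus samples before the detected arrival at ",
         signif(t0_init, 4), " s")

  tmin <- times_s[1L]; tmax <- times_s[length(times_s)]
  # unconstrained parameterization: log for positives, a logit keeps t0
  # inside the observed time range, and m1 = m2 + dm fixes component order
  pack <- function(a1, m1, a2, m2, r, t0)
    c(log(a1), log(m1 - m2), log(a2), log(m2), log(r),
      stats::qlogis((t0 - tmin) / (tmax - tmin)))
  unpack <- function(q) {
    m2 <- exp(q[4])
    list(a1 = exp(q[1]), m1 = m2 + exp(q[2]), a2 = exp(q[3]), m2 = m2,
         r = exp(q[5]),
         t0 = tmin + (tmax - tmin) * stats::plogis(q[6]))
  }
  resid_fn <- function(q) {
    p <- unpack(q)
    aif <- aif_model(p$a1, p$m1, p$a2, p$m2, p$r, p$t0, form = form)
    curve - aif_eval(aif, times_s)
  }

  starts <- list(
    pack(rise, 2, 0.3 * rise, 0.05, 15, t0_init),
    pack(rise, 5, 0.2 * rise, 0.02, 30, t0_init),
    pack(0.5 * rise, 1, 0.5 * rise, 0.1, 10,
         max(tmin + 1e-3 * (tmax - tmin), t0_init - 5)))
  best <- NULL
  for (q0 in starts) {
    ft <- tryCatch(
      minpack.lm::nls.lm(q0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(ft)) next
    if (is.null(best) || ft$deviance < best$deviance) best <- ft
  }
  if (is.null(best)) stop("AIF fit failed from all starting points")
  p <- unpack(best$par)
  out <- aif_model(p$a1, p$m1, p$a2, p$m2, p$r, p$t0, form = form)
  out$fit <- list(rss = best$deviance, n_iter = best$niter,
                  converged = best$info %in% 1:4,
                  residuals = as.numeric(best$fvec))
  out
}
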