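---
title: "Methods: multi-parametric PET/MR correlation analysis"
author: "petmrcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-parametric PET/MR correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmrcorr)
```

## Scope and model

`petmrcorr` quantifies, per patient and within the gross tumor volume
(GTV), how strongly pairs of functional imaging parameters co-vary. The
modalities handled are FDG-PET (glucose metabolism), FMISO-PET in both its
early wash-in and late retention phase (hypoxia), ADC maps from
diffusion-weighted MRI (cellularity), and DCE-MRI with extended Tofts
pharmacokinetic parameters (vascular physiology). The statistic throughout
is the Spearman rank correlation, chosen because the modalities live on
incommensurate scales and because clinically used normalizations (SUV, TBR)
are monotone and must not change the result.

Two sampling levels are supported. At the *voxel level*, paired samples are
the values of two maps at each GTV voxel on the PET grid
(2.8 × 2.8 × 2.0 mm³ voxels). At the *regional level*, samples are means
over non-overlapping 3×3×4-voxel blocks (8.4 × 8.4 × 8 mm³), which trades
spatial resolution for robustness against registration error and noise.
Patients whose GTV yields fewer than ten sub-regions are excluded from the
regional analysis (too few samples for a meaningful coefficient) while
still contributing at the voxel level.

## Wash-in summary maps

Early dynamic series are collapsed by time-averaging over a 0–4 min window
with the rectangle rule: each frame contributes its value times the length
of its overlap with the window, and the sum is divided by the window
length. Two conventions had to be fixed that the underlying acquisition
does not dictate:

- each frame is treated as piecewise-constant over its duration — the
  natural reading for frame-averaged PET counts;
- frames partially overlapping the window edge are pro-rated by overlap
  length rather than included or excluded whole, which removes a
  discretization bias of up to half a frame.

A coverage check refuses windows with gaps of one frame duration or more,
reporting the missing interval. For DCE, the series is first converted to
enhancement by subtracting the per-voxel mean of a configured number of
pre-injection baseline frames; bolus arrival is an acquisition-driven
configuration parameter, not auto-detected.

## Extended Tofts modelling

The tissue concentration model is
$$C_t(t) = v_p C_p(t) + K^\mathrm{trans} \int_0^t C_p(u)\,
e^{-k_{ep}(t-u)}\,du, \qquad k_{ep} = K^\mathrm{trans}/v_e,$$
with plasma volume fraction $v_p$, extravascular-extracellular volume
fraction $v_e$ and transfer constant $K^\mathrm{trans}$ (1/min). The
convolution is evaluated on a refined internal time grid (default 10× the
sampling rate, augmented with the sample times and the bolus arrival so the
kink at $t_0$ is represented exactly); within each step the AIF is taken
linear and the exponential kernel integrated analytically, which is stable
for any $k_{ep}$ and reduces to an exact quadrature whenever the AIF is
piecewise linear. Against the closed-form solution for a constant AIF the
implementation agrees to machine precision (the test suite asserts
< 0.1 %).

**Fit target.** The pipeline fits baseline-subtracted *enhancement* with a
single global enhancement-per-concentration factor that is absorbed into
the AIF amplitude. The alternative — converting enhancement to
concentration through native T1 maps — is implemented
(`enhancement_to_concentration`, with DESPOT1 T1 mapping from dual
flip-angle acquisitions) but off by default: rank-based downstream
statistics are insensitive to the global scale, while the conversion adds
the uncertainty of the T1 maps.

**AIF.** One parametric family is provided: a biexponential decay
modulated by a saturating bolus rise,
$C_p(t) = (a_1 e^{-m_1\tau} + a_2 e^{-m_2\tau})(1 - e^{-r\tau})$ with
$\tau$ the time since bolus arrival. It is fitted per patient to the mean
carotid enhancement curve by Levenberg–Marquardt from three starting
points, with the fast/slow component ordering enforced structurally
($m_1 = m_2 + e^q$) and the arrival time constrained to the observed time
range by a logistic map. A degenerate `"constant"` form exists for
validation against the closed-form solution. Bolus detection requires at
least three pre-bolus points and a peak exceeding three pre-bolus standard
deviations; an all-zero or flat curve is refused with a request for a
manual arrival time.

**Voxel fits.** The voxel-level least-squares problem is solved by
Levenberg–Marquardt in a smooth reparameterization of
$(K^\mathrm{trans}, k_{ep}, v_p)$: logs for $K^\mathrm{trans}$ and
$k_{ep} - K^\mathrm{trans}$ (which enforces $0 < v_e < 1$), and a logistic
for $v_p/(1 - v_e)$ (which enforces $v_e + v_p \le 1$). The
$(K^\mathrm{trans}, k_{ep})$ pair was chosen over the naive
$(K^\mathrm{trans}, v_e)$ pair after the latter produced an ill-conditioned
valley in which the optimizer stalled for slow-kinetics parameter
combinations (small $K^\mathrm{trans}$, large $v_e$); in the
better-conditioned pair, noiseless recovery is exact to solver precision
across the whole physical range at 2.9 s sampling over 4.3 min.
Initialization is $(0.1\ \mathrm{min}^{-1}, 0.2, 0.02)$ with a two-point
multistart triggered when the residual exceeds a noise-scaled threshold
(5 % of the curve maximum by default). All-zero curves short-circuit to the
null model; non-finite curves mark the voxel invalid. Convergence flags and
residual sums of squares are reported honestly, and a map-level fit warns
when more than half its voxels fail to converge.

**Regional fits.** At the regional level the enhancement curves of a
block's GTV voxels are averaged first and one fit is performed per block —
averaging curves (linear) before the nonlinear fit, rather than averaging
fitted parameters.

## Normalization

SUV divides activity by injected dose per body weight (1 g/mL density
assumed; decay correction is the caller's responsibility, since the
acquisition protocol fixes the injection-to-scan interval); TBR divides by
the mean over a background-muscle ROI (median available by configuration).
Both are strictly monotone per-voxel maps, so every Spearman coefficient is
exactly invariant — this is asserted, not assumed, in the test suite.

## Regional partitioning choices

Blocks tile the GTV bounding box anchored at its minimal corner. Two knobs
are exposed because no acquisition constraint fixes them: the partial-block
rule (a block is kept when at least 50 % of its voxels are GTV by default)
and the fact that regional means use only the GTV voxels of a block, never
the full block. Ten kept sub-regions are required for a regional analysis.
Degenerate inputs fail loudly: a constant value vector raises an
undefined-correlation error rather than silently contributing a zero to a
cohort median.

## The phantom generator

Because the pipeline's central claim is about rank correlations, the
generator is built so the population Spearman between modalities is known
*exactly*, not approximately:

1. jointly Gaussian white-noise fields are drawn with Pearson correlation
   $\rho_P = 2\sin(\pi\rho_S/6)$ — the exact Gaussian-copula match for a
   target Spearman $\rho_S$;
2. all fields are smoothed with one shared Gaussian kernel (default FWHM
   4 mm). A shared linear filter applied to jointly stationary fields
   leaves their pointwise cross-correlation unchanged, so smoothing buys
   spatial realism without distorting the correlation targets;
3. each field is mapped through a strictly monotone probit transform onto a
   modality-plausible range (SUV 1–15, TBR 0.8–3, ADC 0.6–2.0 × 10⁻³
   mm²/s, $K^\mathrm{trans}$ 0.01–0.6 min⁻¹, $v_e$ 0.05–0.6, $v_p$
   0.01–0.1; the ranges also guarantee $v_e + v_p \le 1$ everywhere);
4. modality noise is added after the transform: additive Gaussian for
   post-reconstruction PET, Rician for MR magnitude maps.

The default target matrix places its strongest entries at the scale the
pipeline is meant to resolve (FDG/FMISO 0.56, FDG/perfusion 0.55, ADC/FDG
−0.39) with weak plausible couplings elsewhere, chosen once so the matched
Pearson matrix is positive definite; a non-PSD request is refused with the
offending pair named. The default GTV is an ellipsoid of ≈ 32 cm³ (the
cohort-median tumor scale the package emulates) on a 24³ grid of PET
voxels; the default noise magnitudes (e.g. Gaussian SD 1 kBq/mL on FDG,
Rician σ 0.03 × 10⁻³ mm²/s on ADC) are plausible post-reconstruction
values exposed in configuration — they are not claims about any particular
scanner.

DCE series are simulated from the Tofts truth maps at 2.9 s resolution
(89 frames over 258 s) with a flat pre-injection baseline; carotid voxels
are set to an essentially pure-plasma signal ($v_p = 0.95$) so the AIF can
be re-estimated from the phantom itself. Kinetic simulation is restricted
to the GTV and carotid ROIs, with other voxels at baseline — a phantom
economy, not an imaging feature. FMISO wash-in rises as
$P(1 - e^{-t/\tau})$ (τ = 60 s) so its 0–4 min mean is proportional to the
perfusion surrogate $P$ and inherits its rank order exactly.

**What the phantom does not emulate:** anatomy beyond ellipsoidal ROIs,
PET reconstruction physics (attenuation, scatter, partial volume),
registration error between modalities, and patient motion. Passing tests
therefore demonstrate the correctness of the *analysis* — integration,
fitting, sampling, statistics and bookkeeping — under controlled truth,
not the magnitude of acquisition-driven decorrelation in real data, which
is known to pull observed coefficients toward zero.

## Numerical choices

- **Resampling** uses separable B-spline interpolation (degree 0, 1 or 3).
  The cubic path prefilters with the standard recursive filter (pole
  $\sqrt3 - 2$) after extending each line by cubic Lagrange extrapolation,
  which keeps polynomial reproduction exact up to the field-of-view edge
  instead of degrading near boundaries as mirror padding would.
  Out-of-FOV targets become invalid voxels, never extrapolations; invalid
  source voxels are diffusion-inpainted before prefiltering (so the
  recursive filter is not perturbed by hole values) and every target voxel
  whose support touches a hole is flagged invalid.
- **Spearman** is computed as Pearson on average ranks (ties get mean
  rank); the suite cross-checks it against `stats::cor(method =
  "spearman")` and, for tie-free small samples, against the classical
  $1 - 6\sum d_i^2 / (n(n^2-1))$ formula.
- **Determinism**: a phantom is a pure function of its configuration and
  seed (bit-identical across runs); analysis stages are deterministic, so
  re-running a cohort reproduces identical result files, which the
  manifests verify by checksum.

## Problem sizes used in the validation suite

The acceptance checks run on a 5×5×5 grid of Tofts parameter triples
spanning the physical ranges, 512 T1 values spanning 200–3000 ms, 1000
random tie-containing rank vectors, 3-patient noiseless and 20-seed noisy
phantom cohorts at the default 32 cm³ GTV (≈ 2100 GTV voxels, ≈ 45
sub-regions each), and a 9-sub-region phantom for the exclusion rule.
These sizes were chosen as the smallest that exercise every code path at
cohort scale while keeping the whole suite comfortably re-runnable on a
laptop.

## Known limitations

- The AIF family is a single parametric shape; population forms with a
  distinct recirculation peak are not modelled (the carotid fit would not
  constrain their extra parameters at 2.9 s resolution).
- The two-compartment exchange model and other alternatives to the
  extended Tofts model are out of scope, as are B1 and water-exchange
  corrections to the T1 path.
- Deformable registration is out of scope: all inputs are assumed
  co-registered, and only axis-aligned grids are supported (oblique
  affines are rejected at read time).
- Significance testing and confidence intervals for the coefficients are
  deliberately absent; the cohort summaries report medians, ranges and
  patient counts only.
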