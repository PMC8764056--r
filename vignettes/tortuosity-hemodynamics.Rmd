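---
title: "Vessel tortuosity metrics and low-TAWSS area coverage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel tortuosity metrics and low-TAWSS area coverage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tortuometry)
library(dplyr)
```

## The problem

Coronary tortuosity — how strongly a vessel twists away from a straight
course — has been linked to regions of low wall shear stress on the lumen,
which in turn are associated with endothelial dysfunction and disease risk.
But "tortuosity" is measured in several incompatible ways, and the choice of
measure changes the conclusions. `tortuometry` implements the standard
3D tortuosity measures on vessel centerlines, the surface statistic they are
correlated against (the normalized wall area exposed to low time-averaged
wall shear stress, TAWSS), and the cohort-level statistics that compare the
measures — plus a synthetic-cohort generator so the entire analysis runs
without any patient data.

## Tortuosity measures

A centerline is an ordered 3D polyline $r(s)$ in mm, parameterized by arc
length $s$. With vessel length $L$ (arc length), chord $C$ (distance between
endpoints) and curvature $\kappa(s)$ (reciprocal of the osculating-circle
radius), the six measures are

| measure | definition | units |
|---|---|---|
| tortuosity index $\tau$ | $L / C$ | — |
| total absolute-curvature $\kappa_{ta}$ | $\int \kappa \, ds$ | rad |
| total squared-curvature $\kappa_{tr}$ | $\int \kappa^2 \, ds$ | mm$^{-1}$ |
| average absolute-curvature $\kappa_a$ | $\int \kappa \, ds / L$ | mm$^{-1}$ |
| RMS-curvature $\kappa_r$ | $\sqrt{\int \kappa^2 \, ds / L}$ | mm$^{-1}$ |
| average squared-derivative-curvature $\kappa_d$ | $\int (d\kappa/ds)^2 ds / L$ | mm$^{-4}$ |

The parameter of the defining integrals is taken as arc length: uniformly
resampled centerlines are an arc-length parameterization, and curvature
defined as a reciprocal radius is parameterization-free.

The two *total* measures grow with vessel length, which is why cohort
correlation uses the four per-length measures ($\tau$, $\kappa_a$,
$\kappa_r$, $\kappa_d$). Both totals are nevertheless implemented, because
they anchor the exact transformation laws under uniform coordinate scaling
by $\lambda$ (tested at $\lambda \in \{0.5, 2, 10\}$):

* $\tau$ and $\kappa_{ta}$ are invariant ($\kappa_{ta}$ is a total turning
  angle — note that it *is* scale invariant, though not length-independent:
  appending a straight segment leaves it unchanged while it dilutes
  $\kappa_a$ and $\kappa_r$);
* $\kappa_a$, $\kappa_r$, $\kappa_{tr}$ scale as $1/\lambda$;
* $\kappa_d$ scales as $1/\lambda^4$.

$\tau$ and the curvature measures can rank vessels in opposite order: a
low-amplitude, short-wavelength wiggle bends constantly (large $\kappa_a$)
but barely leaves its chord (small $\tau$), while a single sweeping bend
does the opposite. `make_discordant_pair()` constructs exactly such a pair
and asserts both orderings; this discordance is the core reason the choice
of measure matters.

## Numerical pipeline

**Resampling.** Centerlines are resampled at uniform arc-length spacing
(default 0.01 mm) with a cubic spline through the input points,
chord-length parameterized — linear interpolation would make the second
derivative, and hence curvature, degenerate. The spline is evaluated on a
dense parameter grid, its polyline arc length measured, and the monotone
$s(t)$ map inverted, so output samples sit on (near-)exact arc steps. Both
endpoints are always retained, because $L$ and $C$ are defined by the true
vessel ends; the final interval may therefore be shorter than the spacing.

**Curvature.** $\kappa = |r' \times r''| / |r'|^3$ with second-order central
differences on the uniform grid, one-sided second-order stencils at the
endpoints, and exact non-uniform (Vandermonde-solved) stencils across the
short final interval. Values below $10^{-12}$ mm$^{-1}$ are clamped to 0.
Integrals are trapezoidal over the profile's own arc grid, so the short
final interval contributes its true length (a full circle integrates to
$2\pi$ within $10^{-3}$ for any radius). $d\kappa/ds$ uses the same
differencing on the $\kappa$ samples.

**Spacing tolerance.** Jittered-but-nominally-uniform grids (e.g. after
adding segmentation-style noise to a resampled centerline) are accepted and
treated as uniform at the mean spacing — this is deliberately the behaviour
a practitioner gets from index-based differencing, and it is what makes the
noise-amplification demonstration (`add_noise()` inflating $\kappa_a$)
meaningful. Structurally irregular polylines (block-mean spacing deviating
by more than 50%) are refused with a precondition error.

**Smoothing.** `smooth_centerline()` is an opt-in Gaussian kernel over arc
length (default off: upstream toolchains rarely report their smoothing
parameters, so none are assumed). Coordinates are detrended by the endpoint
secant over the index grid, the residual is convolved with a normalized
Gaussian (width `sigma`, truncated at $4\sigma$) using odd reflection at
the boundaries, and the trend is restored. Straight lines and
`sigma = 0` are exact identities; endpoints are fixed; the boundary
handling is unbiased for locally linear residuals.

**Branch truncation.** Branches are analysed over a fixed 10 mm of arc
length from the bifurcation (row 1 of the centerline is the
bifurcation-proximal end); shorter branches are returned whole and flagged.
The cut is snapped to the nearest existing sample rather than interpolated:
an interpolated cut point lies on a chord, off the interpolating curve by
the sagitta (~ $\kappa h^2/8$), and the $1/h^2$ finite-difference stencils amplify that
into an O(1) curvature spike at the new endpoint — ruinous for $\kappa_d$. Snapping
costs at most half a spacing step of length (at most 0.005 mm at the default
spacing, i.e. 0.05% of a 10 mm branch).

## The low-TAWSS area statistic

Given a triangulated lumen surface with a TAWSS scalar (Pa), the statistic
is the fraction of wall area with TAWSS strictly below a threshold
(default 0.4 Pa, the conventional cutoff for non-physiologically low
shear):

$$ f = \frac{\sum_{\text{masked},\ \text{TAWSS} < 0.4} A_i}
           {\sum_{\text{masked}} A_i} $$

Vertex fields are averaged onto triangles (the mean of the three vertex
values) rather than clipped along isocontours: the rule is assumption-free
and stable under mesh refinement (uniform 1-to-4 subdivision changes the
fraction by $<10^{-6}$ on piecewise-constant fields). Boundary-equal values
count as *not* low (strict `<`). The region mask excludes the artificial
flow extensions added for CFD from both numerator and denominator; because
upstream pipelines differ in whether TAWSS lives on nodes or elements and
in where the extension boundary sits, both choices are externalized (array
attribution is auto-detected; the mask is an integer cell array, absent
mask = everything included, with a warning).

## Cohort statistics

Distribution shape uses standardized metrics (sample SD), bias-corrected
(adjusted Fisher–Pearson) skewness and excess kurtosis (normal = 0),
computed via `e1071` (type 2). The correlation analysis regresses the
low-TAWSS area fraction on each primary metric, per segment (LMCA, LAD,
LCx, and the complete bifurcation), via ordinary least squares (`stats::lm`
under the package's `ols_fit()` surface), reporting

* $R^2$ and adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-k-1)$ (negative for models
  worse than the mean-only fit),
* the overall F-test p-value (equal to the slope's two-sided t-test for one
  predictor),
* significance stars: `*` for $p \le 0.05$, `**` for $p \le 0.01$, `***`
  for $p \le 0.001$ (boundaries inclusive).

Simple (single-predictor) regressions are the primary path — one
$R^2$ per metric per segment — with multi-predictor designs available
through the same `ols_fit()`; the adjusted-$R^2$ penalty handles $k \ge 1$
uniformly. No multiple-testing correction is applied across the 16 models,
matching standard practice in this literature.

**Whole-bifurcation aggregation.** How branch-level metrics combine into a
"complete bifurcation" value is genuinely open; the package uses the
length-weighted mean of the branch metrics per case (configurable by
supplying a `whole_fraction` column for the surface side, e.g. measured on
the full mesh). With equal 10 mm branches this reduces to the plain mean.

## The synthetic cohort generator

The generator replaces an unavailable patient cohort; its defaults *are*
the study conditions and are not tuned per run.

* **Geometry.** Per case, three branches (LMCA, LAD, LCx) are built as a
  straight axis plus 2–4 random low-frequency sinusoidal displacement modes
  in the two transverse directions, truncated to 10 mm and resampled at
  0.01 mm. The overall displacement amplitude is calibrated per branch
  (bracketing + regula falsi on a coarse grid, where $\kappa_a$ is already
  grid-converged) so the cohort's $\kappa_a$ distribution matches the
  configured targets: mean ± SD of 0.40 ± 0.11 (LMCA), 0.51 ± 0.10 (LAD),
  0.50 ± 0.08 (LCx) mm$^{-1}$ at n = 127 — the magnitudes reported for left
  main bifurcation cohorts. $\kappa_a(\alpha)$ rises with amplitude
  $\alpha$, peaks, and decays (large loops have gentle curvature), so the
  solver works on the rising flank and redraws modes an octave higher if a
  target exceeds the attainable peak. Metrics are then computed through the
  real resampling/curvature pipeline, never from the construction.
* **Hemodynamic surrogate.** The low-TAWSS fraction is drawn as
  $f = \mathrm{clip}(\beta_0 + \beta_1 \kappa_a + \varepsilon,\ 0,\ 1)$,
  $\varepsilon \sim N(0, \sigma^2)$ — exactly the linear structure the
  regression analysis assumes, which makes parameter recovery a meaningful
  end-to-end check. Defaults $\beta_0 = 0.15$, $\beta_1 = 0.5$,
  $\sigma = 0.11$ give a planned
  $R^2 = \beta_1^2 \mathrm{Var}(\kappa_a) / (\beta_1^2
  \mathrm{Var}(\kappa_a) + \sigma^2) \approx 0.20$ at the LMCA curvature
  spread, the magnitude reported for the best-performing metric in left
  main cohorts; the implied clipping rate is $\approx$ 0.2% and is counted
  (kept < 1%).
* **Surfaces.** Each branch optionally gets a swept circular tube
  (radius 0.75 mm, 12-gon rings every 0.25 mm, parallel-transported frames)
  whose two-level TAWSS field is banded along the axis so that
  `low_tawss_area_fraction()` reproduces the drawn fraction within 0.01;
  flow-extension rings are appended with `region_mask = FALSE` and
  uniformly low TAWSS, so forgetting the mask visibly corrupts the
  statistic.
* **Determinism.** One seed drives every draw; identical configs give
  bit-identical cohort tables.

What the generator does *not* emulate: real CFD physics (no Navier–Stokes;
the TAWSS surrogate only reproduces the statistical coupling the analysis
tests), vessel caliber variation and its interdependent effect on shear,
branch interaction at the bifurcation, non-Gaussian measurement error, and
the empirical right-skew of the tortuosity-index distribution. Passing
tests therefore validate the measurement and inference machinery — not any
claim about real coronary hemodynamics.

## Problem sizes used in the test suite

The statistical acceptance checks run 500 synthetic cohorts of n = 127
cases (LMCA targets) for slope-recovery coverage and mean adjusted $R^2$;
the analytic-oracle checks use 0.01 mm spacing throughout. The
null-surrogate check uses 25 cohorts of n = 40. These sizes put the
Monte-Carlo error of the checked quantities well inside their tolerances
(coverage SE $\approx$ 1% at 500 replicates).

## Known limitations

* Curvature by finite differences amplifies coordinate noise as $h^{-2}$;
  for noisy inputs, smooth first (the noise/smoothing demonstration in the
  test suite quantifies this) and treat unsmoothed $\kappa_d$ with
  suspicion.
* $\tau$ diverges as a vessel closes on itself; chords below 1% of length
  produce a warning, exact closure an error.
* The `.vtp` reader handles ascii-encoded PolyData only (no appended or
  binary blocks); the legacy reader handles ASCII POLYDATA only.
* Units are mm and mm$^{-1}$ throughout; outputs are unit-tagged via
  `metric_units()` to prevent silent mm/cm confusion when comparing with
  published per-centimeter curvature values.
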