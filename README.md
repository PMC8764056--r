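# tortuometry

Vessel centerline tortuosity metrics and low wall-shear-stress area
analysis for R.

Severely tortuous coronary arteries are suspected of creating regions of
non-physiologically low wall shear stress, but published studies quantify
"tortuosity" with incompatible measures and reach contradictory
conclusions. `tortuometry` is for vascular-morphometry and computational
hemodynamics researchers who need those measures computed consistently and
compared on a common footing:

* **Six 3D tortuosity measures** from a centerline r(s) (mm), parameterized
  by arc length, with vessel length L, chord C and curvature
  κ(s) = |r′ × r″| / |r′|³:
  tortuosity index τ = L/C; total absolute-curvature ∫κ ds (the turning
  angle); total squared-curvature ∫κ² ds; average absolute-curvature
  κ_a = ∫κ ds / L; RMS-curvature κ_r = √(∫κ² ds / L); and average
  squared-derivative-curvature κ_d = ∫(dκ/ds)² ds / L.
* **The low-TAWSS area statistic**: the fraction of triangulated lumen wall
  area with time-averaged wall shear stress strictly below a threshold
  (default 0.4 Pa), restricted to the bifurcation region via a mask that
  excludes CFD flow extensions.
* **Cohort statistics**: standardized metric distributions with
  bias-corrected skewness and excess kurtosis, and per-metric / per-segment
  linear regression of the low-TAWSS fraction with adjusted R², overall
  p-values and significance stars (\*, \*\*, \*\*\* at p ≤ 0.05, 0.01,
  0.001).
* **A synthetic cohort generator** (analytic curves with closed-form
  curvature, calibrated random branch geometries, tubular surface meshes
  with banded TAWSS fields, and a linear hemodynamic surrogate) so that the
  entire pipeline runs and is testable with no patient data.

Everything is tidyverse-shaped: data-frame-first functions returning
tibbles, `tidy()`/`glance()` on fitted models, ggplot2 `plot_*()` and
`autoplot()` for every result type. I/O covers centerline CSV, VTK legacy
ASCII and XML `.vtp` PolyData for both polylines and TAWSS-carrying
surfaces. A thin CLI (`inst/cli/tortuometry.R`) exposes the `metrics`,
`tawss-area`, `cohort`, `synth` and `report` subcommands.

## Worked example

Metrics for a helix (a = 2, b = 1, two turns), whose closed-form curvature
is a/(a² + b²) = 0.4 mm⁻¹:

```r
library(tortuometry)
helix <- make_analytic_curve("helix", a = 2, b = 1, turns = 2)
compute_tortuosity(helix, resample = FALSE)
#> # A tibble: 1 x 11
#>   branch   tau kappa_ta kappa_tr kappa_a kappa_r  kappa_d     L     C spacing sigma
#>   <chr>  <dbl>    <dbl>    <dbl>   <dbl>   <dbl>    <dbl> <dbl> <dbl>   <dbl> <dbl>
#> 1 helix   2.24     11.2     4.50   0.400   0.400 4.75e-10  28.1  12.6    0.01     0
```

κ_a and κ_r equal the closed form exactly to three digits; κ_d is zero
because the helix has constant curvature; τ = L/C = 2.24 reflects the
helix's stretched-out path.

A full synthetic cohort — 127 cases, three branches each, metrics computed
through the real pipeline and low-TAWSS fractions drawn from the linear
surrogate — analysed exactly like a patient cohort:

```r
g <- generate_cohort(cohort_config(n_cases = 127, seed = 1), surfaces = FALSE)
rep <- cohort_report(g$cohort)
cat(rep$report, sep = "\n")
#> adjusted R2 (p-value) of low-TAWSS area fraction ~ metric
#> metric     LMCA                   LAD                    LCx                    bifurcation
#> tau         0.016 (0.085)          0.051 (0.006)**       -0.007 (0.800)          0.003 (0.240)
#> kappa_a     0.171 (<0.001)***      0.192 (<0.001)***      0.094 (<0.001)***      0.167 (<0.001)***
#> kappa_r     0.146 (<0.001)***      0.197 (<0.001)***      0.061 (0.003)**        0.146 (<0.001)***
#> kappa_d     0.032 (0.025)*         0.120 (<0.001)***      0.010 (0.139)          0.047 (0.008)**
```

The average absolute-curvature explains the most low-TAWSS variance and
the tortuosity index essentially none — by construction here, since the
surrogate couples the fraction to κ_a; the point of the synthetic cohort is
that the machinery (calibrated geometry, surface statistic, regression
grid) recovers the planted structure. Distribution shape comes out of the
same report (`rep$shape`): the tortuosity index is strongly right-skewed
and heavy-tailed (LMCA kurtosis 12.4, skew 2.93 in this cohort) while the
curvature measures sit much closer to normal.

`autoplot(rep$analysis)` draws the adjusted-R² grid;
`plot_metric_distributions(g$cohort)` overlays the standardized densities.

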