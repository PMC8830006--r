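# pmwmorph

Morphometric analysis of cerebral arterial bifurcations against the
principle of minimum work (PMW), with the full case-control statistical
layer used to ask whether bifurcation geometry predicts intracranial
aneurysm presence.

Intracranial aneurysms form preferentially at arterial bifurcations, where
wall shear stress is highest. The PMW predicts the energetically optimal
bifurcation geometry: radii obeying the cube law and branch angles fixed by
the radii. `pmwmorph` measures how far real (or simulated) bifurcations sit
from that optimum and tests whether the deviation discriminates aneurysmal
from non-aneurysmal bifurcations. It is aimed at researchers in vascular
morphometry and neurovascular epidemiology who have per-bifurcation
landmark or radius/angle tables (e.g. exported from CTA-based 3D models)
and want a reproducible, validated analysis chain.

## The model

For a bifurcation with parent radius $r_0$ and branch radii $r_1 \ge r_2$
(mm, from best-fit diameters $r = d/2$):

- asymmetry ratio $r_2^2/r_1^2$, area ratio $(r_1^2+r_2^2)/r_0^2$;
- junction exponent $n$ solving $r_0^n = r_1^n + r_2^n$ (PMW optimum:
  $n = 3$), found by bracketed root-finding;
- predicted optimal branch angles from the law-of-cosines relations
  $\cos\phi_1 = (r_0^4+r_1^4-r_2^4)/(2r_0^2r_1^2)$,
  $\cos\phi_2 = (r_0^4+r_2^4-r_1^4)/(2r_0^2r_2^2)$,
  $\cos(\phi_1+\phi_2) = (r_0^4-r_1^4-r_2^4)/(2r_1^2r_2^2)$,
  defined exactly when the squared radii satisfy the triangle inequality
  (out-of-domain triples are flagged, not silently clamped);
- deviations $(\phi_1+\phi_2)-\alpha$, $\phi_1-\Phi_1$, $\phi_2-\Phi_2$
  between predicted and observed angles, where $\alpha$ is the total
  bifurcation angle and $\Phi_1 = 180-\beta$, $\Phi_2 = 180-\gamma$ are the
  observed branch angles relative to the extended parent axis, all measured
  in 3D at the centreline-intersection apex.

The statistical layer reproduces the standard case-control workflow:
Shapiro–Wilk-gated ANOVA/Tukey-Kramer or Kruskal–Wallis/Dunn group
comparisons, univariate and stepwise multivariate logistic regression with
tertile-coded predictors, and ROC analysis with Youden-index cut-offs. A
seeded synthetic-cohort generator (three groups, five bifurcation sites,
truncated-normal radii/angles with enforced ordering $r_0 > r_1 \ge r_2$ and
a configurable aneurysm effect) makes every stage testable without imaging
data.

## Worked example

```r
library(pmwmorph)

# PMW indices for a measured basilar-tip radius triple (mm)
pmw_indices(r0 = 1.76, r1 = 1.31, r2 = 1.01)
#> # A tibble: 1 × 9
#>   asymmetry_ratio area_ratio junction_exponent exponent_reason phi1_opt_deg
#>             <dbl>      <dbl>             <dbl> <chr>                  <dbl>
#> 1           0.594      0.883              1.69 <NA>                      NA
#>   phi2_opt_deg total_opt_deg clamped domain_status
#>          <dbl>         <dbl> <lgl>   <chr>
#> 1           NA            NA FALSE   angles_undefined

# seeded two-arm synthetic cohort: +25 deg on alpha, +0.15 mm on r0 at
# the aneurysmal site, 120 records per arm
cfg <- two_arm_config(seed = 42, n_per_arm = 120,
                      alpha_shift = 25, r0_shift = 0.15)
m <- generate_cohort(cfg)$records

compare_groups(m, "alpha_deg")$omnibus_p
#> [1] 6.22893e-16

univariate_logistic(m, "alpha_deg", coding = "tertile")
#> Logistic regression: aneurysm ~ alpha_deg (tertile coding), LRT p = 1.475e-12
#> # A tibble: 2 × 6
#>   term            or ci_low ci_high        p separation
#>   <chr>        <dbl>  <dbl>   <dbl>    <dbl> <lgl>
#> 1 alpha_deg T2  4.65   2.30    9.38 1.80e- 5 FALSE
#> 2 alpha_deg T3 12.8    6.06   27.2  2.84e-11 FALSE

roc_analysis(m, "alpha_deg")
#> ROC for 'alpha_deg': AUC = 0.785; Youden cut-off = 106.7 (sens 0.79, spec 0.70)
```

The junction exponent 1.69 for the basilar triple sits far below the
optimum of 3 (circle-of-Willis bifurcations typically do), and its squared
radii violate the triangle inequality, so the predicted optimal angles are
flagged `angles_undefined` rather than silently forced into range (pass
`clamp = TRUE` for boundary-clamped angles). The cohort run shows an
injected angle effect being recovered: a highly significant group
difference in the total angle, a rising tertile odds-ratio gradient whose
third-tertile CI excludes 1, and a total-angle AUC well above chance.

Full-cohort simulation and the end-to-end pipeline:

```r
cfg <- cohort_config(seed = 20260101)   # Table-calibrated 3-group cohort
run_full_pipeline(cfg, "out/")          # reports + morphometry.csv + manifest
```

A thin CLI wraps the same functions
(`inst/cli/pmwmorph.R simulate|measure|analyze|full`, see `--version`).

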