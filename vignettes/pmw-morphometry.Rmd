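---
title: "Minimum-work morphometry of arterial bifurcations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-work morphometry of arterial bifurcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(pmwmorph)
```

## The scientific problem

Intracranial aneurysms arise preferentially at arterial bifurcations, where
the wall experiences the largest haemodynamic shear. The principle of minimum
work (PMW) predicts the geometry that minimises the energetic cost of
maintaining flow through a bifurcation: the radii of the parent vessel
($r_0$) and the two daughter branches ($r_1 \ge r_2$) should satisfy the cube
law $r_0^3 = r_1^3 + r_2^3$, and the branches should leave the parent axis at
angles fixed by law-of-cosines relations in the squared radii. Departures
from that optimum — a junction exponent below 3, a total bifurcation angle
far wider than predicted — are candidate morphometric risk factors for
aneurysm formation, and case-control studies test exactly that.

`pmwmorph` implements the full analysis chain of such a study:

1. **geometry** — observed angles and radii from exported 3D landmarks;
2. **minimum-work indices** — asymmetry/area ratios, junction exponent,
   predicted optimal angles, observed-minus-predicted deviations;
3. **cohort statistics** — normality-gated group comparisons, tertile-coded
   logistic regression, ROC with Youden cut-offs;
4. **synthetic cohorts** — a seeded generator reproducing the three-group,
   five-site case-control structure, so the pipeline is testable without
   imaging data.

## Geometry: what is measured

A bifurcation is reduced to four 3D points (mm): the centreline intersection
`O` (the apex of every angle) and the points of largest centreline curvature
on the parent (`A`), larger branch (`B`) and smaller branch (`C`), each at
least 5 mm from the apex (violations warn, because landmark extraction
happens upstream of this package). The measured angles are

- $\alpha$ — total bifurcation angle, between the two branch arms at `O`;
- $\beta, \gamma$ — between the parent arm and the larger/smaller branch;
- $\Phi_1 = 180 - \beta$, $\Phi_2 = 180 - \gamma$ — the branch angles
  relative to the *extended* parent axis.

Angles are true 3D angles at the apex (not planar projections): the upstream
CAD construction measures between centreline arms in space, and a planar
projection would need an arbitrary plane choice. All angles are reported in
degrees. Branch labelling is by diameter (`d1 >= d2`); violations are fixed
by swapping with a recorded flag, never silently.

```{r}
lm <- generate_landmarks(alpha_deg = 105, phi1_deg = 60, phi2_deg = 45)
compute_observed_angles(lm)
```

## Minimum-work indices

For a radius triple the package computes the asymmetry ratio $r_2^2/r_1^2$,
the area ratio $(r_1^2+r_2^2)/r_0^2$, the junction exponent $n$ solving
$r_0^n = r_1^n + r_2^n$, and the predicted optimal angles
$\phi_1, \phi_2, \phi_1+\phi_2$ from

$$\cos\phi_1 = \frac{r_0^4 + r_1^4 - r_2^4}{2 r_0^2 r_1^2}, \quad
  \cos\phi_2 = \frac{r_0^4 + r_2^4 - r_1^4}{2 r_0^2 r_2^2}, \quad
  \cos(\phi_1{+}\phi_2) = \frac{r_0^4 - r_1^4 - r_2^4}{2 r_1^2 r_2^2}.$$

Deviation metrics are signed predicted-minus-observed differences:
$(\phi_1+\phi_2)-\alpha$, $\phi_1-\Phi_1$, $\phi_2-\Phi_2$.

```{r}
pmw_indices(r0 = 1.76, r1 = 1.31, r2 = 1.01)
```

### Numerical choices

- **Junction exponent.** $f(n) = (r_1/r_0)^n + (r_2/r_0)^n - 1$ is strictly
  decreasing with $f(0) = 1$, so whenever $r_0 > r_1$ strictly there is a
  unique positive root; it is found by bracketed root-finding on
  $[0.05, 50]$ with up to three ten-fold bracket expansions (near-equal
  parent and branch radii push the root into the thousands) and a relative
  residual tolerance of $10^{-9}$. When $r_0 \le r_1$ no positive root
  exists: the exponent is returned as `NA` with a machine-readable reason,
  never an error. Undefined values are first-class — excluded pairwise
  downstream and counted in every report.
- **Optimal-angle domain.** The three cosines are simultaneously in
  $[-1, 1]$ exactly when the *squared* radii satisfy the strict triangle
  inequality. Measured radii can violate this (e.g. a wide parent with
  narrow branches gives $\cos\phi_1 > 1$). The default is to flag the record
  `angles_undefined` and return `NA`; `clamp = TRUE` clamps the cosines to
  $\pm 1$ and marks the row `clamped`. Refusing to guess silently is
  deliberate: group-mean radii of real basilar-artery cohorts can be outside
  the domain even where finite mean predicted angles are reported, and the
  two modes make the analyst's choice explicit.
- **Cosine clamping tolerance.** Floating-point overshoot of at most
  $10^{-12}$ beyond $\pm 1$ is clamped (this makes exact boundary cases such
  as $r_0 = \sqrt{2}, r_1 = r_2 = 1$ evaluate to $0°$); larger overshoot in
  the landmark geometry is an error, since it indicates corrupt input rather
  than round-off.

## Cohort statistics

`compare_groups()` applies the Shapiro–Wilk test per group at 0.05; only if
*every* group passes is one-way ANOVA with Tukey–Kramer post-hoc used,
otherwise Kruskal–Wallis with Dunn's Bonferroni-adjusted multiple
comparisons. The per-group rule is a design choice (the gate itself is
standard; which groups must pass is rarely stated), as is Dunn–Bonferroni as
the nonparametric post-hoc. Post-hoc tables are attached only when the
omnibus test rejects at 0.05.

Tertile boundaries are the empirical 33.33rd/66.67th percentiles by linear
interpolation between order statistics (R's type-7 quantile); a value
exactly on a boundary joins the lower tertile. Logistic models are plain
single-level maximum-likelihood fits with Wald 95% CIs; bifurcations of one
patient are treated as independent records. (A mixed-effects variant with a
per-patient intercept is a reasonable extension, but which grouping the
original analyses used is ambiguous, so the package does not guess.)

`multivariate_logistic()` mirrors the two-stage selection of case-control
morphometry studies: a univariate entry gate (`entry_p = 0.1` by default),
a redundancy filter dropping the weaker of any candidate pair with
$|r| > 0.7$ (the threshold is configurable; "correlated" is rarely
quantified in print), then forward stepwise addition by likelihood-ratio
test with significance-to-add `add_p = 0.05` — the overall significance
level. Keeping the addition threshold at the 0.1 entry gate would admit a
pure-noise covariate in roughly one of ten cohorts, which is not what a
stepwise analysis at $p < 0.05$ means.

`roc_analysis()` builds the empirical ROC curve with higher values treated
as case-like; candidate cut-offs are midpoints between consecutive distinct
values, the reported cut-off maximises Youden's $J$ (ties broken by the
lowest cut-off), and the AUC is the trapezoidal area — identical, on every
input, to the tie-corrected Mann–Whitney pair-counting statistic, which the
test suite asserts against both an exhaustive pair-counting oracle and
`pROC`.

```{r}
cfg <- two_arm_config(seed = 42, n_per_arm = 120,
                      alpha_shift = 25, r0_shift = 0.15)
m <- generate_cohort(cfg)$records
compare_groups(m, "alpha_deg")$omnibus_p
univariate_logistic(m, "alpha_deg", coding = "tertile")
roc_analysis(m, "alpha_deg")
```

## The synthetic cohort generator

The generator emulates the *statistical* structure of a three-group CTA
case-control cohort — it does not synthesise images or vessels. Its default
calibration (`default_cohort_blocks()`) encodes, per (group, site) block,
the published group sizes and mean ± SD of each radius and angle for ICA,
MCA and BA bifurcations of MCA-aneurysm patients, BA-aneurysm patients and
controls. Design choices, fixed once:

- **Distributional form: truncated normal.** Cohort tables report mean ± SD
  and the original analyses gated on normality; the true generative law is
  unknowable from summary statistics.
- **Radius triple correlation $\rho = 0.5$ (exchangeable).** Parent and
  branch calibres co-vary anatomically; the value is an assumption, is
  configurable, and is recorded in the ground-truth sidecar.
- **Ordering $r_0 > r_1 \ge r_2$** enforced by resampling violating triples
  (capped at 1000 rounds, then an informative error — reachable only with
  pathological configurations such as a branch mean above the parent mean
  with tiny SDs).
- **Angles independent of radii** by default, truncated to $(1°, 179°)$;
  `pmw_coupled = TRUE` instead derives observed angles from the optimal
  angles of the drawn radii plus Gaussian noise, for cohorts that obey the
  optimality model by construction.
- **Aneurysm effect** as additive shifts of the $\alpha$ mean and the $r_0$
  mean at aneurysmal sites; zero by default because the calibrated tables
  already contain the empirical case-control differences.
- **Landmark mode** inverts the angle construction: a pose exists iff
  $|\Phi_1-\Phi_2| \le \alpha \le \min(\Phi_1+\Phi_2,\ 360-(\Phi_1+\Phi_2))$
  (the upper branch of the bound matters when $\Phi_1+\Phi_2 > 180°$); the
  dihedral angle between the branch half-planes is solved from the spherical
  law of cosines, and a random rigid pose is applied. Angle triples outside
  the feasible cone are resampled in landmark mode.

What passing tests on synthetic cohorts do **not** show about real data:
the generator draws sites independently within subject (no within-patient
correlation), has no measurement error model, and pools sites whose radii
scales differ — so pooled-cohort associations of site-scale variables (the
parent radius most of all) are dominated by site composition rather than by
the within-site aneurysm effect. Conclusions about real cohorts require real
measurements; the synthetic cohorts validate the *machinery*, i.e. that
known injected effects are recovered and that null cohorts stay null.

## Problem sizes used in validation

The test suite exercises the triangle identity on 10,000 random in-domain
triples ($<10^{-8}$° gap), the solver against an independent grid+bisection
oracle on 1,000 triples ($<10^{-6}$ agreement, residual $<10^{-9}$),
landmark round-trips on 1,000 random constructions ($<10^{-6}$°), ROC
against pair counting on 500 random samples (exact), and effect
recovery/null behaviour on seeded two-arm cohorts of 120 records per arm,
with the type-I rate of the group comparison estimated from 500 null
replicates of 30 records per arm.

## Known limitations

- Starts at exported landmarks/diameters; segmentation, centreline fitting
  and digital aneurysm removal are out of scope.
- Single-level logistic models only (see above).
- Energy-cost magnitudes and wall-shear-stress estimation are out of scope;
  the package quantifies geometric deviation from the optimum, not its
  haemodynamic consequence.
- The Youden cut-off assumes a positively oriented predictor; an AUC below
  0.5 signals an inverted predictor rather than being re-oriented
  automatically.
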