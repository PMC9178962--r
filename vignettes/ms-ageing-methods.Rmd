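---
title: "Methods: morphometric similarity networks and normative brain ageing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric similarity networks and normative brain ageing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical methods: the
models, their assumptions, the parameters that matter, the numerical
choices, and — because every result in this package is computed on
synthetic cohorts — exactly what the generator emulates and what passing
tests do and do not establish about real MRI data.

## Morphometric similarity networks

For one subject, the input is a 360-region × 7-feature table (grey-matter
volume, surface area, cortical thickness, mean curvature, Gaussian
curvature, folding index, intrinsic curvature index). Each feature column
is z-scored across regions *within the subject* (sample SD, denominator
n − 1). The morphometric similarity of two regions is the Pearson
correlation of their z-scored 7-feature profiles; the full 360 × 360 MS
matrix is symmetric with entries in [−1, 1].

Two conventions are fixed and recorded:

* **Z-scoring is within subject, across regions.** The alternative
  (across subjects per region) destroys the single-subject network
  interpretation; the within-subject convention follows the method's
  original formulation. A useful consequence is exact invariance of the MS
  matrix to any positive affine rescaling of a raw feature column (unit
  changes, calibration offsets), which the suite asserts.
* **Regional mean MS excludes the diagonal**: the mean of a region's 359
  similarities, i.e. weighted degree / (N − 1). Including the
  self-correlation of 1 would add ≈ 1/N to every value.

With only 7 feature points per correlation, single-pair similarities are
coarse (sampling SD ≈ 0.35 for a true correlation near zero). No smoothing
is applied; precision comes from averaging 359 similarities per region and
from cohort sizes.

## Normative trajectories

Per region, regional mean MS is regressed on age by ordinary least squares
for degrees 1–3. Internally the design uses centred age for conditioning;
coefficients and their standard errors are mapped back to the raw-age
scale, so a trajectory is always reported as `a0 + a1 t + a2 t²`.
Degree selection uses per-region nested F-tests (quadratic vs linear,
cubic vs quadratic) aggregated cohort-wide at a configurable α = 0.05: the
quadratic is adopted when it commonly beats the linear fit and the cubic
adds nothing, which is what the default synthetic cohort produces. The
exact aggregation rule is a documented stand-in — the decision it reaches
(degree 2) is the modelling assumption everything downstream relies on.

Screening is exactly `adjusted R² < 0`, with
`adj R² = 1 − (1 − R²)(n − 1)/(n − p − 1)`, p = degree. Under a true null
this excludes a region when R² falls below p/(n − 1); for n = 665 and
p = 2 that happens with probability ≈ 0.63, so roughly that share of the
generator's pure-noise regions is excluded per run — the suite checks the
empirical rate against this Beta-law value rather than against a memorised
count.

Retained regions are classified by the sign pair of the slope
`a1 + 2 a2 t` at the two reference ages (defaults 27 and 60, configurable):
(+,+) increasing, (−,−) decreasing, (+,−) convex (single peak), (−,+)
concave (single trough). A slope of exactly zero counts as positive — a
measure-zero tie-break that only matters for constructed inputs. "Convex"
and "concave" here are the field's labels for peak/trough shapes, not the
mathematical curvature sign.

## Deviations and the accelerated-ageing rule

A subject's deviation in a region is **observed − predicted** regional
mean MS at the subject's age. The opposite sign convention would read more
literally from the phrase "subtracting observed from predicted", but it
contradicts the direction rules that define accelerated ageing (negative
deviations on decreasing trajectories must mean "older-looking"); the
package adopts the internally consistent convention and stamps it into
every output file.

Age categories are [20,30), [30,35), [35,40), [40,45), [45,60] — half-open
with a closed top, resolving the overlap in the conventional labels.
Subjects outside the partition (e.g. age 18) are dropped with a warning
under the pipeline's `drop` policy; ages outside the normative fitting
range are additionally flagged `extrapolated` (the quadratic is evaluated
anyway — trajectories are smooth and the excursion is ≤ 2 years in the
default design).

Within each category, each region's deviations are tested against zero by
a one-sample t-test; p-values are FDR-corrected **across regions within
the category**. Benjamini–Hochberg is the default; a Storey-style q-value
(π₀ estimated at λ = 0.5, then BH scaled by π₀) is available because the
original analysis used a toolbox whose default is Storey's method. A
seeded sign-flip permutation p-value is optional — the exchangeability
assumption is symmetry of null deviations around zero.

The direction consistent with accelerated ageing uses one uniform rule:
over a category [lo, hi], if the trajectory slope is positive throughout,
the direction is +1; negative throughout, −1; if the turning point
`−a1/(2 a2)` lies inside the category, the direction is *indeterminate*
and the region is reported but not counted as consistent or inconsistent.
Because a quadratic's slope is linear in age, checking the slope sign at
the two category endpoints decides the whole interval, and the uniform
rule provably reproduces the four shape-specific cases (decreasing,
increasing, convex and concave with the turning point above or below the
category) whenever those cases are well defined; the suite verifies the
equivalence on 1000 random trajectory × category draws against an
independently coded case-by-case oracle. Returning "indeterminate" for a
turning point inside the category is a deliberate refusal to guess where
the underlying convention is silent.

## Case-control statistics and the PAL model

Regional group comparisons are two-sided two-sample t-tests, pooled
variance by default (Welch optional, recorded). Cohen's d uses the pooled
SD with the n₁ + n₂ − 2 denominator and no small-sample correction.
Permutation p-values shuffle group labels (seeded, default 5000, add-one
estimator). No covariates are adjusted by default — the cohorts the
pipeline emulates were matched on age and sex composition.

PAL total errors are modelled as `errors ~ group + age`; main-effect F
statistics come from the additive model's partial F (drop1), matching the
degrees of freedom convention of reporting main effects at n − 3. The
group × age interaction is tested separately by comparing the additive and
interaction fits. The per-category Cohen's d table uses the same pooled-SD
definition as above.

## Brain age

A lasso (`glmnet`, α = 1) predicts age from the 360 regional MS values;
the penalty is chosen by 5-fold cross-validated MSE with seeded fold
assignment (`lambda.min` by default, one-SE rule optional). The brain-age
**gap is predicted − calendar age**, so an older-looking brain scores
positive; the reverse convention is available by flag, and the choice is
stamped into outputs. Shrinkage makes raw predictions regress toward the
training mean age, so raw gaps correlate negatively with age on held-out
data; the package quantifies this correlation and offers a linear
correction (fit `predicted ~ age` on held-out normative data, invert the
line). The correction is off by default and reported whenever used; the
injection-recovery checks in the suite use it because the quantity being
recovered (a planted +5-year shift) is defined net of the age bias.

## PLS of brain and cognition

Both blocks are z-scored (age in years and error counts share no scale),
then a sequential-deflation PLS2 runs: the component's predictor weight
vector is the leading left singular vector of the current cross-covariance
X'Y, scores are the X projection, and both blocks are deflated by the
component's rank-one reconstruction. Scores are mutually orthogonal, so
the % outcome-block variance attributed to component k,
`|t_k|² |c_k|² / ‖Y‖²`, sums without overlap. Each component is
sign-aligned so its score correlates non-negatively with the first outcome
column (age), removing the algorithm's inherent sign ambiguity from all
reported loadings and correlations.

Component significance shuffles outcome **rows jointly** against predictor
rows — preserving the age–PAL coupling, so the null says "MS is unrelated
to this pair of outcomes", not "age and PAL are unrelated" — with the
add-one estimator over the per-component % variance explained. Subjects
missing PAL are dropped listwise before the blocks are formed (the design
emulated has 115 + 115 complete cases). The first component is
algorithm-agnostic (any PLS variant agrees up to sign), which is the
surface the oracle tests check; later components depend on the deflation
convention, which is why the convention is fixed and documented here.

## The synthetic generator

The generator is the package's study design; its defaults are the
conditions under which every empirical claim in the tests is made.

* **Trajectories.** 360 regions: 312 shaped (105 increasing /
  103 decreasing / 49 convex / 55 concave — the reported shape proportions
  scaled to the retained count) and 48 pure-noise regions that exercise
  the adjusted-R² exclusion. Slope magnitudes at the reference ages are
  drawn from U(0.0018, 0.0045) MS/year; **0.0018 MS/year is the documented
  detectability floor** — at n = 665 with the default noise the slope-sign
  classification resolves every shaped region, and the suite's guarantees
  are stated for regions at or above this floor. Baselines couple to
  shape: decreasing regions start high (0.20–0.45 at age 20), increasing
  regions start low (−0.25 to −0.05), so trajectories converge toward zero
  with age as observed in healthy cohorts — this coupling is also what
  makes case-control difference maps correlate with the hub map.
* **Noise.** Residual SD 0.03 MS per region plus a shared per-subject
  offset (SD 0.02) — real MS data shows subject-level offsets, and without
  them brain-age gaps would be implausibly tight.
* **Injection.** Patients' trajectory evaluation age is shifted by
  Δ = +10 years in all decreasing regions by default (configurable set and
  Δ), planting an unambiguous accelerated-ageing ground truth without
  claiming the true spatial pattern of any disorder.
* **PAL.** Total errors = 12 + 0.45·age + group step + N(0, 10²),
  truncated at zero and rounded; the per-category group steps
  (16/11/12/16/7 errors) are calibrated so realized per-category Cohen's d
  approximates 1.6/1.1/1.2/1.6/0.7. Two consequences are worth knowing:
  truncation at zero slightly attenuates the age effect (the intercept and
  slope were chosen to keep the realized age F near the emulated order of
  magnitude), and a step pattern that varies by category necessarily
  induces some group × age interaction — the generator matches the
  category-wise effect sizes at the cost of a perfectly additive model.
* **Feature-level mode.** Each region has a fixed unit-norm 7-feature
  template; a subject's regional profile mixes a shared per-subject factor
  (loading λ) with template-plus-noise (noise scaled 0.5 relative to the
  factor), and raw features are per-feature affine maps of the profile
  onto plausible scales (so within-subject z-scoring recovers the latent
  profiles exactly; per-region scale realism is a non-goal). The map from
  λ to realized regional mean MS is monotone but has no useful closed form
  — the within-subject z-scoring and profile centring force the average
  off-diagonal covariance toward zero, leaving a variance-structure
  effect — so it is estimated numerically once (isotonic fit over a λ
  grid, cached) and targets are mapped linearly onto λ ∈ [0.05, 0.95].
  One detail matters: the subject factor is standardized to exact zero
  mean and unit variance across its 7 entries, otherwise the factor's
  sample moments act as a per-subject gain that dominates binned-mean
  trajectories. Calibration, frozen at n = 600: monotone-trajectory
  regions above the floor track their targets in decade-binned means at
  r ≥ 0.9 (≥ 95% of regions); curved trajectories, whose binned
  signal amplitude is inherently smaller, are held to a median r ≥ 0.5;
  feature-derived and direct MS-level fits agree on shape classification
  for ≥ 90% of above-floor regions.
* **What is not emulated.** Scanner and site effects, sex-specific
  trajectories, realistic cortical geometry, spatial autocorrelation
  between neighbouring regions, non-uniform age densities (ages are
  uniform by default; the sampler is pluggable), and any claim about the
  true anatomical location of effects. Passing tests therefore establish
  that the estimators recover what they define — not that real cohorts
  satisfy the generator's assumptions.

## Numerical choices and problem sizes

Polynomial fits use a QR decomposition on the centred-age design; the
coefficient covariance is mapped to the raw scale analytically. FDR
methods: BH (default) and the Storey variant above. All permutation and
resampling procedures take explicit seeds; derived per-stage seeds make a
full pipeline run bit-for-bit reproducible, which the suite asserts by
byte-comparing two complete result bundles. The test suite runs the
trajectory-recovery and brain-age checks at the full design sizes
(n = 665 / 360 regions), the FDR-calibration study at 60 regions × 200
replicates, and the PLS null-calibration at 30 × 8 blocks × 200 replicates
with 199 permutations each — sizes chosen so each property is measured
with useful Monte-Carlo precision on a single CPU.

## Known limitations

The model-comparison aggregation rule and the permutation designs are
documented stand-ins where the emulated analysis left details
unspecified. Indeterminate directions (turning point inside a category)
are reported, never resolved by guesswork. The Storey π₀ estimate uses a
single λ rather than a smoother. The feature-level generator's curved
trajectories are resolvable by the quadratic refit but only coarsely by
decade-binned means, as recorded above. Brain-age bias correction is
linear only.
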