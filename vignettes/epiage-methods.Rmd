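---
title: "Models and methods behind epiage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epiage)
```

This vignette is the package's own account of the statistical machinery it
implements: the methylation-calling and QC rules, the linear CpG age
clocks, the age-acceleration construct, the group-comparison statistics,
and the cohort simulator that makes all of it testable. It also records
the numerical choices and the decisions taken where the design was
genuinely open.

## The measurement model

Targeted bisulfite amplicon sequencing reads out, at each CpG of the
panel, three paired-read counts: `C` (methylated cytosine, protected from
conversion), `T` (unmethylated cytosine, converted), and `other`
(anything else — a sequencing or PCR artifact). The methylation level is

```
meth_pct = 100 * C / (C + T)
```

with `other` reads excluded from the denominator: they carry no
methylation information and would only dilute the estimate. Two
consequences follow, and both are enforced as tested invariants: the call
is invariant to the `other` count, and to any common rescaling of the
counts at a site.

A site is reported as missing rather than zero when its `C + T` depth
falls below the calling threshold (default 1000 paired reads per CpG,
applied per site) — reason `"low_depth"` — or when it has no reads at all
(`"no_data"`). Degenerate inputs therefore become reasoned missingness,
never errors.

Three assay-quality summaries accompany calling:

- **Conversion efficiency**: at non-CpG cytosines every molecule should
  convert, so the mean percentage of `T` reads there, averaged over the
  eight amplicons, measures bisulfite completeness per sample. Complete
  conversion gives 100; the simulator's default non-conversion rate of
  0.004 yields cohort means of ~99.6%.
- **Misincorporation**: the read-weighted percentage of `other` reads at
  target CpGs, per site and overall (default simulated rate 0.001 →
  ~0.1%).
- **Normalized read depth**: amplicon balance, computed from one
  designated CpG per marker as that marker's mean depth divided by the
  grand mean of the eight representative sites. The ratios average 1
  under perfectly even allocation. This quantity is often reported but
  rarely defined; the definition used here is recorded in the QC report
  metadata so downstream readers are not left guessing.

## Matched pairs and pair-preserving QC

The cohort design is exposure/control pairs matched exactly on sex and on
integer age (a configurable tolerance exists but defaults to 0). The QC
stage excludes a sample when it is pre-flagged (e.g. a failed library) or
lacks a called value at any *required* site — by default the blood-model
CpGs of *ELOVL2* and *PDE4C*, the two amplicons most prone to depth
dropouts. In pair-preserving mode (the default) the matched partner is
excluded too, with reason `"matched_exclusion"`. This is what keeps the
two groups exchangeable after QC: group sizes stay equal and the age and
sex margins stay identical, which the test suite asserts on constructed
cohorts (e.g. 106 pairs with six flagged samples in six distinct pairs
reduce to exactly 100 analyzable pairs).

Matching is verified statistically with a two-sample Kolmogorov–Smirnov
test on ages and a 2×2 chi-square on sex counts. Integer ages always
produce ties, so the KS p-value is the asymptotic approximation; a
perfectly matched cohort gives D = 0 regardless. The chi-square uses no
continuity correction by default (a `correct` flag exists) because the
package's own cross-checks of printed two-group tables are consistent
with uncorrected statistics; the choice is exposed rather than asserted.

## Linear CpG age clocks

Age prediction is ordinary least squares of chronological age on
methylation percentages, all predictors entered simultaneously. Two site
subsets are packaged: `blood6` (the six blood-model CpGs, one per gene in
*ELOVL2*, *MIR29B2CHG*, *KLF14*, *FHL2*, *TRIM59*, *PDE4C*) and
`mir29_c1` (*MIR29B2CHG* C1 alone, the site most responsive to group
shifts). Coefficients are in years per percentage point.

A deliberate design rule: **the package never ships fixed published
coefficients.** Models are always fit on supplied training data —
synthetic by default, controls-only in the packaged pipeline, since an
age clock should be trained on unexposed individuals. The printed model
provenance says so (`"synthetic-trained, not published coefficients"`),
and the JSON serialization carries a provenance block.

Samples missing any model site are dropped from training and omitted
from prediction with a logged message — never a hard failure, because
pair-preserving co-exclusion is the QC module's job and happens before
modeling. Constant or collinear predictors error with the offending site
named.

Accuracy metrics are MAE (mean absolute error) and ME (mean signed
error, predicted minus chronological), per group, overall and within two
age categories split at 45 years on integer ages (stratum 1: ≤45;
stratum 2: ≥46). `MAE ≥ |ME|` always, with equality exactly when all
errors share a sign — a property-tested invariant.

## Epigenetic age acceleration

EAA is defined as the residual from regressing predicted age on
chronological age. Residuals are computed **once on the full analysis
cohort** (both groups pooled); the group association is then refit within
each requested stratum. Two open choices were settled as follows:

- *Calibration set.* Pooled calibration is the default because the
  construct is "acceleration relative to the cohort-wide age trend".
  With pooled calibration a pure group shift of δ splits into ±δ/2
  residual means at equal group sizes; a controls-only mode
  (`calibration = "controls"`) is offered for users who want the entire
  offset attributed to the exposed group. Both are tested against
  closed-form constructions.
- *Stratification.* Re-calibrating within each stratum would force the
  stratum residual means toward zero and erase exactly the signal the
  stratified analysis looks for; hence one calibration, stratified
  association.

The association model is OLS of EAA on group (exposed = 1), age in
years, and sex (male = 1). The reported effect size is the classical
standardized beta, `b · SD(x) / SD(y)`. On a noiseless +2-year group
shift with equal groups this equals 1 exactly (SD(group)/SD(EAA) = 1/2),
which the tests assert. A covariate that is constant within a stratum —
a single-sex subset, say — is dropped with a warning rather than
breaking the fit. Because age and sex are exactly balanced by the
matched design, the adjusted group estimate coincides with the raw
group gap in residuals; only the residual degrees of freedom differ
from a plain t-test.

## Group comparisons, including from summary statistics

The two-sample machinery is the pooled-variance Student t-test,
implemented from the summary statistics up:

```
Sp² = ((n₁−1)s₁² + (n₂−1)s₂²) / (n₁+n₂−2)
se  = √(Sp² (1/n₁ + 1/n₂))
t   = (m₁ − m₂) / se,  df = n₁ + n₂ − 2
```

`pooled_ttest_summary()` takes `n/mean/SD` directly — so printed rows of
published tables can be re-analyzed without the raw data — and
`ttest_samples()` computes the summaries and delegates, guaranteeing the
two entry points agree exactly. The pooled form is the default because
re-deriving standard errors from printed group summaries under it
reproduces such tables at three decimals; Welch's unequal-variance form
is a flag (`welch = TRUE`), and at equal n the pooled SE reduces to
`√(s₁²/n + s₂²/n)` anyway, making the two barely distinguishable in
balanced designs. Two-sided p-values throughout. When both groups are
constant the SE is zero; the comparison is flagged `degenerate` with
`NA` statistics instead of dividing by zero.

Per-CpG comparisons run one test per panel site (exposed minus control)
with *nominal* p-values feeding the significance flag — mirroring how
such screens are conventionally reported — while Bonferroni and
Benjamini–Hochberg columns are emitted alongside for reference. Per-CpG
age associations are univariate OLS slopes of methylation on age within
each group (equivalent to a Pearson correlation test), with confidence
intervals used by the parameter-recovery suite.

## The cohort simulator

`sim_config()` defines the study conditions the package emulates: a
matched autopsy-blood cohort of heavy alcohol abusers and controls.

| parameter | default | meaning |
|---|---|---|
| `n_pairs` | 100 | matched pairs (200 samples) |
| `age_range` | 30–60 | integer ages, uniform |
| `male_fraction` | 0.83 | pair-level sex probability |
| `b0_j`, `b1_j`, `σ_j` | per site | %-at-age-0, %-points/year, biological SD |
| `group_deltas` | −2.1/−2.8/−3.0 at *MIR29B2CHG* C1–C3, −1.7 at *FHL2* C7 | %-point shift in exposed group |
| `delta_age_interaction` | 0 | per-year scaling of deltas above age 45 |
| `total_depth_mean/sd` | 316,048 / 28,300 | per-sample paired reads, truncated normal |
| `marker_weights` | skewed | amplicon depth allocation |
| `non_conversion_rate` | 0.004 | unmethylated C reading as C |
| `misincorporation_rate` | 0.001 | reads that are neither C nor T |
| `non_cpg_positions` | 20 | conversion-control cytosines per amplicon |

Latent methylation is linear in age with additive Gaussian noise on the
percent scale, clipped to [0, 100]:

```
meth = clip(b0 + b1·age + δ·[exposed]·(1 + dai·max(0, age−45)) + e, 0, 100)
```

A truncated-normal-with-clipping model was chosen over a logit-normal
one because effects and SDs are specified on the percent scale, and
clipping is transparent and directly testable. Read counts are then
binomial: total sample depth is allocated to markers proportionally to
`marker_weights` and split evenly across each marker's CpGs (within-
amplicon variation is not modeled); at depth `d`, `other ~ Bin(d, η)` and
the remaining reads are C with probability `f + (1−f)·ε` — incomplete
conversion inflates apparent methylation — else T. Conversion controls
aggregate each amplicon's non-CpG cytosines with T probability `1−ε`.

**Calibration.** The six model-site slopes and noise SDs are set so that
a six-CpG model fit on synthetic controls reaches a training MAE near
3.2 years. On a 30–60 cohort the corresponding training R² is ~0.83–0.86,
not 0.98: with age variance of only ~80 years², a residual SD of ~4 years
*cannot* coexist with R² ≈ 0.98 — that combination requires a much wider
age range. The MAE target was kept and the R² allowed to follow; reported
R² should always be read against the age span that produced it.

The `marker_weights` default reproduces the characteristic amplicon
imbalance of this panel — *TRIM59* and *FHL2* overperform (normalized
depth > 1) and *PDE4C* receives the least depth per CpG — rather than any
absolute per-marker read count, since per-sample totals and per-marker
depths from different accounting units cannot be matched simultaneously.

`delta_age_interaction` defaults to 0 (a duration-of-exposure effect is a
hypothesis, not an estimated quantity). When the stratified-EAA pattern
is exercised in tests it is set to 0.2 per year above 45, chosen by a
power calculation so that the exposed-group effect is detectable in the
46–60 stratum (expected residual gap ≈ 2 years against an EAA SD of ≈ 4
at n = 90) while the 30–45 stratum stays mostly non-significant — the
qualitative pattern the stratified analysis exists to detect.

**What the simulator does not emulate:** read-level artifacts (PCR bias,
strand asymmetry), batch effects across sequencing runs, non-linear age
trajectories, correlated noise between CpGs of one amplicon, and
non-uniform age distributions. Passing tests therefore demonstrate that
the statistical machinery is correct under the stated generative model,
not that real cohorts satisfy that model.

## Numerical choices and degenerate inputs

- OLS is delegated to `stats::lm` everywhere; no hand-rolled linear
  algebra. Exact-fit constructions (used as oracles) suppress the
  "essentially perfect fit" warning, which is expected there.
- Depth allocation uses `round()`; per-sample totals match the drawn
  total only up to rounding, which is irrelevant at 3×10⁵ reads.
- The age-stratum boundary is ≤45 / ≥46 on integer ages, so the two
  strata partition every cohort.
- Missingness is always carried with a reason code; no silent `NA`s.
- Determinism: every stochastic entry point takes a seed; a fixed seed
  makes cohorts, reports and serialized outputs byte-identical, which
  the pipeline tests verify file-by-file.

## Problem sizes used by the test and acceptance suites

Chosen to balance statistical resolution against a single-CPU runtime of
a few minutes: type-I-error suites use 1000 null replicates (binomial SE
≈ 0.7 points around 5%); parameter recovery uses 50 seeded cohorts of
100 pairs with coverage pooled over sites × replicates (nominal 95%,
required ≥ 90%); the calibration check fits on 160 synthetic controls;
the stratified-EAA pattern check uses 20 seeded cohorts. The acceptance
script averages injected-shift recovery over 50 replicate cohorts to
report stable means.

## Known limitations

- The 36 non-published panel positions are placeholders flagged
  `synthetic = TRUE`; only the eight published coordinates are real
  (GRCh37). Nothing downstream depends on coordinates, only on
  (marker, label) identity.
- The packaged clocks are synthetic-trained; applying them to real data
  requires refitting on a real training set.
- Pooled-vs-controls EAA calibration changes group residual means by
  construction; users comparing against external analyses must match the
  calibration convention.
- The KS matching check is approximate under heavy age ties (always the
  case with integer ages).
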