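---
title: "Methods: construction and validation of the Vascular Health Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: construction and validation of the Vascular Health Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhindex)
library(dplyr)
```

## The index and its assumptions

The Vascular Health Index (VHI) condenses three tiers of microvascular
phenotype — resistance-vessel reactivity, arteriolar wall mechanics, and
microvascular network density — into a single age-normalized percentage.
Its assumptions are deliberately minimal:

1. **Separate beds.** Cerebral and peripheral (skeletal muscle) circulations
   differ structurally and functionally, so each gets its own index; the
   package never mixes beds in a score.
2. **Controls define ideal.** Healthy, untreated, male lean Zucker rats
   (LZR) matched on study, vascular bed, and age define the standard of
   health for each component. Every score is a percentage of that standard,
   so the index reads as *percent of ideal* and is comparable across ages.
3. **Equal weights.** The index is descriptive, not predictive. There is no
   empirical basis for ranking the relative importance of reactivity, wall
   mechanics, and network density, and fitting weights would turn the index
   into an outcome-regression — so all components are averaged unweighted.
4. **Directionality.** Dilator responses and microvessel density fall with
   disease and score as `measurement / standard * 100`. Wall stiffness
   (`beta`) rises with disease; its relative excess above the standard is
   counted as an equal deficit, `200 - measurement / standard * 100`.

Scores are **never clamped**. This is not cosmetic: at 20 weeks the cerebral
stiffness coefficient of obese animals reaches ~245% of the lean standard,
so its component score is about −45. Only with that negative value averaged
in unchanged does the 3-component cerebral index reach the low-30s; clamping
at zero would report ~50 instead.

```{r clamping}
component_score(5.4, 2.2, "increases_with_disease")
score_group_means(zucker_reference(), "3") |>
  filter(group == "OZR", bed == "cerebral", age_weeks == 20)
```

## Measurement-level models

### Logistic concentration-response fit

Agonist series (log10 molar concentration from −9 to −6) are fit with
`y = min + (max − min) / (1 + 10^(logEC50 − x))` by nonlinear least squares
(`minpack.lm::nlsLM`). Starting values are analytic — `min` from the
smallest response, `max` from the largest, `logEC50` from the concentration
nearest the half-range crossing — with up to 5 jittered restarts on
failure. `logEC50` is constrained to the observed concentration range ± 2
log units, which keeps near-flat series from driving the midpoint to
infinity; genuinely flat series raise a degenerate-data error instead of
returning an arbitrary fit. The component value is the fitted upper bound
`max` (um), the asymptotic dilation, not the largest observed response.
Unconverged fits withhold the component and leave a diagnostic row.

When upper bounds have already been computed elsewhere, a component table
can be assembled directly and passed to `score_cohort()` — the scoring layer
is agnostic about whether components came from `compute_components()` or
from the user.

The hypoxic dilator response is a single PO2 step, not a series, so it
passes through as a scalar; a negative value (hypoxic constriction) is
allowed with a warning rather than rejected, since the scoring formula
remains well-defined.

### Exponential stress-strain fit

From each passive pressure–diameter series the package computes, per
pressure step, wall thickness `WT = (OD − ID)/2`, circumferential stress
`sigma = P_IL · ID / (2 WT)` (pressure converted at 1 mmHg = 1.334 × 10^2
N/m^2), and strain `epsilon = (ID − ID5)/ID5` against the inner diameter at
the 5 mmHg anchor (the protocol's "0 mmHg" point, kept slightly positive so
the vessel is never under negative pressure). Choices worth making
explicit:

* **OLS on the log-linear form.** `ln sigma = ln sigma5 + beta · epsilon`
  is fit by ordinary least squares — the natural reading of an
  "ordinary least squares" fit of an exponential — and r^2 is computed on
  that log scale.
* **Strict acceptance rule.** Fits are accepted iff r^2 > 0.85 (strict
  inequality). Rejected vessels are excluded from the index with a logged
  diagnostic; they are not refit or down-weighted.
* **Per-step wall thickness.** WT is recomputed at every pressure from that
  step's OD and ID rather than frozen at the anchor; the defining formulas
  are per-observation.
* **Negative strains retained.** A diameter below ID5 at higher pressure is
  physically odd in a passive vessel but no exclusion rule exists for it, so
  such points stay in the fit.

```{r mechanics}
s <- make_pressure_series(3.1, sigma5 = 2e3, id5_um = 100)
stiffness_component(s$pressure_mmHg, s$inner_um, s$outer_um)$value
```

## Scoring modes

**Per-animal mode** (`score_cohort()`) is primary: each animal is scored
against the mean of its matched controls, and group summaries average the
per-animal indices. Standards match on (study, bed, age) by default; when
study identifiers are absent a pooled-across-studies fallback is available
(`mode = "pooled"`) and logged. A control cohort scored against standards
derived from itself averages exactly 100 per cell — a definitional identity
the test suite checks to 1e−9.

**Group-mean mode** (`score_group_means()`) scores published group means
directly. It is the only mode available when raw per-animal data are not
published, and it approximates per-animal scoring by replacing a mean of
ratios with a ratio of means; across the shipped reference summaries the
two agree to about one percentage point. The package ships those summaries
(`zucker_reference()`, `zucker_counts()`, `zucker_biomarkers()`) so the
published index trajectories can be recomputed from scratch.

**Aggregation** across ages (`aggregate_vhi()`) pools animals, i.e. is
n-weighted; with equal per-age n it coincides with the mean of the per-age
means, which is how the all-ages aggregate of the reference cerebral data
is reproduced (n = 8 at every age).

Ages are arbitrary positive integers throughout: the design contemplates a
15-week time point for which no data exist, so nothing is hard-coded to the
observed {7, 10, 13, 17, 20} grid. One animal may contribute to both
vascular beds under the same `animal_id`; bed is part of every measurement
row and every score.

## Validity analyses

**Criterion validity** (`criterion_validity()`): Pearson correlation of
per-animal VHI with plasma insulin or TNF-alpha, per group, pooling animals
across the whole age span (the criterion hypothesis concerns the disease
trajectory, not a single age). The p-value is the usual two-sided t
transform on n − 2 df. Expected pattern: strongly negative in obese
animals, minimal in lean controls.

**Discriminant validity** (`discriminant_validity()`): at each (age, bed,
variant), each non-control group is compared to LZR, and each treated group
additionally to untreated OZR, using a two-sided **Welch** t-test. The
underlying analyses never name their test; Welch is chosen as the robust
default for the unequal variances and group sizes typical of these designs,
and this is flagged as a departure risk — a different test could flip
borderline calls. No multiple-testing correction is applied by default,
mirroring the conventional per-age presentation; `adjust = "holm"` is
available. Zero-variance cells degrade gracefully (identical constant
groups give p = 1) rather than erroring.

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` emulate the *summary* distributions
of the reference data — group × age × bed cell means and SEs for all five
components and five plasma variables, at the published cell sizes — not any
real per-animal dataset:

* **Per-animal SD** is reconstructed as `se · sqrt(n_published)`, because
  only mean ± SE is published. The published n is used even when the
  simulated cell size differs.
* **Distributions** are Gaussian, truncated at zero for positive-only
  quantities (a no-op in practice at these means). No distributional
  information beyond mean ± SE exists, so normality is an assumption.
* **Severity coupling.** Each animal carries a latent standard-normal
  disease severity. With per-group coupling `c` (default 0.6 for OZR, 0.5
  captopril, 0.4 exercise, 0 for LZR — moderate values chosen once, since
  the real within-animal covariance between components is unreported), each
  measurement is `mean ± c·sd·severity + sqrt(1−c²)·sd·noise`: marginal
  means and SDs are preserved exactly while components and biomarkers
  become correlated through severity, giving criterion-validity tests a
  known ground truth. Lean controls are uncoupled, providing the null.
* **Raw series.** Dose-response series are generated from the logistic
  model (7 points on [−9, −6]; lower bound ~ N(8, 2) um, logEC50 ~
  N(−7.5, 0.2), additive noise 1 um by default) with the drawn dilation as
  `max`. Passive series embed the drawn `beta` exactly: the anchor wall
  thickness follows from `sigma5` (~ N(2000, 100) N/m^2) and `ID5`
  (~ N(100, 5) um) through the stress formula; away from the anchor the
  wall cross-sectional area is conserved (incompressible wall,
  `OD² − ID²` constant — any monotone WT(ID) law would serve, this one is
  standard and keeps geometry physical) and the inner diameter at each
  pressure solves the wall-model balance by root-finding to 1e−10 relative.
  Noiseless series round-trip: refitting recovers the drawn `max` to
  <0.1% and `beta` to <1e−4.
* **Determinism.** Identical spec + seed give byte-identical cohorts; the
  caller's RNG state is restored afterwards.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: within-animal covariance beyond the single
severity factor, non-Gaussian tails, measurement drift across laboratories
and years, vessel-level heterogeneity within animal, and constrictor
responses (excluded from the index by design). Parameter-recovery and
validity results on synthetic cohorts demonstrate that the *pipeline* is
correct and well-calibrated, not that the biological model is.

## Numerical choices and problem sizes

Percent scores are carried at full double precision and rounded only for
presentation. The logistic fit tolerances (recovery ≤0.1% noiseless) and
the stress-strain tolerance (≤1e−4 relative, limited by the root-finder)
are verified in the test suite. Monte-Carlo checks use 200 replicates for
estimator unbiasedness (sign test), 200 for criterion/discriminant power,
and 1000 for the type-I-error calibration of the Welch test against the
95% binomial interval around alpha = 0.05 — sizes chosen to make the
statistical assertions stable across seeds while keeping the default test
run fast. Simulated cohorts in tests use the published cell sizes
(typically 8–28 animals per cell across five ages).

## Known limitations

* Group-mean mode is an approximation (mean-of-ratios vs ratio-of-means);
  reproduction of published per-animal index values is tolerance-banded,
  not exact, because raw per-animal data and study-specific control
  assignments are not published.
* The choice of Welch's t-test and the absence of multiplicity correction
  are conventions, not derivations.
* The index makes no outcome predictions and contains no vasoconstrictor
  component; both exclusions are inherited from its design.
* Only male Zucker-rat biology is emulated by the default generator spec.
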