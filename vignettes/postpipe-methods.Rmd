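---
title: "Methods: the post-pipe score and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the post-pipe score and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postpipe)
```

## The diagnostic model

Post-pipeline headache is a secondary headache after flow-diverter (FD)
treatment of an unruptured intracranial aneurysm. The score that
operationalises it combines two clinician-supplied gate criteria with a
points system:

* **A** (required): a post-procedural headache persisting at least 3 months
  after implantation. The 3-month window exists to avoid misclassifying
  transient procedure-related pain.
* **D** (required): the headache is not better explained by another ICHD-3
  primary or secondary disorder.
* **B** (+9, diagnostic): the patient had no prior headache history. A truly
  new headache in a headache-naive patient needs no change calculus.
* **C1–C6**: for patients with a pre-existing headache disorder, points for
  changes between the 6-month pre-procedural pattern and the 3-month
  post-procedural one. Because individual attacks vary, all comparisons use
  the *average* pattern: mean NRS intensity, mean monthly headache days
  (MHD), typical attack duration, laterality relative to the treated
  aneurysm, associated symptoms, and a patient-reported global
  similarity rating.

The diagnosis is `A + D + (B or C-total) >= 9`. The threshold, every band
edge, and the contested point values live in a single `scoring_config()`
object so the ROC machinery can sweep cut-offs (8/9/10) without touching
scoring code.

Key modelling assumptions: worsening only — decreases in intensity,
frequency or duration never subtract points, because the instrument
detects a *secondary worsening*, not general change; and subjective
perception alone is never sufficient — a patient who reports worsening
but scores below threshold is classified `no_change`, treating
sub-threshold fluctuation as the natural variability of a primary
headache disorder.

## Outcome taxonomy

Five mutually exclusive categories: `never` (no headache before or
after), `new_onset` (naive patient, diagnosis met), `improvement`
(pre-existing headache reported improved — *regardless* of feature
changes), `worsening` (reported worse and diagnosis met), `no_change`
(reported unchanged, or reported worse below threshold). One case has no
bucket in this taxonomy: a headache-naive patient whose new headache
fails criterion A or D (a transient post-procedural headache). Guessing a
bucket would silently contaminate either `never` or `new_onset`, so
`classify_cohort()` raises an `unclassified_transient` error by default
and only keeps such records, as an explicit sixth level, when asked
(`transient = "flag"`).

## Decisions taken where the instrument's description was ambiguous

These are package design choices, stated so tests can be exact:

* **C3 multi-category jump = 4 points** (configurable
  `c3_multi_jump_points`). The instrument's tabular and prose descriptions
  disagree (5 vs 4); the prose is internally consistent, so 4 is the
  default and 5 remains one configuration flag away.
* **Duration bands** `<4`, `[4,24]`, `(24,72]`, `>72` hours: the printed
  band labels touch at 24 h and 72 h; boundaries go to the *lower* band,
  mirroring ICHD-style inclusive upper limits.
* **C1 at exactly 4 NRS points** earns +4: the `>= 4` band wins over the
  overlapping `2–4` label.
* **C2 strict by default**: only contralateral → ipsilateral scores; any
  transition involving bilateral or unknown scores 0. The looser prose
  reading ("toward the aneurysm side") is available as
  `lenient_lateralization = TRUE`, under which any non-ipsilateral →
  ipsilateral shift scores +2. Which variant produced the original cohort
  is not stated; both are implemented.
* **C5 with a headache-free baseline** (0 MHD in the reference window):
  the relative-increase condition is treated as satisfied (an infinite
  relative increase); the absolute 5-day floor still applies.
* **C6 direction**: patients rate *similarity* (0 = very different, 10 =
  identical) but the score bands are on *dissimilarity*; the package
  stores the raw rating plus its declared scale and converts internally
  (`d = 10 - rating`), applying the bands to dissimilarity.
* **Ties at the threshold predict positive** (the threshold is `>= 9`).
* **Missing is never zero**: a criterion whose inputs are absent raises an
  explicit insufficient-data error naming the fields, rather than scoring 0.

## Validation machinery

**Content validity.** I-CVI = proportion of experts rating an item 3–4 on
the 4-point relevance (or clarity) Likert scale — the standard Lynn
dichotomization; the scale description alone does not fix the cut, so
this convention is stated. S-CVI/Ave is the arithmetic mean of item
I-CVIs; the overall figure averages the relevance and clarity item sets
together.

**Single-threshold AUC.** An already-thresholded classifier has a
three-point ROC `(0,0), (1−spec, sens), (1,1)`; its trapezoidal area is
exactly `(sens + spec)/2`. This is the AUC definition used for per-cut-off
validation — stated prominently because "AUC of a binary predictor" is
otherwise ambiguous, and consistent with every printed operating-point /
AUC triple the instrument was validated with. The package checks the
identity against an independent trapezoid computation.

**Binormal ROC.** For smooth curves the score is modelled as normal
within each label class, with the label-positive class as reference:
`a = (μ⁺ − μ⁻)/σ⁺`, `b = σ⁻/σ⁺`, `ROC(t) = Φ(a + b·Φ⁻¹(t))`,
`AUC = Φ(a/√(1+b²))`. The parameterisation (which group anchors `a` and
`b`) is a package choice; the fit is invariant under common affine
rescaling of both groups and degenerate when the positive group has zero
variance. Whether the original smooth curves were fit to the continuous
score or to per-cut-off binary predictions is unstated; both entry points
exist (`fit_binormal()` on totals; `confusion_at_cutoff()` per cut-off).

**Raters are validated independently** — one confusion matrix per rater,
no pooling.

## Statistical conventions

* **Fisher 2×2, two-sided**: probability-mass method — the sum of
  hypergeometric probabilities of all margin-fixed tables no more probable
  than the observed one, with relative tolerance 1e−7 on the comparison.
  Mid-p and doubling conventions differ; they are not used. A zero margin
  is degenerate (p = 1 with a warning).
* **r×c tables** (17-level aneurysm topography): margin-conditional
  Monte-Carlo estimate of the same probability-mass p, `(1 + hits)/(n_mc
  + 1)`, with a binomial standard error and the seed recorded in every
  report. Full network-algorithm exactness is out of scope.
* **Mann–Whitney U**: midrank-based U; exact two-sided p from the null U
  distribution when the pooled sample is tie-free and `n_x·n_y ≤ 400`,
  otherwise a tie-corrected normal approximation with continuity
  correction. (Ties have no clean exact distribution without full
  permutation enumeration, hence the tie-free restriction on the exact
  path.)
* **Normality** is assessed by Shapiro–Wilk (AS R94) but used only as
  metadata: group comparisons of continuous variables are always
  nonparametric, following the source analysis' preference once most
  variables proved non-normal.
* **Logistic regression**: IRLS maximum likelihood with step-halving (the
  log-likelihood is non-decreasing by construction), convergence when the
  score norm falls below 1e−8 or the relative log-likelihood change below
  1e−10 within 50 iterations; Wald intervals `exp(β ± 1.96·se)` from the
  inverse observed information; complete-case analysis with `n_used`
  reported; perfect separation (a margin-positive separating hyperplane,
  detected as a diverging linear predictor with perfect classification)
  is an error naming the most implicated covariate, never a silently
  divergent estimate. Continuous covariates are not standardised, so odds
  ratios keep their per-unit (per-mm, per-month, per-year) meaning; sex is
  coded male = 1.

## The synthetic-data module

Patient-level data for this clinical question are not publicly available,
so the package carries two generators, both first-class tested code.

**`simulate_cohort()`** draws cohorts under the stated study conditions,
which are the defaults of `sim_config()`: age 58.29 ± 12.70 years, 19 %
male, 88/137 with a prior headache disorder (46 migraine / 24
tension-type / 18 suspected aneurysm-attributed secondary), neck and dome
sizes from lognormals moment-matched to 5.09 ± 2.53 mm and 10.90 ± 6.62
mm, and a ground-truth outcome drawn from
`logit P = β₀ + 0.388 · neck_mm`, with β₀ calibrated by quadrature so the
marginal prevalence is 0.212. Conditional on the truth flag, phenotypes
are constructed so the scoring pipeline recovers it: worseners receive
component "recipes" escalated until the score reaches the configured
threshold (with probability `p_signal`, default 1 — the stated world has
no label noise between truth and score; lower values model imperfect
signal), benign courses improve (probability 41/71), stay unchanged, or
worsen minimally below threshold. The generator refuses configurations
whose threshold exceeds the largest realisable total. No joint
distribution linking phenotype changes to aneurysm morphology beyond the
neck-size association is published; the conditional phenotype model is a
modelling choice, and the truth flag travels in a sidecar table outside
the cohort schema so no pipeline stage can read it.

**`make_fixture_cohort()`** is deterministic (no RNG) and reproduces the
published *categorical* marginals exactly once scored and classified:
outcome counts 37/12/41/30/17 (post-pipeline 29/137), subgroup rates
12/49, 17/88 and 3/18, the sex and anterior-circulation splits, and the
topography level counts. Its 17 worsener records realise component
combinations totalling 9–16 with mean 10.82, matching the reported mean
worsener score. Continuous fields (age, neck, dome, therapy durations)
are deterministic moment-matched quantile fills near the printed group
means, decorrelated by stride permutations so the groups are not
artificially linearly separable; record-level continuous data are
unrecoverable from mean ± SD, so these carry *no* exact promise and the
printed continuous-variable p-values are not reproducible. One published
inconsistency is resolved in the fixture's favour of joint consistency:
the topography table admits 20 anatomically posterior aneurysms while the
anterior row prints 118/137, so the fixture codes the `PCA P1-Pcom`
record as anterior to satisfy both marginals at once.

**What a green test establishes — and what it does not.** Simulated
raters flip the ground truth with class-conditional error rates, and
simulated expert panels draw Likert ratings i.i.d. from a configured
distribution; real raters and real experts are not independent
coin-flips, real headache phenotypes are correlated in ways the recipe
construction is not, and the fixture's continuous variables are
quantile grids, not measurements. Green tests establish that the
*machinery* is correct (exact reproduction of published counts from
record-level data, closed-form identities, oracle equivalence, nominal
coverage and type-I error on data from the assumed model) — not that the
instrument is clinically valid on new patients.

## Numerical and degenerate-input choices

Empty samples, out-of-range ratings, non-positive durations, unknown
vocabulary tokens, constant samples (Shapiro–Wilk), zero-variance
positive groups (binormal), zero margins (Fisher), all-missing
covariates, and sub-threshold `n_mc` (< 1000) all raise immediately with
messages naming the offending field or patient. CSV round-trips preserve
the missing/zero distinction (empty cell vs `0`; explicit `"none"` for an
empty symptom set vs empty cell for an absent profile), and a schema
version line at the top of every cohort file guards against silent column
drift.

## Known limitations

* The Monte-Carlo r×c p-value reproduces an exact conditional test only up
  to Monte-Carlo error (a standard error is always reported).
* The Mann–Whitney exact path requires a tie-free pooled sample.
* The published group-comparison p-values and real-cohort CVI/AUC values
  are not reproducible without patient-level data; the pipeline reproduces
  the published *counts* and validates the inferential machinery by oracle
  and simulation instead.
* Twelve-month profiles feed persistence summaries only; the diagnostic
  window is fixed at 3 months and no imputation of missing phenotype
  fields is attempted.
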