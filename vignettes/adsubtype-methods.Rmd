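---
title: "Methods: atrophy-pattern subtyping and its characterization pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atrophy-pattern subtyping and its characterization pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsubtype)
```

## The classifier

Each subject carries four ordinal ratings: MTA left and right (0–4), PA
(0–3) and GCA-F (0–3). The bilateral MTA composite is the arithmetic mean of
the two sides. Averaging (rather than taking the worst side) is the only rule
compatible with half-point cutoffs such as 1.5 and 2.5, and matches how
longitudinal MTA scores are conventionally summarized; a `max` rule remains
available for sensitivity analyses. Abnormality is inclusive (`>=`) at every
threshold, following the cutoffs' own notation.

MTA cutoffs are age-banded — composite ≥ 1.5, 1.5, 2, 2.5 for ages 45–64,
65–74, 75–84, 85–94 — because medial temporal atrophy accumulates in normal
aging; PA and GCA-F use a fixed cutoff of 1, as age correction does not
improve their diagnostic performance. Ages outside 45–94 raise an error by
default: the cutoff scheme is simply undefined there, and silently
extrapolating a clinical threshold seemed worse than refusing. A
`clamp = TRUE` escape hatch assigns the nearest band for users who accept
that approximation.

The four labels are the four cells of the 2×2 table (MTA abnormal?) ×
(PA and/or GCA-F abnormal?), so they are mutually exclusive and exhaustive by
construction; the test suite verifies this by enumerating all 576
composite-MTA × PA × GCA-F × age-band combinations. Only subjects flagged as
AD are labelled — the subtype definitions presuppose a clinical AD diagnosis —
and controls pass through unlabelled.

## The synthetic cohort generator

The generator exists so that every downstream estimator has a test bed with
*known* truth. Its defaults encode the study conditions the analyses assume:

* **Group sizes** 230 controls; 100 / 33 / 35 / 30 AD patients across
  typical, limbic-predominant, hippocampal-sparing and no-atrophy.
* **Demographics** per-group age, education, percent female, baseline MMSE
  and CDR means/SDs, and APOE/CSF abnormality prevalences, matching the
  emulated sample's baseline table.
* **Ratings** are sampled *after* the subtype label, uniformly over the
  label's admissible region given the subject's age band (e.g. a
  limbic-predominant subject aged 80 draws a composite MTA from
  {2, 2.5, …, 4} and PA = GCA-F = 0). This inverts the analysis direction
  deliberately: it guarantees that the classifier must recover the generating
  label exactly, which turns label agreement into a sharp correctness test
  rather than a statistical one.
* **AVLT battery** raw items (0–15 words) are drawn as rounded, clamped
  normals around healthy-control means, with per-group downward shifts in
  control-SD units. The shifts are free calibration constants chosen once so
  that expected impairment frequencies mirror the published ordering (worst
  learning in typical AD; most interference in hippocampal-sparing; best
  recognition in the no-atrophy group). Because the learning component is the
  *sum* of five trials, the configured learning shift is divided by sqrt(5)
  at the trial level so that it lands on the component scale as stated.
* **Delayed recall** is additionally coupled to the non-memory battery and
  learning on a standardized latent scale using the published group-specific
  standardized coefficients (controls: learning 0.744; typical: 0.560;
  limbic-predominant: 0.483; hippocampal-sparing: TMT-B 0.548 + fluency
  0.455; no-atrophy: learning 0.725 with processing speed −0.336), with
  residual variance completing unit variance. Rounding and clamping to the
  0–15 scale attenuates the realized coefficients by a few hundredths — a
  deliberate measurement-scale realism; the exact-recovery experiments use
  `generate_memory_battery()`, which stays on the latent scale.
* **Longitudinal outcomes** follow
  `y_ij = alpha_g + b_i + beta_g t_ij + gamma_g t_ij^2 + e_ij` at visits 0, 1
  and 2 years, with `b_i ~ N(0, sigma_b^2)` and `e_ij ~ N(0, sigma^2)`. Group
  slopes default to the published per-year estimates (CDR 0.03, 0.29, 0.28,
  0.16, 0.14; MMSE −0.01, −2.69, −3.08, −1.48) and intercepts to the baseline
  group means. Two constants are not recoverable from the source and were
  fixed once as plausible: the no-atrophy MMSE slope (−1.60 points/year,
  inside the published AD range and near the milder subtypes) and the
  variance components (CDR sigma_b = 0.2, sigma = 0.15; MMSE sigma_b = 1.5,
  sigma = 1.0), since only fixed effects are printed. CDR is simulated
  continuously, matching how it is modelled; rounding to the clinical
  {0, 0.5, 1, …} grid would distort slope recovery and is not applied.
* **Rating progression** is a monotone step process: each scale independently
  gains one point per follow-up visit with a per-scale probability (defaults
  0.15 for MTA, 0.08 for PA/GCA-F), capped at the scale maximum.

All randomness flows from one integer seed; each generator stage derives a
deterministic sub-seed so that, for example, regenerating the longitudinal
table does not depend on whether the cross-section was generated first.

What the generator does *not* emulate: floor/ceiling effects in cognitive
tests beyond simple clamping, informative dropout, rater disagreement in the
baseline ratings, correlations between demographics and outcomes, and any
real-data idiosyncrasy. Passing tests therefore certify the estimators'
correctness and calibration under the assumed model, not the published
real-data descriptive numbers, which are out of scope by design.

## Memory components and impairment

From the AVLT items we derive: learning (sum of trials 1–5, 0–75),
interference (list B), immediate and delayed free recall, recognition, and
gain = recognition% − delayed%. The source text defines gain in both
directions in different places; we use recognition minus delayed because only
that orientation is consistent with the stated interpretation that *higher
gain means more retrieval problems* (stored information that surfaces with
cues but not freely). Impairment flags use control norms: performance
components are impaired at z ≤ −1.5 (boundary inclusive — the cutoff is
quoted as "−1.5 SD" without strictness, and including the boundary is the
conservative clinical reading); gain is flagged at z ≥ +1.5 because high
gain is the pathological direction.

The component-by-subtype interaction is tested as a split-plot ANOVA on
control-standardized component scores (between factor: subtype; within
factor: component; subject as error stratum). Standardization puts the
within-factor levels on one scale, and makes the analysis invariant to
affine rescaling of any single component. Sphericity is not adjusted by
default (the source is silent); the printed interaction degrees of freedom
in the source are not reproducible from the stated design and are not a
target. Covariates, when supplied, are centered and residualized out of the
z scores before the ANOVA.

## Backward regression, dominance, stability

Backward elimination starts from the full OLS model and repeatedly drops the
predictor with the largest p-value while it is ≥ 0.10 (the classic
backward-elimination convention; the source names the method but not the
alpha — configurable). The final model is refit on z-scored outcome and
predictors so the coefficients are standardized betas.

General dominance decomposes the full-model R² into per-predictor weights by
all-subsets averaging: predictor *j*'s weight is the mean over subset sizes
of the average incremental R² from adding *j*. This is exactly the Shapley
value of the R² game, so the weights are non-negative (incremental R² of an
OLS predictor is never negative) and sum to R² to machine precision — both
identities are asserted in the tests, along with agreement (1e−10) with a
brute-force all-orderings oracle for p ≤ 4. Subset R² values are computed
from centered cross-product matrices rather than repeated `lm()` calls; with
the study's p = 5 this is 32 small solves per decomposition, which keeps the
1000-replicate bootstrap cheap.

The stability screen resamples subjects with replacement (non-parametric,
case resampling), recomputes the weights B = 1000 times, and calls a
predictor stable when the lower bound of its 95% percentile interval exceeds
a floor of 0.01 variance fraction. The source's stability criterion is
verbal; the floor/interval rule is our operationalization, both knobs
configurable and recorded in the output. The reported predictor set is the
intersection of backward-retained and bootstrap-stable, mirroring the
asterisk convention in the published table.

## Longitudinal models

Progression is modelled as `outcome ~ group * time + (1 | id)`, REML, using
all available observations per time point — subjects with missing follow-ups
contribute their remaining visits. The random structure is intercept-only
because the participants are the stated random factor; a random-slope
variant sits behind a flag. Per-group slopes are resolved as reference slope
plus interaction offset, with standard errors from the corresponding
fixed-effect contrast. Pairwise slope contrasts are Wald t tests with
Satterthwaite degrees of freedom, BH-adjusted within the requested family;
the source's printed contrast degrees of freedom come from an unstated
convention and are treated as descriptive. Linearity is tested by adding
`time^2` and `group:time^2` and comparing by likelihood ratio on ML refits
(REML likelihoods are not comparable across fixed-effect structures).

The convergence flag reflects the optimizer's own status; lme4's post-hoc
gradient heuristics fire spuriously on the boundary fits that noise-free
test data produce (zero variance components) and are not treated as
failures. Noise-free recovery of all intercepts and slopes is exact to 1e−8,
and with the random-intercept SD driven to zero the fixed effects agree with
pooled OLS to 1e−4 — both are regression tests.

## Characterization utilities

The random-forest screen (500 trees, as specified; other hyperparameters at
package defaults — sqrt(p) candidate features per split, unlimited depth)
reports per-group out-of-bag error against the analytic chance level
100·(1 − 1/G)% (80% for five groups). OOB error was chosen over k-fold
cross-validation because it is the ensemble's native error estimate; a
k-fold alternative would measure the same quantity more expensively.
Weighted kappa uses linear disagreement weights by default (common practice
for Scheltens-family scales; quadratic selectable). BH adjustment delegates
to `stats::p.adjust(method = "BH")` and is property-tested against explicit
step-up arithmetic and for FDR control under the global null.

## Problem sizes and numerical choices

The parameter-recovery experiments use 5 groups × 500 subjects × 3 visits
for the mixed models and n = 2000 for the regression structures — sizes at
which the Monte-Carlo error of each estimate sits comfortably inside the
recovery tolerances (slope SE ≈ 0.005 CDR points/year; beta SE ≈ 0.015)
while a full run stays in the seconds-to-minutes range. Simulation-based
calibration tests (type-I rates, FDR control, power) use a few hundred
replicates under fixed seeds. Degenerate inputs fail loudly: zero-variance
reference norms, rank-deficient designs, quadratic models with fewer than
three time points, out-of-band ages, and non-integer ratings are all
errors, not silent repairs.

## Known limitations

* The generator's AVLT shift constants and trajectory variance components
  are calibration choices, not estimates; only the quantities listed above
  as published values are recovery targets.
* Ratings at baseline are sampled uniformly within each label's admissible
  region; real rating distributions are not uniform.
* The split-plot ANOVA uses complete cases per component and does not model
  missingness.
* Dominance analysis is exponential in the number of predictors and capped
  at p = 20.
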