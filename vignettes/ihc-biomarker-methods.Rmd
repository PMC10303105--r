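---
title: "Methods: semi-quantitative IHC biomarker analysis in T-cell lymphoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantitative IHC biomarker analysis in T-cell lymphoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcdx)
```

`ihcdx` analyses semi-quantitative immunohistochemistry (IHC) readouts
of STAT3 phosphorylation (pSTAT3-Y705, pSTAT3-S727) and CD30 in mature
T-cell lymphoma, for two purposes: distinguishing ALK-negative
anaplastic large cell lymphoma (ALK⁻ ALCL) from CD30-high PTCL, NOS,
and stratifying the prognosis of PTCL, NOS by pSTAT3-S727 expression in
tumor-infiltrating lymphocytes (TILs). This vignette documents the
scoring model, the statistical procedures and their conventions, the
synthetic-cohort generator, and the numerical choices that were
genuinely open.

## Scoring model

A staining readout is a profile `(frac0, frac1, frac2, frac3)` — the
fractions of cells with no, weak (1+), moderate (2+) and strong (3+)
staining, summing to 1. The H-score is the intensity-weighted sum

$$H = 300 f_3 + 200 f_2 + 100 f_1 \in [0, 300],$$

linear in the profile and monotone under moving cell mass to higher
intensity classes. The staining-extent grade bands the positive-cell
fraction $f_1+f_2+f_3$ into `< 30 %`, `30–70 %` and `> 70 %`; the band
edges 0.30 and 0.70 belong to the middle band (the band labels leave
the boundary membership open; a closed middle interval is the only
choice under which the three printed labels partition $[0,1]$).

**TILs composite.** The prognostic score for S727 in TILs multiplies
the TILs H-score by the fraction of tumor area occupied by TILs:
$S727_{TILs} = H_{TILs} \times \text{TILs fraction}$. Stated as a
formula over percentages this reads "H-score × TILs % × 100", i.e. the
percentage divided by 100; we adopt the fraction reading because it is
the only one under which typical TILs H-scores (≈ 75–150) yield
composite values on the observed 10–31 scale — a literal ×100 reading
would produce values in the thousands. The composite is 0 for
TILs-free tumors (`tils_frac = 0`), which is a real observation,
deliberately distinct from a missing TILs fraction (unknown).

All percentages are stored internally as fractions in $[0,1]$. Input
files may carry 0–100 values behind an explicit `percent` flag — never
auto-detected, because a column of values ≤ 1 is valid under both
dialects.

## CD30 subgrouping

PTCL, NOS cases with CD30 expression in at least 80 % of tumor cells
form the CD30-high subgroup. The published threshold is "80 %" with no
comparator; we use ≥ 0.80 (inclusive) and expose the threshold as a
parameter. The rule returns `NOT_APPLICABLE` for ALCL and for PTCL, NOS
without a recorded CD30 fraction.

## Diagnostic performance

The diagnostic contrast is ALK⁻ ALCL (positive class) versus CD30-high
PTCL, NOS. The ROC curve is built empirically: candidate cutoffs are
the midpoints between adjacent distinct observed scores plus ±∞
sentinels, and a case is called positive when its score is **at or
above** the cutoff ("above the cutoff favours ALK⁻ ALCL"; on
integer-granular H-scores the ≥ and > conventions coincide except
exactly at an observed score, and the convention is a flag). The AUC is
the tie-aware pair-counting statistic — the fraction of
(positive, negative) case pairs ordered correctly, ties counting ½ —
which the tests verify against brute-force enumeration.

The reported optimal cutoff maximises the Youden index
$J = \text{sens} + \text{spec} - 1$ over all enumerated thresholds.
Ties in $J$ are broken towards higher specificity, then towards the
larger cutoff: in this differential, a false ALK⁻ ALCL call
(overcalling the more treatable disease) is the costlier error, so
specificity wins ties. When no cutoff discriminates ($J_{max} = 0$) the
result is flagged degenerate.

Dichotomised markers combine in parallel (logical OR — sensitivity can
only rise) or in series (logical AND — specificity can only rise); by
default each marker is dichotomised at its own Youden-optimal cutoff,
and fixed cutoffs (e.g. 165 for Y705, 145 for S727) can be supplied.
Paired AUCs are compared with the DeLong structural-components
estimator of $\mathrm{var}(AUC_a - AUC_b)$ and a two-sided normal
p-value — the standard choice for paired ROC comparison, and the one
the surrounding ecosystem defaults to.

## Group-comparison statistics

These are implemented from first principles so that each can be pinned
to an enumeration oracle in the tests:

* **Fisher exact (two-sided)** uses the probability-mass convention:
  conditioning on both margins, the p-value sums the hypergeometric
  probabilities of all tables no more probable than the observed one,
  with a relative slack of $10^{-7}$ guarding floating-point
  comparisons of equal masses. This matches the mainstream exact-test
  implementations against which the published clinical tables were
  checked. Seven of the eight recomputable published p-values round
  exactly to their printed values; the eighth (bone-marrow involvement,
  computed 0.0445, printed 0.045) agrees within one unit in the last
  printed digit.
* **Mann–Whitney U** uses mid-ranks for ties. Exact mode enumerates all
  $\binom{n_x+n_y}{n_x}$ assignments of the pooled mid-ranks and
  doubles the smaller tail (capped at 1); it is the default up to
  pooled $n = 12$. Otherwise the tie-corrected normal approximation is
  used, without continuity correction by default (flag available).
* **Kruskal–Wallis** is the tie-corrected $H$ with a
  $\chi^2_{k-1}$ p-value; for two groups it equals the squared normal
  MWU statistic, which the tests verify algebraically.
* **Spearman** is the Pearson correlation of mid-ranks with the
  $t_{n-2}$ approximation.

Missing clinical covariates are excluded pairwise per comparison, which
reproduces the varying denominators of clinical baseline tables. No
multiple-testing correction is applied — comparisons report raw
p-values, mirroring the descriptive use of such tables; treat
significance claims across many covariates accordingly.

## Survival analysis

Time is in months throughout. The Kaplan–Meier estimator uses the
standard product-limit convention that deaths precede censorings at
tied times. `survival_at()` is the right-continuous step value (3-year
OS = S(36)); median OS is the smallest observed event time with
$S(t) \le 0.5$, not interpolated, and `NA` means "not reached". The
log-rank test accumulates observed-minus-expected events over pooled
distinct event times with the hypergeometric variance, for any number
of groups.

**TILs stratification.** PTCL, NOS cases with follow-up are split three
ways: `NO_TILS` (TILs fraction 0), then `LOW`/`HIGH` below/at-or-above
the cohort median of the composite score. "High" is at-or-above because
the published grouping prints "low (< split)" with the comparator of
the high group lost. Whether the split median should include the zero
scores of TILs-free cases is not decidable from the published group
counts (neither reading reproduces them exactly); the default includes
them, and `include_no_tils_in_median = FALSE` gives the other reading.
Cases without follow-up are `EXCLUDED` and do not enter the median.

**Risk indices.** An additive risk index counts satisfied adverse
factors and maps the count to a label. PIT ships as a default (age
> 60, ECOG > 1, elevated LDH, bone-marrow involvement; 0–1 low,
≥ 2 high). The modified-PIT factor set is published only by citation,
so no factor set is invented here: supply one via
`risk_index_definition()` with the 0–1 low / 2–3 high grouping.

## The synthetic-cohort generator

No per-patient data accompany the study this design emulates, so the
generator is a first-class module: it produces cohorts with the
statistical structure the analyses assume, and every quantitative claim
the tests make about the pipeline is made against it.

* **Structure.** Four groups of fixed sizes 33 / 22 / 10 / 24 (total
  89): ALK⁺ ALCL, ALK⁻ ALCL, CD30-high and CD30-low PTCL, NOS.
* **H-scores** are drawn from Beta distributions rescaled to
  $[0, 300]$, parameterised by their median (matched exactly by solving
  for the shape at fixed concentration) — a bounded, flexibly skewed
  family that is the natural minimal choice for a bounded score.
  Default medians: Y705/S727 280/260 (ALK⁺), 250/240 (ALK⁻), 45/75
  (CD30-high), 65/105 (CD30-low, set so the PTCL-wide medians land near
  60/100). Concentrations are fixed at 1.4 (Y705), 3 (S727) and 12
  (CD30) so that the implied ALK⁻-vs-CD30-high discrimination matches
  the reported performance (AUC ≈ 0.86 / 0.90 / 0.90): Y705 is wide to
  the point of bimodality (cases tend to be either diffusely positive
  or largely negative), S727 moderately dispersed, CD30 tightly high in
  both contrast groups.
* **Within-case coupling** of Y705 and S727 uses a Gaussian copula with
  correlation 0.5 — the real correlation is unreported; 0.5 encodes
  "related but not redundant phosphosites" and is configurable.
* **Profiles** are back-filled from each sampled H-score
  deterministically (70 % of the score mass at 3+, the rest at 2+,
  with the unique 3+/2+ split when the cell budget binds), so
  `h_score()` recovers the sampled target exactly; many profiles share
  an H-score, and this rule keeps generation reproducible.
* **TILs.** Each case is TILs-free with probability 0.18 (PTCL groups;
  0.10 for ALCL, where TILs are usually present). For TILs-bearing
  cases the composite score is drawn first (medians 10 / 18 / 14.5 /
  31), then a raw TILs H-score at least as large, and the TILs fraction
  is their ratio — guaranteeing a valid fraction in $(0, 1]$.
* **Survival** is exponential per group with uniform administrative
  censoring. PTCL, NOS uses a 5.0-month median with a 24–60-month
  window; the ALCL groups use event medians (130 / 110 months) far
  beyond their censoring windows, so their Kaplan–Meier medians are
  typically not reached — "not reached" is realised through
  censoring-dominated follow-up, not by forbidding events. Loss to
  follow-up (missing outcome) is 18 % in PTCL, NOS and ≈ 10 % in ALCL.
* **Covariates** are Bernoulli draws at the group prevalences of the
  published baseline tables, with per-covariate missingness rates
  shaped like those tables' denominators.
* **Reproducibility.** Each group draws from its own substream derived
  arithmetically from the root seed, so `(config, seed)` fully
  determines the cohort and adding a group does not perturb the others.

`planted_separation_config()` builds a two-group S727 contrast with
known medians and an `overlap` dial: 0 plants point masses (AUC 1),
`Inf` collapses both groups onto one distribution (AUC ½), finite
values scale the Beta concentration as `4 / overlap`.

**What the generator does not emulate.** Scores are continuous, whereas
real H-scores are integer-granular expert reads; there is no
inter-observer variability; covariates are independent given the group
(no age–stage correlation, say); and survival is independent of the
TILs composite within PTCL, NOS — the generator reproduces the
group-level survival summaries, not the prognostic effect of the TILs
score itself. Passing tests therefore demonstrate correctness of the
estimators and the pipeline under the assumed data-generating
mechanism, not clinical validity of the biomarker on real cohorts.

## Numerical choices and degenerate inputs

* Profile sums are accepted within $10^{-3}$ on file read and
  renormalised to 1; beyond that the record is rejected by case id.
* Single-class ROC input, zero rank variance in Spearman, and a
  zero-variance DeLong comparison with unequal AUCs are errors;
  no-event log-rank, all-identical MWU/Kruskal–Wallis samples, and
  zero-margin Fisher tables return p = 1 flagged `degenerate`.
* p-values are capped into $(0, 1]$.
* The ALCL "not reached" medians mean `median_survival()` returns `NA`;
  downstream summaries carry the `NA` rather than substituting a
  follow-up bound.

## Problem sizes in the test suite

The oracle-equivalence suites run enumeration oracles at the sizes
where enumeration is exact and fast (AUC and Fisher up to $n = 200$,
exact MWU to pooled $n = 12$, product-limit oracles on up to 10 cases);
the simulation suites use 60–500 replicate cohorts of the 89-case
default (or the 32-case planted contrast) and a 400-replicate null for
log-rank size — sizes at which the binomial error of the checked
proportions is well inside the asserted bands. The full suite runs in
a few minutes on one CPU.

## Known limitations

* The exact Mann–Whitney mode enumerates assignments and is
  exponential; it is restricted to small pooled samples (the regime
  where the clinical tables need it).
* The DeLong test relies on asymptotic normality; with very few cases
  per class (the 22 / 10 contrast is near the boundary) its p-values
  are approximate.
* Only the PIT risk index ships; modified-PIT must be supplied by the
  user with its published factor set.
* No Cox regression or multivariable modelling is provided — the
  analyses here are univariate by design.
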