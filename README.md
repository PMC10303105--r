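# ihcdx

Diagnostic and prognostic analysis of semi-quantitative
immunohistochemistry (IHC) biomarkers in mature T-cell lymphoma.

## The problem

ALK-negative anaplastic large cell lymphoma (ALK⁻ ALCL) and peripheral
T-cell lymphoma, not otherwise specified (PTCL, NOS) with diffuse,
strong CD30 expression ("CD30-high", here ≥ 80 % of tumor cells) overlap
in morphology and immunophenotype, yet differ in prognosis and in their
response to CD30-directed therapy. STAT3 is characteristically activated
in ALCL, so the phosphorylation state of STAT3 — at tyrosine 705
(pSTAT3-Y705) and serine 727 (pSTAT3-S727), both readable by routine
IHC — is a candidate discriminator. `ihcdx` implements the full analysis
such a biomarker study needs, for pathologists and biostatisticians
working from per-case staining scores (no image analysis is involved).

## What it computes

**Scoring.** Staining is recorded as the fractions of cells at intensity
0/1+/2+/3+. The H-score is

    H = 300·(% cells 3+) + 200·(% cells 2+) + 100·(% cells 1+)  ∈ [0, 300]

with a three-band staining-extent grade (< 30 %, 30–70 %, > 70 % positive
cells). For pSTAT3-S727 in tumor-infiltrating lymphocytes (TILs), the
composite score weights the TILs H-score by the fraction of tumor area
the TILs occupy: `S727_TILs = H_TILs × TILs fraction` (still on the
[0, 300] scale; a TILs-free tumor scores 0).

**Diagnosis.** Empirical ROC curves with the tie-aware pair-counting
AUC, Youden-index (J = sensitivity + specificity − 1) optimal cutoffs,
fixed-cutoff evaluation (score ≥ cutoff ⇒ ALK⁻ ALCL), parallel (OR) and
serial (AND) combination of dichotomised markers, and the DeLong
structural-components test for paired AUC differences.

**Group comparison.** Two-sided Fisher exact test (probability-mass
convention), Mann–Whitney U (exact by exhaustive enumeration for small
samples, tie-corrected normal approximation otherwise), Kruskal–Wallis,
and Spearman rank correlation — all implemented from first principles
and cross-checked against independent oracles in the test suite, with
pairwise-complete handling of missing clinical covariates.

**Survival.** Kaplan–Meier product-limit estimation (deaths before
censorings at ties), t-year OS and median OS, the k-group log-rank test,
three-way prognostic stratification of PTCL, NOS by the cohort-median
S727_TILs score (no TILs / low / high), and additive clinical risk
indices (PIT shipped; modified-PIT definable).

**Simulation.** A fully seeded synthetic-cohort generator reproducing
the four-group study structure (33 ALK⁺ ALCL / 22 ALK⁻ ALCL / 10
CD30-high / 24 CD30-low PTCL, NOS), with median-matched H-score
distributions, TILs composites, clinical covariate prevalences and
censored exponential survival, so every pipeline stage is testable
without patient-level data.

## Worked example

```r
library(ihcdx)
library(dplyr)

cohort <- generate_cohort(default_study_config(), seed = 1)
scored <- cohort |> score_cohort() |> classify_cd30_subgroup()
subgroup_counts(scored)
#>   subgroup         n
#> 1 ALK_POS_ALCL    33
#> 2 ALK_NEG_ALCL    22
#> 3 PTCL_NOS        34
#> 4 CD30_HIGH       10
#> 5 CD30_LOW        24

roc <- roc_from_cohort(scored, "s727_tumor_hscore")
roc
#> Empirical ROC curve (positive class: ALK_NEG_ALCL)
#>   n = 22 positive / 10 negative
#>   AUC = 0.9818
youden_optimal_cutoff(roc)
#>   cutoff    tp    fp    tn    fn sensitivity specificity youden degenerate
#> 1   139.    22     1     9     0           1         0.9    0.9 FALSE
```

The S727 tumor H-score separates ALK⁻ ALCL from CD30-high PTCL, NOS in
this replicate with AUC 0.98; the Youden-optimal cutoff (midpoint
between adjacent observed scores) is ≈ 139, and a case at or above the
cutoff is called ALK⁻ ALCL with sensitivity 1.00 and specificity 0.90.
Across replicate cohorts the AUC averages ≈ 0.90 (see the acceptance
script below).

```r
surv <- survival_by_group(scored, "diagnosis")
surv$summary
#>   group            n events median_os os_12 os_36 os_60
#> 1 ALK_POS_ALCL    29      5     NA    0.966 0.894 0.847
#> 2 ALK_NEG_ALCL    18      4     75.9  0.944 0.822 0.822
#> 3 PTCL_NOS        29     29      4.36 0.276 0     0
surv$logrank$p_value
#> [1] 5.37e-20
```

PTCL, NOS runs an aggressive course (median OS 4.4 months here; the
generator targets 5.0), while the ALCL groups rarely reach their median
within follow-up (`NA` = not reached). `autoplot()` methods draw the ROC
and Kaplan–Meier step curves; `run_pipeline()` (or
`Rscript scripts/ihcdx-pipeline.R`) executes the whole workflow and
writes a TSV/JSON report bundle.

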