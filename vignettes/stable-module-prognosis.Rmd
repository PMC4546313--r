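---
title: "Building prognostic models from stable co-expression modules"
author: "prognomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building prognostic models from stable co-expression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-blood mRNA profiles predict survival in castration-resistant prostate
cancer (CRPC), but signatures selected by fitting a learner directly to one
training cohort tend to absorb dataset-specific noise: independently derived
blood signatures for the same disease can share no genes at all. `prognomod`
implements an integrative strategy that constrains gene selection by
*biology shared across cohorts* before any classifier sees the training
labels:

1. **Candidate genes.** A moderated-t differential expression analysis
   (empirical-Bayes shrunken variances, Benjamini–Hochberg control) compares
   high- vs low-risk patients in the labelled training cohort and keeps
   genes at FDR < 0.05, split into up- and down-regulated lists.
2. **Co-expression modules.** In each of two *independent, unlabelled*
   reference cohorts of whole-blood profiles, a weighted co-expression
   network is built over each candidate list (Pearson correlation, soft
   threshold, topological overlap), and modules are cut from the
   average-linkage dendrogram of the TOM dissimilarity.
3. **Stability.** Modules from the two reference cohorts are matched by
   one-sided Fisher exact overlap tests; a module is *stable* when its best
   cross-cohort partner overlaps at p < 0.01. The up- and down-regulated
   stable lists are truncated to equal length so that models pair one up-
   with one down-regulated gene — paired designs are less sensitive to
   normalisation shifts.
4. **Functional cores.** Each stable module is annotated against canonical
   pathways (Fisher enrichment, threshold 1e-4); the core is the
   intersection of the module with its top pathway, falling back to the top
   hematopoietic cell-type overexpression signature when no pathway
   qualifies. In blood, up-regulated modules typically map to myeloid
   lineages and down-regulated modules to lymphocytes, so the fallback keeps
   a cell-type interpretation even for pathway-poor modules.
5. **Representatives and the classifier.** One representative gene per core
   — the most differentially expressed gene whose mean expression exceeds
   the genome median — feeds a Gaussian naive-Bayes classifier. The number
   of up/down pairs (k) is chosen by leave-one-out cross-validation: each
   candidate panel's held-out posterior scores are dichotomized at 0.5 and
   scored by the log-rank test on the training survival; minimal p wins
   (ties: larger hazard ratio, then smaller k).

Cross-platform deployment uses a per-gene affine calibration (match median
and raw MAD to the training distribution), and the package also ships the
fixed published four-gene qPCR score
`s = -27.28 - 3.43*MCM2 - 0.68*PROS1 + 3.06*CD22 + 3.49*TMEM66`,
`score = exp(s)/(1+exp(s))`, dichotomized at the universal cutoff 0.5
(delta-Ct inputs; lower Ct means more transcript, hence the flipped signs).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fdr_cutoff` | 0.05 | candidate-gene FDR threshold (BH) |
| `power` | 6 | soft-threshold exponent; `pick_soft_threshold()` selects the smallest power with scale-free fit R² ≥ 0.8, falling back to 6 |
| `signed` | FALSE | unsigned adjacency `|cor|^power` (the historical default) |
| `min_module_size` | 10 | smallest non-grey module |
| `cut_height` | 0.99 | fixed cut height on the 1 − TOM dendrogram |
| `stability_alpha` | 0.01 | Fisher overlap threshold for stable modules |
| `core_p_threshold` | 1e-4 | pathway-enrichment threshold before the cell-type fallback |
| NB variance floor | 1e-9 | guards degenerate one-value folds |
| `cutoff` | 0.5 | posterior / logistic-score dichotomization |

Design choices that were genuinely open, and how they were resolved:

* **Tree cut.** A fixed-height cut with a minimum branch size replaces the
  hybrid dynamic tree cut: it is deterministic, has two transparent knobs,
  and recovers planted blocks reliably at the cohort sizes considered here.
* **Stable gene set.** The genes of a stable module are the *intersection*
  of the matched module pair — genes co-clustered in both cohorts are the
  defensible notion of "stable membership". Matching is anchored on
  dataset-1 modules; one dataset-2 module may serve several dataset-1
  modules (matching is not forced to be bijective).
* **Enrichment universe.** All genes measured in the training cohort, not
  only the candidates: module enrichment is judged against the assay
  background. No multiple-testing adjustment is applied inside `enrich()`;
  the 1e-4 core threshold already plays that role (a Bonferroni-style
  family-wise control at the usual collection sizes).
* **Expression filter.** "Expressed above half the genome" is implemented
  as mean expression across training samples above the median of all genes'
  means — a deterministic, rank-stable reading.
* **Fallback without a second threshold.** When no pathway reaches 1e-4 the
  best cell-type set is accepted regardless of its p; the rule is total
  (threshold 1 never falls back on any non-zero overlap, threshold 0 always
  does).
* **Tie-breaks.** DE ranks break p ties by |log fold change| then gene id;
  enrichment ranks break ties by smaller set then name; module labels are
  assigned in decreasing size order. Everything is deterministic given the
  inputs.
* **Survival backend.** Kaplan–Meier, log-rank, Cox (Efron ties — month
  resolution data produce heavy ties) and the concordance index are backed
  by the `survival` package; the test suite asserts them against in-repo
  enumeration oracles (exhaustive pairs for concordance, an
  observed-minus-expected loop for the log-rank, the score-test/log-rank
  identity for Cox), so the backend is cross-checked, not trusted blindly.
  Monotone likelihood triggers a small ridge (1e-4) refit with a warning
  rather than divergent coefficients; the score test at β = 0 is always
  reported from the unpenalized fit, where it remains well defined.
* **Moderated t.** Implemented in closed form for the two-group design:
  pooled per-gene variances, prior (d0, s0²) by moment matching on the log
  variances (Newton trigamma inversion), d0 capped at 1e6 to represent an
  effectively infinite prior; when the log variances show no excess spread
  the prior variance is the mean pooled variance, making equal-variance
  data an exact fixed point of the shrinkage. The implementation agrees
  with `limma::eBayes` to 1e-9 on shared inputs (asserted in the tests, with
  limma used only as a cross-check).

## What the synthetic generator emulates

`simulation_config()` builds a study with the roles the method assumes:
two unlabelled reference cohorts sharing planted co-expression modules, a
labelled training cohort with survival, and RNA-seq / qPCR validation views.

* **Co-expression** is a one-factor model per module:
  `x = mu_g + noise_sd * (sqrt(rho) * f + sqrt(1 - rho) * eps)`, giving
  expected pairwise within-block correlation exactly `rho` (default 0.7).
  Unshared modules are planted in reference 1 only.
* **Prognostic signal**: high-risk training samples are shifted by the
  module's effect size — 1.5 residual standard deviations by default, the
  planted-effect convention used throughout the recovery checks; genes
  selected as biomarker drivers in real cohorts show effects of this order.
* **Survival** is exponential with hazard `h0 * exp(log_hr * risk)`
  (default hazard ratio 3 between groups, `h0 = 0.02`/month) under
  independent exponential censoring (`0.005`/month, i.e. ~85% observed
  deaths, matching the heavy event rates of advanced-CRPC cohorts).
* **Platform distortion** is per-gene affine: RNA-seq
  `y = a_g + b_g x + e`; qPCR `y = a_g - b_g x + e` with `b_g > 0`, so
  delta-Ct anti-correlates with expression as on a real instrument.

Default problem sizes — 2000 genes, 200 samples per reference cohort,
30 + 30 training samples, 25 validation samples — were chosen as a
desk-scale version of the blood-cohort setting (hundreds of reference
samples, tens of labelled patients) on which every stage is measurably
recoverable; the test suite and `scripts/acceptance.R` run them end to end
in seconds.

What the generator does **not** emulate: probe-level microarray artifacts,
batch structure beyond the affine per-gene map, correlated censoring,
cell-type deconvolution, or the selection-induced correlation between a real
training cohort's candidate list and its reference cohorts. Passing the
planted-recovery suites therefore demonstrates that the machinery is
correct and well calibrated, not that any particular clinical performance
will transfer to real cohorts.

## Numerical notes and degenerate inputs

* Zero-variance genes get correlation 0 (warning), a zero-variance fold in
  the naive Bayes is floored at 1e-9, and posteriors are computed in log
  space and clamped strictly inside (0, 1).
* Duplicate gene rows in expression files collapse to the highest-mean row
  (the standard probe-collapse heuristic) with a warning; `NA` cells are
  rejected unless explicitly allowed as flagged missing.
* A constant validation gene calibrates shift-only (gain 1) with a warning;
  calibration is exactly invariant to any per-gene affine distortion of the
  validation data.
* Fewer genes than `min_module_size` yields a single all-grey assignment
  with a warning; an empty stable list in either direction empties both
  (paired modelling is impossible) with a warning.
* LOO folds that would leave a singleton class skip that candidate size
  with a warning; if no candidate size produces a two-group split, the
  largest panel is returned and flagged non-significant.

## Known limitations

* The stability machinery compares exactly two reference cohorts; multi-way
  stability is out of scope.
* `fit_prognostic_model()` assumes a two-group (high/low) training design;
  there is no covariate adjustment in the differential expression step.
* The qPCR validation view cannot be mapped onto the expression scale by
  the median/MAD calibration (the map's gain is nonnegative by
  construction); qPCR deployment goes through the platform-specific
  logistic refit (`fit_platform_logistic()`) or the fixed four-gene score,
  as in the original design.
* The LOO-CV size selection minimises a noisy log-rank p over nested
  panels; with few training samples adjacent k values are often
  statistically interchangeable, and the reported `cv` table should be
  inspected rather than the selected k taken as sharp.
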