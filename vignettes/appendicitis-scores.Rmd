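---
title: "Scoring pediatric appendicitis: the score engine, its evaluation panel, and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pediatric appendicitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appendiscore)
```

## The clinical problem

Acute appendicitis is the most common reason for abdominal surgery in
children, and the diagnosis is hard precisely where it matters most: early
presentations and young patients. Additive clinical scores — a weighted sum
of history items, examination findings, laboratory thresholds, and an
ultrasound read, dichotomized at a cutoff — are the standard decision aids.
This package implements six of them on a common item vocabulary:

| score    | items (weight)                                                            | positive at |
|----------|----------------------------------------------------------------------------|------|
| Alvarado | tenderness RLQ (2), rebound (1), WBC (2), nausea/vomiting (1), anorexia (1), migration (1), fever (1), neutrophilia (1) | 5/10 |
| PAS      | tenderness RLQ (2), cough/hop (2), WBC (1), nausea/vomiting (1), anorexia (1), migration (1), fever (1), neutrophilia (1) | 6/10 |
| Tzanakis | tenderness RLQ (4), rebound (3), WBC (2), ultrasound (6)                   | 8/15 |
| HAS      | tenderness RLQ (1), rebound (1), ultrasound (1), continuous pain (1)       | 3/4  |
| modified HAS | tenderness RLQ (1), rebound (1), WBC (1), CRP (1), ultrasound (1)      | 3/5  |
| AI score | rebound (1), WBC (1), CRP (1), ultrasound (1)                              | 2/4  |

The laboratory items are strict-threshold indicators: WBC > 11 (or,
optionally, > 12) x 10^9/L, CRP > 20 mg/L, temperature > 38.5 °C, and
neutrophilia as an OR of the absolute (> 7.9 x 10^9/L) and percentage
(> 75 %) criteria. All comparisons are strict: a value exactly at the
cutoff is negative. Positivity is inclusive (`total >= cutoff`); the
printed cutoffs such as 3 of 5 unit items are only discriminative as
inclusive bounds.

Three design choices deserve a note because the published material leaves
them open. First, the WBC cutoff is printed as ">12/>11" without assigning
variants to scores; the package defaults every score to 11 x 10^9/L (the
value the primary cohort used) and exposes the 12 x 10^9/L variant through
`threshold_policy(wbc_cutoff = 12)`. Second, neutrophilia honours either
recorded criterion: it is positive if any recorded branch exceeds its
cutoff, negative if at least one branch is recorded and none exceeds, and
missing only when both branches are missing. Third, "anorexia / urine
acetone" is treated as anorexia alone; urinalysis substitution is not
modelled. Missingness is always represented as an explicit third state —
a missing lab never silently contributes zero points; it makes the score
incomplete, and the complete-case policy of `apply_scores()` decides
exclusion (mirroring the 456/463 complete-case analysis of the reference
cohort).

## The evaluation panel

`diagnostic_panel()` reports sensitivity, specificity, PPV, NPV, LR+, LR−
and ROC-AUC with 95 % intervals. The methods are the standard
diagnostic-accuracy toolkit, chosen because the original report does not
state its CI methods:

* proportions: Wilson score intervals (never degenerate at 0 or 1);
* likelihood ratios: the log method,
  `exp(log(LR) ± z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`;
* AUC: the Mann–Whitney statistic (trapezoidal ROC over all integer
  thresholds, ties at half credit) with the DeLong variance;
* alternatively, a seeded patient-level nonparametric bootstrap
  (2000 resamples by default) for every statistic at once.

A statistic with a zero denominator is reported as `NA`, never coerced to
0. For a purely binary test (no graded totals) the two-point trapezoid
`(sens + spec)/2` is available as `two_point_auc()` but is deliberately
not labelled an AUC of the underlying score. Two dichotomies are
supported: appendicitis vs none over the whole cohort, and perforated vs
non-perforated *within* appendicitis cases (non-appendicitis patients are
excluded from the perforation contrast; the published NPV magnitudes are
only consistent with that reading).

`invert_feature_row()` reconstructs a 2x2 table from a published
(present, PPV, NPV) row — TP and TN by rounding half away from zero, FP
and FN by subtraction so the margins are preserved — and reports the
`consistency_gap` between the implied and the reported case count. Several
published rows are internally inconsistent (the rebound-tenderness row
implies roughly 371 cases against the reported 336); the package surfaces
these gaps and never silently corrects a printed number.

## The cohort simulator

`generate_cohort()` draws synthetic abdominal-pain cohorts so that every
routine in the package is testable without patient data. Defaults encode
the reference cohort: n = 463; class mix 127 : 234 : 102 for
no appendicitis : simple : perforated; per-class ages 11.6 (3.7),
10.9 (3.3), 10.0 (4.2) years as truncated normals on (1, 17); female
fractions 53/127, 143/234, 70/102; symptom durations 57.8 (73.4),
34.3 (39.7), 52.1 (48.7) hours as moment-matched lognormals (the SDs are
of the same order as the means, which is incompatible with a positive
normal; the duration ordering is resolved so that simple appendicitis has
the *shorter* history, as stated in the source's text); and a joint
lab/ultrasound missingness of 7/463 — clinical findings are never missing.

Feature probabilities come from `calibrate_feature_probs()`: each
published (present, PPV, NPV) row is inverted to a 2x2 table and converted
to `P(feature | case) = tp/336`, `P(feature | non-case) = fp/127`. Rows
whose implied case count misses the reported margin by more than the
tolerance (default 5 patients) are renormalized — the gap distributed
proportionally over TP and FN, FP recovered from the fixed `present`
margin — and every adjustment is listed in the report. The temperature row
(present 312/463 with PPV 97.4) is particularly hard to reconcile with a
> 38.5 °C definition; its calibrated probability is taken at face value
after renormalization and carries a flag.

Continuous labs are generated by a two-component construction: the
thresholded indicator is drawn first, then a magnitude on the indicated
side of the strict cutoff (`cutoff * (1 + offset)` above,
`cutoff / (1 + offset)` below, with a lognormal relative offset). The
magnitudes are synthetic conveniences — only the thresholded indicators
are calibrated; nothing downstream interprets the raw values beyond the
thresholds.

Two simplifications matter for interpreting green tests. Features are
conditionally independent given class, because no joint distribution is
published; real clinical findings are correlated (peritonism clusters,
labs rise together), so simulated score AUCs run somewhat higher than
observed ones. And because the published feature rows only condition on
appendicitis vs none, simple and perforated cases share one probability
vector: the simulator is *not* calibrated for perforation discrimination,
and perforation-dichotomy panels on simulated data hover near chance by
construction. Passing tests therefore validate the machinery and the
appendicitis contrast, not perforation-specific performance on real
children.

```{r}
cohort <- generate_cohort(cohort_parameters(seed = 1))
summarize_cohort(cohort)$classes
```

## Score derivation: CART and the random forest

`fit_cart()` grows a classification tree on the binarized items by greedy
Gini gain, with ties broken by feature declaration order (deterministic),
no feature reused along a path (pointless for binary splits), and growth
stopped by purity, `min_leaf` (default 5) or a depth cap. Pruning is
weakest-link cost-complexity on the misclassification scale: a split
survives only if it buys at least `complexity` (default 0.01, in units of
training error fraction) per added leaf; `complexity = 0` keeps the full
tree. The published development only says the tree "was pruned for a small
risk value", so the default is a conventional one, not a reconstruction.
Two finite-sample facts are worth knowing: with balanced classes even
label-independent splits shift both child majorities by order sqrt(n)
samples and can survive moderate pruning (the stump limit is only clean
under unbalanced classes, as in this cohort), and greedy Gini splitting
does not in general attain the accuracy-optimal depth-limited tree — the
equivalence tests use noisy-OR cohorts, where a depth-2 tree expresses the
generating rule exactly and greedy search recovers it.

`fit_forest()` bags 200 such trees (grown to purity, `min_leaf = 1`) on
bootstrap resamples with `mtry = ceiling(sqrt(p))` candidate features per
split, drawn from all features as in conventional forests. Importance is
the normalized mean decrease in Gini impurity; `permutation_importance()`
offers the out-of-bag alternative. On identical cohorts the normalized
importances agree with the `randomForest` reference implementation to
within ±0.01 per feature.

`derive_score()` wires these into the published development loop: 20
random 70/30 train/test splits, importances averaged across repeats,
features at or above `importance_floor` (default 0.05) retained, and a
unit-weight score assembled from them. The published material never states
how the tree became a 5-item unit score with a 3/5 cutoff; this package's
reconstruction picks the cutoff maximizing the Youden index on the pooled
test splits, breaking ties toward the lower (more sensitive) cutoff, which
is the clinically conservative choice for a rule-out instrument.
Derivation aborts informatively when no feature reaches the floor (the
pruned-CART noise limit) or when the derived score's pooled-test Youden
index is not positive; note that *normalized* forest importances on pure
noise concentrate near 1/p rather than zero, so a meaningful forest floor
must sit above that level.

```{r}
dr <- derive_score(cohort[derive_features(cohort)$complete, ],
                   method = "forest", repeats = 5, n_trees = 50, seed = 1)
dr$importance[1:5, ]
dr$definition
```

On cohorts calibrated to the published feature rows, ultrasound dominates
the importance ranking in every seed, as in the original report. The
published second rank (CRP) is reproduced only in roughly six of ten
seeds: under conditional independence the calibrated discriminability of
CRP (0.83 vs 0.42 across classes) barely exceeds that of tenderness,
fever, and rebound, several of whose published rows had large consistency
gaps and were renormalized. The `randomForest` reference shows the same
behaviour on the same simulated cohorts, so the shortfall reflects the
calibration's information content, not the forest implementation.

## Problem sizes and numerical choices

The test-suite simulations use cohorts of 463 (the reference size) for
calibration checks, 10^4 for parameter recovery (20 seeds), and 10^5 for
law-of-large-numbers checks; forests in tests use 25–300 trees. Identity
closures (LR, Bayes) are asserted to 1e-12; implied-count inversions to
half a reporting unit. All randomness flows through explicit seeds, and
seeded routines restore the caller's RNG state, so results are
bit-reproducible.

## Known limitations

* Conditional independence given class is the simulator's central
  simplification; it overstates score separation relative to real cohorts.
* Perforation-specific feature frequencies are not published, so the
  simulator carries no perforation signal.
* Published confidence intervals cannot be exactly attributed to a method;
  Wilson/log/DeLong are conventional choices, and the bootstrap is offered
  where a single convention is not wanted.
* Scores are evaluated on complete cases only, as in the reference
  analysis; no imputation is provided.
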