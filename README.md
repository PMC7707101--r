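# appendiscore

Clinical risk scores for suspected appendicitis in children, and the
machinery to evaluate and re-derive them.

Suspected appendicitis is the most common surgical presentation in
pediatric emergency departments, and additive clinical scores are the
standard decision aids: a weighted sum of binary items (examination
findings, strict-threshold laboratory indicators, an ultrasound read),
dichotomized at a published cutoff. `appendiscore` is for
biostatisticians and clinical researchers who need to

* **score** patients with any of six published systems — Alvarado (5/10),
  Pediatric Appendicitis Score (6/10), Tzanakis (8/15), Heidelberg
  Appendicitis Score (3/4), modified HAS (3/5), and the random-forest
  derived "AI" score (2/4) — on a common item vocabulary with explicit
  missing-data semantics;
* **evaluate** them with the full diagnostic-accuracy panel: sensitivity,
  specificity, PPV, NPV, likelihood ratios (LR+ = sens/(1−spec),
  LR− = (1−sens)/spec), and ROC-AUC, each with 95% confidence intervals
  (Wilson score / log method / DeLong, or a seeded bootstrap), for the
  appendicitis-vs-none and the perforated-vs-non-perforated dichotomies;
* **audit** published summary tables: `invert_feature_row()` reconstructs
  the 2×2 table implied by a (present, PPV, NPV) row and reports its
  consistency gap against the case margin, and
  `ppv_npv_from_sens_spec_prev()` / `lr_from_sens_spec()` recompute panel
  cells through the Bayes and likelihood-ratio identities;
* **simulate** seeded synthetic abdominal-pain cohorts calibrated to a
  published two-center cohort of 463 children (336 appendicitis: 234
  simple, 102 perforated), so everything is testable without patient
  data;
* **re-derive** scores from data with a from-scratch CART (Gini
  splitting, weakest-link cost-complexity pruning) and a bagged random
  forest (200 trees, Gini importance), wrapped in the published 20×70/30
  train/test development loop (`derive_score()`).

## Worked example

```r
library(appendiscore)

p <- patient_record("p1", age = 9, sex = "male", duration_h = 18,
                    tenderness_rlq = TRUE, rebound_tenderness = TRUE,
                    nausea_vomiting = TRUE, temperature_c = 38.9,
                    wbc = 14.2, neutrophils_abs = 9.1,
                    neutrophils_pct = 82, crp = 31,
                    us_appendicitis = TRUE)
compute_score(p, builtin_scores("alvarado")[[1]])
#> <score_result> alvarado: total 8, POSITIVE
compute_score(p, builtin_scores("mhas")[[1]])
#> <score_result> mhas: total 5, POSITIVE
```

Tenderness (2) + rebound (1) + nausea (1) + fever (1) + WBC 14.2 > 11 (2)
+ neutrophilia (1) give Alvarado 8 of 10, past its cutoff of 5; the
modified HAS scores all five of its unit items.

A full simulated study, seeded and bit-reproducible:

```r
cohort <- generate_cohort(cohort_parameters(seed = 1))   # 463 children
scored <- apply_scores(cohort)
scored
#> <score_matrix> 458 patients scored, 5 excluded (of 463)
ev <- evaluate_scores(scored, "appendicitis")
ev$panels[, c("score", "sens", "spec", "ppv", "npv", "auc")]
#>      score  sens  spec   ppv   npv   auc
#> 1 alvarado 0.845 0.691 0.896 0.585 0.853
#> 2      pas 0.491 0.882 0.929 0.354 0.828
#> 3 tzanakis 0.905 0.882 0.960 0.746 0.953
#> 4      has 0.489 1.000 1.000 0.382 0.897
#> 5     mhas 0.940 0.709 0.911 0.788 0.917
#> 6       ai 0.960 0.555 0.872 0.813 0.910
```

Five patients lost their laboratory/ultrasound block (the simulator's
calibrated 7/463 missingness) and are excluded from every score's
evaluation, mirroring a complete-case analysis. The unit-weight scores
that include ultrasound and CRP (mhas, ai) trade specificity for the high
sensitivity that matters for ruling out perforation.

Panels can also be built from raw counts:

```r
diagnostic_panel(confusion_counts(tp = 263, fp = 27, fn = 73, tn = 93))
#> <diagnostic_panel> appendicitis, n = 456
#>   sens   78.3 (73.6-82.4)
#>   spec   77.5 (69.2-84.1)
#>   ppv    90.7 (86.8-93.5)
#>   npv    56.0 (48.4-63.4)
#>   lr_pos 3.48 (2.48-4.87)
#>   lr_neg 0.28 (0.22-0.35)
```

`run_pipeline(n = 463, seed = 1, outdir = "report")` chains
simulate → score → evaluate → report into CSV/JSON tables (feature
predictive values, both dichotomy panels, the missed-perforation
counterfactual, and the underlying confusion matrices). A command-line
front end with `simulate` / `score` / `evaluate` / `derive` / `report`
subcommands ships at
`system.file("cli", "appendiscore.R", package = "appendiscore")`.

See the vignette (`vignettes/appendicitis-scores.Rmd`) for the score
definitions, the calibration of the simulator, the CART/forest
derivation machinery, and the package's design choices.

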