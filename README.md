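# evpanel

Combinatorial biomarker panel discovery from targeted proteomics of plasma
extracellular vesicles (EVs).

## The scientific problem

High-grade serous carcinoma (HGSC), the most lethal epithelial ovarian
cancer, is usually detected late.  Plasma EVs carry tumour-derived protein
cargo, and targeted mass spectrometry (parallel reaction monitoring, PRM) can
quantify hundreds of candidate peptides in EV digests from small case/control
cohorts.  The analytical challenge is everything that happens after
acquisition: turning transition-level signals into a trustworthy peptide ×
sample matrix, screening it for group differences, finding *small
combinations* of peptides that classify HGSC versus benign gynaecological
disease on genuinely held-out samples, explaining what drives the
classifier, and validating a lead marker on an orthogonal platform (ELISA).

`evpanel` implements that pipeline end to end for analysts working in R,
driven by a synthetic-cohort generator with planted ground truth so that
every stage is testable without any patient data.

## What is inside

| Stage | Functions | Method |
|---|---|---|
| Synthetic cohorts | `cohort_config()`, `generate_quant_study()`, `simulate_study()`, `generate_elisa_plate()` | log-normal abundances, per-sample loading, planted folds, MNAR censoring, interference, 4PL plates |
| PRM quantification | `apply_interference_filter()`, `tic_normalize()`, `reference_normalize()`, `impute_mnar()` | dotp = normalized √-intensity dot product; strict `dotp < 0.8` / `ppm > 20` / `< 3 transitions` zeroing; TIC then CD9-reference normalization; minimum-value imputation |
| Scheduling & curation | `calibrate_rt()`, `schedule_windows()`, `curate_peptides()`, `select_top_transitions()`, `gpf_scheme()` | iRT regression with `r > 0.95` QC; 7–18 aa / no-W / ≤ 3 peptides-per-protein rules; staggered GPF-DIA window arithmetic |
| Differential screen | `welch_t()`, `wilcoxon_rank_sum()`, `volcano_table()`, `downshift_impute()` | exact small-n Wilcoxon, log2 ratio of group means, candidates = significant ∪ forced |
| Panel discovery | `zscore_scale()`, `stratified_split()`, `pca_project()`, `train_linear_svm()`, `loocv_score()`, `grid_triangulate()`, `combination_search()`, `roc_auc()`, `kmeans_vmeasure()`, `logistic_fit()` | z-score → PCA → linear SVM (`½‖w‖² + C Σξ`), LOOCV-pooled MCC, exhaustive k-subset search ranked by held-out rank-AUC |
| Attribution | `exact_shapley()`, `attribute_samples()`, `rank_drivers()` | exhaustive-coalition Shapley values, background-mean marginalization |
| ELISA validation | `background_correct()`, `fit_standard_curve()`, `interpolate_concentration()`, `optimal_threshold()`, `evaluate_marker()`, `quantify_plate()` | OD450 − OD570, 4PL `y = d + (a−d)/(1+(x/c)^b)` fit and analytic inverse, Youden-J threshold |
| Orchestration | `pipeline_config()`, `run_pipeline()`, readers/writers | cohort profiles, provenance-checked normalization order, reproducible bundles |

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` views.

## Worked example

Simulate the 10-case / 9-control cohort with the two MUC1 peptides planted
at their reported fold changes (3.14 and 8.86), then run the full discovery
pipeline with a 4 + 3 held-out split and an exhaustive 2-peptide search:

```r
library(evpanel)

cfg <- cohort_preset("cohort1", n_peptides = 25,
                     planted_effects = c(QGGFLGLSNIK = 3.14,
                                         DISEMFLQIYK = 8.86),
                     noise_cv = 0.2, seed = 42)
pc  <- pipeline_config("cohort1", cohort = cfg,
                       split = split_config(test_counts = c(HGSC = 4, Benign = 3),
                                            random_state = 6),
                       k = 2, n_components = 2, cost = 0.025, seed = 42)
res <- run_pipeline(pc)
res
#> <ev_pipeline_result>
#>   quant: 25 peptides x 19 samples (interference_filter -> tic -> reference -> imputed)
#>   screen: 3 significant, 3 candidate peptide(s)
#>   panels: 3 combination(s); best 'DISEMFLQIYK + MIEEGCSQFECR' test ROC-AUC = 1.000

head(as.data.frame(res$volcano)[, c("peptide_sequence", "log2_fold_change",
                                    "p_value", "significant")], 3)
#>   peptide_sequence log2_fold_change p_value significant
#> 1      DISEMFLQIYK            3.166 0.00028        TRUE
#> 2      QGGFLGLSNIK            1.993 0.00028        TRUE
#> 3     MIEEGCSQFECR            0.399 0.04546        TRUE
```

The two planted peptides are recovered with log2 fold changes near
log2(8.86) = 3.15 and log2(3.14) = 1.65 plus sampling noise, one filler
peptide squeaks under α = 0.05 (as ~1 of 23 nulls should), and the
top-ranked pair separates the held-out samples perfectly (rank ROC-AUC 1.0 —
note that at C = 0.025 the LOOCV MCC on the training split is negative,
a documented property of heavily regularized SVMs under leave-one-out, which
is why panels are ranked by held-out AUC).  Shapley attribution
(`res$drivers`) ranks the strong planted peptide first.

The acquisition arithmetic and ELISA stages are one-liners:

```r
gpf_scheme(300, 1000, fraction_width = 100, window_width = 4, staggered = TRUE)
#> <ev_gpf_scheme> 300-1000 m/z: 7 injection(s) of 100 m/z, 4 m/z windows (staggered), 2 m/z demux bins

plate <- generate_elisa_plate(18, 18, curve = four_pl(0.05, 3.2, c = 150, b = 1.2),
                              effect = 3, seed = 7, noise_cv = 0.03)
qp <- quantify_plate(plate)
qp$standard_curve
#> <ev_standard_curve> 4PL: a = 0.05461, d = 3.17, c = 146.7 U/mL, b = 1.23; RSS = 0.000118 (6 points)

evaluate_marker(qp$samples$concentration, qp$samples$group, case = "HGSC")
#> <ev_marker_report> Mann-Whitney p = 4.5e-07; logistic ROC-AUC = 0.994;
#>   Youden threshold = 1163 (J = 0.94, sens 0.94 / spec 1.00)
```

Here the fitted 4PL recovers the generating curve (inflection 146.7 vs 150
U/mL under 3% OD noise), and the planted 3-fold concentration shift is
detected with near-perfect discrimination.

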