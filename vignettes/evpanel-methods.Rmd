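---
title: "Methods: from PRM transition areas to combinatorial biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from PRM transition areas to combinatorial biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evpanel)
```

# The problem this package addresses

High-grade serous carcinoma (HGSC) is usually diagnosed late; the hope of
liquid-biopsy proteomics is that extracellular vesicles (EVs) circulating in
plasma carry tumour-derived protein cargo detectable before imaging does.
`evpanel` implements the computational arm of such a study end to end:
targeted (parallel reaction monitoring, PRM) quantification of pre-selected
peptides in plasma-EV digests, differential screening of HGSC versus benign
gynaecological controls, exhaustive search over small peptide panels with a
PCA + linear-SVM classifier tuned by leave-one-out cross-validation (LOOCV),
exact Shapley attribution of the winning panels, and orthogonal validation of
a single marker by sandwich ELISA.

Every stage is driven by a synthetic-cohort generator with planted ground
truth, so the whole pipeline is testable on a laptop with no patient data.

# The synthetic-data model

## Abundances

For peptide $p$ and sample $s$ the generator draws

$$
X_{ps} = \exp\!\big(m_p + \log(f_p)\,[s \in \text{case}] + \varepsilon_{ps}\big)\cdot L_s,
$$

where $m_p \sim \mathcal N(\mu_0, \sigma_0^2)$ is the peptide's baseline
log-abundance, $f_p$ the planted linear fold change (1 for null peptides),
$\varepsilon_{ps} \sim \mathcal N(0, \sigma_\varepsilon^2)$ multiplicative
biological noise, and $L_s$ a log-normal per-sample loading factor with mean
1.  Defaults: $\mu_0 = 14$, $\sigma_0 = 1.5$ (natural-log scale, spanning the
dynamic range of transition areas), within-group CV 20%
(`noise_cv = 0.2`, via $\sigma_\varepsilon = \sqrt{\log(1+\mathrm{CV}^2)}$)
and loading CV 25% (`tic_cv`).  The loading factor is applied
multiplicatively to *all* peptides of a sample: this is exactly the nuisance
that total-ion-current (TIC) normalization must remove, and makes that
removal exactly invertible in the noise-free limit.  `noise_cv` is the
generator's one dial the abundance model strictly needs beyond the cohort
sizes; the cohort presets (`"cohort1"` = 10 cases / 9 controls, `"cohort2"` =
30 / 30) fix the sample sizes of the two study designs, and the planted
defaults used throughout the tests are the printed 3.14- and 8.86-fold
effects.

## Censoring, interference, chromatograms

Missingness is *left-censoring on the loading-adjusted abundance*: every cell
whose $X_{ps}/L_s$ falls below the `detection_limit_quantile` of the global
abundance distribution records area 0 and a censoring flag.  This is
missing-not-at-random by construction, which is the premise of the
minimum-value imputation rule downstream.  Random dropout is deliberately not
modelled.

A transition-level report is generated by splitting each cell's area across
its library transitions in proportion to the library relative intensities
(Gaussian elution profiles whose apex heights carry those proportions; only
the integrated areas are reported).  Interference-flagged cells instead
receive weights drawn independently of the library pattern (i.i.d.
exponential), so their expected spectral contrast (dotp) is low, and their
mass errors are drawn with a wider sd (15 vs 3 ppm).  Retention times are
library iRT values mapped through a configurable per-sample linear drift plus
jitter.  The constitutive reference peptide (a CD9 analog, default sequence
`EVQEFYK`) is placed high in the abundance distribution and exempted from
censoring and interference — a constitutive, high-abundance control is
exactly what makes reference normalization well-defined.

What the generator does *not* emulate: raw spectra, fragmentation physics,
retention-time-dependent interference, correlated peptide co-regulation
within a sample (features are independent given the loading factor), and
batch structure.  Tests passing on this generator therefore demonstrate the
*procedures* — normalization algebra, filter boundary semantics, ranking and
attribution logic, statistical calibration — not performance on real plasma.

## ELISA plates

Standards are a 6-point, 3-fold serial dilution from 1000 U/mL down to
$1000/3^5 \approx 4.1$ U/mL, run in duplicate wells (kit convention), passed
through a four-parameter-logistic (4PL) forward curve with multiplicative OD
noise; samples are drawn log-normally per group with a planted concentration
fold change and diluted 60-fold (2 × 30) before OD generation.

# The quantification chain

The chain is strictly ordered, and each step records itself in a provenance
attribute so out-of-order calls fail:

raw transition areas → **interference filter** → **TIC normalization** →
optional **reference normalization** → **MNAR imputation**.

* **Interference filter.**  A peptide-by-sample cell's area is the sum of its
  transition areas.  The cell is zeroed when its dotp is *strictly below* the
  threshold, its absolute area-weighted mean mass error *strictly exceeds*
  the ppm tolerance (when one is set), or fewer than `min_transitions`
  transitions have positive area.  The strict inequalities are deliberate
  boundary semantics and are unit-tested at the threshold.  dotp is the
  normalized dot product of the element-wise square roots of library and
  observed intensities — the spectral-contrast convention of the targeted-
  proteomics tooling this report dialect comes from; it is scale-invariant
  and returns 0 for empty patterns.
* **TIC.**  Defined here as the summed integrated transition area of the run;
  a user-supplied TIC vector (e.g. MS1-based) is accepted.  Division by the
  TIC removes the planted loading factor exactly in the noise-free limit.
* **Reference peptide.**  Dividing each sample by its reference-peptide value
  corrects for EV recovery; it also cancels the TIC factor entirely, which is
  why the noise-free round trip recovers planted folds *exactly* only after
  this step — TIC-only ratios additionally carry the ratio of the group total
  signal whenever folds are planted.
* **Imputation.**  Zeros are replaced by the smallest positive value of the
  peptide's row and flagged; peptides never detected anywhere are dropped
  with a warning (the minimum rule is undefined for them).

Two acquisition profiles bundle the thresholds: `"cohort1"` (static PRM)
uses dotp ≥ 0.8, ≤ 20 ppm, top-5 transitions, reference normalization on;
`"cohort2"` (dynamic-retention-time PRM) uses dotp ≥ 0.4, no ppm rule, top-8
transitions, TIC only.  Retention-time calibration regresses observed RT on
iRT and passes QC only when Pearson $r > 0.95$ (strict); scheduling centres
windows of the requested width (8 min static, 3 min dynamic) on the
calibrated prediction plus any cumulative drift correction.

# Library curation and GPF-DIA window arithmetic

Curation removes peptides with missed tryptic cleavages (internal K/R not
followed by P — the standard rule; the outcome, not the rule, is what the
monitoring protocol states), tryptophan-containing peptides
(oxidation-prone), and peptides outside 7–18 residues; optional CV and
product-ion minima apply to library replicates.  At most 3 peptides per
protein are kept, ranked by summed library intensity — a conventional
detectability proxy chosen here because the protocol does not name its
ranking key — with lexicographic tie-breaks for determinism.

Gas-phase fractionation schemes tile a precursor range (default 300–1000
m/z) into equal fractions acquired in separate injections, each fraction
covered by isolation windows; staggered schemes add a second pass offset by
half a window, doubling the window count and halving the effective
demultiplexed bin width.  The 100 m/z × 4 m/z staggered design yields 7
injections of 50 windows with 2 m/z bins; a 24 m/z staggered scheme over the
full range yields 12 m/z bins.  When the window width does not divide the
fraction evenly (as in the 24 m/z case) the final window of a pass overhangs
the fraction edge, as instruments acquire it; the fraction width must still
divide the mass range exactly.

# Differential screening

The screen computes per-peptide log2 fold change — ratio of *arithmetic*
group means of normalized abundances by default (a geometric-mean option
exists), since the volcano convention does not fix the estimator — and a
two-sample test: Wilcoxon rank-sum (the cohort-1 screen) or Welch's *t*.
The Wilcoxon p-value is exact by enumeration when the pooled sample size is
at most 12 and tie-free, otherwise a normal approximation with tie and
continuity corrections; the two paths agree within 0.02 absolute p at
6 + 6.  Significance is called at strict $p < 0.05$ with no multiple-testing
correction, matching the screening procedure (a Benjamini–Hochberg option is
available but off by default — the candidate list feeds a held-out-validated
search, which is where error control actually happens).  A `force_include`
list lets prior-knowledge markers (the MUC16 peptide `ELGPYTLDR` in the
motivating study) join the candidates regardless of p.

Gaussian down-shift imputation (`width = 0.3`, `shift = 1.8`, per observed
column moments on the log scale) is provided for discovery-stage matrices
with missing values.

# Panel discovery

Features are z-scored with *population* (n-denominator) statistics — the
convention is fixed and tested because the two denominators differ
detectably at these sample sizes — computed on the training split only and
applied unchanged to held-out data.  PCA is fit on the scaled training
matrix; a linear soft-margin SVM (objective
$\tfrac12\lVert w\rVert^2 + C\sum_i \xi_i$) is trained on the projected
scores.  Splits are always stratified; because the published 70/30 language
is inconsistent with the printed per-class test counts (4 + 3 of 19,
10 + 10 of 60), explicit per-class counts are first-class configuration and
fractions fall back to round-half-up per class.

LOOCV refits the *entire* pipeline — scaling, PCA, SVM — inside every fold
(leakage-free; whether the original analysis refit the projection per fold
is unstated, so this implementation does and says so), and reports the
Matthews correlation coefficient on the pooled held-out predictions plus the
pooled accuracy.  Per-fold MCC is undefined for single left-out samples,
which is why pooling is the only coherent reading of "mean accuracy score
using MCC"; both numbers are reported.

Two behaviours of this design are worth knowing:

* At very small cost (C = 0.025) on low-dimensional panels the SVM is
  heavily regularized: decision values cluster on one side of zero and LOOCV
  predicts the majority class of each balanced remainder — which is always
  the *opposite* of the held-out label, so pooled LOOCV MCC can be strongly
  negative while the held-out ROC-AUC (a rank statistic, insensitive to the
  bias term) is 1.0.  This is a property of the procedure, not a defect, and
  is why held-out AUC — not LOOCV score — ranks panels.
* LOOCV MCC under label permutation is centred on zero but *noisy* and
  slightly negative at n = 19 (each estimate pools only 19 predictions, and
  leave-one-out is intrinsically pessimistic); its mean over permutations is
  near 0 while its mean absolute value is not small.

The combinatorial search fits one pipeline per unordered $k$-subset of the
candidate features on the *fixed* training split and scores each panel once
on the *fixed* held-out split by rank-based ROC-AUC (concordant + half of
tied pairs over case-control pairs); 22 candidates at $k = 2$ gives
$\binom{22}{2} = 231$ panels.  Ranking is by test AUC with ties broken by
LOOCV MCC and then lexicographic feature ids.  With small test sets many
panels tie at AUC 1.0 and the identity of the single top panel among ties is
not meaningful; recovering *both* planted markers as the unique top pair is
a large-sample property, demonstrated in the tests on a 100 + 100 cohort
with 35 + 35 held out.  The hyperparameter grid defaults to
C ∈ {0.025, 0.05, 0.1, 0.25, 0.5, 1, 2} × components ∈ {2, 3, 5, 10} (the
published account names only the C endpoints); `grid_triangulate()` flags
cells with mean LOOCV accuracy strictly above 0.90 and reports its own fit
count rather than targeting any particular total.

Companions: `kmeans_vmeasure()` (Lloyd's algorithm, multiple restarts,
V-measure = harmonic mean of homogeneity and completeness against the true
labels) for the unsupervised view, and `logistic_fit()` (IRLS, perfect
separation flagged) for single-marker ROC analysis.

# Shapley attribution

Panels are explained by exact Shapley values over the original features:
coalitions are enumerated exhaustively (panels here are ≤ 10 features; the
bound is 15), absent features are marginalized by substituting background
means (the training split), and for the end-to-end linear pipeline the
result provably equals $\tilde w_i (x_i - \bar b_i)$ in composed
coefficients — an identity the tests assert against both the closed form and
an independent permutation-averaging oracle.  Efficiency (values sum to the
decision minus the base value) is asserted to $10^{-8}$ on every sample.
The background/marginalization choice (training split, independent-features
interventional substitution) matches the common linear explainer; the
original analysis does not state its variant.

# ELISA quantification

Corrected absorbance is OD450 − OD570.  The standard curve is a 4PL,
$y = d + (a-d)/(1+(x/c)^b)$, fit by Levenberg–Marquardt least squares to the
replicate-averaged standards (4PL rather than linear-log because sandwich
ELISAs saturate at both ends; the sign of $b$ is constrained to the
monotone direction of the standards).  Concentrations invert the curve
analytically and multiply by the dilution factor (default 60); ODs outside
the open asymptote interval are flagged below/above the quantification
limit rather than extrapolated.  The diagnostic threshold maximizes
Youden's $J$ over midpoints between sorted unique values, ties resolved
toward higher specificity — the published threshold's derivation method is
unstated, and Youden's $J$ is the standard choice; a fixed-specificity
alternative is exposed through the same report.  Units (U/mL vs mU/mL) are
treated as user-declared metadata and never converted silently.

# Numerical choices and degenerate inputs

* SVM dual tolerance defaults to $10^{-6}$ and is tightened to $10^{-10}$
  when comparing against the quadratic-programming reference in the tests.
* Decision-value orientation is normalized after fitting so positive always
  means the case class, independent of label order.
* `welch_t` returns $t = 0, p = 1$ for two identical zero-variance groups
  and errors for shifted zero-variance groups (the statistic is undefined).
* Peak integration subtracts the mean of the two window-endpoint intensities
  as baseline and floors the trapezoidal integral at zero.
* `dotp` returns 0 (not NaN) when either pattern is all zero.
* All-missing peptide rows are dropped, with a warning, before imputation.
* Empty k-means clusters are re-seeded by `stats::kmeans` restarts.
* Every stochastic routine takes an explicit seed and uses it through
  `withr::with_seed`, so identical configurations are byte-identical.

# Problem sizes used in the test-suite simulations

Simulation-based checks use: 100 seeded 10 + 9 cohorts of 25 peptides for
planted-panel recovery; a 501-peptide null cohort for type-I calibration
(generated with `tic_cv = 0`, because the screen operates on normalized
matrices where the shared loading factor has already been removed — with raw
loaded areas the 500 tests would be strongly correlated and a binomial band
meaningless); 100 seeded ELISA plates for 4PL recovery under 5% OD noise;
200 label permutations at n = 19 for the LOOCV null; and a 100 + 100 cohort
for top-pair consistency.  These sizes were chosen so each check has clear
statistical resolution while the whole suite stays quick to run.

# Known limitations

* Features are simulated independently; real EV proteomes are co-regulated,
  so panel-search behaviour on correlated candidates is not characterized
  here.
* The generator's noise model (multiplicative log-normal) is asserted, not
  estimated from instrument data.
* No protein-level roll-up: all statistics are at peptide level.
* No nonlinear kernels, nested cross-validation, or class weighting; none
  appear in the procedure this package implements.
* The published patient-level results (thresholds, AUCs on real cohorts)
  depend on unavailable plasma measurements; this package reproduces the
  procedures and their forced analytic/combinatorial consequences, and
  validates the rest on synthetic data.
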