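---
title: "mpnscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mpnscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mpnscope` implements an end-to-end analysis pipeline for a simulated
pharmaco-proteogenomic study of myeloproliferative neoplasms (MPN): an
image-based ex vivo drug screen ("pharmacoscopy") on patient blood cells,
cell-type-resolved proteome matrices ("proteotypes"), clinical
annotations with driver-mutation allele burden (VAF), and the analyses
that join them. Because no patient data ships with the package, a seeded
synthetic-cohort generator with *planted, machine-readable ground truth*
stands in for the measurement process; every statistical module is
validated by recovering what was planted.

This vignette documents the generative model, the statistical choices,
and their limits. The worked example lives in the repository `README.md`
and the runnable workflow in `analysis/01_simulate.R` through
`analysis/06_integrate.R`.

# The synthetic study

## Cohort model

`simulate_cohort()` draws one row per patient over five disease-by-driver
groups: healthy donors (HD), essential thrombocythemia with CALR or JAK2
driver (ET-CALR, ET-JAK2), and myelofibrosis likewise (MF-CALR,
MF-JAK2). Heterozygous patients draw VAF from U(20, 60) percent; a
configurable fraction of MF-CALR patients is drawn homozygous with VAF
from U(75, 100), and *homozygous* is defined operationally as VAF ≥ 75.
Age, sex, peripheral-blast percentages and a treatment flag are drawn to
emulate a matched cohort but carry no planted signal by default.

All stochastic stages derive their seeds from a single root seed through
`stream_seed(seed, stream)`, a small linear-congruential mix. Distinct
streams (cohort = 1, proteomes = 2, plates = 3, gene sets = 4, edges =
5, classifier = 6, imputation = 7, enrichment = 8, RFE = 9) make each
stage independently replayable while one integer reproduces the whole
study.

## Proteome model

`simulate_proteomes()` emits one log2 intensity matrix per cell type
(granulocyte, HSPC, T-cell) from an additive model:

$$x_{ps} = b_p + \sum_k \text{block}_k(p, s) + \varepsilon_{ps},
\qquad \varepsilon_{ps} \sim N(0, \sigma^2)$$

with per-protein baselines $b_p \sim N(20, 2^2)$ on the log2 scale.
Effect blocks are the planted truth:

* **group_discriminative** — a fixed log2 shift per clinical group over a
  protein block; three such 5-protein blocks (disease-general,
  MF-specific, CALR-specific) generate a 15-protein classifier target
  whose structure mirrors multi-directional disease biology rather than
  a single rank-one contrast.
* **vaf_scaled** — expression increases linearly with VAF (log2 units
  per percent), feeding the mutation-load correlation analyses.
* **anchor_coregulated** — a per-patient latent "replicative activity"
  score, *shared across cell types*, loads on a 50-protein block
  anchored by MCM4/MCM7.
* **contaminant_loading** — a lognormal per-sample red-blood-cell
  contamination latent loads on the hemoglobins HBA/HBB/HBD and,
  optionally, on bystander proteins; this is what the regression stage
  must remove.

Missingness is two-stage: per-protein left-censoring at an empirical
quantile (default 5%) models detection limits, then a small
missing-completely-at-random rate (default 2%) is applied. The censoring
uses the *empirical* quantile of the generated values, so the censored
fraction is exact by construction rather than approximate.

## Pharmacoscopy model

`simulate_pharmacoscopy()` builds per-patient plates from a drug library
in which small molecules run in duplicate at two concentrations against
DMSO control wells, and biologics/antibodies in triplicate at three
concentrations against PBS/isotype controls. Each well seeds a Poisson
number of cells (default mean 10,000, matching a high-content 384-well
screen; the workflow and tests use fewer). Cell classes (HSPC, T-cell,
monocyte, other) are drawn per patient from a composition whose HSPC
fraction is uniform on the log scale over a configured range, with an
option to plant patients below the 0.3% quality-control threshold.

Per-cell channel intensities are lognormal with class-specific location
parameters: a multiplexed lineage channel high in T-cells and monocytes,
CD34 high in HSPCs, and an oncogenic marker high in HSPC/monocyte and
low in T-cells. The draw order matters: the oncogenic channel is drawn
first, marker positivity is determined against the generative threshold,
*then* planted drug effects thin viable targeted cells (HSPC readout:
viable HSPCs; oncogenic readout: viable marker-positive cells), and only
then are the morphology channels drawn with viability-dependent
parameters — so killed cells acquire dead morphology and the classifier
sees a consistent image.

Planted drug effects are survival multipliers per (drug, readout),
optionally restricted to a subcohort (e.g. homozygous-CALR only), and
are returned as a tidy truth table for recovery tests.

## Realism limits

The generator is deliberately simple where simplicity does not affect
the statistics being tested: intensities are independent lognormals
given class (no cell-to-cell covariance, no imaging artifacts, no plate
or batch effects); proteome residuals are homoscedastic Gaussians (no
intensity-dependent variance); missingness is censoring + MCAR (no
peptide-level structure); the drug library is generic (classes exist
only as labels); and there is no clonal structure below the patient
level. Conclusions about *absolute* power or error rates on real screens
do not transfer; conclusions about correctness of the estimators,
gates, and recovery logic do.

# Statistical modules

## Cell classification and gating

`train_cell_classifier()` is a two-stage model over log-transformed
mean-channel features: a logistic viability gate on nuclear
intensity/area, then a multinomial class model on viable cells. It
stands in for the paper-scale image CNN; on the synthetic channels it
reaches ~94% held-out class accuracy. `classify_and_gate()` can bypass
the classifier with truth labels, which downstream tests use to isolate
scoring behavior from classification noise.

## Drug-response scoring

For patient $i$ and drug $d$, all replicate wells across concentrations
are pooled and

$$r = 1 - \frac{\overline{f}_{\text{drug}}}{\overline{f}_{\text{control}}}$$

is the relative reduction of the readout fraction versus the drug's
matched vehicle-control wells. Significance is a plain two-sided
pooled-variance Student's t on the well-level values, and the signed
significance is $\operatorname{sign}(r) \cdot (-\log_{10} p)$ — positive
for on-target depletion. Responders are significant on-target calls
($p < 0.05$, $r > 0$); significant off-target effects are *resistant*;
everything else is a non-responder. Degenerate wells follow fixed rules
(equal constant wells give $p = 1$; unequal constant wells underflow to
the smallest positive double instead of NaN).

The oncogenic-marker positivity threshold per patient is the arithmetic
midpoint of the median marker intensity of that patient's T-cells (an
in-sample negative reference) and HSPCs in control wells — a rule that
needs no fluorescence calibration and is tested against the generative
threshold.

Patient-level QC excludes patients whose mean control-well HSPC fraction
falls below 0.3%, with inclusion *closed at the threshold* (exactly
0.003 passes).

## Proteotype processing

The enforced order is: outlier *flagging* (median-correlation and
missingness, 3·MAD rule, report only — flagged samples are not silently
dropped), group-structured missingness filtering (a protein survives if
observed in ≥ 90% of at least one group, which keeps group-specific
proteins that a global filter would destroy), left-censored imputation
(protein minimum plus up to 5% upward uniform noise on the linear
scale — every imputed value lies in
$[\min_p,\ \min_p + \log_2 1.05]$), and hemoglobin-contamination
regression. The regression computes the per-sample covariate as the
mean log2 hemoglobin level and removes the per-protein OLS projection in
closed form:

$$\hat\beta_p = \frac{\sum_s x_{ps}\,\tilde c_s}{\sum_s \tilde c_s^2},
\qquad x'_{ps} = x_{ps} - \hat\beta_p\,\tilde c_s$$

with $\tilde c$ the centered covariate; after the transform every
protein has *exactly* zero sample correlation with the covariate (up to
floating point), which the acceptance suite checks at $10^{-10}$ on a
4,000 × 113 matrix.

## Discriminative signature (RFE + MLP)

`select_signature()` repeats a seeded run design: stratified 70/20/10
train/validation/test split; recursive feature elimination on the
training split, ranking features by ridge-multinomial coefficient
magnitudes (|coefficient| · feature SD, summed over classes, averaged
over 6 stratified CV folds) and dropping the lowest 10% per step down to
30 features; then a softmax MLP (`nnet`) tuned over a small grid (hidden
size {4, 8} × weight decay {0.01, 0.1}) on the validation split and
scored once on the untouched test split. Proteins selected in ≥ 85% of
runs form the signature.

One numerical choice deserves emphasis: MLP inputs are **centered but
not variance-scaled**. Unit-variance standardization amplifies
pure-noise features to the same scale as informative ones, and with
30 features on ~70 training samples the MLP then overfits noise
catastrophically (test accuracy near chance on trivially separable
data). Centering alone preserves the variance advantage of informative
proteins and restores near-perfect test accuracy. The default is 100
runs with a threshold of 85; the workflow and acceptance tests use the
scaled-down mode (25 runs, threshold 22) with the same qualitative
recovery.

## Association testing

`protein_factor_anova()` tests thousands of proteins against a clinical
factor (with optional confounder) by decomposing the shared design once:
with QR factorizations of the full and reduced design,
$\text{RSS} = \sum y^2 - \|Q^\top y\|^2$ per protein column, and the
nested-model F statistic follows from the two RSS vectors. This is
algebraically identical to per-protein `lm()`/`anova()` (unit-tested to
$10^{-10}$) but runs as two matrix products.

## Preranked GSEA, from scratch

`gsea_preranked()` implements the weighted Kolmogorov–Smirnov running
sum: with the ranking statistic $s$ sorted decreasingly, hits increment
by $|s|^w / \sum_{\text{hits}} |s|^w$ (default weight $w = 1$), misses
decrement by $1/(N - N_h)$, and the enrichment score is the maximal
absolute excursion. Ties in the ranking are broken deterministically
(by |statistic|, then name) so results are reproducible across
platforms. The null is **gene-label permutation** at fixed set size,
shared across sets of the same size; NES divides the observed ES by the
mean |ES| of same-sign null draws, and the p-value carries a +1
pseudo-count so $p \ge 1/(n_{\text{perm}}+1)$. For small problems,
`gsea_enumerate()` computes the exact null by enumerating all
$\binom{N}{k}$ placements — the oracle used by the acceptance suite
(10-protein universe, 3-protein set, 120 placements, 10,000
permutations). The ES implementation is additionally cross-checked
against `fgsea::calcGseaStat` when `fgsea` is installed; `fgsea` is a
test-only dependency, never used by the pipeline itself.

## Integration

The integration module joins modalities strictly by patient identifier:
per-drug Spearman correlation of responses with protein levels plus
enrichment on the correlation ranking; drug–clinical ANOVA significance
counts split into sensitivity/resistance; responder-versus-rest
proteome t-tests; the MCM4/MCM7-anchored top-50 replicative signature
(per-cell-type Pearson correlation with the mean anchor level, averaged
across cell types over shared proteins); MCM tertile categories from
averaged cross-cell-type ranks (the ranking is the paper-style output;
tertiles are this package's cut rule, with ties broken by patient id);
per-drug Pearson correlation of signature scores with responses; VAF
correlations within driver strata (plain Pearson and the
diagnosis-confounded ANOVA, both emitted); and homozygous-CALR
(VAF ≥ 75) versus heterozygous-CALR / JAK2 oncogenic drug differentials
as averaged signed-significance differences, defined only where both
groups have ≥ 2 patients.

# Problem sizes and reproduction

Sizes are the package's own choice, set to keep a single-CPU laptop run
comfortable: the workflow cohort is 40 patients (8 per group) with 2,500
cells per well and a 20-drug library; the signature step uses 500
proteins, 100 patients and 25 RFE runs; the contamination-regression
check uses the full 4,000 × 113 cohort-sized matrix. The full test
suite runs in about three minutes; `Rscript scripts/acceptance.R --seed 1
--out results/acceptance.json` reruns the main pipeline quantities from
scratch against the installed package.
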