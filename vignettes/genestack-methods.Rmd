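---
title: "Gene-based association testing from stacked ensemble predictions: models, calibration and design choices"
author: "genestack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genestack methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The idea

Single-marker association tests ignore the joint, possibly non-additive,
action of the variants in a gene. `genestack` tests a SNP set as a unit by
first *predicting* the phenotype from the SNP dosages with a stacked
ensemble of learners, and then asking whether the cross-validated
predictions agree with the observed phenotype more than chance allows. If
any function of the SNPs — linear or not — carries signal, a sufficiently
flexible prediction model can pick it up, and the agreement between
prediction and observation becomes the gene-level test statistic.

The prediction model ("ensemble learning variation 1") is:

1. rank variables by |Pearson correlation| with the phenotype and keep the
   top fraction (default 30%);
2. train the base-learner roster on the selected features: linear or
   logistic regression, a linear-kernel support vector machine
   (`e1071::svm`), and a random forest with `mtry = 1` (`ranger`);
3. train a meta-level random forest (`mtry = 1`) on the base-learner
   predictions stacked with the selected features (and any covariates,
   which bypass selection and always enter as meta-features). The base
   predictions are the models' own training-set predictions. An
   out-of-bag ("honest") variant for the forest channel was evaluated —
   it captures rare interaction signal better but alters the
   training-noise structure of `P_final` in a way that de-calibrates the
   shared-fold interaction test, so the reference recipe is kept;
4. repeat per cross-validation fold so every sample receives a prediction
   `P_final` from models that never saw it.

The reference forest size is `ntree = 1000`; forests this deep change the
test statistics very little, and the package's own simulation study uses
`ntree = 100` (tests use 30-100) to keep runtimes at desk scale. All
defaults sit in `ensemble_control()`.

The tests built on `P_final` are:

* **Quantitative association** — correlation between `P_final` and
  `P_actual`, `t = r\sqrt{(N-2)/(1-r^2)}` on `N-2` df
  (`assoc_continuous()`).
* **Case-control association** — logistic likelihood-ratio test of
  (all g SNPs + `P_final`) against intercept only, chi-square with `g+1`
  df (`assoc_casecontrol()`).
* **Covariate adjustment** — for quantitative traits, Steiger's Z for the
  dependent correlations of `P_actual` with predictions from
  SNPs+covariates versus covariates alone
  (`assoc_adjusted_continuous()`), using the Meng–Rosenthal–Rubin form
  `Z = (Z_{13} - Z_{12})\sqrt{N-3}/\sqrt{2h(1-r_{23})}` with
  `r_{m}^2 = (r_{12}^2 + r_{13}^2)/2`, `f = (1-r_{23})/(2-2r_m^2)`,
  `h = (1-f r_m^2)/(1-r_m^2)`; for case-control traits the analogous
  logistic LRT with `g+1` df.
* **Interaction** — does the ensemble prediction `P_ensemble` explain
  anything beyond the SNPs and a cross-validated all-SNP *linear*
  prediction `P_linear`? Quantitative:
  `F = (SSE_0 - SSE_1)(N - V_1 - 1)/SSE_1` on `(1, N - V_1 - 1)` df;
  case-control: 1-df logistic LRT (`interaction_continuous()`,
  `interaction_casecontrol()`).

The comparison tests (`fisher_combination()`, `simes_test()`,
`gates_test()`, `vegas_test()`, `regression_gene_test()`) and the
simulator/Monte-Carlo machinery are described below.

## Calibration of tests built on cross-validated predictions

A central methodological point, easy to miss, drives two design choices in
this package.

**Pooled statistics on reciprocally cross-validated predictions are
anti-conservative.** Under classic k-fold cross-validation, a sample in
fold A helps train the model that predicts fold B *and vice versa*. Write
the prediction as a smoother, `P_i = sum_j w_ij y_j` over training samples
j. Each prediction is honestly out-of-sample (`E[y_i P_i] = 0`, and
permuting held-out labels never changes that fold's predictions — the
package tests both), yet the *pooled* covariance
`sum_i y_i P_i` acquires cross terms `w_ij w_ji > 0` from mutually
trained pairs. For any near-symmetric smoother these terms double the null
variance of the pooled correlation. This is not specific to the ensemble:
plain cross-validated ordinary least squares at n = 3000 with 5 null SNPs
rejects the pooled correlation t test at about 20% instead of 5%.

Two remedies are implemented:

* **Rotational cross-fitting** (`cv_ensemble(scheme = "rotational")`):
  fold f is predicted by a model trained on the next
  `floor((k-1)/2)` folds in cyclic order. No two samples ever train each
  other's models, the coupling terms vanish identically, and the textbook
  pooled correlation t test is calibrated (measured 4.75% at nominal 5%,
  400 null replicates). The price is smaller training sets (2 folds of 5
  instead of 4), hence slightly less accurate predictions. This is the
  default pipeline for the quantitative association test
  (`gene_ensemble_test(mode = "assoc")`).
* **Shared partition + rotational training for the interaction test**:
  `P_linear` and `P_ensemble` must come from the *same* fold partition
  (with independent partitions the null rejection is catastrophically
  inflated, about 50%), and both must be trained non-reciprocally.
  Sharing the partition lets the nested comparison project out the
  *linear* part of the training-noise coupling, but the ensemble's
  memorised component is nonlinear in the genotypes, sits outside
  `span(G, P_linear)`, and its residual coupling grows in significance
  with n (measured: 5.0% rejection at n = 1000 but 17.3% at n = 3000
  under reciprocal k-fold). With rotational training for both predictors
  the coupling vanishes identically and the F test is calibrated at the
  study size. The wrappers (`gene_ensemble_test(mode = "interaction")`,
  the `"interaction"` Monte-Carlo method) do all of this; if you
  assemble the test by hand, pass the same `folds =` and
  `scheme = "rotational"` to both predictors.

The same reasoning applies to the case-control LRT and the
covariate-adjusted tests, so every prediction-based pipeline in the
package (`gene_ensemble_test()`, the Monte-Carlo method registry) uses
rotational cross-fitting. Under reciprocal k-fold the case-control
statistic's chi-square(g+1) reference is visibly distorted (QQ quantile
slope 1.7 at n = 300); under rotational cross-fitting the reference
tracks the empirical distribution (slope 1.03, measured over 600 null
replicates; `qq_data()` / `qq_slope()` reproduce this diagnostic).
`empirical_threshold()` additionally provides fully calibrated empirical
referencing when exactness matters.

## The simulator

`snp_panel()` + `simulate_genotypes()` draw two haplotypes per individual
from a Gaussian copula: each block's latent correlation is solved
numerically (1-d quadrature of the bivariate normal CDF) so that the
*allelic* indicator correlation equals the requested `r_within`; thresholds
sit at the allele-frequency quantile, so every SNP is in exact
Hardy-Weinberg equilibrium at its MAF. Infeasible (MAF, r) pairs — beyond
the copula's Frechet-type bound — are reported as errors. SNPs in different
blocks are independent; no population structure or relatedness is
simulated, and samples are unrelated by construction.

`disease_model()` assigns disease by penetrance
`b * prod_l GRR_l(x_l)` with per-locus genotype relative risk
`1 + 0.14 x` (additive) or `1.14^x` (multiplicative), multiplicative
across disease loci; the baseline `b` is solved so the expected population
prevalence is 0.1. `simulate_case_control()` samples 1,500 cases and 1,500
controls from a population of 100,000 by default.

`quant_trait_model()` + `simulate_quantitative()` build quantitative traits
as a standard normal draw plus dosage product terms
(`c * s_a * s_b * ...`) and ratio terms (`c * (1+s_a)/(1+s_b)`), with
dosages coded 0/1/2.

`scenario_preset()` wires these into the rows of the package's simulation
study: `T1/T2/T3-*` case-control scenarios (linkage equilibrium, moderate
LD r = 0.5/0.4, strong LD r = 0.9/0.8, in blocks of five SNPs; genes of
3/10/30 SNPs with DSLs at the first SNP of each block; per-dataset MAFs
uniform on [0.1, 0.5]) and `T4/T5-*` quantitative scenarios (n = 3000,
independent SNPs, epistatic trait models).

**Choice of the quantitative-scenario MAFs.** The epistatic rows are meant
to be *pure epistasis*: marginal per-SNP tests should be nearly blind to a
trait like `0.3*snp1*snp2*snp3`. With dosage coding this is a property of
the allele frequency. At MAF 0.3 a triple product induces strong main
effects (every marginal test approaches 100% power at n = 3000); at MAF
0.1 the interaction variance itself is negligible (~0.1% of trait
variance, beyond any test's reach); at MAF 0.15 the term is almost purely
epistatic while still carrying detectable joint signal — marginal tests
hover near the null level and only interaction-aware methods see the rest.
Pairwise products and ratio terms behave oppositely: their value as
scenarios is precisely that dosage pair-products at common MAFs carry
strong marginal components every method detects. The presets therefore use
MAF 0.15 for the three-way-and-higher product rows and MAF 0.3 for the
pairwise/ratio rows and the nulls; both are explicit arguments of
`qt_scenario()` for anyone wishing to move them.

## Monte-Carlo engine

`mc_estimate_rates()` simulates replicate datasets and applies several
registered tests to each — the natural way to compare methods column-wise
on identical data. Per-replicate seeds are derived once from the master
seed, so results do not depend on scheduling; failures are counted,
excluded and capped at 5%. Rates come with exact Clopper-Pearson 95%
intervals (at 5,000 replicates a rate of 5.02% gives [4.43, 5.66], matching
the interval style of the reference tables). `empirical_threshold()`
returns the empirical (1-alpha) null quantile of a statistic for
empirically calibrated power, and `qq_data()`/`qq_slope()` support
distributional diagnostics.

Problem sizes in the shipped tests and in `scripts/acceptance.R` are
deliberate desk-scale choices: 60-200 replicates per ensemble scenario
with 100-tree forests (the cheap non-ensemble baselines run at up to
1,200 replicates), against the reference study's 5,000 nulls with
1,000-tree forests. Uncertainty is carried by the exact binomial
intervals rather than hidden; the wider intervals are the honest price of
the smaller runs.

## Numerical and degenerate-input policy

* Constant predictions or phenotypes give statistic 0 and p = 1 with a
  warning (keeps Monte-Carlo loops total) rather than NaN.
* Logistic fits falling into separation/non-convergence are refit with a
  tiny ridge (lambda = 1e-4) and flagged in the result's `note`.
* Rank-deficient interaction designs drop collinear columns and note it;
  `V_1` counts the columns actually fitted.
* GATES uses the published sixth-degree polynomial mapping dosage
  correlation to p-value correlation, with |r| = 1 clamped to exactly 1 so
  perfect LD collapses to a single effective test; the effective number of
  tests is `M - sum(lambda_i - 1)` over eigenvalues exceeding 1.
* VEGAS uses the `(r+1)/(n_sim+1)` continuity correction so empirical
  p-values are never 0; non-positive-definite correlation matrices are
  repaired by eigenvalue clamping and flagged.
* Per-SNP statistics use the Armitage trend chi-square (binary) or the
  correlation t (continuous) with `chi2 = qchisq(1-p, 1)` so statistic and
  p-value are always mutually consistent; monomorphic SNPs get p = 1 and
  are flagged.
* Missing dosages are mean-imputed per SNP *within each training fold*;
  test folds reuse the training means.
* Binary traits use stratified folds, and all binary-trait predictions are
  clamped to [0, 1]; the SVM runs as eps-regression on the 0/1 labels
  (a monotone score is all the meta-forest needs, at a fraction of the
  cost of probability-calibrated SVMs).

## What the simulations do and do not show

The generator reproduces the study conditions: HWE genotypes, block-wise
LD with a target allelic correlation, penetrance-based case-control
sampling, and normal-plus-epistasis quantitative traits with unrelated
samples. Real cohorts add population structure, relatedness, genotyping
error, missingness patterns correlated with ancestry, and LD that decays
continuously rather than in blocks — none of which are modelled here, so
passing tests certify the machinery and its calibration under the stated
conditions, not robustness to those complications. Covariate adjustment
accepts externally computed principal components but the package does not
compute ancestry itself, and the tests localise signal to the SNP set as
a whole, never to individual variants.

## Power on pure epistasis: what is achievable

Two facts shape the interaction-power landscape and are worth stating
explicitly. First, forest size governs *power*, not calibration:
Monte-Carlo noise in the meta-forest inflates `sd(P_final)` without
adding covariance with the phenotype, which directly shrinks the
correlation statistic — hence the 1000-tree reference for power studies,
while null calibration is insensitive to tree count. Second, there is an
information ceiling. For a dosage-product trait such as
`0.3*snp1*snp2*snp3`, the marginal and epistatic variance components rise
and fall together with allele frequency; in the regime where marginal
tests are blind (MAF around 0.15), even a saturated cell-mean oracle
that is told which three SNPs interact captures only about a third of
the signal correlation at n = 3000 — an upper bound of roughly 25% power
for any prediction-based correlation test. The ensemble's advantage over
marginal tests in this regime is real but modest; dramatic separations
require interaction signals with more recoverable structure (e.g. the
pairwise-product scenarios, where the interaction F test reaches ~95%
power).

## Open choices made

* `k = 5` folds by default (the reference design reports accuracy under
  20-fold CV but never fixes k for testing); cost/variance trade-off,
  configurable.
* Feature selection runs inside each training fold; a global-selection
  mode exists (off by default) for mirroring analyses that pre-commit to
  using all markers.
* Covariates always bypass feature selection and are retained as
  meta-features.
* Two-sided p-values by default for the correlation and Steiger tests;
  one-sided available via `alternative`.
* Every prediction-based test pipeline (association, case-control LRT,
  covariate-adjusted, interaction) uses rotational cross-fitting; the
  reciprocal k-fold scheme remains the `cv_ensemble()` default for plain
  prediction-accuracy work, where no pooled test statistic is involved
  (see the calibration section).
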