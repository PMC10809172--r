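---
title: "Diet quality, blood DNA methylation and cardiometabolic traits: the dietmethyl pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet quality, blood DNA methylation and cardiometabolic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmethyl)
```

# What the package does

`dietmethyl` implements a complete analysis chain for studying how overall
diet quality relates to blood DNA methylation across several cohorts, and
whether methylation at diet-associated CpGs is causally linked to
cardiometabolic traits:

1. **Diet scores** — three food-based indices (MMDS, DASH, HPDI) computed
   from a common food-group intake table and standardized within cohort.
2. **Per-cohort EWAS** — per-CpG linear regression of standardized M-values
   on the standardized score with covariate adjustment, surrogate variables,
   and family-cluster absorption.
3. **Inflation control** — genomic-lambda diagnostics and a bias/inflation
   correction of the test statistics via a constrained three-component
   Gaussian mixture.
4. **Meta-analysis** — inverse-variance pooling with DerSimonian–Laird
   heterogeneity, a fixed-versus-random reporting rule, Bonferroni and
   Benjamini–Hochberg control, and BMI-attenuation classification.
5. **Two-sample Mendelian randomization** — mQTL instruments with LD
   pruning, allele harmonization, Steiger filtering, IVW with multiplicative
   random effects, MR-Egger, weighted median, and an explicit assumption
   checklist.
6. **Enrichment** — generic hypergeometric gene-set tests and Fisher tests
   of CpG positional categories (the user supplies gene sets).

A synthetic-data module generates multi-cohort phenotypes, methylation,
mQTL and outcome-GWAS summary statistics with known ground truth, so every
stage is testable end to end without access-controlled cohort data.

# Diet scores

All three indices are built from cohort-specific quantile ranks of
food-group intakes, which makes them invariant to units and to any strictly
monotone transformation of a component:

* **DASH** (range 8–40): quintile scores 1–5 for fruits, vegetables,
  nuts + legumes, low-fat dairy and whole grains; reversed (5–1) for sodium,
  sugar-sweetened beverages and red/processed meat.
* **HPDI** (range 18–90): quintile scores for 7 healthy plant foods,
  reversed for 5 less-healthy plant foods and 6 animal foods.
* **MMDS** (range 0–27): quartile scores 0–3 for vegetables, fruits, nuts,
  legumes, whole grains, fish and the MUFA:SFA ratio; reversed for
  red/processed meat; alcohol contributes 3 points inside a sex-specific
  moderate window (5–25 g/day for women, 10–50 g/day for men by default) and
  0 outside.

Scoring details that are design choices of this package: ties are broken by
average rank and binned with right-closed boundaries; a constant component
scores everyone at the midpoint (with a warning); the MUFA:SFA ratio is
capped at its 99th percentile before binning so near-zero saturated-fat
intakes cannot dominate; sodium is ranked on absolute mg/day rather than
energy density; participants missing a component are excluded from that
score with a logged count rather than imputed. The MMDS point scale and
alcohol windows are configurable because published Mediterranean-score
variants differ; the defaults give cohort means near 12 on the 0–27 scale.

Energy under- and over-reporters are removed before scoring using
sex-specific kcal/day bounds (defaults 500–3500 for women, 800–4200 for
men).

# The EWAS model

Methylation enters as M-values, `log2((meth + 1)/(unmeth + 1))`, standardized
per CpG so that coefficients are M-value SDs per SD of diet score. Two
covariate sets are fitted:

* **Model 1**: score, age, total energy, sex (omitted in single-sex
  cohorts), smoking dummies (never = reference), five cell fractions
  (granulocytes dropped because the six fractions sum to one), an ethnicity
  dummy in multi-ethnic cohorts, and `k` surrogate variables (default 2).
* **Model 2**: Model 1 plus BMI.

Surrogate variables are the top principal directions of the residuals after
regressing every CpG on the covariate-only model ("SVA-lite"; the full
iteratively reweighted procedure is not implemented). Two details matter:

* Surrogates are estimated from the model *without* the score. Residualizing
  on the score as well would delete any technical component that happens to
  be empirically collinear with it, and exactly that component would then
  confound the score coefficients.
* In family-clustered cohorts the regression absorbs clusters by
  within-cluster demeaning of all variables, with the residual degrees of
  freedom reduced by the number of clusters. This is a deliberate,
  deterministic replacement for random-effects mixed models: it conditions
  on the cluster means instead of modelling them, at the price of discarding
  between-family information.

P-values are two-sided t-tests; after an inflation correction they are
normal-based.

# Bias and inflation correction

For each (cohort, score, model) the genomic inflation factor
`lambda = median(chi2_observed)/median(chi2_null)` is computed from the
p-values; when it exceeds 1.05 the z-scores are modelled as a mixture
`pi0 N(mu0, sigma0^2) + pi1 N(mu1, sigma1^2) + pi2 N(mu2, sigma2^2)` whose
central component is the empirical null: `mu0` is the bias and `sigma0` the
inflation. Effects are rescaled as `beta' = beta - mu0*se`,
`se' = se*sigma0`, `p' = 2*Phi(-|z'|)` with `z' = (z - mu0)/sigma0`.

The fit is a deterministic EM with fixed initialisation
(`pi = (0.9, 0.05, 0.05)`, `mu = (0, -3, 3)`, `sigma = (1, 2, 2)`), a 1e-6
log-likelihood tolerance and at most 2000 iterations. Three projections are
applied after every M-step: the null keeps the smallest spread
(`sigma0 <= sigma1, sigma2`), and the flanking means stay at least two null
SDs away from the null mean. The separation constraint is essential: an
unconstrained three-component mixture fitted to (near-)null z-scores happily
splits the null into two overlapping lumps, which would report a spurious
bias and an inflation below 1 — and "correcting" with an inflation below 1
would *amplify* every statistic. The projections can make the
log-likelihood dip below strict monotonicity by a relative 1e-7, which is
why convergence is judged on the absolute change.

# Meta-analysis and attenuation

Per (score, CpG), cohort estimates are pooled with inverse-variance weights
`w = 1/se^2`: fixed effect `sum(w*b)/sum(w)`, Cochran's
`Q = sum(w*(b - b_F)^2)`, `I2 = max(0, (Q - (k-1))/Q)`, and the
DerSimonian–Laird between-cohort variance
`tau2 = max(0, (Q-(k-1))/(sum(w) - sum(w^2)/sum(w)))` feeding the
random-effects estimate. The reported triplet is the fixed effect unless
`I2 > 0.50` or the Q-test p-value is below 0.05 (both strict), in which case
the random-effects summary is reported; the reported p uses the normal
approximation. REML and Hartung–Knapp variants are intentionally not
implemented.

Multiple testing: the Bonferroni threshold is `alpha/m` with `m` the number
of CpGs analysed in at least two cohorts (with the published 463,932 CpGs
this reproduces the 1.08e-7 threshold); BH q-values are computed within each
score across the same CpGs. CpGs present only on EPIC arrays are pooled over
the cohorts that measured them, with `k` recorded.

Attenuation after BMI adjustment is
`(beta_M1 - beta_M2)/beta_M1 * 100` (signed); an association is classified
BMI-independent when the signed change is below 10%. Note two properties of
this statistic: a negative value (stronger after adjustment) also counts as
BMI-independent, and the ratio becomes unstable when the Model-1
coefficient is near zero — which is exactly the regime of BMI-mediated
CpGs, whose Model-1 effect is only `bmi_effect * cor(score, BMI)`.

Because the reporting rule switches ~13% of truly homogeneous CpGs to
random effects (P(chi2 with k-1 df exceeding 2(k-1))), the *reported*
p-values are deliberately conservative in the bulk even under the null; the
fixed-effect p-values are the calibrated quantity to inspect in QQ plots.

# Mendelian randomization

For each diet-associated CpG with mQTL instruments: SNPs below the
instrument p-value cutoff (default 1e-8) are greedily LD-pruned
(best p first, keep if r² < 0.8 with everything kept). Outcome records are
aligned to the exposure effect allele, with sign flips for swapped or
strand-complemented representations; palindromic SNPs (A/T, C/G) with
exposure allele frequency in (0.42, 0.58) are discarded as strand-ambiguous
(the window is configurable; frequency-based resolution is not attempted).
Steiger filtering removes SNPs explaining no more variance in the exposure
than in the outcome, using `r2 = F/(F + n - 2)` per side with a strict
inequality.

Estimators: IVW is the weighted regression of outcome on exposure effects
through the origin (weights `1/se_out^2`) with multiplicative random
effects — the SE is scaled by `sqrt(max(1, Q/(J-1)))`, never deflated below
the fixed-effect value; MR-Egger adds an intercept after orienting exposure
effects positive, with Rücker's Q on `J-2` df and the same SE scaling; the
weighted median interpolates the cumulative-weight distribution of Wald
ratios at 0.5 with first-order weights, and its SE comes from a seeded
parametric bootstrap (deterministic given the seed). Binary outcomes are
reported as OR = exp(beta) with 95% CI.

The assumption checklist mirrors standard MR practice: Egger intercept
compatible with zero (p >= 0.05), sign concordance of IVW, Egger slope and
weighted median, no heterogeneity by Cochran's or Rücker's Q (p >= 0.05),
and mean instrument F strictly above 10. A result is `valid` only if all
four hold; with very precise outcome GWAS the heterogeneity checks are
sensitive to the extra dispersion caused by noise in the SNP-exposure
estimates, so strict validity rates below 100% on clean simulations are
expected behaviour of the checklist, not of the estimator.

# The synthetic-data generator

The generator emulates the structure of a multi-cohort adult meta-EWAS; its
defaults mirror a published four-cohort design (five analysis samples:
sizes 1736/1843/573/269/853, one all-female multi-ethnic cohort, one
family-clustered cohort, 450K and EPIC arrays with ~10% EPIC-only CpGs).
Key mechanisms and the values chosen (all configurable):

* **Intakes**: per-person latent healthy-eating factor `h ~ N(0,1)`;
  log-intake of each food group is `log(mu_g) + loading_g*h + sd_g*eps`,
  exponentiated. Default loadings are calibrated once so that the computed
  MMDS–DASH correlation is ≈0.6 at n = 4000 — "moderately correlated", as
  these indices are in real cohorts. Note that the three indices share food
  components by construction, so even with all loadings zero the scores
  correlate ≈0.4–0.6 structurally; the loadings control only the shared
  *latent* part.
* **Confounding**: BMI is `27.5 - 1.5*h + N(0, 4.3^2)` (score–BMI
  correlation ≈ -0.10 to -0.14, the order reported for diet-quality
  indices); smoking prevalence shifts with `h` on the logit scale (0.3 per
  SD), so smoking genuinely confounds diet–methylation associations and
  must be adjusted away.
* **Methylation**: CpG baseline + planted effects + linear cell-composition
  effects (six Dirichlet fractions, concentrations ≈ blood: granulocytes
  ~60%) + per-(CpG, batch) shifts (SD 0.15) + per-(CpG, family) intercepts
  (SD 0.2) in clustered cohorts + N(0,1) noise. Planted diet effects
  (default 0.07 M-value SD per score SD, the middle of the published
  0.05–0.08 range) are applied to the realized standardized score; a
  configurable fraction of diet CpGs is "mediated": their direct diet
  effect is zero and they respond to BMI instead (effect 0.3, the scale of
  top adiposity EWAS hits), so they associate under Model 1 and attenuate
  once BMI enters.
* **Genetics**: per diet CpG, J mQTL SNPs with per-allele effects 0.1–0.5
  SD, standard errors implied by allele frequency and the mQTL sample size
  (27,000), block-structured LD (consecutive pairs at configurable r²),
  a fraction of palindromic SNPs and of outcome rows stored on flipped
  alleles; outcome effects are `theta * b_true` plus optional directional
  pleiotropy plus sampling noise at the outcome GWAS size (300,000).

What the generator does *not* emulate — and hence what green tests do not
certify about real data: array-level artefacts (probe cross-reactivity,
detection failures, normalization residue; the package starts from
M-values), realistic LD from reference panels (blocks are synthetic),
individual-level genotypes, non-linear cell effects, fine-grained ancestry
structure beyond a two-level ethnicity label, and measurement error models
specific to food-frequency questionnaires versus diet records.

# Numerical and testing choices

Determinism: one global seed; every cohort and stage derives a substream
from `(seed, label)`, so adding a cohort never perturbs another, and
identical configurations are byte-identical. All tabular output is TSV with
10 significant digits.

The simulation studies shipped with the package use problem sizes chosen by
power analysis so that the properties they demonstrate are comfortably away
from decision boundaries: planted-effect recovery uses 20 CpGs at 0.07 SD
with combined n = 8000 (the heterogeneity rule spuriously inflates ~11% of
SEs at k = 4, which a naive n = 4000 power calculation misses);
mediation classification uses combined n = 4800 because the mediated
Model-1 effect is only ≈0.03; null calibration uses 4 cohorts of 250–500
with m = 2000 CpGs. At those cohort sizes the normal approximation of the
meta p-values has slightly heavy tails relative to the exact t reference
(a factor ≈1.3 at z ≈ 4.2), so occasional single false positives at the
per-study Bonferroni threshold are expected in long seed sweeps — the
fixed-effect p-values remain KS-uniform.

# Known limitations

* Cluster absorption discards between-family information; cohorts that are
  entirely composed of large families lose efficiency relative to a mixed
  model.
* The bulk conservatism of reported meta p-values under the
  heterogeneity-selection rule is intrinsic to that reporting convention.
* Gene-set enrichment applies no probe-number bias correction (genes with
  more CpGs are more likely hit); supplying a probe-count-weighted
  background is the available mitigation.
* Palindromic SNPs are resolved by exclusion in a frequency window only;
  no strand-aware frequency matching is attempted.
* The MMDS point scale is one of several published variants; comparisons
  across studies should verify the component definitions match.
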