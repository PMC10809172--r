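#' Food groups known to the simulator and the score calculators
#'
#' The vocabulary is the union of the components required by the three diet
#' indices: servings/day for foods, g/day for alcohol, MUFA and SFA, and mg/day
#' for sodium.
#'
#' @return Character vector of column names.
#' @export
food_groups <- function() {
  c("vegetables", "fruits", "fruit_juice", "nuts", "legumes", "whole_grains",
    "refined_grains", "potatoes", "fish", "red_processed_meat", "dairy_lowfat",
    "dairy_total", "eggs", "vegetable_oils", "tea_coffee", "ssb",
    "sweets_desserts", "animal_fat", "misc_animal", "alcohol_g", "sodium_mg",
    "mufa_g", "sfa_g")
}

# Typical intake level (median) and log-scale spread per food group; intakes
# are generated on the log scale and exponentiated so they are nonnegative and
# right-skewed like real dietary data.
.food_params <- function() {
  data.frame(
    group = food_groups(),
    mu = c(2.0, 1.8, 0.5, 0.4, 0.3, 1.5, 1.6, 0.6, 0.4, 0.9, 1.0, 1.9, 0.4,
           1.0, 2.5, 0.4, 1.0, 0.3, 0.3, 5.0, 2800, 12, 24),
    sdlog = c(0.55, 0.55, 0.8, 0.8, 0.7, 0.6, 0.5, 0.6, 0.7, 0.55, 0.7, 0.5,
              0.6, 0.5, 0.6, 0.9, 0.6, 0.8, 0.7, 1.1, 0.25, 0.35, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Default loadings of each food group on the latent healthy-eating factor
#'
#' Positive loadings make a food more abundant in the diet of a person with a
#' high latent healthy-eating factor; negative loadings the opposite. The
#' defaults give pairwise Pearson correlations between the three computed diet
#' scores in the moderate range (about 0.4-0.6 at n = 2000), the regime the
#' indices show in adult cohorts.
#'
#' @return Named numeric vector over [food_groups()].
#' @export
default_diet_loadings <- function() {
  c(vegetables = 0.11, fruits = 0.11, fruit_juice = -0.03, nuts = 0.08,
    legumes = 0.08, whole_grains = 0.11, refined_grains = -0.08,
    potatoes = -0.05, fish = 0.06, red_processed_meat = -0.10,
    dairy_lowfat = 0.07, dairy_total = -0.04, eggs = -0.03,
    vegetable_oils = 0.06, tea_coffee = 0.03, ssb = -0.10,
    sweets_desserts = -0.08, animal_fat = -0.08, misc_animal = -0.06,
    alcohol_g = 0.00, sodium_mg = -0.07, mufa_g = 0.06, sfa_g = -0.06)
}

#' Specification of one simulated cohort
#'
#' @param name Cohort label.
#' @param n Number of participants (> 0).
#' @param array Methylation array, `"450K"` or `"EPIC"`; EPIC cohorts carry the
#'   EPIC-only CpGs that 450K cohorts lack.
#' @param n_batches Number of technical batches (chips/plates).
#' @param female_frac Fraction of women; `1` gives a single-sex cohort.
#' @param age_mean,age_sd Age distribution (years).
#' @param multi_ethnic If `TRUE` an ethnicity covariate with two levels is
#'   generated (and adjusted for downstream).
#' @param family_clusters If `TRUE` participants are grouped into family pairs
#'   whose methylation shares a cluster intercept; downstream models absorb it.
#' @return A list with class `cohort_spec`.
#' @export
cohort_spec <- function(name, n, array = c("450K", "EPIC"), n_batches = 4,
                        female_frac = 0.5, age_mean = 55, age_sd = 10,
                        multi_ethnic = FALSE, family_clusters = FALSE) {
  array <- match.arg(array)
  if (!is.numeric(n) || n <= 0) .fail("cohort '", name, "': n must be positive")
  if (female_frac < 0 || female_frac > 1) .fail("female_frac must be in [0,1]")
  structure(list(name = name, n = as.integer(n), array = array,
                 n_batches = as.integer(n_batches), female_frac = female_frac,
                 age_mean = age_mean, age_sd = age_sd,
                 multi_ethnic = isTRUE(multi_ethnic),
                 family_clusters = isTRUE(family_clusters)),
            class = "cohort_spec")
}

# Default study layout: five samples mirroring a four-cohort adult meta-EWAS
# (one all-female multi-ethnic cohort, one family-clustered cohort, a split
# 450K/EPIC cohort, and one younger EPIC cohort).
.default_cohorts <- function() {
  list(
    cohort_spec("WHI",          1736, "450K", n_batches = 8, female_frac = 1,
                age_mean = 64.2, age_sd = 7.0, multi_ethnic = TRUE),
    cohort_spec("FOS",          1843, "450K", n_batches = 8, female_frac = 0.567,
                age_mean = 66.4, age_sd = 8.9, family_clusters = TRUE),
    cohort_spec("REGICOR-450K",  573, "450K", n_batches = 4, female_frac = 0.497,
                age_mean = 57.9, age_sd = 11.4),
    cohort_spec("REGICOR-EPIC",  269, "EPIC", n_batches = 2, female_frac = 0.517,
                age_mean = 56.0, age_sd = 7.0),
    cohort_spec("AIRWAVE",       853, "EPIC", n_batches = 6, female_frac = 0.429,
                age_mean = 41.1, age_sd = 9.4)
  )
}

#' Simulation configuration with known ground truth
#'
#' Collects every knob of the synthetic-data generator. Identical
#' `(config, seed)` produce byte-identical outputs; per-cohort substreams are
#' derived deterministically from `(seed, cohort name)`.
#'
#' @param seed Integer global seed.
#' @param cohorts List of [cohort_spec()] objects.
#' @param n_cpgs Total number of CpGs on the EPIC layout.
#' @param epic_only_frac Fraction of CpGs present only on EPIC arrays.
#' @param n_diet_cpgs Number of CpGs with a planted diet-score effect.
#' @param diet_effect_sd Planted effect size: M-value SDs per 1 SD of score.
#' @param frac_mediated Fraction of diet CpGs acting only through BMI (their
#'   direct diet effect is 0; methylation responds to BMI instead).
#' @param n_smoking_cpgs,smoking_effect_sd Smoking-responsive CpGs and effect.
#' @param n_bmi_cpgs,bmi_effect_sd Adiposity-responsive CpGs and effect (also
#'   the effect used for BMI-mediated diet CpGs).
#' @param cell_dirichlet_alpha Six positive Dirichlet concentrations for the
#'   leukocyte fractions (NK, CD8T, CD4T, B, Mono, Gran).
#' @param cell_effect_sd SD of per-CpG linear cell-composition coefficients.
#' @param batch_effect_sd SD of per-(CpG, batch) technical shifts.
#' @param cluster_effect_sd SD of per-(CpG, family) shared intercepts in
#'   family-clustered cohorts.
#' @param noise_sd Residual SD of M-values.
#' @param bmi_latent_slope BMI decrease (kg/m2) per SD of the latent
#'   healthy-eating factor; with BMI SD about 4.5 the default gives a
#'   score-BMI correlation near -0.13, the order observed for diet-quality
#'   indices.
#' @param smoking_latent_assoc Logit shift of smoking probability per SD of the
#'   latent factor (healthy eaters smoke less), exercising confounding control.
#' @param latent_diet_loading Named loadings over [food_groups()].
#' @param mqtl List: `snps_per_cpg`, `ld_block_r2` (within-block genotype r2),
#'   `beta_range` (absolute per-allele mQTL effect, SD of methylation),
#'   `n_exposure` (mQTL sample size), `p_palindromic` (fraction of A/T-C/G
#'   SNPs), `p_swapped` (fraction of outcome rows stored on flipped alleles).
#' @param gwas List: `theta_per_trait` (named causal effect of 1 SD methylation
#'   on each trait; log odds for binary traits), `binary_traits`,
#'   `pleiotropy_sd` (SD of direct SNP-outcome effects), `n_outcome`.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       cohorts = .default_cohorts(),
                       n_cpgs = 2000,
                       epic_only_frac = 0.1,
                       n_diet_cpgs = 20,
                       diet_effect_sd = 0.07,
                       frac_mediated = 0,
                       n_smoking_cpgs = 20,
                       smoking_effect_sd = 0.3,
                       n_bmi_cpgs = 20,
                       bmi_effect_sd = 0.3,
                       cell_dirichlet_alpha = c(NK = 2, CD8T = 3.2, CD4T = 6,
                                                B = 2, Mono = 3.2, Gran = 24),
                       cell_effect_sd = 1,
                       batch_effect_sd = 0.15,
                       cluster_effect_sd = 0.2,
                       noise_sd = 1,
                       bmi_latent_slope = 1.5,
                       smoking_latent_assoc = 0.3,
                       latent_diet_loading = default_diet_loadings(),
                       mqtl = list(),
                       gwas = list()) {
  mqtl_def <- list(snps_per_cpg = 20, ld_block_r2 = 0, beta_range = c(0.1, 0.5),
                   n_exposure = 27000, p_palindromic = 0.15, p_swapped = 0.3)
  gwas_def <- list(theta_per_trait = c(bmi = 0.2, sbp = 0, tg = 0,
                                       t2d = 0.1, chd = 0),
                   binary_traits = c("t2d", "chd"),
                   pleiotropy_sd = 0, n_outcome = 300000)
  mqtl <- utils::modifyList(mqtl_def, mqtl)
  gwas <- utils::modifyList(gwas_def, gwas)

  if (!length(cohorts)) .fail("at least one cohort is required")
  cohorts <- lapply(cohorts, function(co) {
    if (inherits(co, "cohort_spec")) co else do.call(cohort_spec, co)
  })
  names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  if (anyDuplicated(names(cohorts))) .fail("cohort names must be unique")
  if (n_cpgs < n_diet_cpgs) .fail("n_cpgs must be >= n_diet_cpgs")
  if (frac_mediated < 0 || frac_mediated > 1) .fail("frac_mediated must be in [0,1]")
  if (any(cell_dirichlet_alpha <= 0)) .fail("cell_dirichlet_alpha must be strictly positive")
  if (length(cell_dirichlet_alpha) != 6L) .fail("cell_dirichlet_alpha needs 6 concentrations")
  miss <- setdiff(food_groups(), names(latent_diet_loading))
  if (length(miss)) .fail("latent_diet_loading missing groups: ", paste(miss, collapse = ", "))

  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 n_cpgs = as.integer(n_cpgs), epic_only_frac = epic_only_frac,
                 n_diet_cpgs = as.integer(n_diet_cpgs),
                 diet_effect_sd = diet_effect_sd, frac_mediated = frac_mediated,
                 n_smoking_cpgs = as.integer(n_smoking_cpgs),
                 smoking_effect_sd = smoking_effect_sd,
                 n_bmi_cpgs = as.integer(n_bmi_cpgs),
                 bmi_effect_sd = bmi_effect_sd,
                 cell_dirichlet_alpha = cell_dirichlet_alpha,
                 cell_effect_sd = cell_effect_sd,
                 batch_effect_sd = batch_effect_sd,
                 cluster_effect_sd = cluster_effect_sd,
                 noise_sd = noise_sd, bmi_latent_slope = bmi_latent_slope,
                 smoking_latent_assoc = smoking_latent_assoc,
                 latent_diet_loading = latent_diet_loading,
                 mqtl = mqtl, gwas = gwas),
            class = "sim_config")
}
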