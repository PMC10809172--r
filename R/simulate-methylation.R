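#' Generate the CpG-level ground truth shared by all cohorts
#'
#' Draws the CpG annotation (hg19-style coordinates, gene labels, island
#' relation, gene-position class, array availability), per-CpG baseline
#' M-values and cell-composition coefficients, and plants three disjoint
#' effect sets: diet-responsive CpGs (a fraction of which act only through
#' BMI), smoking-responsive CpGs and adiposity-responsive CpGs. Causal effects
#' of methylation on the outcome traits are attached for the MR stage.
#'
#' @param config A [sim_config()].
#' @return A list with class `ground_truth`: `annotation`, `baseline`,
#'   `cell_coefs`, `diet_cpgs`, `smoking_cpgs`, `bmi_cpgs`, `causal_theta`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_cpgs
  with_seed(substream_seed(config$seed, "truth"), {
    n_epic <- round(m * config$epic_only_frac)
    array <- rep("450K", m)
    if (n_epic > 0) array[sample.int(m, n_epic)] <- "EPIC"

    ann <- data.frame(
      cpg = sprintf("cg%08d", seq_len(m)),
      chr = sample(1:22, m, replace = TRUE),
      pos = sample.int(2e8, m),
      gene = ifelse(stats::runif(m) < 0.25, "",
                    sprintf("GENE%04d", sample.int(ceiling(m / 2), m, replace = TRUE))),
      island_relation = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf",
                                 "S_Shelf", "OpenSea"), m, replace = TRUE,
                               prob = c(0.30, 0.12, 0.12, 0.05, 0.05, 0.36)),
      position_class = sample(c("TSS1500", "TSS200", "5'UTR", "1stExon",
                                "Body", "3'UTR", "Intergenic"), m,
                              replace = TRUE,
                              prob = c(0.13, 0.10, 0.12, 0.07, 0.33, 0.05, 0.20)),
      array = array, stringsAsFactors = FALSE
    )
    baseline <- stats::rnorm(m, 0, 1.5)
    names(baseline) <- ann$cpg
    cell_coefs <- matrix(stats::rnorm(m * 6, 0, config$cell_effect_sd), m, 6,
                         dimnames = list(ann$cpg, cell_types()))

    # planted sets live on the shared (450K) portion and are disjoint
    shared <- ann$cpg[ann$array == "450K"]
    n_special <- config$n_diet_cpgs + config$n_smoking_cpgs + config$n_bmi_cpgs
    if (n_special > length(shared))
      .fail("not enough shared CpGs for the planted effect sets")
    picks <- sample(shared, n_special)
    diet_ids <- picks[seq_len(config$n_diet_cpgs)]
    smoke_ids <- picks[config$n_diet_cpgs + seq_len(config$n_smoking_cpgs)]
    bmi_ids <- picks[config$n_diet_cpgs + config$n_smoking_cpgs +
                       seq_len(config$n_bmi_cpgs)]

    n_med <- round(config$n_diet_cpgs * config$frac_mediated)
    mediated <- seq_len(config$n_diet_cpgs) <= n_med
    sgn <- sample(c(-1, 1), config$n_diet_cpgs, replace = TRUE)
    diet_cpgs <- data.frame(
      cpg = diet_ids,
      score = rep_len(c("DASH", "MMDS", "HPDI"), config$n_diet_cpgs),
      effect = ifelse(mediated, 0, sgn * config$diet_effect_sd),
      mediated = mediated,
      # mediated CpGs respond to BMI instead of diet; sign chosen so that the
      # induced diet association (via the negative diet-BMI link) matches sgn
      bmi_effect = ifelse(mediated, -sgn * config$bmi_effect_sd, 0),
      stringsAsFactors = FALSE
    )
    smoking_cpgs <- data.frame(
      cpg = smoke_ids,
      effect = sample(c(-1, 1), config$n_smoking_cpgs, TRUE) * config$smoking_effect_sd,
      stringsAsFactors = FALSE
    )
    bmi_cpgs <- data.frame(
      cpg = bmi_ids,
      effect = sample(c(-1, 1), config$n_bmi_cpgs, TRUE) * config$bmi_effect_sd,
      stringsAsFactors = FALSE
    )

    theta <- config$gwas$theta_per_trait
    causal_theta <- data.frame(
      cpg = rep(diet_ids, each = length(theta)),
      trait = rep(names(theta), times = length(diet_ids)),
      theta = rep(unname(theta), times = length(diet_ids)),
      binary = rep(names(theta) %in% config$gwas$binary_traits,
                   times = length(diet_ids)),
      stringsAsFactors = FALSE
    )

    structure(list(annotation = ann, baseline = baseline,
                   cell_coefs = cell_coefs, diet_cpgs = diet_cpgs,
                   smoking_cpgs = smoking_cpgs, bmi_cpgs = bmi_cpgs,
                   causal_theta = causal_theta),
              class = "ground_truth")
  })
}

#' Simulate a cohort's M-value matrix from its phenotypes and the ground truth
#'
#' The M-value of CpG g in person i is the CpG baseline plus the planted
#' diet-score effect (standardized score times effect, direct CpGs only), the
#' BMI effect (standardized BMI), the smoking effect (never 0 / former 0.5 /
#' current 1), linear cell-fraction effects, a per-(CpG, batch) technical
#' shift, a per-(CpG, family) intercept in family-clustered cohorts, and
#' Gaussian noise. EPIC cohorts carry the EPIC-only CpGs that 450K cohorts
#' lack.
#'
#' @param phenotypes One cohort's phenotype table (from [simulate_cohort()]).
#' @param truth A `ground_truth` object from [simulate_truth()].
#' @param config The same [sim_config()].
#' @return A list with class `methylation_matrix`: `M` (CpG x sample matrix),
#'   `annotation`, `batch`, `array`, `cohort`.
#' @export
simulate_methylation <- function(phenotypes, truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  if (!nrow(phenotypes)) .fail("phenotypes table is empty")
  cohort_name <- phenotypes$cohort[1]
  spec <- config$cohorts[[cohort_name]]
  if (is.null(spec)) .fail("unknown cohort name: ", cohort_name)
  if (nrow(phenotypes) != spec$n)
    .fail("phenotype rows (", nrow(phenotypes), ") do not match cohort n (",
          spec$n, ")")
  ann <- truth$annotation
  if (spec$array == "450K") ann <- ann[ann$array == "450K", , drop = FALSE]
  m <- nrow(ann)
  n <- nrow(phenotypes)

  sc <- suppressMessages(compute_diet_scores(phenotypes))
  z_by_score <- list(DASH = sc$dash_z, MMDS = sc$mmds_z, HPDI = sc$hpdi_z)
  bmi_z <- as.numeric(scale(phenotypes$bmi))
  smoke_num <- c(never = 0, former = 0.5, current = 1)[phenotypes$smoking]
  cells <- as.matrix(phenotypes[, cell_types()])
  cells_c <- sweep(cells, 2, config$cell_dirichlet_alpha /
                     sum(config$cell_dirichlet_alpha))

  with_seed(substream_seed(config$seed, paste0("meth:", cohort_name)), {
    M <- matrix(truth$baseline[ann$cpg], m, n)
    M <- M + truth$cell_coefs[ann$cpg, , drop = FALSE] %*% t(cells_c)

    add_rows <- function(M, ids, per_person, effects) {
      idx <- match(ids, ann$cpg)
      keep <- !is.na(idx)
      if (any(keep))
        M[idx[keep], ] <- M[idx[keep], ] +
          effects[keep] * matrix(per_person, sum(keep), n, byrow = TRUE)
      M
    }
    for (s in names(z_by_score)) {
      dd <- truth$diet_cpgs[truth$diet_cpgs$score == s, , drop = FALSE]
      M <- add_rows(M, dd$cpg, z_by_score[[s]], dd$effect)
      M <- add_rows(M, dd$cpg, bmi_z, dd$bmi_effect)
    }
    M <- add_rows(M, truth$bmi_cpgs$cpg, bmi_z, truth$bmi_cpgs$effect)
    M <- add_rows(M, truth$smoking_cpgs$cpg, smoke_num, truth$smoking_cpgs$effect)

    if (config$batch_effect_sd > 0) {
      batches <- sort(unique(phenotypes$batch))
      shift <- matrix(stats::rnorm(m * length(batches), 0, config$batch_effect_sd),
                      m, length(batches))
      M <- M + shift[, match(phenotypes$batch, batches), drop = FALSE]
    }
    if (spec$family_clusters && config$cluster_effect_sd > 0) {
      fams <- sort(unique(phenotypes$cluster_id))
      fam_shift <- matrix(stats::rnorm(m * length(fams), 0, config$cluster_effect_sd),
                          m, length(fams))
      M <- M + fam_shift[, match(phenotypes$cluster_id, fams), drop = FALSE]
    }
    if (config$noise_sd > 0)
      M <- M + matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)

    dimnames(M) <- list(ann$cpg, phenotypes$participant_id)
    structure(list(M = M, annotation = ann[, setdiff(names(ann), "array")],
                   batch = phenotypes$batch, array = spec$array,
                   cohort = cohort_name),
              class = "methylation_matrix")
  })
}
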