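#' Analysis parameters of the end-to-end pipeline
#'
#' @param scores Which diet scores to analyse.
#' @param models Which adjustment models to fit (`"M1"` without BMI, `"M2"`
#'   with BMI).
#' @param k_sv Number of surrogate variables per (cohort, score, model).
#' @param lambda_trigger Genomic-inflation threshold above which the
#'   bias/inflation correction is applied (default 1.05), independently per
#'   (cohort, score, model).
#' @param alpha Family-wise/FDR error rate.
#' @param i2_threshold,q_p_threshold Heterogeneity rule for reporting random
#'   instead of fixed effects.
#' @param attenuation_threshold Percent change classifying an association as
#'   BMI-independent (default 10).
#' @param energy_bounds Sex-specific kcal/day plausibility bounds.
#' @param mr List of MR settings: `p_max`, `r2_max`, `palindromic_window`,
#'   `n_boot`, `seed`.
#' @return A list of validated parameters.
#' @export
pipeline_parameters <- function(scores = c("MMDS", "DASH", "HPDI"),
                                models = c("M1", "M2"),
                                k_sv = 2, lambda_trigger = 1.05, alpha = 0.05,
                                i2_threshold = 0.5, q_p_threshold = 0.05,
                                attenuation_threshold = 10,
                                energy_bounds = list(F = c(500, 3500),
                                                     M = c(800, 4200)),
                                mr = list()) {
  mr <- utils::modifyList(list(p_max = 1e-8, r2_max = 0.8,
                               palindromic_window = c(0.42, 0.58),
                               n_boot = 1000, seed = 1), mr)
  stopifnot(all(scores %in% c("MMDS", "DASH", "HPDI")),
            all(models %in% c("M1", "M2")),
            alpha > 0, alpha < 1, lambda_trigger >= 1,
            i2_threshold >= 0, i2_threshold <= 1)
  list(scores = scores, models = models, k_sv = k_sv,
       lambda_trigger = lambda_trigger, alpha = alpha,
       i2_threshold = i2_threshold, q_p_threshold = q_p_threshold,
       attenuation_threshold = attenuation_threshold,
       energy_bounds = energy_bounds, mr = mr)
}

.score_z_col <- c(MMDS = "mmds_z", DASH = "dash_z", HPDI = "hpdi_z")

#' EWAS of one cohort for every requested score and model
#'
#' Standardizes M-values per CpG, builds the covariate design, estimates
#' surrogate variables by residual PCA, fits the per-CpG regressions (with
#' family-cluster absorption when the cohort has clusters), computes the
#' genomic inflation factor, and applies the mixture-model bias/inflation
#' correction when lambda exceeds the trigger.
#'
#' @param phenotypes One cohort's (energy-filtered) phenotype table.
#' @param methylation Matching `methylation_matrix`.
#' @param scores_tab Output of [compute_diet_scores()] for this cohort.
#' @param params [pipeline_parameters()].
#' @return A list: `records` (stacked corrected EWAS records with `cpg`,
#'   `score`, `model`, `cohort`, `beta`, `se`, `p`, `n`) and `diagnostics`
#'   (per score x model inflation diagnostics).
#' @export
cohort_ewas <- function(phenotypes, methylation, scores_tab, params) {
  M <- methylation$M[, phenotypes$participant_id, drop = FALSE]
  Ms <- suppressWarnings(scale_mvalues(M))
  has_clusters <- anyDuplicated(phenotypes$cluster_id) > 0
  cluster <- if (has_clusters) phenotypes$cluster_id else NULL

  records <- list()
  diags <- list()
  for (score in params$scores) {
    z <- scores_tab[[.score_z_col[[score]]]]
    for (model in params$models) {
      X <- build_design(phenotypes, z, model)
      # surrogates come from the covariate-only model: residualizing on the
      # score as well would strip any batch component that happens to be
      # collinear with it, and that component would then bias the score betas
      sv <- estimate_surrogates(Ms, X[, colnames(X) != "score", drop = FALSE],
                                params$k_sv)
      X2 <- if (ncol(sv)) cbind(X, sv) else X
      fit <- fit_ewas(Ms, X2, cluster_id = cluster)
      bc <- bacon_fit_records(fit, params$lambda_trigger)
      rec <- bc$records
      rec$score <- score
      rec$model <- model
      rec$cohort <- phenotypes$cohort[1]
      records[[paste(score, model)]] <-
        rec[, c("cpg", "score", "model", "cohort", "beta", "se", "p", "n",
                "corrected")]
      dg <- bc$diagnostics
      dg$score <- score; dg$model <- model; dg$cohort <- phenotypes$cohort[1]
      diags[[paste(score, model)]] <- dg
    }
  }
  list(records = do.call(rbind, c(records, make.row.names = FALSE)),
       diagnostics = do.call(rbind, c(diags, make.row.names = FALSE)))
}

# fit the z-score mixture and apply the correction when lambda is inflated;
# with fewer than 100 CpGs lambda is not estimable and records pass through
bacon_fit_records <- function(fit, lambda_trigger) {
  if (nrow(fit) < 100) {
    fit$corrected <- FALSE
    return(list(records = fit,
                diagnostics = data.frame(lambda_raw = NA_real_, bias = 0,
                                         inflation = 1,
                                         lambda_corrected = NA_real_,
                                         corrected = FALSE)))
  }
  lambda_raw <- genomic_lambda(fit$p)
  if (lambda_raw > lambda_trigger) {
    bf <- bacon_fit(fit$beta / fit$se)
    bacon_apply(fit, bf$bias, bf$inflation, lambda_trigger)
  } else {
    fit$corrected <- FALSE
    list(records = fit,
         diagnostics = data.frame(lambda_raw = lambda_raw, bias = 0,
                                  inflation = 1, lambda_corrected = lambda_raw,
                                  corrected = FALSE))
  }
}

#' Run the full analysis on an in-memory study
#'
#' Energy filtering, diet scores, per-cohort EWAS under Models 1 and 2 with
#' inflation correction, cross-cohort meta-analysis with the heterogeneity
#' rule and Bonferroni/FDR control, BMI-attenuation classification of the
#' Bonferroni hits, and two-sample MR of the hit CpGs that have instruments.
#'
#' @param study A `diet_study` (from [simulate_study()] or [read_study()]).
#' @param params [pipeline_parameters()].
#' @param run_mr Whether to run the MR stage (requires `study$mqtl`).
#' @return A list: `scores`, `score_correlations`, `ewas`, `diagnostics`,
#'   `meta` (per model), `attenuation`, `hits`, `mr`, `manifest`.
#' @export
run_study <- function(study, params = pipeline_parameters(), run_mr = TRUE) {
  t0 <- Sys.time()
  n_excluded <- 0L
  ewas_records <- list()
  diagnostics <- list()
  scores_all <- list()

  for (nm in names(study$phenotypes)) {
    ph <- filter_implausible_energy(study$phenotypes[[nm]],
                                    params$energy_bounds)
    n_excluded <- n_excluded + attr(ph, "n_removed")
    sc <- suppressMessages(compute_diet_scores(ph))
    scores_all[[nm]] <- sc
    ce <- cohort_ewas(ph, study$methylation[[nm]], sc, params)
    ewas_records[[nm]] <- ce$records
    diagnostics[[nm]] <- ce$diagnostics
  }
  ewas <- do.call(rbind, c(ewas_records, make.row.names = FALSE))
  diagnostics <- do.call(rbind, c(diagnostics, make.row.names = FALSE))
  score_cor <- score_correlations(do.call(rbind, c(scores_all,
                                                   make.row.names = FALSE)))

  meta <- list()
  for (model in params$models) {
    meta[[model]] <- meta_ewas(ewas[ewas$model == model, , drop = FALSE],
                               alpha = params$alpha,
                               i2_threshold = params$i2_threshold,
                               q_p_threshold = params$q_p_threshold)
  }

  att <- if (all(c("M1", "M2") %in% names(meta)))
    attenuation(meta$M1, meta$M2, params$attenuation_threshold) else NULL

  main <- meta[[params$models[1]]]
  hits <- list(
    bonferroni = unique(main$cpg[main$bonferroni_hit]),
    fdr = unique(main$cpg[!is.na(main$fdr_q) & main$fdr_q < params$alpha])
  )

  mr <- NULL
  if (run_mr && !is.null(study$mqtl) && length(hits$bonferroni)) {
    mq <- study$mqtl[study$mqtl$cpg %in% hits$bonferroni, , drop = FALSE]
    if (nrow(mq))
      mr <- mr_analysis(mq, study$gwas, study$ld,
                        binary_traits = study$config$gwas$binary_traits,
                        p_max = params$mr$p_max, r2_max = params$mr$r2_max,
                        palindromic_window = params$mr$palindromic_window,
                        n_boot = params$mr$n_boot, seed = params$mr$seed)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dietmethyl")),
    n_cohorts = length(study$phenotypes),
    n_participants = sum(vapply(scores_all, nrow, 0L)),
    n_excluded_energy = n_excluded,
    n_cpgs_tested = attr(main, "m_tests"),
    n_bonferroni_hits = length(hits$bonferroni),
    n_fdr_hits = length(hits$fdr),
    n_cpgs_with_instruments = if (is.null(mr)) 0L else
      length(unique(mr$cpg[mr$n_snps > 0])),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S")
  )

  list(scores = scores_all, score_correlations = score_cor, ewas = ewas,
       diagnostics = diagnostics, meta = meta, attenuation = att,
       hits = hits, mr = mr, manifest = manifest)
}

#' Read a study back from the directory layout written by [write_study()]
#'
#' Fails fast, before any computation, if a declared input file is missing or
#' violates its schema.
#'
#' @param dir Study directory.
#' @param cohorts Cohort names; defaults to those found in the directory.
#' @return A `diet_study`-shaped list (without ground truth or config).
#' @export
read_study <- function(dir, cohorts = NULL) {
  if (is.null(cohorts)) {
    ph_files <- list.files(dir, pattern = "^phenotypes_.*\\.tsv$")
    cohorts <- sub("^phenotypes_(.*)\\.tsv$", "\\1", ph_files)
  }
  if (!length(cohorts)) .fail("no phenotype tables found in ", dir)
  # existence pass first: fail before reading anything large
  for (nm in cohorts) {
    for (f in file.path(dir, paste0(c("phenotypes_", "methylation_"), nm, ".tsv")))
      if (!file.exists(f)) .fail("missing input file: ", f)
  }
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  phen <- list(); meth <- list()
  for (nm in cohorts) {
    phen[[nm]] <- read_phenotypes(file.path(dir, paste0("phenotypes_", nm, ".tsv")))
    M <- read_methylation_matrix(file.path(dir, paste0("methylation_", nm, ".tsv")))
    if (!all(colnames(M) == phen[[nm]]$participant_id))
      .fail("samples of methylation_", nm, ".tsv do not match its phenotypes")
    meth[[nm]] <- structure(
      list(M = M, annotation = ann[match(rownames(M), ann$cpg), ],
           batch = phen[[nm]]$batch, array = NA_character_, cohort = nm),
      class = "methylation_matrix")
  }
  mqtl <- NULL; gwas <- NULL; ld <- NULL
  if (file.exists(file.path(dir, "mqtl.tsv"))) {
    mqtl <- read_mqtl_table(file.path(dir, "mqtl.tsv"))
    gw_files <- list.files(dir, pattern = "^gwas_.*\\.tsv$")
    gwas <- lapply(file.path(dir, gw_files), read_gwas_table)
    names(gwas) <- sub("^gwas_(.*)\\.tsv$", "\\1", gw_files)
    ld_files <- list.files(file.path(dir, "ld"), pattern = "\\.tsv$")
    ld <- lapply(file.path(dir, "ld", ld_files), read_ld_matrix)
    names(ld) <- sub("\\.tsv$", "", ld_files)
  }
  structure(list(config = NULL, truth = NULL, phenotypes = phen,
                 methylation = meth, mqtl = mqtl, gwas = gwas, ld = ld),
            class = "diet_study")
}

#' End-to-end pipeline over files on disk
#'
#' Reads a study directory (fail-fast schema validation), runs [run_study()],
#' writes every stage's table under `out_dir` and a run manifest (YAML) whose
#' hit counts are recomputed from the written tables.
#'
#' @param study_dir Directory produced by [write_study()] (or hand-assembled
#'   in the same layout).
#' @param out_dir Output directory.
#' @param params [pipeline_parameters()].
#' @param binary_traits Traits reported as odds ratios in the MR stage.
#' @return The [run_study()] result, invisibly; `manifest.yaml`, EWAS, meta,
#'   attenuation and MR tables are written to `out_dir`.
#' @export
run_pipeline <- function(study_dir, out_dir,
                         params = pipeline_parameters(),
                         binary_traits = c("t2d", "chd")) {
  study <- read_study(study_dir)
  study$config <- list(gwas = list(binary_traits = binary_traits))
  res <- run_study(study, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  for (nm in names(res$scores))
    write_table_tsv(res$scores[[nm]], file.path(out_dir, paste0("scores_", nm, ".tsv")))
  write_table_tsv(res$ewas, file.path(out_dir, "ewas.tsv"))
  write_table_tsv(res$diagnostics, file.path(out_dir, "inflation_diagnostics.tsv"))
  for (model in names(res$meta))
    write_table_tsv(res$meta[[model]], file.path(out_dir, paste0("meta_", model, ".tsv")))
  if (!is.null(res$attenuation))
    write_table_tsv(res$attenuation, file.path(out_dir, "attenuation.tsv"))
  if (!is.null(res$mr))
    write_table_tsv(res$mr, file.path(out_dir, "mr.tsv"))

  # the manifest's counts are recomputed from the files just written
  main <- read_table_tsv(file.path(out_dir, paste0("meta_", params$models[1], ".tsv")))
  res$manifest$n_bonferroni_hits <- length(unique(main$cpg[main$bonferroni_hit]))
  res$manifest$n_fdr_hits <-
    length(unique(main$cpg[!is.na(main$fdr_q) & main$fdr_q < params$alpha]))
  res$manifest$config_hash <- local({
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(params, tmp)
    unname(tools::md5sum(tmp))
  })
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}
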