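#' Simulate one cohort's phenotype table
#'
#' Participants carry age, sex, ethnicity, smoking status, BMI, total energy,
#' six leukocyte fractions (Dirichlet, summing to 1), a batch label, a cluster
#' id, and food-group intakes. Intakes are generated on the log scale from a
#' per-person latent healthy-eating factor with group-specific loadings, then
#' exponentiated; BMI depends negatively on the latent factor; smoking is
#' (configurably) correlated with it so that downstream adjustment is
#' exercised by real confounding.
#'
#' @param config A [sim_config()].
#' @param cohort_name Name of a cohort present in `config$cohorts`.
#' @return A `data.frame` phenotype table; the latent factor used for
#'   generation is attached as `attr(, "latent")` for oracle checks.
#' @export
simulate_cohort <- function(config, cohort_name) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$cohorts[[cohort_name]]
  if (is.null(spec)) .fail("unknown cohort name: ", cohort_name)
  n <- spec$n
  fp <- .food_params()
  loading <- config$latent_diet_loading[fp$group]

  with_seed(substream_seed(config$seed, paste0("cohort:", cohort_name)), {
    h <- stats::rnorm(n)

    sex <- ifelse(stats::runif(n) < spec$female_frac, "F", "M")
    age <- round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1)
    age <- pmin(pmax(age, 20), 95)
    ethnicity <- if (spec$multi_ethnic) {
      ifelse(stats::runif(n) < 0.5, "white", "nonwhite")
    } else rep("white", n)

    # healthy eaters smoke less: logit of being a current smoker shifts with h
    p_cur <- stats::plogis(stats::qlogis(0.15) - config$smoking_latent_assoc * h)
    u <- stats::runif(n)
    smoking <- ifelse(u < p_cur, "current",
                      ifelse(u < p_cur + 0.30, "former", "never"))

    energy <- exp(log(1900) + 0.12 * (sex == "M") + 0.05 * h +
                    0.22 * stats::rnorm(n))
    energy <- round(energy)

    bmi <- 27.5 - config$bmi_latent_slope * h + stats::rnorm(n, sd = 4.3)
    bmi <- round(pmax(bmi, 16), 1)

    # six cell fractions per person, Dirichlet via normalized gammas
    alpha <- config$cell_dirichlet_alpha
    g <- matrix(stats::rgamma(n * 6, shape = rep(alpha, each = n)), nrow = n)
    cells <- g / rowSums(g)
    colnames(cells) <- names(alpha)

    batch <- sprintf("%s_b%02d", cohort_name,
                     sample(rep_len(seq_len(spec$n_batches), n)))
    cluster_id <- if (spec$family_clusters) {
      sprintf("%s_fam%04d", cohort_name, rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)])
    } else sprintf("%s_ind%05d", cohort_name, seq_len(n))

    intakes <- matrix(NA_real_, n, nrow(fp), dimnames = list(NULL, fp$group))
    for (j in seq_len(nrow(fp))) {
      intakes[, j] <- exp(log(fp$mu[j]) + loading[j] * h +
                            fp$sdlog[j] * stats::rnorm(n))
    }
    # a tenth of participants are non-drinkers
    intakes[stats::runif(n) < 0.10, "alcohol_g"] <- 0

    tab <- data.frame(
      participant_id = sprintf("%s_%05d", cohort_name, seq_len(n)),
      cohort = cohort_name, age = age, sex = sex, ethnicity = ethnicity,
      smoking = smoking, bmi = bmi, energy = energy,
      cluster_id = cluster_id, batch = batch,
      stringsAsFactors = FALSE
    )
    tab <- cbind(tab, as.data.frame(cells), as.data.frame(intakes))
    tab$alcohol_g <- round(tab$alcohol_g, 2)
    attr(tab, "latent") <- h
    tab
  })
}

#' Validate the structural invariants of a phenotype table
#'
#' Checks the columns required by the score calculators and the EWAS design,
#' that cell fractions are in [0,1] and sum to 1, that energy is positive, and
#' that smoking has its three levels.
#'
#' @param table A phenotype `data.frame`.
#' @return Invisibly `TRUE`; errors describe the first violated constraint.
#' @export
validate_phenotypes <- function(table) {
  need <- c("participant_id", "cohort", "age", "sex", "smoking", "bmi",
            "energy", "cluster_id", cell_types(), food_groups())
  miss <- setdiff(need, names(table))
  if (length(miss)) .fail("phenotype table missing columns: ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(table$participant_id)) .fail("duplicate participant_id values")
  cf <- as.matrix(table[, cell_types()])
  if (any(cf < -1e-12 | cf > 1 + 1e-12)) .fail("cell fractions outside [0,1]")
  if (any(abs(rowSums(cf) - 1) > 1e-8)) .fail("cell fractions do not sum to 1")
  bad <- setdiff(unique(table$smoking), c("never", "former", "current"))
  if (length(bad)) .fail("unknown smoking levels: ", paste(bad, collapse = ", "))
  if (any(!is.na(table$energy) & table$energy <= 0)) .fail("energy must be positive")
  invisible(TRUE)
}

#' The six leukocyte fractions tracked per participant
#' @return Character vector of column names.
#' @export
cell_types <- function() c("NK", "CD8T", "CD4T", "B", "Mono", "Gran")
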