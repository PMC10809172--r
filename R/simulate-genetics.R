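#' Simulate mQTL instruments and outcome GWAS summary statistics
#'
#' For each diet-responsive CpG, generates J mQTL SNPs with alleles,
#' effect-allele frequencies, per-allele exposure effects (SD of methylation)
#' and standard errors implied by the allele frequency and the mQTL sample
#' size; outcome effects are `theta * b_exposure` plus optional directional
#' pleiotropy and sampling noise, with standard errors implied by the outcome
#' sample size. LD is block structured (consecutive SNP pairs share genotype
#' r2 `ld_block_r2`); a configurable fraction of SNPs is palindromic (A/T or
#' C/G) and a fraction of outcome rows is stored on flipped alleles so that
#' harmonization has real work to do.
#'
#' @param truth A `ground_truth` from [simulate_truth()].
#' @param config The same [sim_config()].
#' @return A list: `mqtl` (exposure table with `cpg` column), `gwas` (named
#'   list of per-trait outcome tables), `ld` (named list of per-CpG r2
#'   matrices), `snp_truth` (true per-allele effects per SNP).
#' @export
simulate_mqtl_and_gwas <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  mq <- config$mqtl
  gw <- config$gwas
  traits <- names(gw$theta_per_trait)
  if (!length(traits)) .fail("gwas$theta_per_trait must name at least one trait")
  miss <- setdiff(unique(truth$causal_theta$trait), traits)
  if (length(miss)) .fail("trait(s) without causal theta: ", paste(miss, collapse = ", "))
  cpgs <- truth$diet_cpgs$cpg
  if (!length(cpgs)) {
    empty <- data.frame()
    return(list(mqtl = empty, gwas = stats::setNames(rep(list(empty), length(traits)), traits),
                ld = list(), snp_truth = empty))
  }
  J <- mq$snps_per_cpg
  r <- sqrt(mq$ld_block_r2)

  with_seed(substream_seed(config$seed, "genetics"), {
    pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    pal_pairs <- list(c("A", "T"), c("C", "G"))

    mqtl_rows <- list()
    ld <- list()
    snp_truth <- list()
    out_rows <- stats::setNames(vector("list", length(traits)), traits)

    for (ci in seq_along(cpgs)) {
      cpg <- cpgs[ci]
      snp <- sprintf("rs%d%03d", 10000 + ci, seq_len(J))
      chr <- truth$annotation$chr[match(cpg, truth$annotation$cpg)]
      pos <- truth$annotation$pos[match(cpg, truth$annotation$cpg)] +
        sample.int(5e5, J) - 250000
      is_pal <- stats::runif(J) < mq$p_palindromic
      al <- t(vapply(seq_len(J), function(j) {
        if (is_pal[j]) unlist(sample(pal_pairs, 1)) else unlist(sample(pairs, 1))
      }, character(2)))
      eaf <- stats::runif(J, 0.10, 0.90)

      # block LD: odd SNPs lead, the following SNP is a proxy with genotype
      # correlation r; its marginal exposure effect is r * the leader's
      b_lead <- stats::runif(J, mq$beta_range[1], mq$beta_range[2]) *
        sample(c(-1, 1), J, replace = TRUE)
      b_true <- b_lead
      follower <- seq_len(J) %% 2 == 0
      if (r > 0) b_true[follower] <- r * b_lead[which(follower) - 1]

      se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * mq$n_exposure)
      b_hat <- b_true + stats::rnorm(J, 0, se_exp)
      p_exp <- 2 * stats::pnorm(-abs(b_hat / se_exp))

      mqtl_rows[[ci]] <- data.frame(
        cpg = cpg, snp = snp, chr = chr, pos = pos,
        effect_allele = al[, 1], other_allele = al[, 2], eaf = eaf,
        beta = b_hat, se = se_exp, p = p_exp, n = mq$n_exposure,
        stringsAsFactors = FALSE
      )
      R2 <- diag(J)
      if (r > 0)
        for (j in which(follower)) R2[j, j - 1] <- R2[j - 1, j] <- r^2
      dimnames(R2) <- list(snp, snp)
      ld[[cpg]] <- R2
      snp_truth[[ci]] <- data.frame(cpg = cpg, snp = snp, beta_true = b_true,
                                    stringsAsFactors = FALSE)

      for (tr in traits) {
        theta <- truth$causal_theta$theta[truth$causal_theta$cpg == cpg &
                                            truth$causal_theta$trait == tr]
        se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * gw$n_outcome)
        pleio <- if (gw$pleiotropy_sd > 0)
          stats::rnorm(J, 0, gw$pleiotropy_sd) else 0
        by_hat <- theta * b_true + pleio + stats::rnorm(J, 0, se_out)

        swap <- stats::runif(J) < mq$p_swapped
        out_rows[[tr]][[ci]] <- data.frame(
          snp = snp, chr = chr, pos = pos,
          effect_allele = ifelse(swap, al[, 2], al[, 1]),
          other_allele = ifelse(swap, al[, 1], al[, 2]),
          eaf = ifelse(swap, 1 - eaf, eaf),
          beta = ifelse(swap, -by_hat, by_hat),
          se = se_out, p = 2 * stats::pnorm(-abs(by_hat / se_out)),
          n = gw$n_outcome, stringsAsFactors = FALSE
        )
      }
    }

    list(mqtl = do.call(rbind, mqtl_rows),
         gwas = lapply(out_rows, function(x) do.call(rbind, x)),
         ld = ld,
         snp_truth = do.call(rbind, snp_truth))
  })
}

#' Simulate a complete multi-cohort study with known ground truth
#'
#' Convenience wrapper generating the CpG-level truth, every cohort's
#' phenotype table and M-value matrix, and the mQTL/outcome-GWAS summary
#' statistics, all deterministically from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with class `diet_study`: `config`, `truth`, `phenotypes`
#'   (named list per cohort), `methylation` (named list per cohort), `mqtl`,
#'   `gwas`, `ld`, `snp_truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  phen <- lapply(names(config$cohorts), function(nm) simulate_cohort(config, nm))
  names(phen) <- names(config$cohorts)
  meth <- lapply(phen, simulate_methylation, truth = truth, config = config)
  gen <- simulate_mqtl_and_gwas(truth, config)
  structure(list(config = config, truth = truth, phenotypes = phen,
                 methylation = meth, mqtl = gen$mqtl, gwas = gen$gwas,
                 ld = gen$ld, snp_truth = gen$snp_truth),
            class = "diet_study")
}
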