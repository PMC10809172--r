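#' Select mQTL instruments for one CpG with greedy LD pruning
#'
#' Keeps SNPs associated with the CpG below `p_max`, then walks them in order
#' of ascending p-value, retaining a SNP only if its LD r2 with every
#' previously retained SNP is below `r2_max`.
#'
#' @param mqtl Exposure records for a single CpG (columns `snp`, `p`).
#' @param ld Square r2 matrix with SNP ids as dimnames.
#' @param p_max Instrument significance cutoff (default 1e-8).
#' @param r2_max LD pruning threshold (default 0.8).
#' @return The retained rows of `mqtl` (possibly zero rows: "no instruments").
#' @export
select_instruments <- function(mqtl, ld, p_max = 1e-8, r2_max = 0.8) {
  if (length(unique(mqtl$cpg)) > 1) .fail("records must share a single CpG")
  cand <- mqtl[mqtl$p < p_max, , drop = FALSE]
  cand <- cand[order(cand$p), , drop = FALSE]
  kept <- character(0)
  for (s in cand$snp) {
    if (!length(kept) || all(ld[s, kept] < r2_max)) kept <- c(kept, s)
  }
  out <- cand[match(kept, cand$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize exposure and outcome summary statistics to shared effect alleles
#'
#' Aligns every outcome record to the exposure's effect allele: records stored
#' on swapped alleles get their effect sign flipped and frequency mirrored;
#' allele-incompatible SNPs are dropped; palindromic SNPs (A/T or C/G) whose
#' exposure allele frequency falls inside the ambiguity window are dropped
#' because their strand cannot be resolved. The operation is idempotent.
#'
#' @param exposure,outcome Summary-statistic tables sharing `snp` ids, each
#'   with `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @param palindromic_window Open interval of allele frequencies within which
#'   palindromic SNPs are discarded (default `(0.42, 0.58)`).
#' @return `data.frame` of harmonized instruments: `snp`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf`, `palindromic`, `F`
#'   (`(beta_exp/se_exp)^2`), `wald_ratio`.
#' @export
harmonize <- function(exposure, outcome, palindromic_window = c(0.42, 0.58)) {
  if (anyDuplicated(exposure$snp)) .fail("duplicate SNP rows in exposure")
  if (anyDuplicated(outcome$snp)) .fail("duplicate SNP rows in outcome")
  shared <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]

  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  # palindromic SNPs read identically on both strands, so strand flips are
  # undetectable for them; for the rest, compare against the complement too
  flip_same <- ex$effect_allele == .complement[ou$effect_allele] &
    ex$other_allele == .complement[ou$other_allele]
  flip_swapped <- ex$effect_allele == .complement[ou$other_allele] &
    ex$other_allele == .complement[ou$effect_allele]
  palindromic <- ex$effect_allele == .complement[ex$other_allele]

  beta_out <- ou$beta
  use_swap <- swapped | (!same & !swapped & flip_swapped)
  beta_out[use_swap] <- -beta_out[use_swap]
  compatible <- same | swapped | flip_same | flip_swapped

  ambiguous <- palindromic & ex$eaf > palindromic_window[1] &
    ex$eaf < palindromic_window[2]
  keep <- compatible & !ambiguous
  if (any(!compatible))
    message(sum(!compatible), " allele-incompatible SNP(s) dropped")
  if (any(ambiguous))
    message(sum(ambiguous), " ambiguous palindromic SNP(s) dropped")

  out <- data.frame(snp = ex$snp, beta_exp = ex$beta, se_exp = ex$se,
                    beta_out = beta_out, se_out = ou$se, eaf = ex$eaf,
                    palindromic = palindromic, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  out$F <- (out$beta_exp / out$se_exp)^2
  out$wald_ratio <- out$beta_out / out$beta_exp
  rownames(out) <- NULL
  out
}

#' Steiger filter against reverse causation
#'
#' Per SNP, compares the variance explained in exposure and outcome,
#' `r2 = F / (F + n - 2)`, and keeps the SNP only when it explains strictly
#' more variance in the exposure than in the outcome.
#'
#' @param instruments Harmonized instruments from [harmonize()].
#' @param n_exp,n_out Exposure and outcome sample sizes (> 2).
#' @return `instruments` with a `steiger_keep` column, restricted to the kept
#'   rows.
#' @export
steiger_filter <- function(instruments, n_exp, n_out) {
  stopifnot(n_exp > 2, n_out > 2)
  F_exp <- (instruments$beta_exp / instruments$se_exp)^2
  F_out <- (instruments$beta_out / instruments$se_out)^2
  r2_exp <- F_exp / (F_exp + n_exp - 2)
  r2_out <- F_out / (F_out + n_out - 2)
  instruments$steiger_keep <- r2_exp > r2_out
  out <- instruments[instruments$steiger_keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inverse-variance weighted MR with multiplicative random effects
#'
#' Weighted regression of the outcome effects on the exposure effects through
#' the origin (weights `1/se_out^2`). The standard error is scaled by
#' `sqrt(max(1, Q/(J-1)))` where Q is Cochran's heterogeneity statistic, i.e.
#' under-dispersion never shrinks it below the fixed-effect value.
#'
#' @param instruments Harmonized instruments (>= 2 rows).
#' @param binary If `TRUE` the estimate is also reported as an odds ratio with
#'   a 95 percent confidence interval.
#' @return A list: `beta`, `se`, `p`, `n_snps`, `phi` (residual scale), and
#'   for binary outcomes `or`, `or_lo`, `or_hi`.
#' @export
ivw_mre <- function(instruments, binary = FALSE) {
  J <- nrow(instruments)
  if (J < 2) .fail("IVW needs at least 2 instruments")
  x <- instruments$beta_exp; y <- instruments$beta_out
  w <- 1 / instruments$se_out^2
  beta <- sum(w * x * y) / sum(w * x^2)
  se_fixed <- sqrt(1 / sum(w * x^2))
  Q <- sum(w * (y - beta * x)^2)
  phi <- Q / (J - 1)
  se <- se_fixed * sqrt(max(1, phi))
  p <- 2 * stats::pnorm(-abs(beta / se))
  out <- list(beta = beta, se = se, p = p, n_snps = J, phi = phi)
  if (binary) {
    out$or <- exp(beta)
    out$or_lo <- exp(beta - 1.96 * se)
    out$or_hi <- exp(beta + 1.96 * se)
  }
  out
}

#' MR-Egger regression and Ruecker's Q
#'
#' Weighted regression of outcome on exposure effects with an intercept
#' (weights `1/se_out^2`), after orienting all SNPs so the exposure effect is
#' positive. A non-zero intercept indicates directional pleiotropy; Ruecker's
#' Q is the weighted residual sum of squares on `J - 2` degrees of freedom.
#' Standard errors carry the same multiplicative random-effects scaling as
#' [ivw_mre()].
#'
#' @param instruments Harmonized instruments (>= 3 rows).
#' @return A list: `slope`, `slope_se`, `slope_p`, `intercept`,
#'   `intercept_se`, `intercept_p`, `rucker_q`, `rucker_p`, `n_snps`.
#' @export
mr_egger <- function(instruments) {
  J <- nrow(instruments)
  if (J < 3) .fail("MR-Egger needs at least 3 instruments")
  s <- sign(instruments$beta_exp)
  s[s == 0] <- 1
  x <- abs(instruments$beta_exp)
  y <- instruments$beta_out * s
  w <- 1 / instruments$se_out^2
  X <- cbind(1, x)
  XtWX <- crossprod(X, w * X)
  cf <- solve(XtWX, crossprod(X, w * y))
  res <- y - X %*% cf
  rucker_q <- sum(w * res^2)
  scale2 <- max(1, rucker_q / (J - 2))
  V <- solve(XtWX) * scale2
  se <- sqrt(diag(V))
  z <- cf / se
  list(slope = cf[2], slope_se = se[2],
       slope_p = 2 * stats::pnorm(-abs(z[2])),
       intercept = cf[1], intercept_se = se[1],
       intercept_p = 2 * stats::pnorm(-abs(z[1])),
       rucker_q = rucker_q,
       rucker_p = stats::pchisq(rucker_q, df = J - 2, lower.tail = FALSE),
       n_snps = J)
}

# weighted median with cumulative-weight interpolation at 0.5
.weighted_median_point <- function(ratios, w) {
  o <- order(ratios)
  r <- ratios[o]; w <- w[o]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The weighted median of the per-SNP Wald ratios (weights are the inverse
#' first-order variances of the ratios), consistent when at least half the
#' weight comes from valid instruments. Its standard error comes from a
#' seeded parametric bootstrap, so the same seed reproduces it exactly.
#'
#' @param instruments Harmonized instruments (>= 3 rows).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (default 1).
#' @return A list: `beta`, `se`, `p`, `n_snps`.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed = 1) {
  J <- nrow(instruments)
  if (J < 3) .fail("weighted median needs at least 3 instruments")
  ratios <- instruments$beta_out / instruments$beta_exp
  w <- instruments$beta_exp^2 / instruments$se_out^2
  beta <- .weighted_median_point(ratios, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, instruments$beta_exp, instruments$se_exp)
      by <- stats::rnorm(J, instruments$beta_out, instruments$se_out)
      .weighted_median_point(by / bx, bx^2 / instruments$se_out^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)), n_snps = J)
}

#' Cochran's Q for between-SNP heterogeneity around the IVW estimate
#'
#' @param instruments Harmonized instruments (>= 2 rows).
#' @param beta_ivw IVW point estimate.
#' @return A list: `Q`, `df`, `p`.
#' @export
cochran_q <- function(instruments, beta_ivw) {
  J <- nrow(instruments)
  if (J < 2) .fail("Cochran's Q needs at least 2 instruments")
  Q <- sum((instruments$beta_out - beta_ivw * instruments$beta_exp)^2 /
             instruments$se_out^2)
  list(Q = Q, df = J - 1, p = stats::pchisq(Q, df = J - 1, lower.tail = FALSE))
}

#' Assumption checklist for an MR result
#'
#' Four checks: (i) the MR-Egger intercept is compatible with zero
#' (`intercept_p >= 0.05`); (ii) IVW, Egger slope and weighted median agree in
#' sign; (iii) no between-SNP heterogeneity by either Cochran's or Ruecker's Q
#' (`p >= 0.05`); (iv) instruments are strong (`mean F > 10`, strict). The
#' result is `valid` only when all four hold; a missing estimator marks its
#' check `NA` and invalidates the result.
#'
#' @param ivw,egger,wmedian Results of [ivw_mre()], [mr_egger()],
#'   [weighted_median()] (any may be `NULL`).
#' @param q_cochran Result of [cochran_q()] (may be `NULL`).
#' @param mean_f Mean instrument F-statistic.
#' @return A list: `egger_intercept_ok`, `concordance_ok`, `heterogeneity_ok`,
#'   `strength_ok`, `valid`.
#' @export
assess_assumptions <- function(ivw, egger, wmedian, q_cochran, mean_f) {
  egger_ok <- if (is.null(egger)) NA else egger$intercept_p >= 0.05
  conc_ok <- if (is.null(ivw) || is.null(egger) || is.null(wmedian)) NA else {
    sgn <- sign(c(ivw$beta, egger$slope, wmedian$beta))
    all(sgn == sgn[1])
  }
  het_ok <- if (is.null(q_cochran) || is.null(egger)) NA else
    q_cochran$p >= 0.05 && egger$rucker_p >= 0.05
  strength_ok <- if (is.na(mean_f)) NA else mean_f > 10
  checks <- c(egger_ok, conc_ok, het_ok, strength_ok)
  list(egger_intercept_ok = egger_ok, concordance_ok = conc_ok,
       heterogeneity_ok = het_ok, strength_ok = strength_ok,
       valid = !anyNA(checks) && all(checks))
}

#' Two-sample MR of methylation at diet-associated CpGs on outcome traits
#'
#' Full per-(CpG, outcome) analysis: instrument selection with LD pruning,
#' allele harmonization, Steiger filtering, IVW (multiplicative random
#' effects) as the main estimate, MR-Egger and weighted-median as
#' sensitivity estimators, heterogeneity statistics and the assumption
#' checklist.
#'
#' @param mqtl Exposure mQTL table (columns of a GWAS summary table plus
#'   `cpg`).
#' @param gwas Named list of outcome summary tables, one per trait.
#' @param ld Named list of per-CpG LD r2 matrices.
#' @param binary_traits Traits whose estimates are odds ratios.
#' @param p_max,r2_max,palindromic_window,n_boot,seed Tuning parameters, see
#'   the individual estimators.
#' @return `data.frame` with one row per CpG x trait (CpGs without
#'   instruments are reported with `n_snps = 0`).
#' @export
mr_analysis <- function(mqtl, gwas, ld, binary_traits = character(),
                        p_max = 1e-8, r2_max = 0.8,
                        palindromic_window = c(0.42, 0.58),
                        n_boot = 1000, seed = 1) {
  rows <- list()
  for (cpg in unique(mqtl$cpg)) {
    exp_cpg <- mqtl[mqtl$cpg == cpg, , drop = FALSE]
    sel <- select_instruments(exp_cpg, ld[[cpg]], p_max, r2_max)
    for (trait in names(gwas)) {
      binary <- trait %in% binary_traits
      base <- data.frame(cpg = cpg, outcome = trait, n_snps = 0L,
                         beta = NA_real_, se = NA_real_, p = NA_real_,
                         or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                         egger_intercept = NA_real_, egger_intercept_p = NA_real_,
                         wmedian_beta = NA_real_, Q_cochran = NA_real_,
                         p_Qc = NA_real_, Q_rucker = NA_real_, p_Qr = NA_real_,
                         mean_F = NA_real_, egger_intercept_ok = NA,
                         concordance_ok = NA, heterogeneity_ok = NA,
                         strength_ok = NA, valid = FALSE,
                         stringsAsFactors = FALSE)
      if (!nrow(sel)) { rows[[length(rows) + 1L]] <- base; next }
      h <- harmonize(sel, gwas[[trait]], palindromic_window)
      if (nrow(h) >= 1)
        h <- steiger_filter(h, n_exp = exp_cpg$n[1], n_out = gwas[[trait]]$n[1])
      base$n_snps <- nrow(h)
      if (nrow(h) < 2) { rows[[length(rows) + 1L]] <- base; next }

      ivw <- ivw_mre(h, binary = binary)
      eg <- if (nrow(h) >= 3) mr_egger(h) else NULL
      wm <- if (nrow(h) >= 3)
        weighted_median(h, n_boot, substream_seed(seed, paste0(cpg, trait))) else NULL
      qc <- cochran_q(h, ivw$beta)
      mean_f <- mean(h$F)
      checks <- assess_assumptions(ivw, eg, wm, qc, mean_f)

      base$beta <- ivw$beta; base$se <- ivw$se; base$p <- ivw$p
      if (binary) { base$or <- ivw$or; base$or_lo <- ivw$or_lo; base$or_hi <- ivw$or_hi }
      if (!is.null(eg)) {
        base$egger_intercept <- eg$intercept
        base$egger_intercept_p <- eg$intercept_p
        base$Q_rucker <- eg$rucker_q; base$p_Qr <- eg$rucker_p
      }
      if (!is.null(wm)) base$wmedian_beta <- wm$beta
      base$Q_cochran <- qc$Q; base$p_Qc <- qc$p; base$mean_F <- mean_f
      base$egger_intercept_ok <- checks$egger_intercept_ok
      base$concordance_ok <- checks$concordance_ok
      base$heterogeneity_ok <- checks$heterogeneity_ok
      base$strength_ok <- checks$strength_ok
      base$valid <- checks$valid
      rows[[length(rows) + 1L]] <- base
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
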