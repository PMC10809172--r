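#' Inverse-variance meta-analysis with DerSimonian-Laird heterogeneity
#'
#' Fixed-effect pooling with weights `1/se^2`, Cochran's Q with its chi-square
#' p-value, `I2 = max(0, (Q - (k-1))/Q)`, the DerSimonian-Laird between-study
#' variance `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, and the
#' random-effects estimate with weights `1/(se^2 + tau2)`.
#'
#' @param betas,ses Per-cohort effect estimates and standard errors (`k >= 2`,
#'   all `ses > 0`). A single study is passed through with `k = 1` and the
#'   fixed and random summaries equal to the study itself.
#' @return One-row `data.frame`: `k`, `beta_fixed`, `se_fixed`, `Q`, `p_Q`,
#'   `I2`, `tau2`, `beta_random`, `se_random`.
#' @export
inverse_variance_meta <- function(betas, ses) {
  stopifnot(length(betas) == length(ses))
  ok <- is.finite(betas) & is.finite(ses)
  betas <- betas[ok]; ses <- ses[ok]
  if (any(ses <= 0)) .fail("all standard errors must be positive")
  k <- length(betas)
  if (k == 0) .fail("no studies to combine")
  if (k == 1) {
    return(data.frame(k = 1L, beta_fixed = betas, se_fixed = ses, Q = 0,
                      p_Q = NA_real_, I2 = 0, tau2 = 0, beta_random = betas,
                      se_random = ses))
  }
  w <- 1 / ses^2
  bF <- sum(w * betas) / sum(w)
  seF <- sqrt(1 / sum(w))
  Q <- sum(w * (betas - bF)^2)
  p_Q <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  bR <- sum(ws * betas) / sum(ws)
  seR <- sqrt(1 / sum(ws))
  data.frame(k = as.integer(k), beta_fixed = bF, se_fixed = seF, Q = Q,
             p_Q = p_Q, I2 = I2, tau2 = tau2, beta_random = bR, se_random = seR)
}

#' Choose the reported effect under the heterogeneity rule
#'
#' The random-effects summary is reported iff `I2 > 0.50` or the Q-test
#' p-value is below 0.05; otherwise the fixed effect is reported. The p-value
#' of the chosen effect uses the normal approximation.
#'
#' @param meta A (possibly many-row) `data.frame` from
#'   [inverse_variance_meta()].
#' @param i2_threshold,q_p_threshold Rule parameters (defaults 0.50 and 0.05).
#' @return `meta` with `chosen` (`"fixed"`/`"random"`), `beta`, `se`, `p`
#'   appended.
#' @export
select_effect <- function(meta, i2_threshold = 0.5, q_p_threshold = 0.05) {
  random <- meta$I2 > i2_threshold |
    (!is.na(meta$p_Q) & meta$p_Q < q_p_threshold)
  meta$chosen <- ifelse(random, "random", "fixed")
  meta$beta <- ifelse(random, meta$beta_random, meta$beta_fixed)
  meta$se <- ifelse(random, meta$se_random, meta$se_fixed)
  meta$p <- 2 * stats::pnorm(-abs(meta$beta / meta$se))
  meta
}

#' Bonferroni significance threshold
#'
#' @param m_tests Number of tests (> 0).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / m_tests`.
#' @export
bonferroni_threshold <- function(m_tests, alpha = 0.05) {
  if (m_tests <= 0) .fail("m_tests must be positive")
  alpha / m_tests
}

#' Flag Bonferroni-significant records
#'
#' @param records `data.frame` with a `p` column.
#' @param m_tests Number of tests; defaults to `nrow(records)`.
#' @param alpha Family-wise error rate.
#' @return `records` with a logical `bonferroni_hit` column
#'   (`p < alpha/m_tests`, strict).
#' @export
flag_hits <- function(records, m_tests = nrow(records), alpha = 0.05) {
  records$bonferroni_hit <- records$p < bonferroni_threshold(m_tests, alpha)
  records
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p P-values in (0, 1].
#' @return Vector of q-values (monotone in the sorted p-values, each `>=` its
#'   raw p-value).
#' @export
bh_fdr <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) .fail("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Meta-analyse per-cohort EWAS records across cohorts
#'
#' Combines records per (score, CpG) with [inverse_variance_meta()], applies
#' the heterogeneity rule, flags Bonferroni hits (the number of tests is the
#' count of CpGs analysed in at least two cohorts) and computes BH q-values
#' within each score across those CpGs.
#'
#' @param records `data.frame` with columns `cpg`, `score`, `cohort`, `beta`,
#'   `se` (e.g. stacked [fit_ewas()] outputs).
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param i2_threshold,q_p_threshold Heterogeneity-rule parameters.
#' @return `data.frame` with one row per (score, CpG): meta summaries, the
#'   chosen triplet, `bonferroni_hit` and `fdr_q` (NA for single-cohort CpGs,
#'   which are excluded from multiplicity control).
#' @export
meta_ewas <- function(records, alpha = 0.05, i2_threshold = 0.5,
                      q_p_threshold = 0.05) {
  need <- c("cpg", "score", "cohort", "beta", "se")
  miss <- setdiff(need, names(records))
  if (length(miss)) .fail("records missing columns: ", paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(records[, need])

  out <- lapply(split(dt, by = "score"), function(d) {
    B <- data.table::dcast(d, cpg ~ cohort, value.var = "beta")
    S <- data.table::dcast(d, cpg ~ cohort, value.var = "se")
    cpgs <- B$cpg
    Bm <- as.matrix(B[, -1]); Sm <- as.matrix(S[, -1])
    w <- 1 / Sm^2
    k <- rowSums(is.finite(w))
    sw <- rowSums(w, na.rm = TRUE)
    bF <- rowSums(w * Bm, na.rm = TRUE) / sw
    seF <- sqrt(1 / sw)
    Q <- rowSums(w * (Bm - bF)^2, na.rm = TRUE)
    p_Q <- ifelse(k >= 2, stats::pchisq(Q, df = k - 1, lower.tail = FALSE), NA)
    I2 <- ifelse(Q > 0, pmax(0, (Q - (k - 1)) / Q), 0)
    tau2 <- pmax(0, (Q - (k - 1)) / (sw - rowSums(w^2, na.rm = TRUE) / sw))
    tau2[k < 2] <- 0
    ws <- 1 / (Sm^2 + tau2)
    bR <- rowSums(ws * Bm, na.rm = TRUE) / rowSums(ws, na.rm = TRUE)
    seR <- sqrt(1 / rowSums(ws, na.rm = TRUE))
    res <- data.frame(cpg = cpgs, score = d$score[1], k = as.integer(k),
                      beta_fixed = bF, se_fixed = seF, Q = Q, p_Q = p_Q,
                      I2 = I2, tau2 = tau2, beta_random = bR, se_random = seR,
                      stringsAsFactors = FALSE)
    select_effect(res, i2_threshold, q_p_threshold)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tested <- res$k >= 2
  m_tests <- length(unique(res$cpg[tested]))
  res$bonferroni_hit <- tested & res$p < bonferroni_threshold(m_tests, alpha)
  res$fdr_q <- NA_real_
  for (s in unique(res$score)) {
    idx <- tested & res$score == s
    res$fdr_q[idx] <- bh_fdr(res$p[idx])
  }
  attr(res, "m_tests") <- m_tests
  res
}

#' Attenuation of the diet-CpG coefficient after BMI adjustment
#'
#' `pct_change = (beta_M1 - beta_M2) / beta_M1 * 100` (signed): positive
#' values mean the association weakens once BMI enters the model, negative
#' values mean it strengthens. An association is classified BMI-independent
#' when the signed change is below 10 percent.
#'
#' @param meta_m1,meta_m2 Meta-analysis results for Model 1 and Model 2 with
#'   columns `cpg`, `score`, `beta`.
#' @param threshold Attenuation threshold in percent (default 10).
#' @return `data.frame` with `cpg`, `score`, `beta_m1`, `beta_m2`,
#'   `pct_change`, `bmi_independent`. A zero Model-1 coefficient yields `NA`
#'   with `undefined = TRUE`.
#' @export
attenuation <- function(meta_m1, meta_m2, threshold = 10) {
  m <- merge(meta_m1[, c("cpg", "score", "beta")],
             meta_m2[, c("cpg", "score", "beta")],
             by = c("cpg", "score"), suffixes = c("_m1", "_m2"))
  names(m)[names(m) == "beta_m1"] <- "beta_m1"
  undef <- m$beta_m1 == 0
  pct <- ifelse(undef, NA_real_, (m$beta_m1 - m$beta_m2) / m$beta_m1 * 100)
  data.frame(cpg = m$cpg, score = m$score, beta_m1 = m$beta_m1,
             beta_m2 = m$beta_m2, pct_change = pct,
             bmi_independent = !undef & pct < threshold,
             undefined = undef, stringsAsFactors = FALSE)
}

#' Sensitivity meta-analysis excluding one cohort
#'
#' @param records Per-cohort EWAS records as in [meta_ewas()].
#' @param cohort Name of the cohort to leave out.
#' @param ... Passed to [meta_ewas()].
#' @return Meta results on the remaining cohorts, with the per-CpG percent
#'   change of the chosen coefficient versus the full meta-analysis attached
#'   as column `pct_change_vs_full`.
#' @export
leave_cohort_out <- function(records, cohort, ...) {
  if (!cohort %in% records$cohort) .fail("unknown cohort: ", cohort)
  full <- meta_ewas(records, ...)
  sub <- meta_ewas(records[records$cohort != cohort, , drop = FALSE], ...)
  idx <- match(paste(sub$cpg, sub$score), paste(full$cpg, full$score))
  b_full <- full$beta[idx]
  sub$pct_change_vs_full <- ifelse(b_full == 0, NA_real_,
                                   (b_full - sub$beta) / b_full * 100)
  sub
}

#' Correlation of meta-analysed coefficients between two diet scores
#'
#' @param meta_a,meta_b Meta results (columns `cpg`, `beta`) for two scores.
#' @return Pearson correlation over the shared CpGs (at least 10 required).
#' @export
coefficient_correlation <- function(meta_a, meta_b) {
  shared <- intersect(meta_a$cpg, meta_b$cpg)
  if (length(shared) < 10) .fail("need at least 10 shared CpGs")
  stats::cor(meta_a$beta[match(shared, meta_a$cpg)],
             meta_b$beta[match(shared, meta_b$cpg)])
}
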