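make_gwas <- function(snp, ea, oa, eaf, beta, se = 0.01, n = 300000) {
  data.frame(snp = snp, chr = 1, pos = seq_along(snp), effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), n = n, stringsAsFactors = FALSE)
}

test_that("greedy LD pruning keeps the best of each correlated pair", {
  mq <- data.frame(cpg = "cgX", snp = c("rs1", "rs2", "rs3"),
                   p = c(1e-20, 1e-10, 1e-15))
  ld <- diag(3); dimnames(ld) <- list(mq$snp, mq$snp)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- 0.95
  sel <- select_instruments(mq, ld, p_max = 1e-5)
  expect_setequal(sel$snp, c("rs1", "rs3"))
  # uncorrelated SNPs all pass; the p filter applies first
  ld0 <- diag(3); dimnames(ld0) <- dimnames(ld)
  expect_equal(nrow(select_instruments(mq, ld0, p_max = 1e-5)), 3)
  expect_equal(nrow(select_instruments(mq, ld0, p_max = 1e-30)), 0)
  # independent oracle on a random 12-SNP block instance
  with_seed(149, {
    J <- 12
    mq2 <- data.frame(cpg = "cgY", snp = paste0("s", 1:J), p = runif(J, 1e-30, 1e-9))
    R <- diag(J)
    for (j in seq(2, J, by = 2)) R[j, j - 1] <- R[j - 1, j] <- 0.9
    dimnames(R) <- list(mq2$snp, mq2$snp)
    sel2 <- select_instruments(mq2, R, p_max = 1e-8)
    cand <- mq2[mq2$p < 1e-8, ]
    cand <- cand[order(cand$p), ]
    kept <- character(0)
    for (s in cand$snp) if (!length(kept) || all(R[s, kept] < 0.8)) kept <- c(kept, s)
    expect_equal(sel2$snp, kept)
  })
})

test_that("harmonization aligns alleles per the full case table and is idempotent", {
  ex <- make_gwas(paste0("rs", 1:6),
                  ea = c("A", "A", "A", "A", "A", "A"),
                  oa = c("G", "G", "G", "G", "T", "T"),
                  eaf = c(0.3, 0.3, 0.3, 0.3, 0.50, 0.20),
                  beta = rep(0.2, 6), se = 0.02, n = 27000)
  ou <- make_gwas(paste0("rs", 1:6),
                  ea = c("A", "G", "T", "A", "A", "T"),
                  oa = c("G", "A", "C", "C", "T", "A"),
                  eaf = c(0.3, 0.7, 0.3, 0.3, 0.5, 0.8),
                  beta = c(0.10, 0.10, 0.10, 0.10, 0.10, 0.10))
  h <- suppressMessages(harmonize(ex, ou))
  # rs1 same orientation; rs2 swapped (sign flip); rs3 strand-flipped same;
  # rs4 incompatible (dropped); rs5 palindromic at eaf 0.5 (dropped);
  # rs6 palindromic outside the window, stored swapped (sign flip)
  expect_setequal(h$snp, c("rs1", "rs2", "rs3", "rs6"))
  expect_equal(h$beta_out[h$snp == "rs1"], 0.10)
  expect_equal(h$beta_out[h$snp == "rs2"], -0.10)
  expect_equal(h$beta_out[h$snp == "rs3"], 0.10)
  expect_equal(h$beta_out[h$snp == "rs6"], -0.10)
  expect_true(all(h$palindromic[h$snp == "rs6"]))
  expect_equal(h$F, (h$beta_exp / h$se_exp)^2)
  expect_equal(h$wald_ratio, h$beta_out / h$beta_exp)

  # idempotence: re-harmonizing the already aligned outcome changes nothing
  ou2 <- ou[ou$snp %in% h$snp, ]
  ou2$beta <- h$beta_out[match(ou2$snp, h$snp)]
  ou2$effect_allele <- ex$effect_allele[match(ou2$snp, ex$snp)]
  ou2$other_allele <- ex$other_allele[match(ou2$snp, ex$snp)]
  ou2$eaf <- ex$eaf[match(ou2$snp, ex$snp)]
  h2 <- suppressMessages(harmonize(ex, ou2))
  expect_equal(h2[, c("snp", "beta_out", "se_out")],
               h[, c("snp", "beta_out", "se_out")])

  expect_error(harmonize(rbind(ex, ex[1, ]), ou), "duplicate")
})

test_that("Steiger filtering keeps forward-causal SNPs and drops ties", {
  ins <- data.frame(snp = c("fwd", "rev", "tie"),
                    beta_exp = c(0.30, 0.02, 0.10), se_exp = 0.01,
                    beta_out = c(0.06, 0.30, 0.10), se_out = 0.01)
  # equal z and equal n on both sides fails the strict inequality
  out <- steiger_filter(ins, n_exp = 10000, n_out = 10000)
  expect_setequal(out$snp, "fwd")
  # explicit r2 example: strong exposure, weak outcome, unequal n
  ins2 <- data.frame(snp = "a", beta_exp = 0.3, se_exp = 0.01,
                     beta_out = 0.01, se_out = 0.01)
  expect_equal(nrow(steiger_filter(ins2, 27000, 300000)), 1)
})

test_that("IVW matches the weighted-through-origin oracle and its edge cases", {
  # identical Wald ratios collapse to that ratio with no extra dispersion
  ins <- data.frame(beta_exp = c(0.2, 0.4, 0.3), se_exp = 0.01,
                    beta_out = c(0.1, 0.2, 0.15), se_out = c(0.01, 0.02, 0.015))
  est <- ivw_mre(ins)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_lte(est$phi, 1)

  with_seed(151, {
    ins <- sim_instruments(J = 3, theta = 0.15, seed = 7)
    est <- ivw_mre(ins)
    w <- 1 / ins$se_out^2
    b_or <- sum(w * ins$beta_exp * ins$beta_out) / sum(w * ins$beta_exp^2)
    expect_equal(est$beta, b_or, tolerance = 1e-12)
    # independent route: weighted lm through the origin
    lmfit <- lm(beta_out ~ 0 + beta_exp, data = ins, weights = w)
    expect_equal(est$beta, unname(coef(lmfit)), tolerance = 1e-12)
    # scale invariance: multiplying exposure betas by c divides the slope by c
    ins2 <- ins; ins2$beta_exp <- ins$beta_exp * 2.5
    expect_equal(ivw_mre(ins2)$beta, est$beta / 2.5, tolerance = 1e-12)
  })
  expect_error(ivw_mre(ins[1, , drop = FALSE]), "at least 2")
  # binary outcomes are exponentiated with a 95% CI
  ins <- sim_instruments(J = 10, theta = 0.1, seed = 9)
  eb <- ivw_mre(ins, binary = TRUE)
  expect_equal(eb$or, exp(eb$beta))
  expect_lt(eb$or_lo, eb$or); expect_gt(eb$or_hi, eb$or)
})

test_that("MR-Egger recovers proportionality, pleiotropy, and the WLS oracle", {
  # exact proportionality: zero intercept, slope equals the ratio
  ins <- data.frame(beta_exp = c(0.2, 0.3, 0.4, 0.5), se_exp = 0.01,
                    beta_out = c(0.04, 0.06, 0.08, 0.10), se_out = 0.01)
  eg <- mr_egger(ins)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_equal(eg$slope, 0.2, tolerance = 1e-12)
  expect_equal(eg$rucker_q, 0, tolerance = 1e-18)

  with_seed(157, {
    ins <- sim_instruments(J = 8, theta = 0.2, seed = 11, positive_exposure = TRUE)
    eg <- mr_egger(ins)
    lmfit <- lm(beta_out ~ beta_exp, data = ins, weights = 1 / ins$se_out^2)
    expect_equal(eg$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
    expect_equal(eg$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)

    # planted directional pleiotropy of +0.05 shows up in the intercept
    ins50 <- sim_instruments(J = 50, theta = 0.2, pleio = 0.05, seed = 13,
                             positive_exposure = TRUE)
    eg50 <- mr_egger(ins50)
    expect_lt(abs(eg50$intercept - 0.05), 0.02)
    expect_lt(eg50$intercept_p, 0.05)
  })
  expect_error(mr_egger(ins[1:2, ]), "at least 3")
})

test_that("weighted median is exact on symmetric ratios, robust, and seeded", {
  ins <- data.frame(beta_exp = c(1, 1, 1), se_exp = 0.01,
                    beta_out = c(1, 2, 3), se_out = 1)
  wm <- weighted_median(ins, n_boot = 50, seed = 5)
  expect_equal(wm$beta, 2)
  # one wild outlier among consistent ratios barely moves the estimate
  ins10 <- data.frame(beta_exp = rep(1, 10), se_exp = 0.01,
                      beta_out = c(rep(0.2, 9), 5), se_out = 0.1)
  wm10 <- weighted_median(ins10, n_boot = 100, seed = 5)
  expect_lt(abs(wm10$beta - 0.2), 0.05)
  # determinism of the bootstrap SE
  a <- weighted_median(ins10, n_boot = 200, seed = 42)
  b <- weighted_median(ins10, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
})

test_that("Cochran's Q is zero under proportionality and matches its formula", {
  ins <- data.frame(beta_exp = c(0.2, 0.4), se_exp = 0.01,
                    beta_out = c(0.1, 0.2), se_out = 0.01)
  q <- cochran_q(ins, ivw_mre(ins)$beta)
  expect_equal(q$Q, 0, tolerance = 1e-18)
  ins <- sim_instruments(J = 12, theta = 0.2, seed = 17)
  b <- ivw_mre(ins)$beta
  q <- cochran_q(ins, b)
  manual <- sum((ins$beta_out - b * ins$beta_exp)^2 / ins$se_out^2)
  expect_equal(q$Q, manual, tolerance = 1e-12)
  expect_equal(q$p, pchisq(manual, 11, lower.tail = FALSE))
})

test_that("the assumption checklist applies its strict rules", {
  ivw <- list(beta = 0.2); wm <- list(beta = 0.1)
  eg <- list(slope = 0.15, intercept_p = 0.5, rucker_p = 0.6)
  qc <- list(p = 0.7)
  ck <- assess_assumptions(ivw, eg, wm, qc, mean_f = 100)
  expect_true(ck$valid)
  # mean F exactly 10 fails the strict inequality
  ck10 <- assess_assumptions(ivw, eg, wm, qc, mean_f = 10)
  expect_false(ck10$strength_ok); expect_false(ck10$valid)
  # discordant sign breaks concordance
  ckd <- assess_assumptions(list(beta = -0.2), eg, wm, qc, 100)
  expect_false(ckd$concordance_ok)
  # a missing estimator leaves its check unknown and invalidates the result
  ckm <- assess_assumptions(ivw, NULL, wm, qc, 100)
  expect_true(is.na(ckm$egger_intercept_ok))
  expect_false(ckm$valid)
})

test_that("the per-CpG MR pipeline runs on simulated summary data", {
  cfg <- sim_config(seed = 163, cohorts = list(cohort_spec("A", 50, "450K")),
                    n_cpgs = 40, n_diet_cpgs = 2, n_smoking_cpgs = 0,
                    n_bmi_cpgs = 0,
                    gwas = list(theta_per_trait = c(bmi = 0.2, t2d = 0.1),
                                binary_traits = "t2d"))
  truth <- simulate_truth(cfg)
  gen <- simulate_mqtl_and_gwas(truth, cfg)
  res <- mr_analysis(gen$mqtl, gen$gwas, gen$ld, binary_traits = "t2d",
                     n_boot = 100)
  expect_equal(nrow(res), 2 * 2)
  bmi_rows <- res[res$outcome == "bmi", ]
  expect_true(all(bmi_rows$n_snps >= 2))
  expect_true(all(abs(bmi_rows$beta - 0.2) < 4 * bmi_rows$se))
  expect_true(all(res$mean_F > 10, na.rm = TRUE))
  t2d_rows <- res[res$outcome == "t2d", ]
  expect_true(all(is.finite(t2d_rows$or)))
  # a CpG with no instruments is reported, not dropped
  mq_weak <- gen$mqtl; mq_weak$p <- 0.5
  res0 <- mr_analysis(mq_weak, gen$gwas, gen$ld, n_boot = 10)
  expect_true(all(res0$n_snps == 0))
  expect_true(all(!res0$valid))
})
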