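test_that("two symmetric equal-weight studies reproduce the closed form", {
  m <- inverse_variance_meta(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(m$beta_fixed, 0.2)
  expect_equal(m$se_fixed, sqrt(1 / 200), tolerance = 1e-12)  # 0.07071...
  expect_equal(m$Q, 2)
  expect_equal(m$I2, 0.5)
  expect_equal(m$tau2, 0.01)
  expect_equal(m$beta_random, 0.2)
  expect_equal(m$se_random, 0.1)
})

test_that("identical studies show no heterogeneity and fixed equals random", {
  m <- inverse_variance_meta(rep(0.12, 4), rep(0.03, 4))
  expect_equal(m$Q, 0)
  expect_equal(m$I2, 0)
  expect_equal(m$tau2, 0)
  expect_equal(m$beta_random, m$beta_fixed)
  expect_equal(m$se_random, m$se_fixed)
})

test_that("random instances match the closed-form oracle and metafor", {
  skip_if_not_installed("metafor")
  with_seed(113, {
    for (i in 1:25) {
      k <- sample(3:7, 1)
      b <- rnorm(k, 0.05, 0.1)
      s <- runif(k, 0.01, 0.2)
      m <- inverse_variance_meta(b, s)
      o <- oracle_meta(b, s)
      for (f in names(o)) expect_equal(m[[f]], o[[f]], tolerance = 1e-12)
      # independent route: metafor's DerSimonian-Laird fit
      rma_re <- metafor::rma(yi = b, sei = s, method = "DL")
      expect_equal(m$tau2, unname(rma_re$tau2), tolerance = 1e-8)
      expect_equal(m$beta_random, unname(rma_re$beta[1]), tolerance = 1e-8)
      expect_equal(m$se_random, unname(rma_re$se), tolerance = 1e-8)
      rma_fe <- metafor::rma(yi = b, sei = s, method = "FE")
      expect_equal(m$beta_fixed, unname(rma_fe$beta[1]), tolerance = 1e-8)
      expect_equal(m$Q, unname(rma_fe$QE), tolerance = 1e-8)
    }
  })
  # se_random never undercuts se_fixed
  with_seed(119, {
    for (i in 1:20) {
      b <- rnorm(4); s <- runif(4, 0.05, 0.2)
      m <- inverse_variance_meta(b, s)
      expect_gte(m$se_random, m$se_fixed - 1e-12)
    }
  })
})

test_that("the heterogeneity rule selects the reported effect", {
  base <- data.frame(k = 5, beta_fixed = 0.1, se_fixed = 0.02, Q = 4,
                     I2 = NA, p_Q = NA, tau2 = 0.001,
                     beta_random = 0.12, se_random = 0.03)
  m <- base; m$I2 <- 0.557; m$p_Q <- 0.2
  expect_equal(select_effect(m)$chosen, "random")
  m <- base; m$I2 <- 0.2; m$p_Q <- 0.5
  expect_equal(select_effect(m)$chosen, "fixed")
  m <- base; m$I2 <- 0.3; m$p_Q <- 0.01
  expect_equal(select_effect(m)$chosen, "random")
  # boundary: I2 exactly 0.50 with p_Q at 0.05 stays fixed (strict rules)
  m <- base; m$I2 <- 0.50; m$p_Q <- 0.05
  expect_equal(select_effect(m)$chosen, "fixed")
  # tau2 = 0 implies random equals fixed exactly
  m0 <- inverse_variance_meta(rep(0.1, 3), rep(0.05, 3))
  sel <- select_effect(m0)
  expect_equal(sel$beta, m0$beta_fixed)
})

test_that("Bonferroni threshold and flags behave", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(signif(bonferroni_threshold(463932), 3), 1.08e-7)
  rec <- data.frame(p = c(1e-9, 2e-7, 0.5))
  fl <- flag_hits(rec, m_tests = 463932)
  expect_equal(fl$bonferroni_hit, c(TRUE, FALSE, FALSE))
  expect_error(bonferroni_threshold(0), "positive")
})

test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  with_seed(127, {
    p <- runif(200)^2
    q <- bh_fdr(p)
    # brute-force step-up: q_(i) = min over j >= i of m p_(j) / j
    o <- order(p)
    m <- length(p)
    q_oracle <- numeric(m)
    sorted <- p[o] * m / seq_len(m)
    q_oracle[o] <- rev(cummin(rev(sorted)))
    q_oracle <- pmin(q_oracle, 1)
    expect_equal(q, q_oracle, tolerance = 1e-12)
    expect_true(all(q >= p))
  })
  expect_error(bh_fdr(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("attenuation arithmetic and classification follow the formula", {
  m1 <- data.frame(cpg = c("a", "b", "c"), score = "MMDS",
                   beta = c(0.0774, 0.0688, 0.05))
  m2 <- data.frame(cpg = c("a", "b", "c"), score = "MMDS",
                   beta = c(0.0771, 0.0800, 0.05))
  at <- attenuation(m1, m2)
  expect_equal(at$pct_change[at$cpg == "a"], (0.0774 - 0.0771) / 0.0774 * 100)
  expect_equal(round(at$pct_change[at$cpg == "b"], 2), -16.28)
  expect_equal(at$pct_change[at$cpg == "c"], 0)
  expect_true(all(at$bmi_independent))
  # strong attenuation flips the flag; beta_m1 = 0 is undefined
  m1$beta <- c(0.10, 0, 0.05); m2$beta <- c(0.05, 0.01, 0.05)
  at <- attenuation(m1, m2)
  expect_false(at$bmi_independent[at$cpg == "a"])  # 50% attenuation
  expect_true(at$undefined[at$cpg == "b"])
})

test_that("fixed effect is invariant to ordering and study splitting", {
  b <- c(0.1, -0.05, 0.2); s <- c(0.05, 0.08, 0.1)
  m <- inverse_variance_meta(b, s)
  m_rev <- inverse_variance_meta(rev(b), rev(s))
  expect_equal(m$beta_fixed, m_rev$beta_fixed)
  expect_equal(m$Q, m_rev$Q)
  # splitting study 1 into two half-precision copies leaves beta_F unchanged
  m_split <- inverse_variance_meta(c(0.1, 0.1, -0.05, 0.2),
                                   c(0.05 * sqrt(2), 0.05 * sqrt(2), 0.08, 0.1))
  expect_equal(m_split$beta_fixed, m$beta_fixed, tolerance = 1e-12)
})

test_that("meta_ewas pools per (score, CpG), honours k and multiplicity rules", {
  with_seed(131, {
    cpgs <- sprintf("cg%03d", 1:40)
    recs <- do.call(rbind, lapply(c("C1", "C2", "C3"), function(co) {
      data.frame(cpg = cpgs, score = "DASH", cohort = co,
                 beta = rnorm(40, 0, 0.05), se = runif(40, 0.02, 0.05))
    }))
    # five CpGs observed in only two cohorts, one in a single cohort
    recs <- recs[!(recs$cohort == "C3" & recs$cpg %in% cpgs[1:5]), ]
    recs <- recs[!(recs$cohort %in% c("C2", "C3") & recs$cpg == cpgs[6]), ]
    res <- meta_ewas(recs)
    expect_equal(res$k[match(cpgs[1], res$cpg)], 2L)
    expect_equal(res$k[match(cpgs[6], res$cpg)], 1L)
    expect_true(is.na(res$fdr_q[match(cpgs[6], res$cpg)]))
    expect_equal(attr(res, "m_tests"), 39L)
    # per-CpG agreement with the scalar function
    for (cpg in cpgs[c(1, 10, 20)]) {
      sub <- recs[recs$cpg == cpg, ]
      m <- inverse_variance_meta(sub$beta, sub$se)
      i <- match(cpg, res$cpg)
      expect_equal(res$beta_fixed[i], m$beta_fixed, tolerance = 1e-12)
      expect_equal(res$tau2[i], m$tau2, tolerance = 1e-12)
    }
    # Bonferroni hits are a subset of FDR hits at matched alpha
    hits_b <- res$cpg[res$bonferroni_hit]
    hits_f <- res$cpg[!is.na(res$fdr_q) & res$fdr_q < 0.05]
    expect_true(all(hits_b %in% hits_f))
    expect_true(all(res$fdr_q >= res$p - 1e-15, na.rm = TRUE))
  })
})

test_that("leave-one-cohort-out equals a fresh meta-analysis of the subset", {
  with_seed(137, {
    recs <- do.call(rbind, lapply(c("C1", "C2", "C3", "C4"), function(co) {
      data.frame(cpg = sprintf("cg%03d", 1:15), score = "MMDS", cohort = co,
                 beta = rnorm(15, 0, 0.05), se = runif(15, 0.02, 0.05))
    }))
    loo <- leave_cohort_out(recs, "C2")
    fresh <- meta_ewas(recs[recs$cohort != "C2", ])
    expect_equal(loo$beta, fresh$beta, tolerance = 1e-12)
    expect_true(all(loo$k == 3))
    expect_true("pct_change_vs_full" %in% names(loo))
    expect_error(leave_cohort_out(recs, "NOPE"), "unknown cohort")
  })
})

test_that("coefficient correlation over shared CpGs matches cor()", {
  with_seed(139, {
    a <- data.frame(cpg = sprintf("cg%03d", 1:30), beta = rnorm(30))
    b <- data.frame(cpg = sprintf("cg%03d", 11:40), beta = rnorm(30))
    shared <- sprintf("cg%03d", 11:30)
    manual <- cor(a$beta[match(shared, a$cpg)], b$beta[match(shared, b$cpg)])
    expect_equal(coefficient_correlation(a, b), manual)
    expect_equal(coefficient_correlation(a, a), 1)
    expect_error(coefficient_correlation(a[1:5, ], b), "at least 10")
  })
})
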