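test_that("cohort simulation is deterministic and validates its inputs", {
  cfg <- sim_config(seed = 11, cohorts = small_cohorts(), n_cpgs = 50,
                    n_diet_cpgs = 3, n_smoking_cpgs = 3, n_bmi_cpgs = 3)
  a <- simulate_cohort(cfg, "ALPHA")
  b <- simulate_cohort(cfg, "ALPHA")
  expect_identical(a, b)
  expect_error(simulate_cohort(cfg, "NOPE"), "unknown cohort")
  expect_error(cohort_spec("X", 0), "positive")

  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1, st2)
})

test_that("cell fractions are a simplex and the table passes validation", {
  cfg <- sim_config(seed = 3, cohorts = small_cohorts(), n_cpgs = 20,
                    n_diet_cpgs = 0, n_smoking_cpgs = 0, n_bmi_cpgs = 0)
  for (nm in c("ALPHA", "BETA")) {
    ph <- simulate_cohort(cfg, nm)
    cf <- as.matrix(ph[, cell_types()])
    expect_true(all(cf >= 0))
    expect_lt(max(abs(rowSums(cf) - 1)), 1e-12)
    expect_true(validate_phenotypes(ph))
  }
  # single-sex cohort really is single sex
  expect_setequal(unique(simulate_cohort(cfg, "ALPHA")$sex), "F")
})

test_that("zero latent loadings remove the shared diet factor", {
  zero <- default_diet_loadings() * 0
  cfg <- sim_config(seed = 5, cohorts = list(cohort_spec("BIG", 2000, "450K")),
                    n_cpgs = 10, n_diet_cpgs = 0, n_smoking_cpgs = 0,
                    n_bmi_cpgs = 0, latent_diet_loading = zero)
  ph <- simulate_cohort(cfg, "BIG")
  h <- attr(ph, "latent")
  sc <- suppressMessages(compute_diet_scores(ph))
  # no score carries the latent factor any more ...
  expect_lt(abs(cor(sc$mmds_raw, h)), 0.1)
  expect_lt(abs(cor(sc$dash_raw, h)), 0.1)
  expect_lt(abs(cor(sc$hpdi_raw, h)), 0.1)
  # ... and the pairwise correlations fall back to the structural floor the
  # shared food components impose (the indices overlap by construction)
  cfg_def <- sim_config(seed = 5, cohorts = list(cohort_spec("BIG", 2000, "450K")),
                        n_cpgs = 10, n_diet_cpgs = 0, n_smoking_cpgs = 0,
                        n_bmi_cpgs = 0)
  sc_def <- suppressMessages(compute_diet_scores(simulate_cohort(cfg_def, "BIG")))
  expect_lt(cor(sc$mmds_raw, sc$dash_raw), cor(sc_def$mmds_raw, sc_def$dash_raw))
})

test_that("default generator gives moderately correlated scores", {
  cfg <- sim_config(seed = 21, cohorts = list(cohort_spec("BIG", 2000, "450K")),
                    n_cpgs = 10, n_diet_cpgs = 0, n_smoking_cpgs = 0,
                    n_bmi_cpgs = 0)
  sc <- suppressMessages(compute_diet_scores(simulate_cohort(cfg, "BIG")))
  r <- cor(sc$mmds_raw, sc$dash_raw)
  expect_gt(r, 0.3)
  expect_lt(r, 0.7)
})

test_that("methylation with no effects and no noise is constant per CpG", {
  cfg <- sim_config(seed = 9, cohorts = list(cohort_spec("A", 40, "450K")),
                    n_cpgs = 30, epic_only_frac = 0, n_diet_cpgs = 0,
                    n_smoking_cpgs = 0, n_bmi_cpgs = 0, cell_effect_sd = 0,
                    batch_effect_sd = 0, cluster_effect_sd = 0, noise_sd = 0)
  truth <- simulate_truth(cfg)
  me <- simulate_methylation(simulate_cohort(cfg, "A"), truth, cfg)
  expect_equal(dim(me$M), c(30, 40))
  expect_true(all(apply(me$M, 1, function(x) max(x) - min(x)) == 0))
  expect_equal(unname(me$M[, 1]), unname(truth$baseline[rownames(me$M)]))
})

test_that("OLS on the generating design recovers the planted diet effect", {
  cfg <- sim_config(seed = 13, cohorts = list(cohort_spec("BIG", 2000, "450K")),
                    n_cpgs = 60, n_diet_cpgs = 6, n_smoking_cpgs = 0,
                    n_bmi_cpgs = 0, batch_effect_sd = 0, cell_effect_sd = 0)
  truth <- simulate_truth(cfg)
  ph <- simulate_cohort(cfg, "BIG")
  me <- simulate_methylation(ph, truth, cfg)
  sc <- suppressMessages(compute_diet_scores(ph))
  z <- list(DASH = sc$dash_z, MMDS = sc$mmds_z, HPDI = sc$hpdi_z)
  for (i in seq_len(nrow(truth$diet_cpgs))) {
    row <- truth$diet_cpgs[i, ]
    fit <- lm(me$M[row$cpg, ] ~ z[[row$score]])
    est <- coef(summary(fit))[2, ]
    expect_lt(abs(est["Estimate"] - row$effect), 2 * est["Std. Error"])
  }
})

test_that("mediated CpGs associate under Model 1 and attenuate once BMI enters", {
  cfg <- sim_config(seed = 17, cohorts = list(cohort_spec("BIG", 4000, "450K")),
                    n_cpgs = 40, n_diet_cpgs = 6, frac_mediated = 1,
                    n_smoking_cpgs = 0, n_bmi_cpgs = 0, batch_effect_sd = 0,
                    cell_effect_sd = 0, noise_sd = 0.3)
  truth <- simulate_truth(cfg)
  ph <- simulate_cohort(cfg, "BIG")
  me <- simulate_methylation(ph, truth, cfg)
  sc <- suppressMessages(compute_diet_scores(ph))
  z <- list(DASH = sc$dash_z, MMDS = sc$mmds_z, HPDI = sc$hpdi_z)
  atten <- vapply(seq_len(nrow(truth$diet_cpgs)), function(i) {
    row <- truth$diet_cpgs[i, ]
    y <- me$M[row$cpg, ]
    b1 <- coef(lm(y ~ z[[row$score]]))[2]
    b2 <- coef(lm(y ~ z[[row$score]] + ph$bmi))[2]
    c(b1 = unname(b1), pct = unname((b1 - b2) / b1 * 100))
  }, numeric(2))
  expect_true(all(abs(atten["b1", ]) > 0.01))  # Model-1 association present
  expect_true(all(atten["pct", ] > 10))        # attenuates once BMI adjusted
})

test_that("EPIC-only CpGs are absent from 450K cohorts and meta-analysable at k=2", {
  cfg <- sim_config(seed = 23, cohorts = small_cohorts(c(60, 60, 60, 60)),
                    n_cpgs = 100, epic_only_frac = 0.2, n_diet_cpgs = 0,
                    n_smoking_cpgs = 0, n_bmi_cpgs = 0)
  st <- simulate_study(cfg)
  epic_only <- st$truth$annotation$cpg[st$truth$annotation$array == "EPIC"]
  expect_gt(length(epic_only), 0)
  expect_false(any(epic_only %in% rownames(st$methylation$ALPHA$M)))
  expect_true(all(epic_only %in% rownames(st$methylation$GAMMA$M)))
})

test_that("mQTL/GWAS generator honours theta, pleiotropy and LD structure", {
  cfg <- sim_config(seed = 29, cohorts = list(cohort_spec("A", 50, "450K")),
                    n_cpgs = 40, n_diet_cpgs = 3, n_smoking_cpgs = 0,
                    n_bmi_cpgs = 0,
                    mqtl = list(snps_per_cpg = 20, ld_block_r2 = 0.95),
                    gwas = list(theta_per_trait = c(bmi = 0.2, chd = 0),
                                binary_traits = "chd", pleiotropy_sd = 0))
  truth <- simulate_truth(cfg)
  gen <- simulate_mqtl_and_gwas(truth, cfg)

  # theta = 0 outcome: every SNP effect within 4 SE of zero
  chd <- gen$gwas$chd
  expect_true(all(abs(chd$beta) < 4 * chd$se))

  # theta = 0.2: IVW on truth-harmonized instruments recovers it
  cpg <- truth$diet_cpgs$cpg[1]
  ex <- gen$mqtl[gen$mqtl$cpg == cpg, ]
  bmi <- gen$gwas$bmi[match(ex$snp, gen$gwas$bmi$snp), ]
  aligned_beta <- ifelse(bmi$effect_allele == ex$effect_allele,
                         bmi$beta, -bmi$beta)
  h <- data.frame(beta_exp = ex$beta, se_exp = ex$se,
                  beta_out = aligned_beta, se_out = bmi$se)
  est <- ivw_mre(h)
  expect_lt(abs(est$beta - 0.2), 3 * est$se)

  # LD blocks: pruning at 0.8 keeps one SNP per correlated pair
  sel <- select_instruments(ex, gen$ld[[cpg]], p_max = 1, r2_max = 0.8)
  expect_equal(nrow(sel), 10)

  # trait without theta errors
  bad <- truth
  bad$causal_theta$trait[1] <- "unknown_trait"
  expect_error(simulate_mqtl_and_gwas(bad, cfg), "without causal theta")
})
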