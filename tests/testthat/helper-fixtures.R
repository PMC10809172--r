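# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; nothing is read from disk except the
# bundled example tables.

# a small four-cohort layout exercising every structural feature: one
# single-sex multi-ethnic cohort, one family-clustered cohort, two EPIC
small_cohorts <- function(n = c(300, 400, 250, 350)) {
  list(
    cohort_spec("ALPHA", n[1], "450K", n_batches = 3, female_frac = 1,
                age_mean = 64, multi_ethnic = TRUE),
    cohort_spec("BETA",  n[2], "450K", n_batches = 3, female_frac = 0.55,
                age_mean = 66, family_clusters = TRUE),
    cohort_spec("GAMMA", n[3], "EPIC", n_batches = 2, female_frac = 0.5,
                age_mean = 57),
    cohort_spec("DELTA", n[4], "EPIC", n_batches = 3, female_frac = 0.45,
                age_mean = 41)
  )
}

# a deterministic single-cohort phenotype table with n distinct intake levels
# per food group (so quantile bins are fully determined)
grid_phenotypes <- function(n = 5, cohort = "GRID") {
  ranks <- seq_len(n)
  tab <- data.frame(
    participant_id = sprintf("%s_%03d", cohort, ranks), cohort = cohort,
    age = 50 + ranks, sex = rep("F", n), ethnicity = "white",
    smoking = "never", bmi = 25 + ranks / 10, energy = 2000,
    cluster_id = sprintf("c%03d", ranks), batch = "b1",
    stringsAsFactors = FALSE
  )
  cf <- matrix(1 / 6, n, 6, dimnames = list(NULL, cell_types()))
  tab <- cbind(tab, as.data.frame(cf))
  for (g in food_groups()) tab[[g]] <- as.numeric(ranks)
  tab
}

# a tiny two-cohort study with genetics, for IO and pipeline tests
small_study <- function(seed = 191) {
  cfg <- sim_config(seed = seed,
                    cohorts = list(cohort_spec("A", 40, "450K", n_batches = 2),
                                   cohort_spec("B", 50, "EPIC", n_batches = 2)),
                    n_cpgs = 30, n_diet_cpgs = 2, n_smoking_cpgs = 2,
                    n_bmi_cpgs = 2, mqtl = list(snps_per_cpg = 6))
  simulate_study(cfg)
}

# independent rank-then-bin oracle (positions in the sorted vector, average
# rank for ties, equal-probability right-closed bins)
oracle_bin <- function(x, nb, reverse = FALSE) {
  n <- length(x)
  o <- order(x)
  pos <- seq_len(n)
  r <- numeric(n)
  for (v in unique(x)) r[x == v] <- mean(pos[x[o] == v])
  b <- pmin(pmax(ceiling(nb * r / n), 1), nb)
  if (reverse) b <- nb + 1 - b
  b
}

oracle_dash <- function(tb) {
  oracle_bin(tb$fruits, 5) + oracle_bin(tb$vegetables, 5) +
    oracle_bin(tb$nuts + tb$legumes, 5) + oracle_bin(tb$dairy_lowfat, 5) +
    oracle_bin(tb$whole_grains, 5) +
    oracle_bin(tb$sodium_mg, 5, TRUE) + oracle_bin(tb$ssb, 5, TRUE) +
    oracle_bin(tb$red_processed_meat, 5, TRUE)
}

oracle_hpdi <- function(tb) {
  healthy <- c("whole_grains", "fruits", "vegetables", "nuts", "legumes",
               "vegetable_oils", "tea_coffee")
  rev_cols <- c("fruit_juice", "refined_grains", "potatoes", "ssb",
                "sweets_desserts", "animal_fat", "dairy_total", "eggs",
                "fish", "red_processed_meat", "misc_animal")
  Reduce(`+`, lapply(tb[healthy], oracle_bin, nb = 5)) +
    Reduce(`+`, lapply(tb[rev_cols], oracle_bin, nb = 5, reverse = TRUE))
}

oracle_mmds <- function(tb, window = list(F = c(5, 25), M = c(10, 50))) {
  ratio <- tb$mufa_g / pmax(tb$sfa_g, 1e-8)
  ratio <- pmin(ratio, quantile(ratio, 0.99, names = FALSE))
  pos_cols <- list(tb$vegetables, tb$fruits, tb$nuts, tb$legumes,
                   tb$whole_grains, tb$fish, ratio)
  tot <- Reduce(`+`, lapply(pos_cols, function(x) oracle_bin(x, 4) - 1)) +
    oracle_bin(tb$red_processed_meat, 4, TRUE) - 1
  lo <- unname(vapply(window[tb$sex], `[`, 0, 1))
  hi <- unname(vapply(window[tb$sex], `[`, 0, 2))
  unname(tot + 3 * (tb$alcohol_g >= lo & tb$alcohol_g <= hi))
}

# independent DerSimonian-Laird oracle, written from the closed formulas
oracle_meta <- function(b, s) {
  w <- 1 / s^2
  bF <- sum(w * b) / sum(w)
  Q <- sum(w * (b - bF)^2)
  k <- length(b)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (s^2 + tau2)
  list(beta_fixed = bF, se_fixed = sqrt(1 / sum(w)), Q = Q,
       p_Q = pchisq(Q, k - 1, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0, tau2 = tau2,
       beta_random = sum(ws * b) / sum(ws), se_random = sqrt(1 / sum(ws)))
}

# simulate an already-harmonized instrument set under known causal theta
sim_instruments <- function(J = 20, theta = 0.2, pleio = 0, n_exp = 27000,
                            n_out = 300000, seed = 1, positive_exposure = FALSE) {
  with_seed(seed, {
    eaf <- runif(J, 0.1, 0.9)
    bx <- runif(J, 0.1, 0.5)
    if (!positive_exposure) bx <- bx * sample(c(-1, 1), J, replace = TRUE)
    se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exp)
    se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * n_out)
    bxh <- bx + rnorm(J, 0, se_exp)
    byh <- theta * bx + pleio + rnorm(J, 0, se_out)
    data.frame(snp = paste0("rs", seq_len(J)), beta_exp = bxh, se_exp = se_exp,
               beta_out = byh, se_out = se_out, eaf = eaf, palindromic = FALSE,
               F = (bxh / se_exp)^2, wald_ratio = byh / bxh,
               stringsAsFactors = FALSE)
  })
}
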