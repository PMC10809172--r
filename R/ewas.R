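#' M-values from probe intensities or beta-values
#'
#' `m_from_intensities()` computes `log2((meth + alpha) / (unmeth + alpha))`
#' with the usual offset `alpha = 1`; `m_from_beta()` is the logit2 transform
#' `log2(beta / (1 - beta))`. M-values near 0 correspond to half-methylated
#' CpGs; positive values mean more methylated than unmethylated signal.
#'
#' @param meth,unmeth Nonnegative probe intensities.
#' @param alpha Constant offset (default 1).
#' @param beta Methylation proportions strictly inside (0, 1).
#' @return Numeric M-values.
#' @export
m_from_intensities <- function(meth, unmeth, alpha = 1) {
  if (any(meth < 0) || any(unmeth < 0)) .fail("intensities must be nonnegative")
  log2((meth + alpha) / (unmeth + alpha))
}

#' @rdname m_from_intensities
#' @export
m_from_beta <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) .fail("beta-values must lie strictly in (0,1)")
  log2(beta / (1 - beta))
}

#' Standardize an M-value matrix per CpG
#'
#' Centers and scales each CpG (row) to mean 0, SD 1, the scale on which
#' effect sizes are reported as "M-value SDs per SD of score". Zero-variance
#' CpGs are dropped with a warning.
#'
#' @param M CpG x sample numeric matrix.
#' @return The standardized matrix (possibly with fewer rows).
#' @export
scale_mvalues <- function(M) {
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2) / (ncol(M) - 1))
  zero <- s == 0 | !is.finite(s)
  if (any(zero)) {
    warning(sum(zero), " zero-variance CpG(s) dropped")
    M <- M[!zero, , drop = FALSE]
    mu <- mu[!zero]; s <- s[!zero]
  }
  (M - mu) / s
}

#' Build the covariate design matrix for one cohort, score and model
#'
#' Columns: intercept, the standardized diet score, age, energy, a sex dummy
#' (omitted in single-sex cohorts), two smoking dummies (never = reference),
#' five cell fractions (granulocytes dropped to avoid collinearity with the
#' intercept), an ethnicity dummy when the cohort is multi-ethnic, BMI under
#' Model 2, and any surrogate variables supplied.
#'
#' @param phenotypes One cohort's phenotype table.
#' @param score_z Standardized diet score vector (one value per row).
#' @param model `"M1"` (no BMI) or `"M2"` (adds BMI).
#' @param surrogates Optional n x k matrix of surrogate variables.
#' @return Numeric design matrix with column names; the exposure column is
#'   named `"score"`. A rank-deficient design raises an error listing the
#'   collinear columns.
#' @export
build_design <- function(phenotypes, score_z, model = c("M1", "M2"),
                         surrogates = NULL) {
  model <- match.arg(model)
  n <- nrow(phenotypes)
  stopifnot(length(score_z) == n)
  X <- cbind(intercept = rep(1, n), score = score_z,
             age = phenotypes$age, energy = phenotypes$energy)
  if (length(unique(phenotypes$sex)) > 1)
    X <- cbind(X, sex_M = as.numeric(phenotypes$sex == "M"))
  # never = reference; a dummy is emitted only for levels actually present
  # (a single-level cohort or stratum contributes no smoking columns)
  if (any(phenotypes$smoking == "former"))
    X <- cbind(X, smoking_former = as.numeric(phenotypes$smoking == "former"))
  if (any(phenotypes$smoking == "current"))
    X <- cbind(X, smoking_current = as.numeric(phenotypes$smoking == "current"))
  cell_cols <- setdiff(cell_types(), "Gran")
  X <- cbind(X, as.matrix(phenotypes[, cell_cols]))
  if ("ethnicity" %in% names(phenotypes) &&
      length(unique(phenotypes$ethnicity)) > 1)
    X <- cbind(X, ethnicity_nonwhite = as.numeric(phenotypes$ethnicity != "white"))
  if (model == "M2") X <- cbind(X, bmi = phenotypes$bmi)
  if (!is.null(surrogates)) {
    surrogates <- as.matrix(surrogates)
    if (ncol(surrogates) > 0) {
      colnames(surrogates) <- paste0("sv", seq_len(ncol(surrogates)))
      X <- cbind(X, surrogates)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    .fail("design matrix is rank deficient; collinear column(s): ",
          paste(dropped, collapse = ", "))
  }
  X
}

#' Estimate surrogate variables by residual-space PCA
#'
#' Regresses every CpG on the base design, then extracts the top-k principal
#' directions of the samples in the residual space (left singular vectors of
#' the residual matrix), capturing unmodelled technical or biological
#' structure such as batch. Vectors are orthonormal with the sign fixed so the
#' first nonzero loading is positive.
#'
#' @param M CpG x sample matrix.
#' @param design Base design matrix (n x p).
#' @param k Number of surrogate variables; `k <= 0` returns a zero-column
#'   matrix.
#' @return n x k matrix of surrogate variables.
#' @export
estimate_surrogates <- function(M, design, k) {
  n <- ncol(M)
  if (k <= 0) return(matrix(0, n, 0))
  if (k >= n) .fail("k must be smaller than the number of samples")
  Y <- t(M)
  B <- solve(crossprod(design), crossprod(design, Y))
  R <- Y - design %*% B
  ev <- eigen(tcrossprod(R), symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    nz <- which(abs(V[, j]) > 1e-8)[1]
    if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("sv", seq_len(k))
  V
}

# demean columns of a matrix within clusters (fixed-effects absorption)
.cluster_demean <- function(A, cluster) {
  cluster <- as.character(cluster)
  sums <- rowsum(A, cluster)
  sizes <- as.vector(table(cluster)[rownames(sums)])
  A - (sums / sizes)[cluster, , drop = FALSE]
}

#' Per-CpG linear association of methylation with the diet score
#'
#' Ordinary least squares of every CpG's (standardized) M-values on the design
#' matrix, reporting the coefficient of the exposure column with its standard
#' error and a two-sided t-test p-value. When `cluster_id` is supplied, all
#' variables are demeaned within clusters before fitting (fixed-effects
#' absorption of family/chip groups) and the residual degrees of freedom are
#' reduced by the number of clusters.
#'
#' @param M CpG x sample matrix (typically from [scale_mvalues()]).
#' @param design Design matrix from [build_design()].
#' @param cluster_id Optional cluster labels (length n).
#' @param coef Name of the exposure column (default `"score"`).
#' @return `data.frame` with `cpg`, `beta`, `se`, `t`, `p`, `n`, `df`. CpGs
#'   with non-finite values are skipped with a warning.
#' @export
fit_ewas <- function(M, design, cluster_id = NULL, coef = "score") {
  stopifnot(coef %in% colnames(design), ncol(M) == nrow(design))
  bad <- !apply(is.finite(M), 1, all)
  if (any(bad)) {
    warning(sum(bad), " CpG(s) with non-finite values skipped")
    M <- M[!bad, , drop = FALSE]
  }
  n <- ncol(M)
  Y <- t(M)
  X <- design
  if (!is.null(cluster_id)) {
    stopifnot(length(cluster_id) == n)
    n_cl <- length(unique(cluster_id))
    Y <- .cluster_demean(Y, cluster_id)
    X <- .cluster_demean(X, cluster_id)
    keep <- colnames(X) != "intercept" & apply(X, 2, function(x) any(abs(x) > 1e-10))
    if (!coef %in% colnames(X)[keep])
      .fail("exposure column has no within-cluster variation")
    X <- X[, keep, drop = FALSE]
    df <- n - ncol(X) - n_cl
  } else {
    df <- n - ncol(X)
  }
  if (df <= 2) .fail("not enough residual degrees of freedom (", df, ")")

  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  j <- match(coef, colnames(X))
  beta <- B[j, ]
  se <- sqrt(sigma2 * XtXi[j, j])
  tval <- beta / se
  data.frame(cpg = colnames(Y), beta = unname(beta), se = unname(se),
             t = unname(tval), p = unname(2 * stats::pt(-abs(tval), df)),
             n = n, df = df, stringsAsFactors = FALSE, row.names = NULL)
}

#' Genomic inflation factor of a set of p-values
#'
#' `lambda = median(observed chi-square) / median(null chi-square)`, where the
#' observed statistics are the 1-df chi-square quantiles of the p-values.
#' Values above about 1.05 indicate residual confounding or other inflation.
#'
#' @param p P-values in (0, 1]; at least 100 are required.
#' @return The inflation factor lambda.
#' @export
genomic_lambda <- function(p) {
  if (length(p) < 100) .fail("need at least 100 p-values to estimate lambda")
  if (any(p <= 0 | p > 1)) .fail("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Smoking-stratified EWAS
#'
#' Runs [fit_ewas()] separately in never smokers and ever smokers (former +
#' current), with the smoking dummies removed from the design. Strata with too
#' few participants are skipped with a warning.
#'
#' @param M CpG x sample matrix.
#' @param phenotypes Matching phenotype table.
#' @param score_z Standardized score vector.
#' @param model `"M1"` or `"M2"`.
#' @param surrogates Optional surrogate-variable matrix (n x k), subset per
#'   stratum.
#' @return Named list of per-stratum `data.frame`s (`never`, `ever`).
#' @export
stratified_ewas <- function(M, phenotypes, score_z, model = "M1",
                            surrogates = NULL) {
  strata <- list(never = phenotypes$smoking == "never",
                 ever = phenotypes$smoking %in% c("former", "current"))
  out <- list()
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    if (!any(idx)) {
      warning("stratum '", nm, "' is empty; skipped")
      next
    }
    ph <- phenotypes[idx, , drop = FALSE]
    ph$smoking <- "never"  # collapses the smoking dummies to zero columns
    X <- build_design(ph, score_z[idx], model,
                      surrogates = if (is.null(surrogates)) NULL
                      else surrogates[idx, , drop = FALSE])
    X <- X[, !grepl("^smoking_", colnames(X)), drop = FALSE]
    if (nrow(X) <= ncol(X) + 2) {
      warning("stratum '", nm, "' too small; skipped")
      next
    }
    out[[nm]] <- fit_ewas(M[, idx, drop = FALSE], X)
  }
  out
}
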