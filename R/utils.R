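#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a known state, evaluates `expr`, and restores the caller's
#' RNG state afterwards, so that internally seeded simulations never disturb
#' the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic substream seed from a global seed and a label
#'
#' One global seed drives the whole simulation; per-cohort (and per-stage)
#' substreams are derived from `(seed, label)` so that adding a cohort never
#' shifts the random numbers of another. The result is kept inside the 32-bit
#' integer range R requires of `set.seed()`.
#'
#' @param seed Integer global seed.
#' @param label Character label of the substream (e.g. `"cohort:FOS"`).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  ints <- utf8ToInt(label)
  h <- sum(ints * seq_along(ints)) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 1009 + 17) %% 2147483646 + 1)
}

#' Quantile-based component scoring
#'
#' Assigns each observation to one of `n_bins` equal-probability bins of the
#' empirical distribution (ties resolved by average rank, right-closed bins),
#' the construction used by quintile/quartile diet-index components. Because it
#' operates on ranks, the binning is invariant to any strictly monotone
#' transform of the input.
#'
#' @param x Numeric vector of intakes.
#' @param n_bins Number of bins (5 for quintiles, 4 for quartiles).
#' @param reverse If `TRUE`, the highest intake gets bin 1 (reverse scoring).
#' @return Integer-ish vector of bins in `1:n_bins` (midpoint `(n_bins+1)/2`
#'   with a warning when `x` is constant).
#' @export
quantile_score <- function(x, n_bins, reverse = FALSE) {
  stopifnot(n_bins >= 2)
  ok <- !is.na(x)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  if (length(unique(x[ok])) == 1L) {
    warning("constant component: all participants scored at the midpoint")
    out[ok] <- (n_bins + 1) / 2
    return(out)
  }
  r <- rank(x[ok], ties.method = "average")
  b <- ceiling(n_bins * r / length(r))
  b[b < 1] <- 1
  b[b > n_bins] <- n_bins
  if (reverse) b <- n_bins + 1 - b
  out[ok] <- b
  out
}

#' Quantile-quantile plot of association p-values
#'
#' Draws observed versus expected -log10 p-values with the identity line, the
#' standard diagnostic for residual inflation in epigenome-wide scans.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param main Plot title.
#' @return Invisibly, the genomic inflation factor computed from `p`.
#' @export
qq_pvalues <- function(p, main = "QQ plot") {
  p <- sort(p[is.finite(p)])
  n <- length(p)
  exp_q <- -log10((seq_len(n) - 0.5) / n)
  graphics::plot(exp_q, -log10(p), pch = 16, cex = 0.4,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), main = main)
  graphics::abline(0, 1, col = "red")
  invisible(genomic_lambda(p))
}

# internal: stop() with a compact message assembled from pieces
.fail <- function(...) stop(paste0(...), call. = FALSE)
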