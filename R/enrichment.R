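#' Gene-set overrepresentation of the genes annotated to significant CpGs
#'
#' One-sided hypergeometric tail test per gene set: given a foreground of hit
#' genes inside a background universe, the p-value is the probability of
#' drawing at least the observed overlap when sampling `|foreground|` genes
#' without replacement. BH FDR is computed across the sets of the collection.
#' Genes with more array probes are more likely to be hit; no probe-number
#' correction is applied here (a documented limitation), but a pre-weighted
#' background may be supplied instead.
#'
#' @param foreground Character vector of hit genes (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @return `data.frame` with `set`, `set_size` (within the universe),
#'   `overlap`, `p`, `fdr_q`, sorted by p.
#' @export
gene_overrepresentation <- function(foreground, background, collection) {
  foreground <- unique(foreground)
  background <- unique(background)
  stray <- setdiff(foreground, background)
  if (length(stray))
    .fail("foreground gene(s) absent from background: ",
          paste(utils::head(stray, 5), collapse = ", "),
          if (length(stray) > 5) ", ..." else "")
  if (!length(collection) || is.null(names(collection)))
    .fail("collection must be a non-empty named list of gene sets")
  N <- length(background)
  n_fg <- length(foreground)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), background)
    ov <- length(intersect(set, foreground))
    p <- stats::phyper(ov - 1, length(set), N - length(set), n_fg,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Positional/chromatin category overrepresentation of hit CpGs
#'
#' For each category level (gene-position class, island relation or chromatin
#' state), builds the 2x2 table of hit versus non-hit CpGs in and out of the
#' category and runs Fisher's exact test, with BH FDR across levels.
#'
#' @param hit_categories Category labels of the significant CpGs.
#' @param background_categories Category labels of all tested CpGs (the hits
#'   must be drawn from this background).
#' @return `data.frame` with `category`, counts, `odds_ratio`, `p`, `fdr_q`,
#'   and `degenerate = TRUE` (p forced to 1) for zero-margin tables.
#' @export
category_overrepresentation <- function(hit_categories, background_categories) {
  n_hit <- length(hit_categories)
  n_bg <- length(background_categories)
  if (n_hit > n_bg) .fail("more hits than background CpGs")
  levels_all <- sort(unique(background_categories))
  rows <- lapply(levels_all, function(lv) {
    a <- sum(hit_categories == lv)            # hit, in category
    b <- n_hit - a                            # hit, out
    c_ <- sum(background_categories == lv) - a # non-hit, in
    d <- (n_bg - n_hit) - c_                  # non-hit, out
    tab <- matrix(c(a, b, c_, d), 2)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      p <- 1; or <- NA_real_
    } else {
      ft <- stats::fisher.test(tab)
      p <- ft$p.value; or <- unname(ft$estimate)
    }
    data.frame(category = lv, hit_in = a, hit_out = b, bg_in = c_ + a,
               bg_out = d + b, odds_ratio = or, p = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$p)
  out
}
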