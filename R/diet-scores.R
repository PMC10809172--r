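#' Exclude energy under- and over-reporters
#'
#' Removes participants whose reported total energy intake falls outside
#' sex-specific plausibility bounds, the standard cleaning step before diet
#' scores are computed. Rows with missing energy are flagged and removed with
#' a warning.
#'
#' @param table Phenotype table.
#' @param bounds Named list with elements `F` and `M`, each `c(lower, upper)`
#'   kcal/day.
#' @return The filtered table, with `attr(,"n_removed")` recording the count.
#' @export
filter_implausible_energy <- function(table,
                                      bounds = list(F = c(500, 3500),
                                                    M = c(800, 4200))) {
  for (s in c("F", "M")) {
    b <- bounds[[s]]
    if (is.null(b) || length(b) != 2 || any(b <= 0) || b[1] >= b[2])
      .fail("energy bounds for sex '", s, "' must be positive with lower < upper")
  }
  na_energy <- is.na(table$energy)
  if (any(na_energy))
    warning(sum(na_energy), " row(s) with missing energy removed")
  lo <- unlist(bounds)[paste0(table$sex, "1")]
  hi <- unlist(bounds)[paste0(table$sex, "2")]
  keep <- !na_energy & table$energy >= lo & table$energy <= hi
  out <- table[keep, , drop = FALSE]
  n_removed <- nrow(table) - nrow(out)
  if (n_removed > 0)
    message("energy filter: removed ", n_removed, " of ", nrow(table),
            " participants")
  attr(out, "n_removed") <- n_removed
  out
}

# sum of bin scores across components, keeping NA participants (missing any
# component) out of the total
.sum_components <- function(bins, label) {
  total <- Reduce(`+`, bins)
  n_na <- sum(is.na(total))
  if (n_na > 0)
    message(label, ": ", n_na, " participant(s) with missing components excluded")
  total
}

#' DASH diet score (quintile-based, range 8-40)
#'
#' Eight components: fruits, vegetables, nuts and legumes, low-fat dairy and
#' whole grains scored 1-5 by cohort-specific quintile rank; sodium, sweetened
#' beverages and red/processed meat reverse-scored 5-1.
#'
#' @param table Phenotype table for a single cohort.
#' @return Numeric vector of raw DASH totals (one per row of `table`).
#' @export
compute_dash <- function(table) {
  pos <- list(fruits = table$fruits, vegetables = table$vegetables,
              nuts_legumes = table$nuts + table$legumes,
              dairy_lowfat = table$dairy_lowfat,
              whole_grains = table$whole_grains)
  neg <- list(sodium = table$sodium_mg, ssb = table$ssb,
              red_processed_meat = table$red_processed_meat)
  bins <- c(lapply(pos, quantile_score, n_bins = 5),
            lapply(neg, quantile_score, n_bins = 5, reverse = TRUE))
  .sum_components(bins, "DASH")
}

#' Healthful plant-based diet index (quintile-based, range 18-90)
#'
#' Seven healthy plant foods scored 1-5 by cohort quintiles; five less-healthy
#' plant foods and six animal foods reverse-scored 5-1.
#'
#' @inheritParams compute_dash
#' @return Numeric vector of raw HPDI totals.
#' @export
compute_hpdi <- function(table) {
  healthy <- c("whole_grains", "fruits", "vegetables", "nuts", "legumes",
               "vegetable_oils", "tea_coffee")
  unhealthy_plant <- c("fruit_juice", "refined_grains", "potatoes", "ssb",
                       "sweets_desserts")
  animal <- c("animal_fat", "dairy_total", "eggs", "fish",
              "red_processed_meat", "misc_animal")
  bins <- c(lapply(table[healthy], quantile_score, n_bins = 5),
            lapply(table[c(unhealthy_plant, animal)], quantile_score,
                   n_bins = 5, reverse = TRUE))
  .sum_components(bins, "HPDI")
}

#' Modified Mediterranean diet score (quartile-based, range 0-27)
#'
#' Vegetables, fruits, nuts, legumes, whole grains, fish and the MUFA:SFA
#' ratio are scored 0-3 by cohort quartiles; red and processed meat is
#' reverse-scored 3-0; alcohol scores 3 inside a sex-specific moderate window
#' (default 5-25 g/day for women, 10-50 g/day for men) and 0 outside. The
#' MUFA:SFA ratio is capped at its 99th percentile before binning so that
#' near-zero SFA intakes cannot blow it up.
#'
#' @inheritParams compute_dash
#' @param alcohol_window Named list of `c(lower, upper)` g/day per sex.
#' @return Numeric vector of raw MMDS totals.
#' @export
compute_mmds <- function(table,
                         alcohol_window = list(F = c(5, 25), M = c(10, 50))) {
  ratio <- table$mufa_g / pmax(table$sfa_g, 1e-8)
  cap <- stats::quantile(ratio, 0.99, na.rm = TRUE, names = FALSE)
  ratio <- pmin(ratio, cap)
  pos <- list(vegetables = table$vegetables, fruits = table$fruits,
              nuts = table$nuts, legumes = table$legumes,
              whole_grains = table$whole_grains, fish = table$fish,
              mufa_sfa = ratio)
  bins <- c(lapply(pos, function(x) quantile_score(x, 4) - 1),
            list(red_processed_meat =
                   quantile_score(table$red_processed_meat, 4, reverse = TRUE) - 1))
  lo <- vapply(alcohol_window[table$sex], `[`, 0, 1)
  hi <- vapply(alcohol_window[table$sex], `[`, 0, 2)
  alc <- ifelse(is.na(table$alcohol_g), NA_real_,
                3 * (table$alcohol_g >= lo & table$alcohol_g <= hi))
  .sum_components(c(bins, list(alcohol = alc)), "MMDS")
}

#' Standardize raw diet scores within each cohort
#'
#' @param scores `data.frame` with `participant_id`, `cohort` and raw score
#'   columns (any of `mmds_raw`, `dash_raw`, `hpdi_raw`).
#' @return The input with `*_z` columns appended: `(x - cohort mean)/cohort SD`
#'   (n-1 denominator). A zero-SD score raises an error naming the score.
#' @export
standardize_scores <- function(scores) {
  raw_cols <- intersect(c("mmds_raw", "dash_raw", "hpdi_raw"), names(scores))
  if (!length(raw_cols)) .fail("no raw score columns found")
  for (col in raw_cols) {
    z <- rep(NA_real_, nrow(scores))
    for (co in unique(scores$cohort)) {
      idx <- scores$cohort == co
      x <- scores[[col]][idx]
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.na(s) && s == 0)
        .fail("score '", col, "' is constant in cohort '", co,
              "': cannot standardize")
      z[idx] <- (x - mean(x, na.rm = TRUE)) / s
    }
    scores[[sub("_raw$", "_z", col)]] <- z
  }
  scores
}

#' Compute all three diet scores for a (possibly multi-cohort) phenotype table
#'
#' @param table Phenotype table; rows may span several cohorts, quantile
#'   boundaries and standardization are always cohort-specific.
#' @return `data.frame` with raw and per-cohort standardized scores.
#' @export
compute_diet_scores <- function(table) {
  validate_phenotypes(table)
  pieces <- lapply(split(table, table$cohort), function(tb) {
    data.frame(participant_id = tb$participant_id, cohort = tb$cohort,
               mmds_raw = compute_mmds(tb), dash_raw = compute_dash(tb),
               hpdi_raw = compute_hpdi(tb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[match(table$participant_id, out$participant_id), ]
  rownames(out) <- NULL
  standardize_scores(out)
}

#' Pairwise Pearson correlations of the three diet scores, per cohort
#'
#' @param scores Output of [compute_diet_scores()].
#' @return Named list of 3x3 symmetric correlation matrices with unit
#'   diagonal; constant scores give `NA` entries with a warning.
#' @export
score_correlations <- function(scores) {
  cols <- c("mmds_raw", "dash_raw", "hpdi_raw")
  lapply(split(scores, scores$cohort), function(sc) {
    if (nrow(sc) < 3) .fail("need at least 3 participants per cohort")
    m <- as.matrix(sc[, cols])
    const <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
    if (any(const))
      warning("constant score(s): ", paste(cols[const], collapse = ", "),
              "; correlation undefined")
    r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
    diag(r) <- 1
    r
  })
}
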