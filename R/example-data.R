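#' Bundled example summary tables
#'
#' Small plain-text tables distributed with the package, from a published
#' meta-analysis of three diet-quality scores and blood DNA methylation in
#' four adult cohorts (about 5300 participants, 450K/EPIC arrays):
#'
#' * `meta_tophits.tsv` — the 20 score-CpG meta-analysis records reaching
#'   epigenome-wide significance (18 distinct CpGs), with chosen coefficient,
#'   SE, p-value and between-cohort I2.
#' * `attenuation_published.tsv` — the six CpGs whose association survived
#'   BMI adjustment, with Model 1 and Model 2 coefficients and the percent
#'   change the source computed from unrounded coefficients.
#' * `cohort_summary.tsv` — descriptive characteristics per analysis sample
#'   (size, women, age, BMI, energy, score means/SDs).
#'
#' These tables let the multiple-testing, attenuation and pooling arithmetic
#' be exercised on real published numbers without any access-controlled data.
#'
#' @param name File name of the table.
#' @return `data.frame` of the requested table.
#' @examples
#' hits <- example_table("meta_tophits.tsv")
#' table(hits$score)
#' @export
example_table <- function(name = c("meta_tophits.tsv",
                                   "attenuation_published.tsv",
                                   "cohort_summary.tsv")) {
  name <- match.arg(name)
  path <- system.file("extdata", name, package = "dietmethyl", mustWork = TRUE)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = NULL))
}
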