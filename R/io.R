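#' @importFrom data.table fread fwrite as.data.table dcast :=
NULL

# round numeric columns to 10 significant digits so written tables are
# diff-able and deterministic across platforms
.signif_cols <- function(df, digits = 10) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

.check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    .fail("file '", path, "' is missing column(s): ", paste(miss, collapse = ", "))
}

.check_unique <- function(x, what, path) {
  d <- which(duplicated(x))
  if (length(d))
    .fail("file '", path, "' has duplicate ", what, " (first at row ", d[1], ")")
}

#' Read and write the pipeline's TSV schemas
#'
#' All tables are tab-separated with a header; floats are serialized with 10
#' significant digits. Readers validate the declared columns and key
#' uniqueness and fail fast naming the file, column and row; extra columns
#' are preserved.
#'
#' @param path File path.
#' @param table,matrix Object to write.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) .fail("phenotype file not found: ", path)
  df <- as.data.frame(fread(path, sep = "\t"))
  .check_columns(df, c("participant_id", "cohort", "age", "sex", "smoking",
                       "bmi", "energy", "cluster_id", "batch",
                       cell_types(), food_groups()), path)
  .check_unique(df$participant_id, "participant_id", path)
  validate_phenotypes(df)
  df
}

#' @rdname pipeline_io
#' @export
write_phenotypes <- function(table, path) {
  fwrite(.signif_cols(as.data.frame(table)), path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) .fail("annotation file not found: ", path)
  df <- as.data.frame(fread(path, sep = "\t"))
  .check_columns(df, c("cpg", "chr", "pos", "gene", "island_relation",
                       "position_class"), path)
  .check_unique(df$cpg, "cpg ids", path)
  df
}

#' @rdname pipeline_io
#' @export
write_annotation <- function(table, path) {
  fwrite(as.data.frame(table), path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_methylation_matrix <- function(path) {
  if (!file.exists(path)) .fail("methylation file not found: ", path)
  df <- fread(path, sep = "\t")
  if (names(df)[1] != "cpg") .fail("file '", path, "' must start with a 'cpg' column")
  .check_unique(df$cpg, "cpg ids", path)
  M <- as.matrix(df[, -1])
  rownames(M) <- df$cpg
  if (!is.numeric(M)) .fail("file '", path, "' has non-numeric M-values")
  M
}

#' @rdname pipeline_io
#' @export
write_methylation_matrix <- function(matrix, path) {
  df <- data.table::data.table(cpg = rownames(matrix))
  df <- cbind(df, signif(matrix, 10))
  fwrite(df, path, sep = "\t")
  invisible(path)
}

.gwas_cols <- c("snp", "chr", "pos", "effect_allele", "other_allele", "eaf",
                "beta", "se", "p", "n")

#' @rdname pipeline_io
#' @export
read_gwas_table <- function(path) {
  if (!file.exists(path)) .fail("summary-statistics file not found: ", path)
  df <- as.data.frame(fread(path, sep = "\t"))
  .check_columns(df, .gwas_cols, path)
  bad <- which(df$eaf <= 0 | df$eaf >= 1)
  if (length(bad)) .fail("file '", path, "': eaf outside (0,1) at row ", bad[1])
  bad <- which(df$se <= 0)
  if (length(bad)) .fail("file '", path, "': non-positive se at row ", bad[1])
  bad <- which(!(df$effect_allele %in% c("A", "C", "G", "T")) |
                 !(df$other_allele %in% c("A", "C", "G", "T")))
  if (length(bad)) .fail("file '", path, "': invalid allele at row ", bad[1])
  df
}

#' @rdname pipeline_io
#' @export
read_mqtl_table <- function(path) {
  df <- read_gwas_table(path)
  .check_columns(df, "cpg", path)
  .check_unique(paste(df$cpg, df$snp), "(cpg, snp) pairs", path)
  df
}

#' @rdname pipeline_io
#' @export
write_gwas_table <- function(table, path) {
  fwrite(.signif_cols(as.data.frame(table)), path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) .fail("LD file not found: ", path)
  df <- fread(path, sep = "\t")
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    .fail("file '", path, "' is not a square SNP-keyed matrix")
  m
}

#' @rdname pipeline_io
#' @export
write_ld_matrix <- function(matrix, path) {
  df <- data.table::data.table(snp = rownames(matrix))
  df <- cbind(df, signif(matrix, 10))
  fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_table_tsv <- function(table, path) {
  fwrite(.signif_cols(as.data.frame(table)), path, sep = "\t")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  as.data.frame(fread(path, sep = "\t"))
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (the descriptions are kept as
#'   `attr(,"description")`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .fail("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    .fail("file '", path, "': line ", short[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(names(sets))) .fail("file '", path, "': duplicate set names")
  attr(sets, "description") <- vapply(parts, `[`, "", 2)
  sets
}

#' Write a simulated study to a directory of plain-text files
#'
#' Phenotypes, M-value matrices and CpG annotation per cohort, mQTL and
#' per-trait GWAS tables, per-CpG LD matrices, and the ground truth as YAML.
#'
#' @param study A `diet_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "diet_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in names(study$phenotypes)) {
    paths[[paste0("phenotypes_", nm)]] <-
      write_phenotypes(study$phenotypes[[nm]],
                       file.path(dir, paste0("phenotypes_", nm, ".tsv")))
    paths[[paste0("methylation_", nm)]] <-
      write_methylation_matrix(study$methylation[[nm]]$M,
                               file.path(dir, paste0("methylation_", nm, ".tsv")))
  }
  paths$annotation <- write_annotation(study$truth$annotation,
                                       file.path(dir, "annotation.tsv"))
  paths$mqtl <- write_gwas_table(study$mqtl, file.path(dir, "mqtl.tsv"))
  for (tr in names(study$gwas))
    paths[[paste0("gwas_", tr)]] <-
      write_gwas_table(study$gwas[[tr]], file.path(dir, paste0("gwas_", tr, ".tsv")))
  dir.create(file.path(dir, "ld"), showWarnings = FALSE)
  for (cpg in names(study$ld))
    paths[[paste0("ld_", cpg)]] <-
      write_ld_matrix(study$ld[[cpg]], file.path(dir, "ld", paste0(cpg, ".tsv")))
  truth <- study$truth
  yaml::write_yaml(list(diet_cpgs = truth$diet_cpgs,
                        smoking_cpgs = truth$smoking_cpgs,
                        bmi_cpgs = truth$bmi_cpgs,
                        causal_theta = truth$causal_theta),
                   file.path(dir, "truth.yaml"))
  paths$truth <- file.path(dir, "truth.yaml")
  invisible(paths)
}
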