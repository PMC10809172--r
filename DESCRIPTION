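Package: dietmethyl
Title: Meta-Analysis of Epigenome-Wide Associations with Diet Quality and
    Downstream Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how overall diet quality relates to blood DNA
    methylation and, through methylation, to cardiometabolic traits. Computes
    three food-based diet-quality indices (a modified Mediterranean diet score,
    a DASH score and a healthful plant-based diet index) from food-group intake
    tables; runs per-cohort epigenome-wide association studies of standardized
    scores on M-values with cell-type, smoking and surrogate-variable
    adjustment; estimates and corrects test-statistic bias and inflation with a
    three-component Gaussian-mixture model; combines cohorts by inverse-variance
    meta-analysis with DerSimonian-Laird heterogeneity and Bonferroni/FDR
    control; classifies associations by their attenuation after BMI adjustment;
    and performs two-sample Mendelian randomization of methylation on
    cardiometabolic outcomes using mQTL instruments with LD pruning, allele
    harmonization, Steiger filtering and a pleiotropy assumption checklist.
    A synthetic-data module generates multi-cohort phenotype, methylation,
    mQTL and outcome-GWAS data with known ground truth so that every stage of
    the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
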