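Package: vitapath
Title: Microbe-Mediated Vitamin Metabolism Profiling for Gut Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles B-vitamin and menaquinone biosynthesis and transport
    pathways in shotgun metagenomes from KEGG Orthology annotated gene counts;
    classifies microbial species as vitamin producers, consumers, or dual
    producer-consumers; builds Spearman co-occurrence networks between species
    with thresholded edge classification; evaluates boolean gene-protein-reaction
    rules from genome-scale metabolic models to score vitamin-pathway coverage
    and assemble cohort-ordered abundance-weighted coverage matrices; and runs
    the accompanying nonparametric group comparisons (Mann-Whitney-Wilcoxon,
    Kruskal-Wallis, Bonferroni correction, indicator regression). Ships a
    synthetic-data generator that plants recoverable phenotypes, correlations,
    group shifts, and pathway completeness so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
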