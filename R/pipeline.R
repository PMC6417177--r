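#' Pipeline run configuration
#'
#' Bundles the input paths and tuning parameters for [run_pipeline()].
#'
#' @param catalog,gene_counts,annotation,totals,gene_species,species_phylum,
#'   species_abundance,gpr_models,metadata Input file paths (`totals` and
#'   `gpr_models` optional).
#' @param vitamins Vitamin filter for phenotype-pair edge labels (default:
#'   biotin, cobalamin, thiamine — the three vitamins most prevalent across
#'   gut species).
#' @param alpha Edge significance level in (0, 1), default 0.01.
#' @param rho_cutoff Positive-correlation threshold in \[0, 1\], default 0.4.
#' @param family Optional Bonferroni family-size override for the group
#'   comparisons.
#' @param reference_group Reference (healthy) group for the coverage matrix
#'   and as first level of comparisons.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the run manifest.
#' @return A `vita_config` list.
#' @export
run_config <- function(catalog, gene_counts, annotation, gene_species,
                       species_phylum, species_abundance, metadata,
                       totals = NULL, gpr_models = NULL,
                       vitamins = c("BIO", "COB", "THI"),
                       alpha = 0.01, rho_cutoff = 0.4, family = NULL,
                       reference_group = "healthy",
                       out_dir = "vitapath_results", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, rho_cutoff >= 0, rho_cutoff <= 1)
  check_vitamin(vitamins)
  structure(list(
    catalog = catalog, gene_counts = gene_counts, annotation = annotation,
    totals = totals, gene_species = gene_species,
    species_phylum = species_phylum, species_abundance = species_abundance,
    gpr_models = gpr_models, metadata = metadata, vitamins = vitamins,
    alpha = alpha, rho_cutoff = rho_cutoff, family = family,
    reference_group = reference_group, out_dir = out_dir, seed = as.integer(seed)
  ), class = "vita_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "vitapath_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Reads every configured input, computes pathway abundance profiles,
#' phenotype assignments, phylum prevalence, the co-occurrence network,
#' cohort coverage matrices (when models are configured) and group
#' comparisons, and writes all results plus a run manifest to the output
#' directory. Any stage failure raises an error naming the stage.
#'
#' @param config A `vita_config` from [run_config()].
#' @return Invisibly, a list of the in-memory results (`profile`,
#'   `phenotypes`, `prevalence`, `network`, `coverage`, `comparisons`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vita_config"))
  for (f in c("catalog", "gene_counts", "annotation", "gene_species",
              "species_phylum", "species_abundance", "metadata")) {
    if (!file.exists(config[[f]])) {
      abort(sprintf("Pipeline input '%s' not readable: %s", f, config[[f]]),
            class = "vitapath_pipeline_error")
    }
  }

  catalog <- pipeline_stage("catalog", load_catalog(config$catalog))
  counts <- pipeline_stage("io", read_gene_counts(config$gene_counts))
  annotation <- pipeline_stage("io", read_annotation(config$annotation))
  totals <- if (!is.null(config$totals)) pipeline_stage("io", read_sample_totals(config$totals))
  gene_species <- pipeline_stage("io", read_gene_species(config$gene_species))
  species_phylum <- pipeline_stage("io", read_species_phylum(config$species_phylum))
  abund <- pipeline_stage("io", read_species_abundance(config$species_abundance))
  metadata <- pipeline_stage("io", read_metadata(config$metadata))
  models <- if (!is.null(config$gpr_models)) pipeline_stage("io", read_gpr_models(config$gpr_models))

  profile <- pipeline_stage("abundance_profiling",
                            total_pathway_abundance(counts, annotation, catalog, totals))
  phenotypes <- pipeline_stage("phenotype_assignment",
                               assign_phenotypes(annotation, gene_species, catalog))
  prevalence <- pipeline_stage("phenotype_assignment",
                               phylum_prevalence(phenotypes, species_phylum))
  network <- pipeline_stage("cooccurrence_network",
                            build_network(abund, phenotypes,
                                          vitamins = intersect(config$vitamins,
                                                               unique(phenotypes$vitamin)),
                                          alpha = config$alpha,
                                          rho_cutoff = config$rho_cutoff))
  coverage <- if (!is.null(models)) {
    pipeline_stage("gem_coverage",
                   build_cohort_matrix(models, abund, metadata, config$reference_group))
  }
  comparisons <- pipeline_stage("group_stats",
                                compare_groups(profile, metadata, family = config$family))

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pipeline_stage("write_outputs", {
    readr::write_tsv(profile, file.path(out, "pathway_profile.tsv"))
    readr::write_tsv(phenotypes, file.path(out, "phenotypes.tsv"))
    readr::write_tsv(prevalence$counts, file.path(out, "phylum_prevalence.tsv"))
    readr::write_tsv(prevalence$shares, file.path(out, "phylum_shares.tsv"))
    readr::write_tsv(network$edges, file.path(out, "network_edges.tsv"))
    readr::write_tsv(network$summary, file.path(out, "network_summary.tsv"))
    if (!is.null(network$phenotype_tally)) {
      readr::write_tsv(network$phenotype_tally, file.path(out, "network_phenotype_tally.tsv"))
    }
    if (!is.null(coverage)) {
      readr::write_tsv(tibble::as_tibble(coverage), file.path(out, "coverage_matrix.tsv"))
    }
    readr::write_tsv(comparisons, file.path(out, "comparisons.tsv"))
    yaml::write_yaml(list(
      package = "vitapath",
      version = as.character(utils::packageVersion("vitapath")),
      seed = config$seed,
      alpha = config$alpha,
      rho_cutoff = config$rho_cutoff,
      reference_group = config$reference_group,
      vitamins = config$vitamins,
      inputs = config[c("catalog", "gene_counts", "annotation", "totals",
                        "gene_species", "species_phylum", "species_abundance",
                        "gpr_models", "metadata")]
    ), file.path(out, "manifest.yaml"))
  })

  invisible(list(profile = profile, phenotypes = phenotypes,
                 prevalence = prevalence, network = network,
                 coverage = coverage, comparisons = comparisons))
}
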