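#' Specification for a synthetic input bundle
#'
#' Describes a synthetic gut-metagenome study with planted, exactly
#' recoverable structure: species phenotypes, pairwise species
#' correlations, multiplicative group shifts on pathway gene abundance, and
#' per-species vitamin-pathway completeness. [generate_synthetic()] turns a
#' spec into the full set of pipeline inputs.
#'
#' Defaults describe a two-group case-control study: 50 samples per group,
#' 30 species over 4 phyla, about 200,000 reads per sample of which half
#' map to unannotated background (so sample totals exceed annotated sums),
#' log-normal species abundances, one planted positive species pair (latent
#' correlation 0.9), one planted antagonistic pair (-0.8), and a two-fold
#' increase of biotin-biosynthesis gene abundance in the diseased group.
#'
#' @param n_samples Named integer vector: samples per group. The first
#'   group is the reference (healthy) group.
#' @param n_species Number of species.
#' @param n_vitamins Number of vitamins simulated (first `n_vitamins` of
#'   [vitamin_labels()]).
#' @param kos_per_category Synthetic KO identifiers per (vitamin, category).
#' @param reads_per_sample Total reads per sample (the normalization
#'   denominator).
#' @param background_fraction Fraction of read mass on unannotated
#'   background genes.
#' @param sdlog Log-scale standard deviation of species abundances.
#' @param planted_edges Tibble `species_a`, `species_b`, `r` of latent
#'   correlations in (-1, 1); species given as integer indices.
#' @param planted_shifts Tibble `vitamin`, `category`, `group`, `shift`
#'   (multiplicative, > 0) applied to that gene set's read mass in that
#'   group.
#' @param planted_completeness Optional tibble `species`, `vitamin`,
#'   `completeness` (indices / label / fraction). Defaults to a
#'   deterministic spread over `{0, 0.25, 0.5, 0.75, 1}`.
#' @param reactions_per_vitamin Reactions per vitamin pathway in the
#'   synthetic models; every planted completeness must be an exact multiple
#'   of `1 / reactions_per_vitamin`.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @return A `vita_spec` list.
#' @export
synthetic_spec <- function(n_samples = c(healthy = 50, diseased = 50),
                           n_species = 30,
                           n_vitamins = 9,
                           kos_per_category = 3,
                           reads_per_sample = 200000,
                           background_fraction = 0.5,
                           sdlog = 1,
                           planted_edges = tibble::tibble(
                             species_a = 1L, species_b = 2L, r = c(0.9)
                           ) |> tibble::add_row(species_a = 3L, species_b = 4L, r = -0.8),
                           planted_shifts = tibble::tibble(
                             vitamin = "BIO", category = "biosynthesis",
                             group = "diseased", shift = 2
                           ),
                           planted_completeness = NULL,
                           reactions_per_vitamin = 4,
                           seed = 1L) {
  stopifnot(length(n_samples) >= 1, all(n_samples >= 3), !is.null(names(n_samples)),
            n_species >= 2, n_vitamins >= 1, n_vitamins <= 9,
            kos_per_category >= 1, reads_per_sample > 0,
            background_fraction >= 0, background_fraction < 1,
            reactions_per_vitamin >= 1)
  if (nrow(planted_edges) > 0) {
    stopifnot(all(abs(planted_edges$r) < 1), all(planted_edges$r != 0),
              all(planted_edges$species_a != planted_edges$species_b),
              all(c(planted_edges$species_a, planted_edges$species_b) <= n_species))
  }
  if (nrow(planted_shifts) > 0) {
    stopifnot(all(planted_shifts$shift > 0),
              all(planted_shifts$group %in% names(n_samples)))
    check_vitamin(planted_shifts$vitamin)
    check_category(planted_shifts$category)
  }
  structure(list(
    n_samples = n_samples, n_species = n_species, n_vitamins = n_vitamins,
    kos_per_category = kos_per_category, reads_per_sample = reads_per_sample,
    background_fraction = background_fraction, sdlog = sdlog,
    planted_edges = planted_edges, planted_shifts = planted_shifts,
    planted_completeness = planted_completeness,
    reactions_per_vitamin = reactions_per_vitamin, seed = as.integer(seed)
  ), class = "vita_spec")
}

#' Synthetic vitamin catalog
#'
#' Builds a catalog of syntactically valid placeholder KO and EC
#' identifiers (disjoint across vitamins and categories) for simulation.
#'
#' @param vitamins Vitamin labels to include.
#' @param kos_per_category KOs per (vitamin, category).
#' @return A [vita_catalog].
#' @export
synthetic_catalog <- function(vitamins = vitamin_labels(), kos_per_category = 3) {
  check_vitamin(vitamins)
  vi <- match(vitamins, vitamin_labels())
  entries <- tidyr::expand_grid(
    vitamin = vitamins, category = category_labels(),
    slot = seq_len(kos_per_category)
  ) |>
    dplyr::mutate(ko = sprintf("K9%02d%d%d",
                               match(.data$vitamin, vitamin_labels()),
                               match(.data$category, category_labels()),
                               .data$slot)) |>
    dplyr::select("vitamin", "category", "ko")
  enzymes <- dplyr::bind_rows(
    tibble::tibble(vitamin = vitamins, role = "biosynthetic",
                   ec = sprintf("1.1.%d.1", vi)),
    tibble::tibble(vitamin = vitamins, role = "dependent",
                   ec = sprintf("2.2.%d.1", vi))
  )
  vita_catalog(entries, enzymes)
}

#' Generate a synthetic input bundle
#'
#' Realizes a [synthetic_spec()]: species relative abundances are drawn
#' log-normal per sample (correlated pairs share a latent Gaussian factor
#' with loading `sqrt(|r|)`, sign-flipped for antagonistic pairs) and
#' closed to fractions; per-species gene complements are constructed so
#' that [assign_phenotypes()] recovers every planted phenotype exactly;
#' read counts are drawn multinomially from species abundance times gene
#' weight, with planted group shifts applied multiplicatively to the
#' target gene set's weights before the draw; and GPR models are built so
#' that [pathway_coverage()] reproduces every planted completeness
#' fraction exactly.
#'
#' @param spec A `vita_spec` from [synthetic_spec()].
#' @return A `vita_bundle` list: `catalog`, `counts`, `annotation`,
#'   `totals`, `gene_species`, `species_phylum`, `species_abund`, `models`,
#'   `metadata`, `model_genes`, and `truth` (the planted `phenotypes`,
#'   `edges`, `shifts`, `completeness`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "vita_spec"))
  withr::with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  vitamins <- vitamin_labels()[seq_len(spec$n_vitamins)]
  catalog <- synthetic_catalog(vitamins, spec$kos_per_category)
  species <- sprintf("sp%03d", seq_len(spec$n_species))
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria")
  species_phylum <- tibble::tibble(
    species = species,
    phylum = phyla[(seq_len(spec$n_species) - 1) %% length(phyla) + 1]
  )

  groups <- rep(names(spec$n_samples), spec$n_samples)
  samples <- sprintf("%s_%02d", groups, unlist(lapply(spec$n_samples, seq_len)))
  metadata <- tibble::tibble(sample = samples, group = groups)

  ## planted phenotypes: deterministic cycle over the labels, overridable
  truth_pheno <- tidyr::expand_grid(species = species, vitamin = vitamins) |>
    dplyr::mutate(phenotype = phenotype_labels()[
      (match(.data$species, species) + match(.data$vitamin, vitamins)) %% 4 + 1
    ])

  ## gene complement realizing the phenotypes
  gene_rows <- truth_pheno |>
    dplyr::mutate(
      biosynthesis = .data$phenotype %in% c("P", "PC"),
      transport = .data$phenotype %in% c("C", "PC")
    ) |>
    tidyr::pivot_longer(c("biosynthesis", "transport"),
                        names_to = "category", values_to = "has") |>
    dplyr::filter(.data$has)
  annotation <- gene_rows |>
    dplyr::rowwise() |>
    dplyr::mutate(ko = list(kos_for(catalog, .data$vitamin, .data$category)[1])) |>
    dplyr::ungroup() |>
    tidyr::unnest("ko") |>
    dplyr::mutate(gene = sprintf("%s_%s_%s", .data$species, .data$vitamin,
                                 substr(.data$category, 1, 1)))
  gene_species <- dplyr::bind_rows(
    annotation |> dplyr::distinct(.data$gene, .data$species),
    tibble::tibble(gene = sprintf("%s_hk", species), species = species)  # unannotated housekeeping
  )
  annotation_tbl <- annotation |> dplyr::select("gene", "ko")

  ## species abundances: log-normal with shared latent factors for planted pairs
  ns <- length(samples)
  z <- matrix(rnorm(ns * spec$n_species), nrow = ns)
  if (nrow(spec$planted_edges) > 0) {
    for (k in seq_len(nrow(spec$planted_edges))) {
      a <- spec$planted_edges$species_a[k]
      b <- spec$planted_edges$species_b[k]
      r <- spec$planted_edges$r[k]
      shared <- rnorm(ns)
      load <- sqrt(abs(r))
      resid <- sqrt(1 - abs(r))
      z[, a] <- load * shared + resid * rnorm(ns)
      z[, b] <- sign(r) * load * shared + resid * rnorm(ns)
    }
  }
  raw <- exp(spec$sdlog * z)   # common log-mean; closure removes the scale
  rel <- raw / rowSums(raw)
  species_abund <- tibble::as_tibble(t(rel), .name_repair = "minimal")
  names(species_abund) <- samples
  species_abund <- dplyr::bind_cols(tibble::tibble(species = species), species_abund)

  ## read counts: multinomial over genes, weights = species abundance x shift
  gene_tab <- gene_species |>
    dplyr::left_join(annotation |> dplyr::distinct(.data$gene, .data$vitamin, .data$category),
                     by = "gene")
  shift_for <- function(group) {
    sh <- rep(1, nrow(gene_tab))
    ps <- spec$planted_shifts
    if (nrow(ps) > 0) {
      for (k in seq_len(nrow(ps))) {
        if (ps$group[k] == group) {
          hit <- !is.na(gene_tab$vitamin) & gene_tab$vitamin == ps$vitamin[k] &
            gene_tab$category == ps$category[k]
          sh[hit] <- sh[hit] * ps$shift[k]
        }
      }
    }
    sh
  }
  sp_index <- match(gene_tab$species, species)
  counts_mat <- matrix(0L, nrow = nrow(gene_tab), ncol = ns)
  for (j in seq_len(ns)) {
    w <- rel[j, sp_index] * shift_for(groups[j])
    w <- w / sum(w) * (1 - spec$background_fraction)
    probs <- c(w, spec$background_fraction)
    draw <- rmultinom(1, size = spec$reads_per_sample, prob = probs)
    counts_mat[, j] <- draw[-length(probs), 1]
  }
  counts <- dplyr::bind_cols(
    tibble::tibble(gene = gene_tab$gene),
    tibble::as_tibble(counts_mat, .name_repair = ~samples)
  )
  totals <- tibble::tibble(sample = samples, total_reads = spec$reads_per_sample)

  ## GPR models realizing planted completeness
  nr <- spec$reactions_per_vitamin
  completeness <- spec$planted_completeness %||% (
    tidyr::expand_grid(species = species, vitamin = vitamins) |>
      dplyr::mutate(completeness = ((match(.data$species, species) +
                                       match(.data$vitamin, vitamins)) %% (nr + 1)) / nr)
  )
  bad <- completeness$completeness * nr
  if (any(abs(bad - round(bad)) > 1e-9)) {
    i <- which(abs(bad - round(bad)) > 1e-9)[1]
    abort(sprintf(
      "Infeasible completeness %.3f for (%s, %s): not a multiple of 1/%d reactions.",
      completeness$completeness[i], completeness$species[i], completeness$vitamin[i], nr),
      class = "vitapath_infeasible_spec_error")
  }
  model_genes <- setNames(
    lapply(species, function(sp) gene_species$gene[gene_species$species == sp]),
    species
  )
  models <- completeness |>
    dplyr::rowwise() |>
    dplyr::mutate(rows = list({
      k <- round(.data$completeness * nr)
      sp <- .data$species
      vit <- .data$vitamin
      own <- model_genes[[sp]]
      tibble::tibble(
        reaction = sprintf("rxn_%s_%d", vit, seq_len(nr)),
        rule = dplyr::if_else(
          seq_len(nr) <= k,
          sprintf("%s or %s_gap", own[1], sp),
          sprintf("%s_missing_a and %s_missing_b", sp, sp)
        )
      )
    })) |>
    dplyr::ungroup() |>
    tidyr::unnest("rows") |>
    dplyr::select("species", "reaction", "vitamin", "rule")

  structure(list(
    catalog = catalog,
    counts = counts,
    annotation = annotation_tbl,
    totals = totals,
    gene_species = gene_species,
    species_phylum = species_phylum,
    species_abund = species_abund,
    models = models,
    metadata = metadata,
    model_genes = model_genes,
    truth = list(
      phenotypes = truth_pheno,
      edges = spec$planted_edges |>
        dplyr::mutate(species_a = species[.data$species_a],
                      species_b = species[.data$species_b]),
      shifts = spec$planted_shifts,
      completeness = completeness
    ),
    spec = spec
  ), class = "vita_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Writes every table in the TSV dialect its consumer reads, plus a
#' `manifest.yaml` recording the generating spec and seed. Identical specs
#' produce byte-identical directories.
#'
#' @param bundle A `vita_bundle` from [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "vita_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_catalog(bundle$catalog, p("catalog.tsv"))
  readr::write_tsv(bundle$counts, p("gene_counts.tsv"))
  readr::write_tsv(bundle$annotation, p("annotation.tsv"))
  readr::write_tsv(bundle$totals, p("sample_totals.tsv"))
  readr::write_tsv(bundle$gene_species, p("gene_species.tsv"))
  readr::write_tsv(bundle$species_phylum, p("species_phylum.tsv"))
  readr::write_tsv(bundle$species_abund, p("species_abundance.tsv"))
  readr::write_tsv(bundle$models, p("gpr_models.tsv"))
  readr::write_tsv(bundle$metadata, p("metadata.tsv"))
  spec <- bundle$spec
  manifest <- list(
    generator = "vitapath::generate_synthetic",
    seed = spec$seed,
    n_samples = as.list(spec$n_samples),
    n_species = spec$n_species,
    n_vitamins = spec$n_vitamins,
    kos_per_category = spec$kos_per_category,
    reads_per_sample = spec$reads_per_sample,
    background_fraction = spec$background_fraction,
    sdlog = spec$sdlog,
    reactions_per_vitamin = spec$reactions_per_vitamin,
    planted_edges = as.list(as.data.frame(spec$planted_edges)),
    planted_shifts = as.list(as.data.frame(spec$planted_shifts))
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(dir)
}
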