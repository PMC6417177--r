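#' Assign vitamin phenotypes to species
#'
#' For each species and vitamin, evidence is the presence of at least one
#' gene annotated to any KO of the respective catalog gene set. A species is
#' a Producer (`P`, vitamin prototroph) when it carries biosynthesis genes
#' but no transporter for the vitamin; a Consumer (`C`, vitamin auxotroph)
#' when it carries a transporter but no biosynthesis genes; Dual (`PC`) when
#' it carries both; and `absent` when neither. Pathway completeness is not
#' required for the `P` call — that is scored separately by
#' [pathway_coverage()].
#'
#' Strains sharing a species name are merged before assignment (their gene
#' evidence pools at the species level).
#'
#' @param annotation Tibble `gene`, `ko`.
#' @param gene_species Tibble `gene`, `species` mapping genes to species.
#' @param catalog A [vita_catalog].
#' @param vitamins Optional character vector restricting the vitamins
#'   considered (default: all vitamins in the catalog).
#' @param strict When `TRUE`, a gene with no species mapping is an error;
#'   when `FALSE` (default) such genes are skipped with a message.
#' @return Tibble `species`, `vitamin`, `phenotype` with exactly one row per
#'   (species, vitamin) pair; `phenotype` is one of `P`, `C`, `PC`, `absent`.
#' @export
assign_phenotypes <- function(annotation, gene_species, catalog,
                              vitamins = NULL, strict = FALSE) {
  stopifnot(inherits(catalog, "vita_catalog"))
  annotation <- tibble::as_tibble(annotation)
  gene_species <- tibble::as_tibble(gene_species)
  stopifnot(all(c("gene", "ko") %in% names(annotation)),
            all(c("gene", "species") %in% names(gene_species)))

  vitamins <- vitamins %||% unique(catalog$entries$vitamin)
  check_vitamin(vitamins)

  unmapped <- setdiff(annotation$gene, gene_species$gene)
  if (length(unmapped) > 0) {
    msg <- sprintf("%d annotated gene(s) have no species mapping.", length(unmapped))
    if (strict) abort(msg, class = "vitapath_taxonomy_error")
    inform(paste(msg, "They are skipped."))
  }

  evidence <- annotation |>
    dplyr::inner_join(gene_species, by = "gene", relationship = "many-to-many") |>
    dplyr::inner_join(catalog$entries, by = "ko", relationship = "many-to-many") |>
    dplyr::filter(.data$vitamin %in% vitamins) |>
    dplyr::distinct(.data$species, .data$vitamin, .data$category)

  grid <- tidyr::expand_grid(species = sort(unique(gene_species$species)),
                             vitamin = sort(vitamins))

  flags <- evidence |>
    dplyr::group_by(.data$species, .data$vitamin) |>
    dplyr::summarise(biosynthesis = any(.data$category == "biosynthesis"),
                     transport = any(.data$category == "transport"),
                     .groups = "drop")

  grid |>
    dplyr::left_join(flags, by = c("species", "vitamin")) |>
    dplyr::mutate(
      biosynthesis = dplyr::coalesce(.data$biosynthesis, FALSE),
      transport = dplyr::coalesce(.data$transport, FALSE),
      phenotype = dplyr::case_when(
        .data$biosynthesis & .data$transport ~ "PC",
        .data$biosynthesis ~ "P",
        .data$transport ~ "C",
        TRUE ~ "absent"
      )
    ) |>
    dplyr::select("species", "vitamin", "phenotype")
}

#' Prevalence of vitamin gene sets across phyla
#'
#' Tallies, per phylum and (vitamin, category), the number of species with
#' evidence for that gene set (biosynthesis evidence = phenotype `P` or
#' `PC`; transport evidence = `C` or `PC`), and the per-phylum percentage
#' share of all species–vitamin associations. Shares sum to 100 over phyla
#' (up to rounding).
#'
#' @param phenotypes Tibble `species`, `vitamin`, `phenotype` as returned by
#'   [assign_phenotypes()].
#' @param species_phylum Tibble `species`, `phylum`.
#' @return List with `counts` (tibble `phylum`, `vitamin`, `category`, `n`)
#'   and `shares` (tibble `phylum`, `n_associations`, `share_pct`).
#' @export
phylum_prevalence <- function(phenotypes, species_phylum) {
  phenotypes <- tibble::as_tibble(phenotypes)
  species_phylum <- tibble::as_tibble(species_phylum)
  stopifnot(all(c("species", "vitamin", "phenotype") %in% names(phenotypes)),
            all(c("species", "phylum") %in% names(species_phylum)))

  assoc <- phenotypes |>
    dplyr::filter(.data$phenotype != "absent") |>
    dplyr::inner_join(species_phylum, by = "species") |>
    dplyr::mutate(
      biosynthesis = .data$phenotype %in% c("P", "PC"),
      transport = .data$phenotype %in% c("C", "PC")
    ) |>
    tidyr::pivot_longer(c("biosynthesis", "transport"),
                        names_to = "category", values_to = "present") |>
    dplyr::filter(.data$present)

  counts <- assoc |>
    dplyr::count(.data$phylum, .data$vitamin, .data$category, name = "n") |>
    dplyr::arrange(.data$phylum, .data$vitamin, .data$category)

  total <- nrow(assoc)
  shares <- assoc |>
    dplyr::count(.data$phylum, name = "n_associations") |>
    dplyr::mutate(share_pct = if (total > 0) .data$n_associations / total * 100 else numeric(0)) |>
    dplyr::arrange(dplyr::desc(.data$n_associations), .data$phylum)

  list(counts = counts, shares = shares)
}
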