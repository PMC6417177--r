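#' Cohort-ordered, abundance-weighted coverage matrix
#'
#' Assembles the matrix behind the cohort coverage heatmaps: rows are the
#' union of species present in any sample group, columns the model
#' reactions grouped by vitamin, and each (species, reaction, group) cell
#' carries the reaction's 0/1 presence for that species and the
#' abundance-weighted value `presence x group-mean relative abundance`.
#'
#' Row order follows the reference (healthy) cohort: species present there
#' are sorted by descending mean relative abundance in that group; species
#' absent from the reference group are appended at the end, sorted by their
#' best mean abundance among the other groups. Ties break lexicographically
#' by species name, so the order is a deterministic function of the
#' abundance table.
#'
#' A species absent from a group (zero mean abundance there) is flagged
#' `species_absent` and its weighted value is `NA` — distinct from a species
#' that is present but lacks the reaction (weighted 0). A species in the
#' abundance table without any model is kept as a flagged
#' `annotation_missing` row with `NA` presence.
#'
#' @param models Model tibble (`species`, `reaction`, `vitamin`, `rule`).
#' @param abund Wide species-abundance tibble (first column `species`,
#'   remaining columns samples).
#' @param metadata Tibble `sample`, `group`.
#' @param reference_group Name of the reference (healthy) group.
#' @param vitamins Optional vitamin ordering/filter for the reaction
#'   columns (default: all vitamins in the models, alphabetical).
#' @param present_genes Optional named list, species -> character vector of
#'   present genes. When `NULL` (pure pathway-completeness mode) every gene
#'   mentioned in a species' rules is taken as present.
#' @return A `vita_coverage` tibble in long form: `species`, `vitamin`,
#'   `reaction`, `group`, `presence`, `mean_abundance`, `weighted`,
#'   `species_absent`, `annotation_missing`, with attributes
#'   `species_order` and `reaction_order`.
#' @export
build_cohort_matrix <- function(models, abund, metadata, reference_group,
                                vitamins = NULL, present_genes = NULL) {
  abund <- tibble::as_tibble(abund)
  metadata <- tibble::as_tibble(metadata)
  stopifnot(names(abund)[1] == "species",
            all(c("sample", "group") %in% names(metadata)))
  if (!reference_group %in% metadata$group) {
    abort(sprintf("Reference group '%s' not found in metadata.", reference_group),
          class = "vitapath_input_error")
  }
  vitamins <- vitamins %||% sort(unique(models$vitamin))
  check_vitamin(vitamins)
  models <- models[models$vitamin %in% vitamins, , drop = FALSE]

  samples <- setdiff(names(abund), "species")
  missing_meta <- setdiff(samples, metadata$sample)
  if (length(missing_meta) > 0) {
    abort(sprintf("Samples without group metadata: %s",
                  paste(head(missing_meta, 5), collapse = ", ")),
          class = "vitapath_input_error")
  }

  groups <- unique(metadata$group)
  group_means <- abund |>
    tidyr::pivot_longer(-"species", names_to = "sample", values_to = "value") |>
    dplyr::inner_join(metadata, by = "sample") |>
    dplyr::group_by(.data$species, .data$group) |>
    dplyr::summarise(mean_abundance = mean(.data$value), .groups = "drop")

  # reference-first ordering; ties broken lexicographically
  ref <- group_means |>
    dplyr::filter(.data$group == reference_group, .data$mean_abundance > 0) |>
    dplyr::arrange(dplyr::desc(.data$mean_abundance), .data$species)
  nonref_src <- group_means |>
    dplyr::filter(.data$group != reference_group, .data$mean_abundance > 0,
                  !.data$species %in% ref$species)
  nonref <- if (nrow(nonref_src) == 0) character(0) else {
    nonref_src |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(mean_abundance = max(.data$mean_abundance), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$mean_abundance), .data$species) |>
      dplyr::pull("species")
  }
  species_order <- c(ref$species, nonref)

  model_species <- unique(models$species)
  reactions <- models |>
    dplyr::distinct(.data$vitamin, .data$reaction) |>
    dplyr::mutate(vitamin = factor(.data$vitamin, levels = vitamins)) |>
    dplyr::arrange(.data$vitamin, .data$reaction) |>
    dplyr::mutate(vitamin = as.character(.data$vitamin))

  presence_for <- function(sp) {
    if (!sp %in% model_species) {
      return(dplyr::mutate(reactions, presence = NA, annotation_missing = TRUE))
    }
    sub <- models[models$species == sp, , drop = FALSE]
    genes <- present_genes[[sp]] %||%
      unique(unlist(lapply(sub$rule[!is.na(sub$rule)], function(r) gpr_genes(parse_gpr(r)))))
    pres <- setNames(
      vapply(seq_len(nrow(sub)), function(i) {
        if (is.na(sub$rule[i])) FALSE else evaluate_gpr(sub$rule[i], genes)
      }, logical(1)),
      paste(sub$vitamin, sub$reaction)
    )
    miss <- setNames(is.na(sub$rule), paste(sub$vitamin, sub$reaction))
    key <- paste(reactions$vitamin, reactions$reaction)
    reactions |>
      dplyr::mutate(presence = as.logical(pres[key]),
                    annotation_missing = dplyr::coalesce(unname(miss[key]), TRUE))
  }

  cells <- purrr::map_dfr(species_order, function(sp) {
    dplyr::mutate(presence_for(sp), species = sp, .before = 1)
  }) |>
    dplyr::cross_join(tibble::tibble(group = groups)) |>
    dplyr::left_join(group_means, by = c("species", "group")) |>
    dplyr::mutate(
      mean_abundance = dplyr::coalesce(.data$mean_abundance, 0),
      species_absent = .data$mean_abundance <= 0,
      weighted = dplyr::if_else(.data$species_absent, NA_real_,
                                as.numeric(.data$presence) * .data$mean_abundance)
    ) |>
    dplyr::select("species", "vitamin", "reaction", "group", "presence",
                  "mean_abundance", "weighted", "species_absent", "annotation_missing")

  structure(cells,
            class = c("vita_coverage", class(cells)),
            species_order = species_order,
            reaction_order = paste(reactions$vitamin, reactions$reaction, sep = ":"),
            reference_group = reference_group)
}

# All gene identifiers mentioned in a GPR tree.
gpr_genes <- function(tree) {
  node <- unclass(tree)
  if (!is.null(node$gene)) return(node$gene)
  unique(unlist(lapply(node$args, gpr_genes)))
}
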