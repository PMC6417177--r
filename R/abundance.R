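#' Normalized abundance of one gene in one sample
#'
#' The per-gene normalized abundance is the number of reads aligned to the
#' gene divided by the total number of reads in the sample (all reads, not
#' only annotated ones).
#'
#' @param counts Wide count tibble: first column `gene`, remaining columns
#'   one per sample, cells = reads aligned to the gene.
#' @param sample Sample identifier (a column of `counts`).
#' @param gene Gene identifier (a row of `counts`).
#' @param totals Optional tibble `sample`, `total_reads`. When `NULL`, the
#'   per-sample sum of annotated counts is used, with a warning (see
#'   [sample_totals()]).
#' @return A fraction in `[0, 1]`.
#' @export
normalize_gene <- function(counts, sample, gene, totals = NULL) {
  totals <- sample_totals(counts, totals)
  tot <- totals$total_reads[match(sample, totals$sample)]
  if (is.na(tot)) abort(sprintf("Unknown sample '%s'.", sample), class = "vitapath_io_error")
  if (tot <= 0) {
    abort(sprintf("Sample '%s' has zero total reads; normalized abundance undefined.", sample),
          class = "vitapath_degenerate_sample_error")
  }
  i <- match(gene, counts$gene)
  if (is.na(i)) abort(sprintf("Unknown gene '%s'.", gene), class = "vitapath_io_error")
  counts[[sample]][i] / tot
}

#' Resolve per-sample read totals
#'
#' Returns the explicit totals when supplied; otherwise falls back to the
#' column sums of the annotated count table with a warning, since the
#' denominator of the normalized abundance should be the total reads in the
#' sample, which the count table (annotated genes only) underestimates.
#'
#' @inheritParams normalize_gene
#' @return Tibble with columns `sample`, `total_reads` covering every sample
#'   column of `counts`.
#' @export
sample_totals <- function(counts, totals = NULL) {
  samples <- setdiff(names(counts), "gene")
  if (is.null(totals)) {
    warn("No sample totals supplied; falling back to the column sums of annotated genes.",
         class = "vitapath_totals_fallback")
    return(tibble::tibble(
      sample = samples,
      total_reads = unname(vapply(samples, function(s) sum(counts[[s]]), numeric(1)))
    ))
  }
  totals <- tibble::as_tibble(totals)
  stopifnot(all(c("sample", "total_reads") %in% names(totals)))
  missing <- setdiff(samples, totals$sample)
  if (length(missing) > 0) {
    abort(sprintf("Samples without a read total: %s", paste(missing, collapse = ", ")),
          class = "vitapath_io_error")
  }
  ann <- vapply(samples, function(s) sum(counts[[s]]), numeric(1))
  tot <- totals$total_reads[match(samples, totals$sample)]
  if (any(tot < ann)) {
    warn("Some sample totals are smaller than the annotated column sums.",
         class = "vitapath_totals_inconsistent")
  }
  tibble::tibble(sample = samples, total_reads = tot)
}

#' Total normalized pathway abundance per sample
#'
#' For every sample and every (vitamin, category) gene set in the catalog,
#' sums the normalized abundances (reads aligned to a gene / total reads in
#' the sample) of all genes annotated to any KO of that set. A gene
#' annotated to several KOs of the same (vitamin, category) contributes once
#' to that sum; a gene shared between vitamins contributes to each.
#' Unannotated genes contribute to the denominator only.
#'
#' @inheritParams normalize_gene
#' @param annotation Tibble `gene`, `ko` (one row per gene-KO link).
#' @param catalog A [vita_catalog].
#' @return Tibble `sample`, `vitamin`, `category`, `abundance` with one row
#'   per sample and catalog (vitamin, category) pair; `abundance` is 0
#'   exactly when no annotated gene of the set has nonzero counts.
#' @export
total_pathway_abundance <- function(counts, annotation, catalog, totals = NULL) {
  stopifnot(inherits(catalog, "vita_catalog"))
  counts <- tibble::as_tibble(counts)
  if (ncol(counts) < 2) abort("Count table has no sample columns.", class = "vitapath_io_error")
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("gene", "ko") %in% names(annotation)))
  stray <- setdiff(annotation$gene, counts$gene)
  if (length(stray) > 0) {
    abort(sprintf("Annotated gene(s) missing from the count table: %s",
                  paste(head(stray, 5), collapse = ", ")),
          class = "vitapath_io_error")
  }

  totals <- sample_totals(counts, totals)
  if (any(totals$total_reads <= 0)) {
    abort(sprintf("Sample(s) with zero total reads: %s",
                  paste(totals$sample[totals$total_reads <= 0], collapse = ", ")),
          class = "vitapath_degenerate_sample_error")
  }

  # one contribution per gene per (vitamin, category), however many KOs link them
  gene_sets <- annotation |>
    dplyr::inner_join(catalog$entries, by = "ko", relationship = "many-to-many") |>
    dplyr::distinct(.data$gene, .data$vitamin, .data$category)

  long <- counts |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "count") |>
    dplyr::left_join(totals, by = "sample") |>
    dplyr::mutate(rel = .data$count / .data$total_reads)

  sets <- dplyr::distinct(catalog$entries, .data$vitamin, .data$category)
  grid <- tidyr::expand_grid(sample = totals$sample, sets)

  sums <- gene_sets |>
    dplyr::inner_join(long, by = "gene", relationship = "many-to-many") |>
    dplyr::group_by(.data$sample, .data$vitamin, .data$category) |>
    dplyr::summarise(abundance = sum(.data$rel), .groups = "drop")

  grid |>
    dplyr::left_join(sums, by = c("sample", "vitamin", "category")) |>
    dplyr::mutate(abundance = dplyr::coalesce(.data$abundance, 0)) |>
    dplyr::arrange(.data$sample, .data$vitamin, .data$category)
}

# Pull an EC token out of a HUMAnN2-style feature identifier, e.g.
# "1.1.1.1", "EC:1.1.1.1" or "1.1.1.1: alcohol dehydrogenase|g__...".
extract_ec <- function(feature) {
  m <- regexpr("[0-9]+\\.[0-9]+\\.[0-9]+\\.(n?[0-9]+|-)", feature)
  out <- rep(NA_character_, length(feature))
  out[m > 0] <- regmatches(feature, m)
  out
}

#' Group EC-keyed feature abundances per vitamin
#'
#' Sums a HUMAnN2-style EC-keyed relative-abundance table per sample over
#' each vitamin's EC set — its biosynthetic enzymes or its vitamin-dependent
#' enzymes. Features whose EC token is absent from the catalog (or that carry
#' no EC token) are ignored, and their count is reported with a message.
#'
#' @param features Wide tibble: first column `feature` (identifier containing
#'   an EC token), remaining columns samples, cells = non-negative relative
#'   abundances.
#' @param catalog A [vita_catalog].
#' @param mode `"biosynthetic"` (sum over the vitamin's biosynthetic EC set)
#'   or `"dependent"` (over its vitamin-dependent enzymes).
#' @return Tibble `sample`, `vitamin`, `abundance`, one row per sample per
#'   vitamin present in the catalog's EC sets for `mode`.
#' @export
group_ec_abundance <- function(features, catalog, mode = c("biosynthetic", "dependent")) {
  stopifnot(inherits(catalog, "vita_catalog"))
  mode <- match.arg(mode)
  features <- tibble::as_tibble(features)
  stopifnot(names(features)[1] == "feature")

  ec_map <- catalog$enzymes |>
    dplyr::filter(.data$role == mode) |>
    dplyr::select("vitamin", "ec")
  samples <- setdiff(names(features), "feature")
  grid <- tidyr::expand_grid(sample = samples, vitamin = unique(ec_map$vitamin))
  if (nrow(features) == 0 || length(samples) == 0) {
    return(dplyr::mutate(grid, abundance = 0))
  }

  feats <- features |>
    dplyr::mutate(ec = extract_ec(.data$feature))
  ignored <- sum(is.na(feats$ec) | !feats$ec %in% ec_map$ec)
  if (ignored > 0) {
    inform(sprintf("group_ec_abundance: ignored %d feature(s) not in the catalog's %s EC set.",
                   ignored, mode))
  }

  sums <- feats |>
    dplyr::inner_join(ec_map, by = "ec", relationship = "many-to-many") |>
    tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample", values_to = "value") |>
    dplyr::group_by(.data$sample, .data$vitamin) |>
    dplyr::summarise(abundance = sum(.data$value), .groups = "drop")

  grid |>
    dplyr::left_join(sums, by = c("sample", "vitamin")) |>
    dplyr::mutate(abundance = dplyr::coalesce(.data$abundance, 0)) |>
    dplyr::arrange(.data$sample, .data$vitamin)
}
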