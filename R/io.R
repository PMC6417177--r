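# Readers and writers for the pipeline's TSV dialects. Every output written
# by run_pipeline() round-trips through the corresponding reader.

tsv_cols <- function(path, first, numeric_rest = TRUE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != first) {
    abort(sprintf("Expected first column '%s' in %s, found '%s'.",
                  first, path, names(tab)[1]), class = "vitapath_io_error")
  }
  tab
}

#' Read a gene-count table
#'
#' Dialect: TSV, first column `gene`, remaining columns one per sample,
#' cells = raw mapped-read counts.
#'
#' @param path File path.
#' @return Wide count tibble.
#' @export
read_gene_counts <- function(path) {
  tab <- tsv_cols(path, "gene")
  vals <- as.matrix(tab[-1])
  if (any(vals < 0) || any(vals != round(vals))) {
    abort(sprintf("Negative or non-integer counts in %s.", path),
          class = "vitapath_validation_error")
  }
  tab
}

#' Read a gene-to-KO annotation table
#'
#' Dialect: TSV `gene<TAB>ko`, one row per gene-KO link.
#'
#' @param path File path.
#' @return Tibble `gene`, `ko`.
#' @export
read_annotation <- function(path) {
  tab <- tsv_cols(path, "gene")
  stopifnot("ko" %in% names(tab))
  bad <- tab$ko[!is_ko_id(tab$ko)]
  if (length(bad) > 0) {
    abort(sprintf("Malformed KO identifier(s) in %s: %s", path,
                  paste(unique(head(bad, 5)), collapse = ", ")),
          class = "vitapath_validation_error")
  }
  tab
}

#' Read per-sample read totals
#'
#' Dialect: TSV `sample<TAB>total_reads`.
#'
#' @param path File path.
#' @return Tibble `sample`, `total_reads`.
#' @export
read_sample_totals <- function(path) {
  tab <- tsv_cols(path, "sample")
  stopifnot("total_reads" %in% names(tab))
  tab
}

#' Read a gene-to-species taxonomy table
#'
#' Dialect: TSV `gene<TAB>species`.
#'
#' @param path File path.
#' @return Tibble `gene`, `species`.
#' @export
read_gene_species <- function(path) {
  tab <- tsv_cols(path, "gene")
  stopifnot("species" %in% names(tab))
  tab
}

#' Read a species-to-phylum taxonomy table
#'
#' Dialect: TSV `species<TAB>phylum`.
#'
#' @param path File path.
#' @return Tibble `species`, `phylum`.
#' @export
read_species_phylum <- function(path) {
  tab <- tsv_cols(path, "species")
  stopifnot("phylum" %in% names(tab))
  tab
}

#' Read a species relative-abundance table
#'
#' Dialect: TSV, first column `species`, remaining columns samples, cells =
#' relative-abundance fractions. Values must be non-negative and per-sample
#' sums at most 1 (plus a small tolerance).
#'
#' @param path File path.
#' @return Wide abundance tibble.
#' @export
read_species_abundance <- function(path) {
  tab <- tsv_cols(path, "species")
  vals <- as.matrix(tab[-1])
  if (any(vals < 0)) abort(sprintf("Negative abundances in %s.", path),
                           class = "vitapath_validation_error")
  if (any(colSums(vals) > 1 + 1e-6)) {
    abort(sprintf("Per-sample abundance sums exceed 1 in %s.", path),
          class = "vitapath_validation_error")
  }
  tab
}

#' Read sample metadata
#'
#' Dialect: TSV with a `sample` column plus grouping columns (e.g.
#' `group`, `country`, `status`).
#'
#' @param path File path.
#' @return Metadata tibble.
#' @export
read_metadata <- function(path) {
  tsv_cols(path, "sample")
}

#' Read a HUMAnN2-style EC-keyed feature table
#'
#' Dialect: TSV, first column `feature` (identifier containing an EC
#' token), remaining columns samples, cells = non-negative relative
#' abundances.
#'
#' @param path File path.
#' @return Wide feature tibble.
#' @export
read_ec_features <- function(path) {
  tab <- tsv_cols(path, "feature")
  vals <- as.matrix(tab[-1])
  if (any(vals < 0)) abort(sprintf("Negative feature abundances in %s.", path),
                           class = "vitapath_validation_error")
  tab
}
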