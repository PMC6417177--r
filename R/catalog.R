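#' Construct a vitamin catalog
#'
#' A vitamin catalog defines which KEGG Orthology (KO) identifiers make up
#' each vitamin's biosynthesis and transport gene sets, and which Enzyme
#' Commission (EC) numbers correspond to vitamin-biosynthetic and
#' vitamin-dependent enzymes. It is the configuration object consumed by
#' pathway profiling, phenotype assignment and enzyme-level grouping.
#'
#' @param entries Tibble with columns `vitamin`, `category`
#'   (`"biosynthesis"` or `"transport"`) and `ko` (identifiers matching
#'   `K#####`). Duplicate rows are collapsed.
#' @param enzymes Tibble with columns `vitamin`, `role` (`"biosynthetic"` or
#'   `"dependent"`) and `ec` (four dot-separated fields, first three numeric).
#'   May be empty.
#'
#' @return An object of class `vita_catalog`: a list with tibbles `entries`
#'   and `enzymes`.
#' @export
vita_catalog <- function(entries, enzymes = NULL) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("vitamin", "category", "ko") %in% names(entries)))
  if (is.null(enzymes)) {
    enzymes <- tibble::tibble(vitamin = character(), role = character(), ec = character())
  }
  enzymes <- tibble::as_tibble(enzymes)
  stopifnot(all(c("vitamin", "role", "ec") %in% names(enzymes)))

  check_vitamin(unique(c(entries$vitamin, enzymes$vitamin)))
  check_category(unique(entries$category))
  bad_ko <- entries$ko[!is_ko_id(entries$ko)]
  if (length(bad_ko) > 0) {
    abort(sprintf("Malformed KO identifier(s): %s", paste(unique(bad_ko), collapse = ", ")),
          class = "vitapath_validation_error")
  }
  bad_ec <- enzymes$ec[!is_ec_number(enzymes$ec)]
  if (length(bad_ec) > 0) {
    abort(sprintf("Malformed EC number(s): %s", paste(unique(bad_ec), collapse = ", ")),
          class = "vitapath_validation_error")
  }
  bad_role <- setdiff(enzymes$role, c("biosynthetic", "dependent"))
  if (length(bad_role) > 0) {
    abort(sprintf("Invalid enzyme role(s): %s", paste(bad_role, collapse = ", ")),
          class = "vitapath_vocabulary_error")
  }

  entries <- dplyr::distinct(entries, .data$vitamin, .data$category, .data$ko) |>
    dplyr::arrange(.data$vitamin, .data$category, .data$ko)
  enzymes <- dplyr::distinct(enzymes, .data$vitamin, .data$role, .data$ec) |>
    dplyr::arrange(.data$vitamin, .data$role, .data$ec)

  # every vitamin present anywhere in the catalog needs biosynthesis evidence
  vits <- unique(c(entries$vitamin, enzymes$vitamin))
  no_bio <- setdiff(vits, entries$vitamin[entries$category == "biosynthesis"])
  if (length(no_bio) > 0) {
    abort(sprintf("Vitamin(s) without any biosynthesis KO entry: %s",
                  paste(no_bio, collapse = ", ")),
          class = "vitapath_validation_error")
  }

  structure(list(entries = entries, enzymes = enzymes), class = "vita_catalog")
}

#' @export
print.vita_catalog <- function(x, ...) {
  cat("<vita_catalog>\n")
  cat(sprintf("  %d KO entries across %d vitamin(s)\n",
              nrow(x$entries), dplyr::n_distinct(x$entries$vitamin)))
  cat(sprintf("  %d EC enzyme entries (%d biosynthetic, %d dependent)\n",
              nrow(x$enzymes),
              sum(x$enzymes$role == "biosynthetic"),
              sum(x$enzymes$role == "dependent")))
  invisible(x)
}

#' Load a vitamin catalog from TSV
#'
#' Reads the catalog dialect: UTF-8 TSV with header
#' `vitamin<TAB>category<TAB>id_type<TAB>identifier`, `#` comment lines
#' ignored. Rows with `id_type == "KO"` populate the KO gene sets
#' (`category` is `biosynthesis` or `transport`); rows with
#' `id_type == "EC"` populate the enzyme sets (`category` is `biosynthetic`
#' or `dependent`). Duplicate rows collapse to one entry. Malformed
#' identifiers or labels raise a validation error naming the offending line.
#'
#' @param path Path to the catalog TSV file.
#' @return A [vita_catalog] object.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Catalog file not found: %s", path), class = "vitapath_io_error")
  }
  raw <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0) abort("Catalog file is empty.", class = "vitapath_validation_error")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (!identical(tolower(trimws(header)), c("vitamin", "category", "id_type", "identifier"))) {
    abort("Catalog header must be 'vitamin\\tcategory\\tid_type\\tidentifier'.",
          class = "vitapath_validation_error")
  }
  rows <- fields[-1]
  lineno <- lineno[-1]

  parsed <- purrr::map2(rows, lineno, function(f, ln) {
    if (length(f) != 4) {
      abort(sprintf("Line %d: expected 4 tab-separated fields, found %d.", ln, length(f)),
            class = "vitapath_validation_error")
    }
    f <- trimws(f)
    if (!f[1] %in% vitamin_labels()) {
      abort(sprintf("Line %d: unknown vitamin label '%s'.", ln, f[1]),
            class = "vitapath_validation_error")
    }
    if (f[3] == "KO") {
      if (!f[2] %in% category_labels()) {
        abort(sprintf("Line %d: unknown KO category '%s'.", ln, f[2]),
              class = "vitapath_validation_error")
      }
      if (!is_ko_id(f[4])) {
        abort(sprintf("Line %d: malformed KO identifier '%s'.", ln, f[4]),
              class = "vitapath_validation_error")
      }
    } else if (f[3] == "EC") {
      if (!f[2] %in% c("biosynthetic", "dependent")) {
        abort(sprintf("Line %d: unknown EC role '%s'.", ln, f[2]),
              class = "vitapath_validation_error")
      }
      if (!is_ec_number(f[4])) {
        abort(sprintf("Line %d: malformed EC number '%s'.", ln, f[4]),
              class = "vitapath_validation_error")
      }
    } else {
      abort(sprintf("Line %d: unknown id_type '%s' (expected KO or EC).", ln, f[3]),
            class = "vitapath_validation_error")
    }
    tibble::tibble(vitamin = f[1], category = f[2], id_type = f[3], identifier = f[4])
  })
  tab <- dplyr::bind_rows(parsed)

  entries <- tab |>
    dplyr::filter(.data$id_type == "KO") |>
    dplyr::select(vitamin = "vitamin", category = "category", ko = "identifier")
  enzymes <- tab |>
    dplyr::filter(.data$id_type == "EC") |>
    dplyr::select(vitamin = "vitamin", role = "category", ec = "identifier")
  vita_catalog(entries, enzymes)
}

#' Write a vitamin catalog to TSV
#'
#' Inverse of [load_catalog()]: the written file reparses to an identical
#' catalog.
#'
#' @param catalog A [vita_catalog].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "vita_catalog"))
  tab <- dplyr::bind_rows(
    catalog$entries |>
      dplyr::transmute(vitamin = .data$vitamin, category = .data$category,
                       id_type = "KO", identifier = .data$ko),
    catalog$enzymes |>
      dplyr::transmute(vitamin = .data$vitamin, category = .data$role,
                       id_type = "EC", identifier = .data$ec)
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' KO identifiers for a (vitamin, category) pair
#'
#' @param catalog A [vita_catalog].
#' @param vitamin One of the nine vitamin labels, see [vitamin_labels()].
#' @param category `"biosynthesis"` or `"transport"`.
#' @return Character vector of KO identifiers; empty for a valid-but-absent
#'   combination (never an error).
#' @export
kos_for <- function(catalog, vitamin, category) {
  stopifnot(inherits(catalog, "vita_catalog"))
  check_vitamin(vitamin)
  check_category(category)
  catalog$entries$ko[catalog$entries$vitamin == vitamin &
                       catalog$entries$category == category]
}

#' EC numbers for a vitamin and enzyme role
#'
#' @param catalog A [vita_catalog].
#' @param vitamin A vitamin label.
#' @param role `"biosynthetic"` (enzymes of the vitamin's biosynthesis
#'   pathway) or `"dependent"` (enzymes requiring the vitamin as cofactor).
#' @return Character vector of EC numbers (possibly empty).
#' @export
ecs_for <- function(catalog, vitamin, role = c("biosynthetic", "dependent")) {
  stopifnot(inherits(catalog, "vita_catalog"))
  check_vitamin(vitamin)
  role <- match.arg(role)
  catalog$enzymes$ec[catalog$enzymes$vitamin == vitamin & catalog$enzymes$role == role]
}

#' Illustrative default vitamin catalog
#'
#' A small, hand-picked subset of real KO and EC identifiers covering all
#' nine vitamins — enough to exercise the pipeline end to end. It is
#' illustrative, not an authoritative pathway definition: production analyses
#' should supply a curated catalog via [load_catalog()].
#'
#' @return A [vita_catalog].
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "default_catalog.tsv", package = "vitapath",
                           mustWork = TRUE))
}
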