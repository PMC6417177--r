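#' Spearman rank correlation with a small-sample exact p-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks
#' (average ranks for ties). The two-sided p-value comes from the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom for `n >= 10`, and from an exact permutation
#' distribution (all `n!` rearrangements of one vector) for `n < 10`.
#'
#' A constant vector leaves the correlation undefined: the result carries
#' `rho = NA`, `p = NA` (downstream, such an edge is unclassified) rather
#' than raising an error.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A list with elements `rho` and `p`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length.", class = "vitapath_input_error")
  if (n < 3) abort("Spearman correlation needs at least 3 paired observations.",
                   class = "vitapath_insufficient_data_error")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.",
                                  class = "vitapath_input_error")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(x, y, method = "spearman")
  list(rho = rho, p = spearman_pvalue(rho, x, y))
}

spearman_pvalue <- function(rho, x, y) {
  n <- length(x)
  if (n >= 10) {
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * pt(-abs(tstat), df = n - 2))
  }
  rx <- rank(x)
  ry <- rank(y)
  perms <- all_permutations(n)
  rho_perm <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rho_perm) >= abs(rho) - 1e-12)
}

# All permutations of 1..n as an n! x n matrix (n <= 9 by construction of
# the exact branch above).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

#' Build a species co-occurrence network
#'
#' Computes Spearman correlations between all unordered pairs of species
#' across samples, and classifies each pair: `positive` when
#' `rho >= rho_cutoff` (default 0.4) with `p` below `alpha`, `negative` when
#' `rho < 0` with `p` below `alpha`, otherwise `unclassified` (the band
#' `0 <= rho < rho_cutoff`, non-significant correlations, and undefined
#' correlations from constant vectors). Each edge is additionally labelled
#' with the unordered phenotype pair of its two species for every requested
#' vitamin (e.g. `"P-PC"`).
#'
#' @param abund Wide species-abundance tibble: first column `species`,
#'   remaining columns samples, cells = relative abundance fractions.
#' @param phenotypes Optional tibble `species`, `vitamin`, `phenotype` from
#'   [assign_phenotypes()]; required when `vitamins` is given.
#' @param vitamins Character vector of vitamin labels for which to attach
#'   phenotype-pair edge labels (default none).
#' @param alpha Significance level for edge classification (default 0.01).
#' @param rho_cutoff Positive-correlation threshold (default 0.4).
#' @param bonferroni_edges When `TRUE`, Bonferroni-adjust the edge p-values
#'   across all pairs before classification (off by default).
#' @return A `vita_network`: list with `edges` (one row per unordered pair:
#'   `species_a`, `species_b`, `rho`, `p`, `classification`, plus one
#'   `pheno_<vitamin>` column per requested vitamin) and `summary` (see
#'   [summarize_network()]), plus `phenotype_tally` counts per
#'   (vitamin, classification, phenotype pair).
#' @export
build_network <- function(abund, phenotypes = NULL, vitamins = character(),
                          alpha = 0.01, rho_cutoff = 0.4,
                          bonferroni_edges = FALSE) {
  abund <- tibble::as_tibble(abund)
  stopifnot(names(abund)[1] == "species")
  samples <- setdiff(names(abund), "species")
  if (nrow(abund) < 2) abort("Need at least 2 species.", class = "vitapath_insufficient_data_error")
  if (length(samples) < 3) {
    abort("Need at least 3 samples to correlate species.",
          class = "vitapath_insufficient_data_error")
  }
  if (length(vitamins) > 0) {
    check_vitamin(vitamins)
    if (is.null(phenotypes)) abort("Phenotype labels requested but `phenotypes` is NULL.",
                                   class = "vitapath_input_error")
  }
  stopifnot(alpha > 0, alpha < 1, rho_cutoff >= 0, rho_cutoff <= 1)

  mat <- t(as.matrix(abund[samples]))
  colnames(mat) <- abund$species
  n <- ncol(mat)
  ns <- nrow(mat)

  pair_idx <- combn(n, 2)
  rho_mat <- suppressWarnings(cor(mat, method = "spearman"))
  rho <- rho_mat[cbind(pair_idx[1, ], pair_idx[2, ])]
  constant <- apply(mat, 2, function(v) length(unique(v)) == 1)
  undef <- constant[pair_idx[1, ]] | constant[pair_idx[2, ]]
  rho[undef] <- NA_real_

  if (ns >= 10) {
    p <- ifelse(abs(rho) >= 1, 0,
                2 * pt(-abs(rho * sqrt((ns - 2) / (1 - rho^2))), df = ns - 2))
  } else {
    p <- vapply(seq_len(ncol(pair_idx)), function(k) {
      if (is.na(rho[k])) return(NA_real_)
      spearman_pvalue(rho[k], mat[, pair_idx[1, k]], mat[, pair_idx[2, k]])
    }, numeric(1))
  }
  p[undef] <- NA_real_
  p_class <- if (bonferroni_edges) bonferroni(p) else p

  edges <- tibble::tibble(
    species_a = abund$species[pair_idx[1, ]],
    species_b = abund$species[pair_idx[2, ]],
    rho = rho,
    p = p,
    classification = dplyr::case_when(
      is.na(rho) | is.na(p_class) ~ "unclassified",
      rho >= rho_cutoff & p_class < alpha ~ "positive",
      rho < 0 & p_class < alpha ~ "negative",
      TRUE ~ "unclassified"
    )
  )

  for (v in vitamins) {
    ph <- phenotypes |> dplyr::filter(.data$vitamin == v)
    lab <- setNames(ph$phenotype, ph$species)
    a <- dplyr::coalesce(unname(lab[edges$species_a]), "absent")
    b <- dplyr::coalesce(unname(lab[edges$species_b]), "absent")
    edges[[paste0("pheno_", v)]] <- paste(pmin(a, b), pmax(a, b), sep = "-")
  }

  tally <- NULL
  if (length(vitamins) > 0) {
    tally <- purrr::map_dfr(vitamins, function(v) {
      edges |>
        dplyr::count(.data$classification, pair = .data[[paste0("pheno_", v)]],
                     name = "n") |>
        dplyr::mutate(vitamin = v, .before = 1)
    })
  }

  structure(list(
    edges = edges,
    summary = summarize_network(edges),
    phenotype_tally = tally,
    n_species = n,
    alpha = alpha,
    rho_cutoff = rho_cutoff
  ), class = "vita_network")
}

#' Summarize network edge classifications
#'
#' Tallies edges per classification and expresses each count as a percentage
#' of all `n_species * (n_species - 1) / 2` pairs
#' (`pct = n / n_pairs * 100`).
#'
#' @param edges Edge tibble with a `classification` column (from
#'   [build_network()], or assembled from reported pair counts).
#' @return Tibble `classification`, `n`, `pct` covering `positive`,
#'   `negative` and `unclassified`; counts sum to the number of pairs and
#'   percentages to 100.
#' @export
summarize_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot("classification" %in% names(edges))
  n_pairs <- nrow(edges)
  tibble::tibble(classification = c("positive", "negative", "unclassified")) |>
    dplyr::left_join(dplyr::count(edges, .data$classification, name = "n"),
                     by = "classification") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = .data$n / n_pairs * 100)
}

#' @export
print.vita_network <- function(x, ...) {
  cat(sprintf("<vita_network> %d species, %d pairs (alpha = %g, rho cutoff = %g)\n",
              x$n_species, nrow(x$edges), x$alpha, x$rho_cutoff))
  print(x$summary)
  invisible(x)
}

#' Tidy a co-occurrence network into its edge list
#'
#' @param x A `vita_network`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.vita_network <- function(x, ...) x$edges

#' One-row summary of a co-occurrence network
#'
#' @param x A `vita_network`.
#' @param ... Unused.
#' @return One-row tibble: species and pair counts, edge counts and
#'   percentages per classification.
#' @export
glance.vita_network <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_species = x$n_species,
    n_pairs = nrow(x$edges),
    n_positive = s$n[s$classification == "positive"],
    n_negative = s$n[s$classification == "negative"],
    n_unclassified = s$n[s$classification == "unclassified"],
    pct_positive = s$pct[s$classification == "positive"],
    pct_negative = s$pct[s$classification == "negative"]
  )
}
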