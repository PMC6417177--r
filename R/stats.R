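#' Mann-Whitney-Wilcoxon two-sample test
#'
#' Rank-sum test for a location difference between two independent groups.
#' The U statistic uses mid-ranks for ties. The two-sided p-value is exact
#' (full enumeration of the U null distribution) when both groups have at
#' most 8 observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, each with at least one value.
#' @return List with `U` (statistic for `x`), `p` (two-sided), and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both groups must contain at least one value.", class = "vitapath_input_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal")
}

#' Kruskal-Wallis test across three or more groups
#'
#' H statistic with tie correction; p-value from the chi-square distribution
#' on `k - 1` degrees of freedom.
#'
#' @param groups List of at least 3 non-empty numeric vectors.
#' @return List with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    abort("Kruskal-Wallis needs at least 3 groups; use mann_whitney() for two.",
          class = "vitapath_input_error")
  }
  if (any(lengths(groups) == 0)) abort("All groups must be non-empty.",
                                       class = "vitapath_input_error")
  if (length(unique(unlist(groups))) == 1) {
    # every observation tied: no rank variation, trivially null
    return(list(H = 0, p = 1, df = length(groups) - 1))
  }
  ht <- kruskal.test(groups)
  list(H = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of simultaneous tests, capping at
#' 1. `NA` entries pass through unchanged and do not count toward the
#' family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param m Family size; defaults to the number of non-missing p-values.
#' @return Adjusted p-values, same length as `p`.
#' @export
bonferroni <- function(p, m = sum(!is.na(p))) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1].", class = "vitapath_input_error")
  pmin(1, p * max(m, 1))
}

#' Significance star labels
#'
#' The conventional star coding used on violin-plot group comparisons:
#' `ns` for p > 0.05, `*` for p <= 0.05, `**` for p <= 0.01, `***` for
#' p <= 0.001 and `****` for p <= 0.0001 (boundaries inclusive toward the
#' stronger label's upper edge).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels in `{ns, *, **, ***, ****}`.
#' @export
stars <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1].", class = "vitapath_input_error")
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.0001 ~ "****",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Group comparison of pathway abundance profiles
#'
#' Runs, for every (vitamin, category) in the profile, a two-group
#' Mann-Whitney-Wilcoxon test or a Kruskal-Wallis test (three or more
#' groups), applies a Bonferroni correction across all tests of the
#' invocation, and attaches star labels. Stars reflect the raw p-value (the
#' adjusted p is reported alongside).
#'
#' @param profile Tibble `sample`, `vitamin`, `category` (optional),
#'   `abundance` — e.g. from [total_pathway_abundance()] or
#'   [group_ec_abundance()].
#' @param metadata Tibble `sample`, `group`.
#' @param family Bonferroni family size override; defaults to the number of
#'   tests performed in this invocation.
#' @return Tibble `vitamin`, `category`, `groups`, `test`, `statistic`,
#'   `p`, `p_adj`, `stars`.
#' @export
compare_groups <- function(profile, metadata, family = NULL) {
  profile <- tibble::as_tibble(profile)
  metadata <- tibble::as_tibble(metadata)
  stopifnot(all(c("sample", "vitamin", "abundance") %in% names(profile)),
            all(c("sample", "group") %in% names(metadata)))
  if (!"category" %in% names(profile)) profile$category <- NA_character_

  dat <- dplyr::inner_join(profile, metadata, by = "sample")
  glabs <- sort(unique(dat$group))
  if (length(glabs) < 2) abort("Need at least two groups.", class = "vitapath_input_error")

  res <- dat |>
    dplyr::group_by(.data$vitamin, .data$category) |>
    dplyr::group_modify(function(d, key) {
      vals <- split(d$abundance, factor(d$group, levels = glabs))
      if (length(glabs) == 2) {
        ht <- mann_whitney(vals[[1]], vals[[2]])
        tibble::tibble(groups = paste(glabs, collapse = " vs "),
                       test = "Mann-Whitney-Wilcoxon",
                       statistic = ht$U, p = ht$p)
      } else {
        ht <- kruskal_wallis(vals)
        tibble::tibble(groups = paste(glabs, collapse = " vs "),
                       test = "Kruskal-Wallis",
                       statistic = ht$H, p = ht$p)
      }
    }) |>
    dplyr::ungroup()

  res |>
    dplyr::mutate(p_adj = bonferroni(.data$p, m = family %||% dplyr::n()),
                  stars = stars(.data$p)) |>
    dplyr::arrange(.data$vitamin, .data$category)
}

#' Association between pathway abundance and a pooled binary indicator
#'
#' Pools samples into a binary classification (e.g. one country versus the
#' rest, diseased versus healthy) and tests, per (vitamin, category),
#' whether abundance is associated with the indicator. The default
#' direction regresses abundance on the 0/1 indicator by ordinary least
#' squares and reports the slope and the model F statistic with its p-value.
#' `direction = "logistic"` instead fits a logistic regression of the
#' indicator on abundance and reports the slope and the likelihood-ratio
#' chi-square statistic.
#'
#' @param profile Tibble `sample`, `vitamin`, `category` (optional),
#'   `abundance`.
#' @param metadata Tibble with `sample` and the indicator source column.
#' @param column Metadata column to pool on (e.g. `"country"`).
#' @param level Level of `column` coded 1 (the rest coded 0).
#' @param direction `"ols"` (abundance ~ indicator, default) or
#'   `"logistic"` (indicator ~ abundance).
#' @return Tibble `vitamin`, `category`, `indicator`, `slope`, `statistic`,
#'   `p` (statistic is the F statistic for `"ols"`, the LR chi-square for
#'   `"logistic"`).
#' @export
indicator_association <- function(profile, metadata, column, level,
                                  direction = c("ols", "logistic")) {
  direction <- match.arg(direction)
  profile <- tibble::as_tibble(profile)
  metadata <- tibble::as_tibble(metadata)
  stopifnot(all(c("sample", "vitamin", "abundance") %in% names(profile)),
            "sample" %in% names(metadata), column %in% names(metadata))
  if (!"category" %in% names(profile)) profile$category <- NA_character_

  metadata$indicator <- as.integer(metadata[[column]] == level)
  if (length(unique(metadata$indicator)) < 2) {
    abort(sprintf("Indicator '%s == %s' is constant across samples.", column, level),
          class = "vitapath_input_error")
  }
  dat <- dplyr::inner_join(profile, metadata[c("sample", "indicator")], by = "sample")
  ind_name <- sprintf("%s=%s vs rest", column, level)

  dat |>
    dplyr::group_by(.data$vitamin, .data$category) |>
    dplyr::group_modify(function(d, key) {
      if (direction == "ols") {
        fit <- lm(abundance ~ indicator, data = d)
        av <- anova(fit)
        tibble::tibble(indicator = ind_name,
                       slope = unname(coef(fit)["indicator"]),
                       statistic = av[["F value"]][1],
                       p = av[["Pr(>F)"]][1])
      } else {
        fit <- glm(indicator ~ abundance, data = d, family = binomial())
        lr <- fit$null.deviance - fit$deviance
        tibble::tibble(indicator = ind_name,
                       slope = unname(coef(fit)["abundance"]),
                       statistic = lr,
                       p = pchisq(lr, df = 1, lower.tail = FALSE))
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$vitamin, .data$category)
}
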