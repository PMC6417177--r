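#' Violin plot of pathway abundance by group
#'
#' The standard presentation for per-vitamin group comparisons: one violin
#' per (vitamin, category, group), with a point-range marking mean and
#' standard deviation.
#'
#' @param profile Tibble `sample`, `vitamin`, `category` (optional),
#'   `abundance`.
#' @param metadata Tibble `sample`, `group`.
#' @return A ggplot object.
#' @export
plot_pathway_abundance <- function(profile, metadata) {
  dat <- dplyr::inner_join(tibble::as_tibble(profile), tibble::as_tibble(metadata),
                           by = "sample")
  if ("category" %in% names(dat)) {
    dat$pathway <- paste0(dat$vitamin, "-", toupper(substr(dat$category, 1, 1)))
  } else {
    dat$pathway <- dat$vitamin
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pathway, y = .data$abundance,
                                    fill = .data$group)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         alpha = 0.6, scale = "width") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "pointrange", size = 0.2,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = "Total normalized abundance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a cohort coverage matrix
#'
#' Tiles species (cohort-ordered rows) against reactions (grouped by
#' vitamin); fill encodes the abundance-weighted reaction presence, with a
#' distinct colour for species absent from the cohort.
#'
#' @param object A `vita_coverage` from [build_cohort_matrix()].
#' @param group Sample group to display (default: the reference group).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vita_coverage <- function(object, group = NULL, ...) {
  group <- group %||% attr(object, "reference_group")
  dat <- dplyr::filter(tibble::as_tibble(object), .data$group == !!group) |>
    dplyr::mutate(
      species = factor(.data$species, levels = rev(attr(object, "species_order"))),
      rxn = factor(paste(.data$vitamin, .data$reaction, sep = ":"),
                   levels = attr(object, "reaction_order"))
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rxn, y = .data$species,
                                    fill = .data$weighted)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_gradient(low = "#f2e6ff", high = "#3b0a70",
                                 na.value = "grey70",
                                 name = "Weighted\ncoverage") +
    ggplot2::labs(x = "Reaction (grouped by vitamin)", y = NULL,
                  title = sprintf("Vitamin-pathway coverage, %s group", group)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' Bar chart of network edge classifications
#'
#' @param object A `vita_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vita_network <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$classification, y = .data$pct,
                               fill = .data$classification)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(positive = "#2166ac",
                                          negative = "#b2182b",
                                          unclassified = "grey60")) +
    ggplot2::labs(x = NULL, y = "% of species pairs") +
    ggplot2::theme_minimal()
}
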