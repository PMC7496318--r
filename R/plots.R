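#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_errorbarh geom_col geom_histogram geom_tile geom_line labs
#'   facet_wrap scale_fill_gradient theme_minimal
NULL

#' Plot per-species segment positions with confidence intervals
#'
#' One row per species, mean relative position of each segment with its 95%
#' confidence interval, coloured by segment.
#'
#' @param object a `segmorph_species_summary`.
#' @param ... ignored.
#' @export
autoplot.segmorph_species_summary <- function(object, ...) {
  ggplot(object$by_segment,
         aes(x = .data$mean_p, y = .data$species, colour = .data$segment)) +
    geom_errorbarh(aes(xmin = .data$ci95_low, xmax = .data$ci95_high), height = 0.3) +
    geom_point(size = 1) +
    labs(x = "relative segment position (fraction of larval length)",
         y = NULL, colour = "segment") +
    theme_minimal()
}

#' Plot PCA variance explained
#' @param object a `segmorph_pca`.
#' @param ... ignored.
#' @export
autoplot.segmorph_pca <- function(object, ...) {
  ve <- tibble(component = names(object$variance_explained),
               variance = object$variance_explained)
  ve$component <- factor(ve$component, levels = ve$component)
  ggplot(ve, aes(x = .data$component, y = .data$variance)) +
    geom_col() +
    labs(y = "fraction of variance explained", x = NULL) +
    theme_minimal()
}

#' Heatmap of pairwise species differences
#' @param object a `segmorph_pairdiff`.
#' @param ... ignored.
#' @export
autoplot.segmorph_pairdiff <- function(object, ...) {
  ggplot(object$pair_counts,
         aes(x = .data$species_a, y = .data$species_b, fill = .data$n_differing)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = NULL, y = NULL, fill = "segments\ndiffering") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Within-species correlation vs segment distance
#'
#' Across-species mean Pearson correlation between segment-position pairs
#' against the pair's mean relative distance, split by A8 involvement.
#'
#' @param object a `segmorph_corprofile`.
#' @param ... ignored.
#' @export
autoplot.segmorph_corprofile <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$mean_distance, y = .data$mean_r, colour = .data$involves_a8)) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0) +
    geom_point() +
    labs(x = "mean relative distance between segments",
         y = "mean within-species correlation", colour = "involves A8") +
    theme_minimal()
}

#' Distribution of normalised branch changes
#' @param object a `segmorph_branch_changes`.
#' @param bins histogram bins.
#' @param ... ignored.
#' @export
autoplot.segmorph_branch_changes <- function(object, bins = 60, ...) {
  ggplot(tibble(c_b = object$pooled), aes(x = .data$c_b)) +
    geom_histogram(bins = bins) +
    labs(x = "change in relative position per unit time", y = "count") +
    theme_minimal()
}

#' Between-segment rate correlation vs anatomical distance
#' @param object a `segmorph_rate_correlations`.
#' @param ... ignored.
#' @export
autoplot.segmorph_rate_correlations <- function(object, ...) {
  ggplot(object, aes(x = .data$distance, y = .data$r, colour = .data$seg_a)) +
    geom_point() +
    labs(x = "anatomical distance (fraction of larval length)",
         y = "correlation of branch log rates", colour = "first segment") +
    theme_minimal()
}
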