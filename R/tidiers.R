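#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fused feature set
#'
#' @param x A `ranked_feature_set`.
#' @param ... Unused.
#' @return Tibble with `feature`, `score` and `fused_rank` (1 = best), plus
#'   `dataset` when tagged.
#' @exportS3Method generics::tidy
tidy.ranked_feature_set <- function(x, ...) {
  out <- dplyr::mutate(x$fused, fused_rank = dplyr::row_number())
  if (!is.null(x$dataset)) out <- dplyr::mutate(out, dataset = x$dataset)
  out
}

#' @rdname tidy.ranked_feature_set
#' @exportS3Method generics::glance
glance.ranked_feature_set <- function(x, ...) {
  tibble(dataset = x$dataset %||% NA_character_,
         n_rankings = x$n_rankings, top_k = x$top_k)
}

#' Tidy a post-hoc rank comparison
#'
#' @param x A `posthoc_result`.
#' @param ... Unused.
#' @return The per-group tibble (`group`, `n`, `mean_rank`, `halfwidth`,
#'   `significant_vs_top`).
#' @exportS3Method generics::tidy
tidy.posthoc_result <- function(x, ...) x$groups

#' @rdname tidy.posthoc_result
#' @exportS3Method generics::glance
glance.posthoc_result <- function(x, ...) {
  tibble(statistic = x$kw$statistic, p_value = x$kw$p_value, df = x$kw$df,
         n_groups = nrow(x$groups), top_group = x$top_group, alpha = x$alpha)
}

#' Forest-style plot of post-hoc rank intervals
#'
#' Mean-rank estimates with their comparison intervals, the top-ranked
#' group's interval marked by dotted verticals; groups whose intervals are
#' disjoint from the top group's (significantly lower-ranked) are filled.
#'
#' @param object A `posthoc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.posthoc_result <- function(object, ...) {
  d <- dplyr::arrange(object$groups, .data$mean_rank)
  d$group <- factor(d$group, levels = d$group)
  top <- object$groups[object$groups$group == object$top_group, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_rank, y = .data$group)) +
    ggplot2::geom_vline(xintercept = c(top$mean_rank - top$halfwidth,
                                       top$mean_rank + top$halfwidth),
                        linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean_rank - .data$halfwidth,
                                         xmax = .data$mean_rank + .data$halfwidth),
                            height = 0.3) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant_vs_top),
                        size = 2.5, fill = "black") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 23),
                                name = "significantly below top") +
    ggplot2::labs(x = "mean rank of balanced accuracy", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the balanced-accuracy grid
#'
#' One tile per (classifier, feature count) cell, faceted by delineation
#' and modality.
#'
#' @param object A `bar_grid` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bar_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$n_features),
                               y = .data$classifier, fill = .data$bar)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(delineation ~ modality) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "BAR") +
    ggplot2::labs(x = "number of fused features", y = NULL) +
    ggplot2::theme_minimal()
}
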