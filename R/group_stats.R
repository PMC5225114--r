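#' Midrank transform
#'
#' Ranks 1..n with tied values receiving the average of their positional
#' ranks, e.g. `c(0.5, 0.7, 0.7, 0.9)` becomes `c(1, 2.5, 2.5, 4)`.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector of ranks summing to `n(n+1)/2`.
#' @export
midrank <- function(values) {
  if (!length(values)) abort("empty input")
  rank(values, ties.method = "average")
}

#' Kruskal-Wallis test across groups of balanced-accuracy values
#'
#' The tie-corrected H statistic on pooled midranks with a chi-square
#' p-value on `length(groups) - 1` degrees of freedom (a thin wrapper over
#' [stats::kruskal.test()]). A fully tied pooled sample yields H = 0, p = 1.
#'
#' @param groups List (>= 2) of non-empty numeric vectors.
#' @return List with `statistic` (H), `p_value` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) abort("need >= 2 groups")
  if (any(!lengths(groups))) abort("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn-Šidák post-hoc comparison of group mean ranks
#'
#' Each group is summarized by the mean of its pooled midranks, displayed
#' with a comparison interval: half-width \eqn{c \sqrt{\sigma^2 / (2 n_g)}},
#' where \eqn{\sigma^2 = N(N+1)/12 - \sum(t^3 - t)/(12(N-1))} is the
#' tie-corrected rank variance and \eqn{c} the normal critical value at the
#' Šidák-adjusted level \eqn{1 - (1-\alpha)^{1/m}} over all
#' \eqn{m = k(k-1)/2} pairwise comparisons. With equal group sizes, two
#' intervals are disjoint exactly when the mean-rank difference exceeds
#' \eqn{c} standard errors — the decision rule used to flag groups as
#' significantly different from the top-ranked group. Ties for the top group
#' are broken by group name.
#'
#' @param groups Named list (>= 2) of non-empty numeric vectors.
#' @param alpha Family-wise significance level (default 0.05).
#' @return An object of class `posthoc_result`: list with `groups` (tibble
#'   `group`, `n`, `mean_rank`, `halfwidth`, `significant_vs_top`),
#'   `top_group`, `kw` (the [kruskal_wallis()] result), `alpha`,
#'   `n_comparisons`.
#' @export
dunn_sidak_compare <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) abort("need >= 2 groups")
  if (any(!lengths(groups))) abort("all groups must be non-empty")
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    names(groups) <- sprintf("group%02d", seq_along(groups))
  }
  kw <- kruskal_wallis(groups)
  pooled <- unlist(groups, use.names = FALSE)
  n_total <- length(pooled)
  r <- midrank(pooled)
  g <- rep(names(groups), lengths(groups))
  mean_ranks <- tapply(r, g, mean)[names(groups)]
  sizes <- lengths(groups)

  ties <- table(pooled)
  tie_adj <- if (n_total > 1) sum(ties^3 - ties) / (12 * (n_total - 1)) else 0
  sigma2 <- n_total * (n_total + 1) / 12 - tie_adj
  m <- length(groups) * (length(groups) - 1) / 2
  alpha_sidak <- 1 - (1 - alpha)^(1 / m)
  crit <- stats::qnorm(1 - alpha_sidak / 2)
  halfwidth <- crit * sqrt(pmax(sigma2, 0) / (2 * sizes))

  ord <- order(-mean_ranks, names(groups))
  top <- names(groups)[ord[1]]
  disjoint <- (mean_ranks[top] - halfwidth[top]) > (mean_ranks + halfwidth)
  disjoint[top] <- FALSE

  res <- tibble(
    group = names(groups),
    n = as.integer(sizes),
    mean_rank = as.numeric(mean_ranks),
    halfwidth = as.numeric(halfwidth),
    significant_vs_top = as.logical(disjoint)
  )
  structure(
    list(groups = res, top_group = top, kw = kw, alpha = alpha,
         n_comparisons = m),
    class = "posthoc_result"
  )
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf(
    "<posthoc_result> %d groups, KW H = %.3f (p = %.3g), top group: %s\n",
    nrow(x$groups), x$kw$statistic, x$kw$p_value, x$top_group))
  print(x$groups)
  invisible(x)
}

# The four grouping schemes of the benchmark grid.
GROUPING_SCHEMES <- list(
  delineation_modality_classifier = c("delineation", "modality", "classifier"),
  delineation_modality = c("delineation", "modality"),
  delineation_classifier = c("delineation", "classifier"),
  delineation_n_features = c("delineation", "n_features")
)

#' Group the benchmark grid four ways and compare ranks
#'
#' Partitions the 560-cell balanced-accuracy grid by (a) delineation x
#' modality x classifier (56 groups of 10), (b) delineation x modality
#' (8 of 70), (c) delineation x classifier (14 of 40) and (d) delineation x
#' feature count (20 of 28), feeding each partition to [kruskal_wallis()]
#' and [dunn_sidak_compare()].
#'
#' @param grid A [run_grid()] tibble (must cover the full grid for the
#'   stated group counts; an incomplete grid over the implied axes is an
#'   error naming the missing cells).
#' @param alpha Significance level passed to [dunn_sidak_compare()].
#' @return Named list of four `posthoc_result` objects.
#' @export
build_groupings <- function(grid, alpha = 0.05) {
  axes <- list(delineation = unique(grid$delineation),
               modality = unique(grid$modality),
               classifier = unique(grid$classifier),
               n_features = unique(grid$n_features))
  full <- expand.grid(axes, stringsAsFactors = FALSE)
  key <- function(d) do.call(paste, c(d[names(axes)], sep = "|"))
  missing_cells <- setdiff(key(full), key(grid))
  if (length(missing_cells)) {
    abort(sprintf("incomplete grid; missing cells: %s%s",
                  paste(head(missing_cells, 5), collapse = "; "),
                  if (length(missing_cells) > 5) " ..." else ""))
  }
  out <- lapply(GROUPING_SCHEMES, function(cols) {
    keys <- do.call(paste, c(grid[cols], sep = "-"))
    if (length(unique(keys)) < 2) return(NULL)  # scheme collapses on a restricted grid
    dunn_sidak_compare(split(grid$bar, keys), alpha = alpha)
  })
  out[!vapply(out, is.null, logical(1))]
}
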