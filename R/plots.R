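# ggplot2 visualisations for the main result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_hline
#'   geom_density geom_vline labs scale_fill_gradient2 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Heatmap of a genomic relationship matrix
#'
#' Clones are ordered by complete-linkage clustering of 1 - G so related
#' groups appear as blocks.
#'
#' @param object a [compute_grm()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.grm <- function(object, ...) {
  G <- object$values
  ord <- hclust(stats::as.dist(max(G) - G), method = "complete")$order
  ids <- rownames(G)[ord]
  df <- as_tibble(G[ord, ord], rownames = "clone_i") %>%
    tidyr::pivot_longer(-"clone_i", names_to = "clone_j",
                        values_to = "relationship") %>%
    mutate(clone_i = factor(.data$clone_i, levels = ids),
           clone_j = factor(.data$clone_j, levels = ids))
  ggplot(df, aes(.data$clone_i, .data$clone_j, fill = .data$relationship)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "G") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Per-fold predictive ability plot
#'
#' Points per fold with the mean r_y as a horizontal line.
#'
#' @param object a [cross_validate()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot(object$folds, aes(factor(.data$fold), .data$r)) +
    geom_point(size = 2) +
    geom_hline(yintercept = object$r_y, linetype = 2) +
    labs(x = "fold", y = "predictive ability r",
         title = sprintf("r_y = %.3f +- %.3f (%d-fold)", object$r_y,
                         object$sd, object$k)) +
    theme_minimal()
}

#' Permutation-null density with the observed predictive ability
#'
#' @param object a [permutation_null()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.perm_null <- function(object, ...) {
  ggplot(tibble(r = object$null), aes(.data$r)) +
    geom_density(fill = "grey80") +
    geom_vline(xintercept = object$observed, colour = "#b2182b") +
    labs(x = "permuted r_y", y = "density",
         title = sprintf("observed r_y = %.3f, p = %.3g", object$observed,
                         object$p_value)) +
    theme_minimal()
}

#' Ranked clonal BLUP plot
#'
#' Clone values ordered by rank, with the overall mean as a reference line.
#'
#' @param object a [clonal_blups()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.clonal_blups <- function(object, ...) {
  df <- object$blups %>% arrange(.data$value) %>%
    mutate(rank = dplyr::row_number())
  ggplot(df, aes(.data$rank, .data$value)) +
    geom_point() +
    geom_hline(yintercept = object$mean, linetype = 2) +
    labs(x = "clone rank", y = "predicted clonal value",
         title = sprintf("H2 = %.2f", object$H2)) +
    theme_minimal()
}
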