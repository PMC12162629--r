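#' Plot the training loss history
#'
#' One line per loss component (prediction loss, the two KL terms, total)
#' against the epoch.
#'
#' @param object A `dvamda_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvamda_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold ROC curves of a cross-validation run
#'
#' @param object A `dvamda_cv`.
#' @param ... Unused.
#' @return A ggplot with one ROC curve per fold and the chance diagonal.
#' @export
autoplot.dvamda_cv <- function(object, ...) {
  roc_points <- function(df) {
    ord <- order(-df$score)
    y <- df$label[ord]
    tibble::tibble(
      fpr = c(0, cumsum(1 - y) / max(sum(1 - y), 1)),
      tpr = c(0, cumsum(y) / max(sum(y), 1))
    )
  }
  curves <- dplyr::group_modify(
    dplyr::group_by(object$predictions, .data$fold),
    ~ roc_points(.x)
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       color = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = "fold") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Heatmap of an association matrix
#'
#' @param A An `association_matrix`.
#' @return A ggplot tile map (microbes on the y axis).
#' @export
plot_association <- function(A) {
  stopifnot(inherits(A, "association_matrix"))
  df <- tidyr::expand_grid(
    microbe = seq_along(A$microbe_names),
    disease = seq_along(A$disease_names)
  )
  df$value <- A$values[cbind(df$microbe, df$disease)]
  ggplot2::ggplot(df, ggplot2::aes(.data$disease, .data$microbe,
                                   fill = factor(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "grey15"),
                               guide = "none") +
    ggplot2::labs(x = "disease", y = "microbe") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
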