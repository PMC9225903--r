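#' Plot the LD similarity (or closure) structure of a clustering
#'
#' A tile heatmap of the pairwise |D'| similarity matrix with loci ordered
#' by equivalence class, so the block structure the lambda-cut found shows
#' up as squares along the diagonal.
#'
#' @param object An `ld_clustering` from [ld_cluster()].
#' @param matrix Which relation to draw: the raw `"similarity"` or the
#'   transitive `"closure"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ld_clustering
#' @export
autoplot.ld_clustering <- function(object, matrix = c("similarity", "closure"),
                                   ...) {
  matrix <- match.arg(matrix)
  M <- if (matrix == "closure") object$closure else object$similarity
  ord <- order(object$class_of, seq_len(object$m))
  M <- M[ord, ord]
  ids <- factor(object$locus_ids[ord], levels = object$locus_ids[ord])
  df <- tibble::tibble(
    locus_i = rep(ids, times = object$m),
    locus_j = rep(ids, each = object$m),
    ld = as.vector(M))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus_j, y = .data$locus_i,
                                   fill = .data$ld)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "|D'|") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Pairwise LD (%s), loci ordered by class",
                                  matrix)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the swarm's incumbent fitness trajectory
#'
#' @param object A `tag_selection` from [bpso_select()].
#' @param ... Unused.
#' @return A ggplot object: gbest fitness against iteration.
#' @method autoplot tag_selection
#' @export
autoplot.tag_selection <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$history) - 1L,
                       fitness = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "incumbent (gbest) fitness",
                  title = sprintf("BPSO trajectory: %d tags from %d candidates",
                                  object$n_tags, length(object$position))) +
    ggplot2::theme_minimal()
}

#' Plot per-fold leave-one-out imputation accuracy
#'
#' @param object An `accuracy_report` from [loocv_accuracy()].
#' @param ... Unused.
#' @return A ggplot object: histogram of per-fold accuracies with the
#'   overall accuracy marked.
#' @method autoplot accuracy_report
#' @export
autoplot.accuracy_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_acc)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$acc, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "per-fold accuracy", y = "folds",
                  title = sprintf("LOOCV imputation accuracy = %.4f",
                                  object$acc)) +
    ggplot2::theme_minimal()
}
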