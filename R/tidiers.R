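#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an LD clustering into one row per locus
#'
#' @param x An `ld_clustering` from [ld_cluster()].
#' @param ... Unused.
#' @return A tibble with columns `locus`, `locus_id`, `class_index`,
#'   `is_center`, `class_size`.
#' @method tidy ld_clustering
#' @export
tidy.ld_clustering <- function(x, ...) {
  tibble::tibble(locus = seq_len(x$m),
                 locus_id = x$locus_ids,
                 class_index = x$class_of,
                 is_center = seq_len(x$m) %in% x$centers,
                 class_size = x$class_size[x$class_of])
}

#' @rdname tidy.ld_clustering
#' @method glance ld_clustering
#' @export
glance.ld_clustering <- function(x, ...) {
  tibble::tibble(n_loci = x$m,
                 lambda = x$lambda,
                 n_classes = length(x$classes),
                 largest_class = max(x$class_size),
                 n_singletons = sum(x$class_size == 1L))
}

#' Tidy a tag selection into one row per selected tag
#'
#' @param x A `tag_selection` from [bpso_select()].
#' @param ... Unused.
#' @return A tibble with columns `locus`, `locus_id`, `class_index`,
#'   `class_size`.
#' @method tidy tag_selection
#' @export
tidy.tag_selection <- function(x, ...) {
  clus <- x$clustering
  tibble::tibble(locus = x$tags,
                 locus_id = x$tag_ids,
                 class_index = clus$class_of[x$tags],
                 class_size = clus$class_size[clus$class_of[x$tags]])
}

#' @rdname tidy.tag_selection
#' @method glance tag_selection
#' @export
glance.tag_selection <- function(x, ...) {
  tibble::tibble(n_candidates = length(x$position),
                 n_tags = x$n_tags,
                 fitness = x$fitness,
                 iterations = length(x$history) - 1L,
                 first_hit = which.max(x$history) - 1L)
}

#' Tidy an accuracy report into one row per LOOCV fold
#'
#' @param x An `accuracy_report` from [loocv_accuracy()].
#' @param ... Unused.
#' @return A tibble with columns `fold`, `errors`, `comparisons`,
#'   `fold_acc`.
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$n_samples),
                 errors = x$per_fold_errors,
                 comparisons = x$per_fold_comparisons,
                 fold_acc = ifelse(x$per_fold_comparisons > 0,
                                   1 - x$per_fold_errors / x$per_fold_comparisons,
                                   NA_real_))
}

#' @rdname tidy.accuracy_report
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(acc = x$acc,
                 n_samples = x$n_samples,
                 n_nontag = x$n_nontag,
                 total_comparisons = x$total_comparisons,
                 total_errors = sum(x$per_fold_errors))
}

#' One-row summary of a full pipeline run
#'
#' @param x A `tag_run` from [select_tags()].
#' @param ... Unused.
#' @return A tibble with the run's headline numbers.
#' @method glance tag_run
#' @export
glance.tag_run <- function(x, ...) {
  tibble::tibble(n_loci = x$clustering$m,
                 lambda = x$lambda,
                 n_candidates = length(x$clustering$centers),
                 n_tags = x$n_tags,
                 fitness = x$selection$fitness,
                 acc = if (is.null(x$accuracy)) NA_real_ else x$accuracy$acc)
}
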