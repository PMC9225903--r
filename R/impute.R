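#' Configuration for SVM genotype imputation
#'
#' Non-tag genotypes are predicted by one soft-margin support-vector
#' classifier (C-SVC) per non-tag locus, with an RBF kernel and the tag
#' genotypes as features.
#'
#' @param gamma RBF kernel width, `> 0`. Default 0.07.
#' @param cost Soft-margin cost C, `> 0`. Default 7.
#' @param missing_policy How missing calls in the training data are
#'   handled: `"impute_major"` replaces them with the locus's major allele
#'   computed on the training rows; `"drop_sample"` drops training rows
#'   with any missing call among the loci in use. Missing entries of a
#'   test row's non-tag loci are always excluded from scoring.
#' @return An `impute_config` list.
#' @export
impute_config <- function(gamma = 0.07, cost = 7,
                          missing_policy = c("impute_major", "drop_sample")) {
  stopifnot(gamma > 0, cost > 0)
  structure(list(gamma = gamma, cost = cost,
                 missing_policy = match.arg(missing_policy)),
            class = "impute_config")
}

# fill NA entries of a 0/1 matrix column-wise with the column major allele
fill_major <- function(x) {
  for (j in seq_len(ncol(x))) {
    if (anyNA(x[, j])) {
      f <- mean(x[, j] == 1L, na.rm = TRUE)
      maj <- if (is.nan(f) || f >= 0.5) 1L else 0L
      x[is.na(x[, j]), j] <- maj
    }
  }
  x
}

#' Predict the non-tag genotypes of one held-out haplotype
#'
#' Trains one binary RBF C-SVC per non-tag locus on the training
#' haplotypes (features: tag genotypes; label: the locus's genotype) and
#' predicts the held-out row's non-tag genotypes from its tag genotypes.
#' A non-tag locus that is constant in training is predicted as that
#' constant without fitting a classifier.
#'
#' @param train A [haplotype_matrix()] of training haplotypes (>= 2 rows).
#' @param test_row A vector of length m (one haplotype) coded 0/1/NA.
#' @param tags Tag locus indices or ids; a nonempty proper subset of loci.
#' @param config An [impute_config()].
#' @return A named integer vector of predictions, one per non-tag locus.
#' @export
predict_nontags <- function(train, test_row, tags,
                            config = impute_config()) {
  stopifnot(inherits(train, "haplotype_matrix"))
  m <- ncol(train)
  tag_idx <- resolve_loci(train, tags)
  if (length(tag_idx) == 0L) stop("tag set is empty", call. = FALSE)
  if (length(test_row) != m) {
    stop("test_row must have one entry per locus", call. = FALSE)
  }
  nontag <- setdiff(seq_len(m), tag_idx)
  X <- unclass(train)[, tag_idx, drop = FALSE]
  Y <- unclass(train)[, nontag, drop = FALSE]
  if (config$missing_policy == "drop_sample") {
    keep <- stats::complete.cases(cbind(X, Y))
    if (sum(keep) < 2L) stop("fewer than 2 complete training rows",
                             call. = FALSE)
    X <- X[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  } else {
    X <- fill_major(X)
    Y <- fill_major(Y)
  }
  xt <- test_row[tag_idx]
  if (anyNA(xt)) {   # impute missing tag features with the training major
    for (k in which(is.na(xt))) {
      xt[k] <- if (mean(X[, k] == 1L) >= 0.5) 1L else 0L
    }
  }
  xt <- matrix(as.numeric(xt), nrow = 1L)
  preds <- integer(length(nontag))
  cache <- new.env(parent = emptyenv())   # same labels => same prediction
  for (k in seq_along(nontag)) {
    y <- Y[, k]
    if (length(unique(y)) == 1L) {
      preds[k] <- y[1L]
      next
    }
    key <- paste(y, collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) {
      preds[k] <- hit
      next
    }
    fit <- e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                      type = "C-classification", kernel = "radial",
                      gamma = config$gamma, cost = config$cost,
                      scale = FALSE)
    p <- as.integer(as.character(stats::predict(fit, xt)))
    assign(key, p, envir = cache)
    preds[k] <- p
  }
  names(preds) <- colnames(train)[nontag]
  preds
}

#' Leave-one-out imputation accuracy of a tag set
#'
#' Scores how well the tag SNPs reconstruct the non-tag SNPs: each
#' haplotype in turn is held out, every non-tag genotype is predicted from
#' its tag genotypes by [predict_nontags()] trained on the remaining
#' haplotypes, and the accuracy is
#' `1 - sum(prediction errors) / (number of scored comparisons)`. With
#' complete data the denominator is `|O| * N` (non-tag loci times
#' haplotypes); missing non-tag calls in a held-out row are excluded from
#' both numerator and denominator.
#'
#' @param hm A [haplotype_matrix()] with at least 2 rows.
#' @param tags Tag locus indices or ids; nonempty proper subset.
#' @param config An [impute_config()].
#' @return An `accuracy_report` with `acc`, `n_samples`, `n_nontag`,
#'   `per_fold_errors`, `per_fold_comparisons`, `total_comparisons`.
#'   Use [tidy()] for per-fold rows and [glance()] for the summary.
#' @export
loocv_accuracy <- function(hm, tags, config = impute_config()) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  n <- nrow(hm)
  m <- ncol(hm)
  tag_idx <- resolve_loci(hm, tags)
  if (length(tag_idx) == 0L) stop("tag set is empty", call. = FALSE)
  if (length(unique(tag_idx)) >= m) {
    stop("tag set must be a proper subset of the loci (no non-tag loci left)",
         call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 haplotypes for LOOCV", call. = FALSE)
  nontag <- setdiff(seq_len(m), tag_idx)
  errs <- integer(n)
  comps <- integer(n)
  for (i in seq_len(n)) {
    train <- haplotype_matrix(unclass(hm)[-i, , drop = FALSE],
                              sample_ids = rownames(hm)[-i],
                              locus_ids = colnames(hm))
    pred <- predict_nontags(train, unclass(hm)[i, ], tag_idx, config)
    obs <- unclass(hm)[i, nontag]
    ok <- !is.na(obs)
    errs[i] <- sum(abs(obs[ok] - pred[ok]))
    comps[i] <- sum(ok)
  }
  total <- sum(comps)
  out <- list(acc = if (total > 0) 1 - sum(errs) / total else NA_real_,
              n_samples = n,
              n_nontag = length(nontag),
              per_fold_errors = errs,
              per_fold_comparisons = comps,
              total_comparisons = total,
              tags = sort(unique(tag_idx)),
              config = config)
  class(out) <- "accuracy_report"
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> LOOCV accuracy %.4f (%d haplotypes, %d non-tag loci, %d comparisons)\n",
              x$acc, x$n_samples, x$n_nontag, x$total_comparisons))
  invisible(x)
}
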