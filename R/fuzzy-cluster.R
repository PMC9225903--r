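check_similarity <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("similarity relation must be a square matrix", call. = FALSE)
  }
  if (any(R < -tol | R > 1 + tol)) {
    stop("similarity entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(R - t(R))) > tol) {
    stop("similarity relation must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > tol)) {
    stop("similarity relation must be reflexive (unit diagonal)",
         call. = FALSE)
  }
  invisible(R)
}

#' Max-min transitive closure of a fuzzy similarity relation
#'
#' Computes t(R), the smallest fuzzy relation above R that is max-min
#' transitive, turning a reflexive symmetric similarity relation into a
#' fuzzy equivalence relation. Uses the fuzzy Warshall update
#' `r(i,k) <- max(r(i,k), min(r(i,j), r(j,k)))`, one in-place sweep over
#' intermediate loci (O(m^3) scalar work, vectorized per sweep).
#'
#' @param R A reflexive, symmetric numeric matrix with entries in `[0, 1]`,
#'   e.g. from [ld_similarity()].
#' @return A matrix of the same shape: the fuzzy equivalence relation t(R).
#' @export
fuzzy_closure <- function(R) {
  check_similarity(R)
  m <- nrow(R)
  for (k in seq_len(m)) {
    R <- pmax(R, outer(R[, k], R[k, ], pmin))
  }
  R
}

#' Threshold a fuzzy relation at level lambda
#'
#' The lambda-cut replaces each membership value by 1 if it is `>= lambda`
#' and 0 otherwise. Cutting a fuzzy equivalence relation at any level
#' yields a crisp equivalence relation, i.e. a partition of the loci.
#'
#' @param closure A fuzzy relation matrix (typically [fuzzy_closure()] output).
#' @param lambda Cut level in `[0, 1]`. The comparison is a plain `>=`.
#' @return A 0/1 integer matrix of the same shape.
#' @export
lambda_cut <- function(closure, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  }
  cut <- (closure >= lambda) * 1L
  storage.mode(cut) <- "integer"
  cut
}

#' Equivalence classes of a crisp relation
#'
#' @param cut A 0/1 matrix encoding an equivalence relation (a lambda-cut
#'   of a transitive closure). Reflexivity, symmetry and Boolean
#'   transitivity are verified.
#' @return A list of integer vectors partitioning `1..m`, ordered by each
#'   class's smallest member.
#' @export
cut_classes <- function(cut) {
  m <- nrow(cut)
  B <- cut != 0
  if (any(!diag(B)) || any(B != t(B))) {
    stop("cut is not reflexive/symmetric", call. = FALSE)
  }
  # Boolean transitivity: reachability in one hop adds nothing new
  if (any((B %*% B > 0) & !B)) {
    stop("cut is not transitive: not an equivalence relation", call. = FALSE)
  }
  first <- apply(B, 1L, function(r) which(r)[1L])
  unname(split(seq_len(m), factor(first, levels = sort(unique(first)))))
}

#' Pick a center locus for each equivalence class
#'
#' The center of a class is the member with the largest total LD (row sum
#' of the original similarity matrix `R`, not the closure) to the other
#' members of its class; ties go to the lower locus index. The centers
#' form the candidate tag-SNP set.
#'
#' @param classes A list of disjoint locus-index sets covering `1..m`.
#' @param R The original LD similarity matrix.
#' @param lambda The cut level used (stored for the record).
#' @param closure Optionally the closure matrix (stored for the record).
#' @param locus_ids Optional locus labels; defaults to `R`'s dimnames.
#' @return An `ld_clustering` object; see [ld_cluster()].
#' @export
class_centers <- function(classes, R, lambda = NA_real_, closure = NULL,
                          locus_ids = NULL) {
  m <- nrow(R)
  if (length(classes) == 0L || any(lengths(classes) == 0L)) {
    stop("empty class in partition", call. = FALSE)
  }
  members <- sort(unlist(classes))
  if (!identical(members, seq_len(m))) {
    stop("classes must partition the loci 1..", m, call. = FALSE)
  }
  if (is.null(locus_ids)) locus_ids <- colnames(R)
  if (is.null(locus_ids)) locus_ids <- paste0("snp", seq_len(m))
  centers <- vapply(classes, function(cl) {
    cl <- sort(cl)
    sums <- rowSums(R[cl, cl, drop = FALSE])
    cl[which.max(sums)]   # which.max returns the first max: lowest index
  }, integer(1))
  class_of <- integer(m)
  for (k in seq_along(classes)) class_of[classes[[k]]] <- k
  size_of <- lengths(classes)[class_of]
  out <- list(similarity = R,
              closure = closure,
              lambda = lambda,
              classes = lapply(classes, sort),
              centers = centers,
              class_of = class_of,
              class_size = unname(lengths(classes)),
              locus_ids = locus_ids,
              m = m)
  class(out) <- "ld_clustering"
  out
}

#' Cluster SNP loci by fuzzy LD equivalence and extract candidate tags
#'
#' The full candidate-set construction: LD similarity matrix ->
#' max-min transitive closure -> lambda-cut -> equivalence classes ->
#' class centers. The centers are the candidate tag SNPs handed to the
#' swarm optimizer; each carries its class size, the number of loci it
#' represents.
#'
#' @param hm A [haplotype_matrix()].
#' @param lambda Cut level in `[0, 1]`; higher values give more, tighter
#'   classes. Default 0.8, the conventional strong-LD threshold.
#' @return An `ld_clustering` object with components `similarity`,
#'   `closure`, `lambda`, `classes`, `centers` (locus indices),
#'   `class_of`, `class_size`, `locus_ids`, `m`. Use [tidy()] for a
#'   per-locus tibble and [glance()] for a one-row summary.
#' @examples
#' sim <- simulate_haplotypes(n_haplotypes = 40, n_blocks = 2,
#'                            loci_per_block = 3, seed = 1)
#' clus <- ld_cluster(sim$haplotypes, lambda = 0.8)
#' tidy(clus)
#' @export
ld_cluster <- function(hm, lambda = 0.8) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  R <- ld_similarity(hm)
  tr <- fuzzy_closure(R)
  cut <- lambda_cut(tr, lambda)
  classes <- cut_classes(cut)
  class_centers(classes, R, lambda = lambda, closure = tr,
                locus_ids = colnames(hm))
}

#' @export
print.ld_clustering <- function(x, ...) {
  cat(sprintf("<ld_clustering> %d loci, lambda = %s -> %d classes (candidate tags)\n",
              x$m, format(x$lambda), length(x$classes)))
  cat("class sizes:", paste(x$class_size, collapse = " "), "\n")
  cat("centers:", paste(x$locus_ids[x$centers], collapse = " "), "\n")
  invisible(x)
}
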