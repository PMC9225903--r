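#' Simulate block-structured haplotypes with known ground truth
#'
#' Emulates the haplotype-block architecture tag-SNP selection assumes: a
#' small number of founder haplotype patterns per block, high LD within a
#' block and free recombination (independent founder choice) between
#' blocks. Each haplotype picks one founder per block; every allele then
#' flips with probability `mutation_rate` and is masked missing with
#' probability `missing_rate`.
#'
#' Founder patterns within a block are distinct and segregate at every
#' locus (each within-block column is drawn uniformly over the
#' non-constant allele configurations of the founder set), so every
#' emitted locus is a genuine SNP before noise; with two founders per
#' block this makes the founders complementary and puts every
#' within-block locus pair in complete LD at zero noise. With
#' `founders_per_block = 1` the block is deliberately monomorphic (useful
#' for degenerate-case tests).
#'
#' @param n_haplotypes Number of haplotype rows (>= 2). Default 200.
#' @param n_blocks Number of LD blocks. Default 4.
#' @param loci_per_block Loci per block; a single number or one per block.
#'   Default 5.
#' @param founders_per_block Distinct founder patterns per block; must not
#'   exceed `2^loci_per_block`. Default 2.
#' @param mutation_rate Per-allele flip probability in `[0, 1)`. Default 0.
#' @param missing_rate Per-call masking probability in `[0, 1)`. Default 0.
#' @param seed Optional integer seed; fixes the whole draw.
#' @return A list with `haplotypes` (a [haplotype_matrix()] with locus ids
#'   `b<block>_s<locus>`) and `truth`, a tibble with columns `locus`,
#'   `locus_id`, `block`.
#' @examples
#' sim <- simulate_haplotypes(n_haplotypes = 50, seed = 1)
#' table(sim$truth$block)
#' @export
simulate_haplotypes <- function(n_haplotypes = 200L, n_blocks = 4L,
                                loci_per_block = 5L, founders_per_block = 2L,
                                mutation_rate = 0, missing_rate = 0,
                                seed = NULL) {
  stopifnot(n_haplotypes >= 2, n_blocks >= 1, founders_per_block >= 1,
            mutation_rate >= 0, mutation_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  L <- rep_len(as.integer(loci_per_block), n_blocks)
  if (any(L < 1L)) stop("loci_per_block must be positive", call. = FALSE)
  k <- as.integer(founders_per_block)
  if (any(k > 2^L)) {
    stop("founders_per_block = ", k, " exceeds the 2^", min(L),
         " distinct patterns of the shortest block", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n_haplotypes)

  draw_founders <- function(len) {
    if (k == 1L) {
      return(matrix(stats::rbinom(len, 1L, 0.5), nrow = 1L))
    }
    # column-wise draw over segregating configurations; redraw the rare
    # column set that leaves two founder rows identical
    repeat {
      F <- matrix(0L, k, len)
      for (j in seq_len(len)) {
        repeat {
          col <- stats::rbinom(k, 1L, 0.5)
          if (length(unique(col)) > 1L) break
        }
        F[, j] <- col
      }
      if (nrow(unique(F)) == k) return(F)
    }
  }

  cols <- purrr::map(seq_len(n_blocks), function(b) {
    F <- draw_founders(L[b])
    pick <- sample.int(nrow(F), n, replace = TRUE)
    F[pick, , drop = FALSE]
  })
  H <- do.call(cbind, cols)
  if (mutation_rate > 0) {
    flip <- matrix(stats::runif(length(H)) < mutation_rate, nrow = n)
    H[flip] <- 1L - H[flip]
  }
  if (missing_rate > 0) {
    H[matrix(stats::runif(length(H)) < missing_rate, nrow = n)] <- NA_integer_
  }
  block_of <- rep(seq_len(n_blocks), times = L)
  ids <- unlist(lapply(seq_len(n_blocks),
                       function(b) paste0("b", b, "_s", seq_len(L[b]))))
  hm <- haplotype_matrix(H, locus_ids = ids)
  list(haplotypes = hm,
       truth = tibble::tibble(locus = seq_len(sum(L)),
                              locus_id = ids,
                              block = block_of))
}

#' Within- vs between-block LD contrast
#'
#' Summarizes the LD structure of a simulated (or real, given labels)
#' haplotype matrix: the mean pairwise |D'| over locus pairs in the same
#' block and over pairs in different blocks. Used to check that the
#' simulator produces the high-within / low-between contrast the
#' clustering stage assumes.
#'
#' @param hm A [haplotype_matrix()].
#' @param truth A tibble with columns `locus` and `block` (as returned by
#'   [simulate_haplotypes()]).
#' @return A tibble with one row: `mean_within`, `mean_between` (`NA` when
#'   there is a single block), `n_within`, `n_between`.
#' @export
ld_block_contrast <- function(hm, truth) {
  R <- ld_similarity(hm)
  m <- nrow(R)
  blk <- truth$block[order(truth$locus)]
  stopifnot(length(blk) == m)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- tibble::tibble(ld = R[ut],
                          within = blk[ut[, "row"]] == blk[ut[, "col"]])
  out <- pairs |>
    dplyr::group_by(.data$within) |>
    dplyr::summarise(mean_ld = mean(.data$ld), n = dplyr::n())
  grab <- function(w, col) {
    v <- out[[col]][out$within == w]
    if (length(v) == 0L) if (col == "n") 0L else NA_real_ else v
  }
  tibble::tibble(mean_within = grab(TRUE, "mean_ld"),
                 mean_between = grab(FALSE, "mean_ld"),
                 n_within = grab(TRUE, "n"),
                 n_between = grab(FALSE, "n"))
}
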