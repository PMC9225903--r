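#' Per-locus major/minor allele frequencies
#'
#' Frequencies are computed over non-missing calls only. Code 1 is the
#' major allele by construction of the input, but the returned `f_major`
#' is simply the observed frequency of code 1 (it can drop below 0.5 when
#' missingness or recoding make it so).
#'
#' @param hm A [haplotype_matrix()].
#' @param loci Optional locus indices or locus ids; defaults to all loci.
#' @return A tibble with columns `locus`, `locus_id`, `f_major`, `f_minor`
#'   and `n_obs` (non-missing calls).
#' @export
allele_frequencies <- function(hm, loci = NULL) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  idx <- if (is.null(loci)) seq_len(ncol(hm)) else resolve_loci(hm, loci)
  n_obs <- colSums(!is.na(hm[, idx, drop = FALSE]))
  if (any(n_obs == 0L)) {
    stop("all calls missing at locus ",
         paste(colnames(hm)[idx[n_obs == 0L]], collapse = ", "),
         call. = FALSE)
  }
  f1 <- colSums(hm[, idx, drop = FALSE] == 1L, na.rm = TRUE) / n_obs
  tibble::tibble(locus = idx,
                 locus_id = colnames(hm)[idx],
                 f_major = unname(f1),
                 f_minor = 1 - unname(f1),
                 n_obs = unname(n_obs))
}

# D' on two 0/1 vectors over pairwise-complete entries; the workhorse
# behind ld_dprime() and ld_similarity().
dprime_pair <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  a <- a[ok]
  b <- b[ok]
  fA <- mean(a == 1L)
  fB <- mean(b == 1L)
  if (fA %in% c(0, 1) || fB %in% c(0, 1)) return(0)
  fAB <- mean(a == 1L & b == 1L)
  D <- fAB - fA * fB
  if (D == 0) return(0)
  d_max <- if (D > 0) min(fA * (1 - fB), (1 - fA) * fB)
           else       min(fA * fB, (1 - fA) * (1 - fB))
  min(abs(D) / d_max, 1)
}

#' Pairwise linkage disequilibrium |D'| between two loci
#'
#' Lewontin's normalized LD. With A/B the major alleles at the two loci,
#' `D = f_AB - f_A * f_B`; the normalizer is `min(f_A f_b, f_a f_B)` for
#' `D > 0` and `min(f_A f_B, f_a f_b)` for `D < 0`, and `|D| / D_max` is
#' returned so the value lies in `[0, 1]`. Haplotypes with a missing call
#' at either locus are excluded (pairwise-complete). If `D = 0`, or either
#' locus is monomorphic in the pairwise-complete subset, the LD is 0.
#'
#' @param hm A [haplotype_matrix()].
#' @param i,j Locus indices or locus ids, `i != j`.
#' @return A single number in `[0, 1]`.
#' @export
ld_dprime <- function(hm, i, j) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  i <- resolve_loci(hm, i)
  j <- resolve_loci(hm, j)
  stopifnot(length(i) == 1L, length(j) == 1L)
  if (i == j) stop("i and j must be distinct loci", call. = FALSE)
  v <- dprime_pair(hm[, i], hm[, j])
  if (is.na(v)) {
    stop(sprintf("no haplotype with both loci %s and %s observed",
                 colnames(hm)[i], colnames(hm)[j]), call. = FALSE)
  }
  v
}

#' LD fuzzy similarity matrix over all loci
#'
#' Builds the m x m fuzzy similarity relation whose (i, j) entry is
#' [ld_dprime()] between loci i and j, with a unit diagonal. The result is
#' reflexive and symmetric, hence a fuzzy similarity relation ready for
#' transitive closure.
#'
#' @param hm A [haplotype_matrix()].
#' @return A symmetric numeric matrix with unit diagonal and entries in
#'   `[0, 1]`; dimnames carry the locus ids.
#' @export
ld_similarity <- function(hm) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  m <- ncol(hm)
  af <- allele_frequencies(hm)   # errors on all-missing columns, with ids
  R <- diag(1, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      ai <- hm[, i]
      for (j in seq.int(i + 1L, m)) {
        v <- dprime_pair(ai, hm[, j])
        if (is.na(v)) {
          stop(sprintf("no haplotype with both loci %s and %s observed",
                       colnames(hm)[i], colnames(hm)[j]), call. = FALSE)
        }
        R[i, j] <- R[j, i] <- v
      }
    }
  }
  dimnames(R) <- list(colnames(hm), colnames(hm))
  R
}
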