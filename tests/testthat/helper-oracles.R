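# Fixtures and independent oracles shared across the suite. The oracles
# deliberately reimplement the quantities from first principles (plain
# counting, repeated max-min composition) so the package code is checked
# against a second, independent route.

make_hm <- function(...) {
  rows <- strsplit(c(...), "")
  ent <- do.call(rbind, lapply(rows, function(t) {
    v <- rep(NA_integer_, length(t))
    v[t == "0"] <- 0L
    v[t == "1"] <- 1L
    v
  }))
  haplotype_matrix(ent)
}

random_hm <- function(n, m, missing_rate = 0.1) {
  x <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    x[, j] <- stats::rbinom(n, 1L, stats::runif(1, 0.2, 0.8))
  }
  if (missing_rate > 0) {
    x[matrix(stats::runif(n * m) < missing_rate, n)] <- NA_integer_
  }
  # keep at least one observed call per column so loci stay scoreable
  for (j in seq_len(m)) {
    if (all(is.na(x[, j]))) x[sample.int(n, 1L), j] <- stats::rbinom(1, 1, 0.5)
  }
  haplotype_matrix(x)
}

# Lewontin D' by direct haplotype counting on the pairwise-complete subset
oracle_dprime <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  fA <- sum(a == 1) / n
  fB <- sum(b == 1) / n
  fa <- 1 - fA
  fb <- 1 - fB
  if (fA == 0 || fa == 0 || fB == 0 || fb == 0) return(0)
  fAB <- sum(a == 1 & b == 1) / n
  D <- fAB - fA * fB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(fA * fb, fa * fB) else min(fA * fB, fa * fb)
  abs(D) / dmax
}

oracle_similarity <- function(hm) {
  m <- ncol(hm)
  S <- diag(1, m)
  if (m > 1) {
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        S[i, j] <- S[j, i] <- oracle_dprime(hm[, i], hm[, j])
      }
    }
  }
  S
}

# max-min self-composition repeated to a fixpoint
oracle_closure <- function(R) {
  compose <- function(A, B) {
    m <- nrow(A)
    out <- matrix(0, m, m)
    for (i in seq_len(m)) {
      for (k in seq_len(m)) out[i, k] <- max(pmin(A[i, ], B[, k]))
    }
    out
  }
  repeat {
    R2 <- pmax(R, compose(R, R))
    if (max(abs(R2 - R)) == 0) return(R)
    R <- R2
  }
}

random_similarity <- function(m) {
  R <- matrix(stats::runif(m * m), m, m)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

# equivalence clustering with injected class sizes (consecutive blocks of
# loci, identity similarity) for exercising the optimizer in isolation
make_clus <- function(sizes) {
  m <- sum(sizes)
  classes <- unname(split(seq_len(m), rep(seq_along(sizes), sizes)))
  class_centers(classes, diag(1, m))
}

# is partition p_fine a refinement of p_coarse? (both: lists of index sets)
is_refinement <- function(p_fine, p_coarse) {
  all(vapply(p_fine, function(cl) {
    any(vapply(p_coarse, function(big) all(cl %in% big), logical(1)))
  }, logical(1)))
}

# partition as canonical membership vector for equality checks
membership <- function(classes, m) {
  v <- integer(m)
  for (k in seq_along(classes)) v[classes[[k]]] <- k
  match(v, unique(v))
}
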