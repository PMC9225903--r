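test_that("the fuzzy Warshall closure reproduces hand-computed and oracle values", {
  R <- matrix(c(1, 0.8, 0.3,
                0.8, 1, 0.6,
                0.3, 0.6, 1), 3, byrow = TRUE)
  expect_equal(fuzzy_closure(R),
               matrix(c(1, 0.8, 0.6,
                        0.8, 1, 0.6,
                        0.6, 0.6, 1), 3, byrow = TRUE))
  # already an equivalence relation: unchanged
  expect_equal(fuzzy_closure(diag(1, 4)), diag(1, 4))
})

test_that("closure is idempotent, monotone, elementwise >= R, and matches the fixpoint oracle", {
  set.seed(202)
  for (rep in 1:25) {
    R <- random_similarity(6)
    tr <- fuzzy_closure(R)
    expect_equal(tr, oracle_closure(R), tolerance = 0)
    expect_true(all(tr >= R))
    expect_equal(fuzzy_closure(tr), tr, tolerance = 0)
    # monotone: a larger relation closes to a larger closure
    R2 <- pmax(R, random_similarity(6))
    expect_true(all(fuzzy_closure(R2) >= tr))
  }
})

test_that("closure rejects non-similarity input", {
  bad <- matrix(c(1, 0.2, 0.9, 1), 2)
  expect_error(fuzzy_closure(bad), "symmetric")
  bad2 <- diag(0.5, 3)
  expect_error(fuzzy_closure(bad2), "reflexive")
  expect_error(fuzzy_closure(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("lambda-cut thresholds with >= and validates lambda", {
  tr <- matrix(c(1, 0.8, 0.6,
                 0.8, 1, 0.6,
                 0.6, 0.6, 1), 3, byrow = TRUE)
  expect_identical(lambda_cut(tr, 0.7),
                   matrix(c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L), 3))
  expect_identical(lambda_cut(tr, 0), matrix(1L, 3, 3))
  id3 <- matrix(0L, 3, 3); diag(id3) <- 1L
  expect_identical(lambda_cut(tr, 1), id3)
  expect_identical(lambda_cut(tr, 0.6), matrix(1L, 3, 3))  # >= is inclusive
  expect_error(lambda_cut(tr, 1.2), "lambda")
  expect_error(lambda_cut(tr, -0.1), "lambda")
})

test_that("equivalence classes read off the cut, ordered by smallest member", {
  tr <- matrix(c(1, 0.8, 0.6,
                 0.8, 1, 0.6,
                 0.6, 0.6, 1), 3, byrow = TRUE)
  expect_identical(cut_classes(lambda_cut(tr, 0.7)), list(c(1L, 2L), 3L))
  expect_identical(cut_classes(matrix(1L, 4, 4)), list(1:4))
  expect_identical(cut_classes(diag(4L)), list(1L, 2L, 3L, 4L))
  # a non-transitive Boolean relation is rejected
  bad <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3)
  expect_error(cut_classes(bad), "not transitive")
})

test_that("class centers maximize within-class LD sums, ties to the lower index", {
  R <- matrix(c(1.0, 0.2, 0.2,
                0.2, 1.0, 0.3,
                0.2, 0.3, 1.0), 3, byrow = TRUE)
  # within-class R-sums: 1.4, 1.5, 1.5 -> max is shared; lower index 2 wins
  clus <- class_centers(list(1:3), R)
  expect_identical(clus$centers, 2L)
  # distinct sums pick the unique maximizer
  R2 <- matrix(c(1.0, 0.4, 0.3,
                 0.4, 1.0, 0.5,
                 0.3, 0.5, 1.0), 3, byrow = TRUE)
  expect_identical(class_centers(list(1:3), R2)$centers, 2L)
  # singleton class is its own center; a 2-member class always ties, so
  # the lower index wins again
  expect_identical(class_centers(list(1L, 2:3), R2)$centers, c(1L, 2L))
  expect_error(class_centers(list(1:2), R2), "partition")
  expect_error(class_centers(list(integer(0), 1:3), R2), "empty class")
})

test_that("lambda-cut partitions are nested: lowering lambda only merges classes", {
  set.seed(303)
  sim <- simulate_haplotypes(n_haplotypes = 80, n_blocks = 3,
                             loci_per_block = 4, mutation_rate = 0.05,
                             missing_rate = 0.05, seed = 303)
  tr <- fuzzy_closure(ld_similarity(sim$haplotypes))
  grid <- seq(1, 0, by = -0.1)
  parts <- lapply(grid, function(l) cut_classes(lambda_cut(tr, l)))
  m <- ncol(sim$haplotypes)
  for (k in seq_along(parts)) {
    expect_identical(sort(unlist(parts[[k]])), 1:m)      # partition
    if (k > 1) expect_true(is_refinement(parts[[k - 1]], parts[[k]]))
  }
  expect_identical(parts[[length(parts)]], list(1:m))    # lambda = 0
})

test_that("the candidate set pipeline finds duplicated column groups", {
  # two groups of three duplicated columns: perfect LD within, weak across
  set.seed(404)
  a <- rep(c(1L, 0L), each = 4)
  b <- c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L)
  hm <- haplotype_matrix(cbind(a, a, a, b, b, b))
  clus <- ld_cluster(hm, lambda = 0.9)
  expect_identical(membership(clus$classes, 6),
                   membership(list(1:3, 4:6), 6))
  expect_length(clus$centers, 2L)
  expect_identical(ld_cluster(hm, lambda = 0)$class_size, 6L)
  expect_error(ld_cluster(hm, lambda = 1.01), "lambda")
  # every locus is in the class of exactly one center; sizes sum to m
  expect_identical(sum(clus$class_size), 6L)
  expect_identical(sort(unique(clus$class_of)), seq_along(clus$centers))
})

test_that("similarity invariants hold on random matrices with missing data", {
  set.seed(505)
  for (rep in 1:10) {
    hm <- random_hm(sample(10:30, 1), sample(2:8, 1), missing_rate = 0.1)
    S <- ld_similarity(hm)
    expect_identical(S, t(S))
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(unname(diag(S)), rep(1, ncol(hm)))
  }
})
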