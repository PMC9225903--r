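test_that("the velocity-to-probability maps have the stated shape", {
  expect_equal(flip_probability(0, "early"), 0.5)
  expect_equal(flip_probability(0, "late"), 0)
  expect_equal(flip_probability(log(3), "late"), 0.5)
  # late map is even in v; both phases monotone in |v| on each branch
  v <- seq(0.1, 6, by = 0.3)
  expect_equal(flip_probability(-v, "late"), flip_probability(v, "late"))
  expect_true(all(diff(flip_probability(v, "late")) > 0))
  expect_true(all(diff(flip_probability(v, "early")) > 0))
  expect_true(all(diff(flip_probability(-v, "early")) < 0))
  # saturation
  expect_equal(flip_probability(50, "late"), 1, tolerance = 1e-12)
  expect_equal(flip_probability(-50, "late"), 1, tolerance = 1e-12)
  expect_equal(flip_probability(50, "early"), 1, tolerance = 1e-12)
})

test_that("repair trims the worked 15-bit particle from 8 to 6 selected loci", {
  pos <- as.integer(strsplit("010100110010111", "")[[1]])
  expect_identical(which(pos == 1L), c(2L, 4L, 7L, 8L, 11L, 13L, 14L, 15L))
  set.seed(11)
  for (rep in 1:10) {
    sizes <- sample(1:9, 15, replace = TRUE)
    fixed <- repair_position(pos, 6, sizes)
    expect_identical(sum(fixed), 6L)
    expect_true(all(which(fixed == 1L) %in% which(pos == 1L)))
    # kept loci have the largest class sizes among the selected (sort oracle)
    sel <- which(pos == 1L)
    kept <- which(fixed == 1L)
    oracle <- sort(sel[order(-sizes[sel], sel)][1:6])
    expect_identical(kept, oracle)
  }
})

test_that("repair grows under-size particles by class size and is identity at size S", {
  # all-zero position: switch on the two largest classes (sizes 5 and 3)
  fixed <- repair_position(rep(0L, 4), 2, c(5, 3, 3, 1))
  expect_identical(fixed, c(1L, 1L, 0L, 0L))
  ok <- c(1L, 0L, 1L, 0L)
  expect_identical(repair_position(ok, 2, c(5, 3, 3, 1)), ok)
  expect_error(repair_position(ok, 5, c(5, 3, 3, 1)), "cannot select")
  # property: ones-count is exactly S for arbitrary inputs
  set.seed(12)
  for (rep in 1:20) {
    K <- sample(5:15, 1)
    pos <- as.integer(stats::runif(K) < 0.5)
    S <- sample(1:K, 1)
    expect_identical(sum(repair_position(pos, S, sample(1:6, K, TRUE))),
                     as.integer(S))
  }
})

test_that("fitness is the represented-locus fraction", {
  expect_equal(bpso_fitness(c(0, 0, 0), c(4, 3, 3), 10), 0)
  expect_equal(bpso_fitness(c(1, 0), c(10, 3), 10), 1)
  expect_equal(bpso_fitness(c(1, 1, 0), c(4, 3, 2), 10), 0.7)
})

test_that("velocity updates follow the phase rules", {
  cfg <- list(c1 = 2, c2 = 2, w = 1, v_max = 4)
  # at a consensus point the late-phase velocity vanishes exactly
  x <- c(1, 0, 1)
  set.seed(1)
  expect_equal(snptag:::velocity_step(c(2, -1, 3), x, x, x, cfg, "late"),
               c(0, 0, 0))
  # pure inertia: w = 1, c1 = c2 = 0 keeps the (clamped) velocity
  cfg0 <- list(c1 = 0, c2 = 0, w = 1, v_max = 4)
  expect_equal(snptag:::velocity_step(c(2, -1, 3), x, 1 - x, 1 - x, cfg0,
                                      "early"),
               c(2, -1, 3))
  expect_equal(snptag:::velocity_step(c(9, -9, 0), x, x, x, cfg0, "early"),
               c(4, -4, 0))
  # sign analysis: x = 0, pbest = gbest = 1 gives non-negative velocity
  set.seed(2)
  for (rep in 1:10) {
    v <- snptag:::velocity_step(rep(0, 5), rep(0, 5), rep(1, 5), rep(1, 5),
                                cfg, "late")
    expect_true(all(v >= 0))
  }
})

test_that("late-phase position updates only move with the velocity sign", {
  x <- c(0L, 1L, 0L, 1L)
  # v = 0: position never changes
  set.seed(3)
  for (rep in 1:5) {
    expect_identical(snptag:::position_step(x, rep(0, 4), "late"), x)
  }
  # huge |v|: flips fire almost surely in the velocity direction
  expect_identical(snptag:::position_step(x, rep(50, 4), "late"),
                   rep(1L, 4))
  expect_identical(snptag:::position_step(x, rep(-50, 4), "late"),
                   rep(0L, 4))
  # early phase, v = 0: bit is resampled fairly
  set.seed(4)
  bits <- replicate(400, snptag:::position_step(0L, 0, "early"))
  expect_gt(mean(bits), 0.4)
  expect_lt(mean(bits), 0.6)
})

test_that("swarm runs are reproducible and their incumbent fitness never decreases", {
  clus <- make_clus(c(4, 1, 3, 2, 5, 1, 2, 3))
  cfg <- swarm_config(pop_size = 10, max_iter = 40)
  a <- bpso_select(clus, 3, cfg, seed = 99)
  b <- bpso_select(clus, 3, cfg, seed = 99)
  expect_identical(a$tags, b$tags)
  expect_identical(a$history, b$history)
  expect_true(all(diff(a$history) >= 0))
  expect_identical(sum(a$position), 3L)
})

test_that("a swarm over |SI| = S candidates is forced to the unique solution", {
  clus <- make_clus(c(3, 2, 4))
  sel <- bpso_select(clus, 3, swarm_config(pop_size = 5, max_iter = 5),
                     seed = 1)
  expect_identical(sel$position, rep(1L, 3))
  expect_equal(sel$fitness, 1)
  expect_error(bpso_select(clus, 4), "lower lambda")
})

test_that("small instances reach the exhaustive optimum", {
  set.seed(21)
  sizes <- sample(1:8, 12, replace = TRUE)
  clus <- make_clus(sizes)
  best <- max(combn(12, 4, function(ix) sum(sizes[ix])))
  for (s in 1:3) {
    sel <- bpso_select(clus, 4, swarm_config(pop_size = 20, max_iter = 60),
                       seed = s)
    expect_equal(sel$fitness, best / sum(sizes))
  }
})

test_that("tag decoding maps candidate bits back to center loci", {
  sim <- simulate_haplotypes(n_haplotypes = 60, n_blocks = 3,
                             loci_per_block = 4, seed = 31)
  clus <- ld_cluster(sim$haplotypes)
  sel <- bpso_select(clus, 2, swarm_config(pop_size = 10, max_iter = 20),
                     seed = 31)
  expect_length(sel$tags, 2L)
  expect_true(all(sel$tags %in% clus$centers))
  expect_identical(sel$tag_ids, colnames(sim$haplotypes)[sel$tags])
})
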