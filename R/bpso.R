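#' Swarm configuration for the binary PSO tag selector
#'
#' The optimizer runs in two phases. In the early phase the classic BPSO
#' rules apply: inertia-weighted velocity update and sigmoid probability
#' mapping. In the late phase the inertia term is dropped (velocity is
#' driven by self- and social cognition only), the probability map is the
#' folded sigmoid that is 0 at v = 0, and positions change only in the
#' direction of the velocity sign, so particles settle onto the incumbent
#' optimum instead of skipping over it.
#'
#' @param pop_size Number of particles.
#' @param max_iter Number of iterations.
#' @param switch_fraction Fraction of `max_iter` run under the early-phase
#'   rules; the remainder uses the late-phase rules. In `(0, 1]`.
#' @param c1,c2 Cognitive and social acceleration constants.
#' @param w Inertia weight (early phase only).
#' @param v_min,v_max Velocity bounds; components are clamped to
#'   `[-v_max, v_max]` after each update and initialized uniformly on
#'   `[v_min, v_max]`.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(pop_size = 30L, max_iter = 200L,
                         switch_fraction = 0.5, c1 = 2, c2 = 2, w = 1,
                         v_min = -4, v_max = 4) {
  stopifnot(pop_size >= 1, max_iter >= 1,
            switch_fraction > 0, switch_fraction <= 1,
            c1 > 0, c2 > 0, w >= 0, v_min < v_max, v_max > 0)
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 switch_fraction = switch_fraction,
                 c1 = c1, c2 = c2, w = w,
                 v_min = v_min, v_max = v_max),
            class = "swarm_config")
}

#' Fitness of a candidate-tag selection
#'
#' The fitness of a binary position over the candidate set is the total
#' number of loci represented by the selected candidates — the sum of
#' their class sizes — divided by the total locus count `m_total`, so a
#' selection whose classes cover every locus scores 1.
#'
#' @param position 0/1 vector over the candidate tags.
#' @param class_sizes Class size of each candidate (same length).
#' @param m_total Total number of loci in the data.
#' @return A number in `[0, 1]`.
#' @export
bpso_fitness <- function(position, class_sizes, m_total) {
  stopifnot(length(position) == length(class_sizes))
  sum(class_sizes[position == 1]) / m_total
}

#' Probability map from velocity to bit-flip probability
#'
#' Early phase: the logistic sigmoid `1 / (1 + exp(-v))`, the probability
#' that the bit is set to 1. Late phase: the folded map
#' `|2 / (1 + exp(-v)) - 1|`, which is 0 at `v = 0` (the bit must not
#' change) and tends to 1 as `|v|` grows — it is the probability that the
#' bit flips in the direction of the velocity sign.
#'
#' @param v Velocity value(s).
#' @param phase `"early"` or `"late"`.
#' @return Value(s) in `[0, 1]`.
#' @export
flip_probability <- function(v, phase = c("early", "late")) {
  phase <- match.arg(phase)
  s <- 1 / (1 + exp(-v))
  if (phase == "early") s else abs(2 * s - 1)
}

#' Repair a position to exactly S selected tags
#'
#' Over-size positions keep the `n_tags` selected candidates with the
#' largest class sizes and drop the rest; under-size positions switch on
#' the unselected candidates with the largest class sizes until the count
#' is met. Ties go to the lower candidate index.
#'
#' @param position 0/1 vector over the candidate set.
#' @param n_tags Required number of selected tags (S).
#' @param class_sizes Class size per candidate.
#' @return A 0/1 vector with exactly `n_tags` ones.
#' @export
repair_position <- function(position, n_tags, class_sizes) {
  K <- length(position)
  stopifnot(length(class_sizes) == K)
  if (n_tags > K) {
    stop("cannot select ", n_tags, " tags from ", K, " candidates",
         call. = FALSE)
  }
  ones <- which(position == 1)
  k <- length(ones)
  if (k > n_tags) {
    ranked <- ones[order(-class_sizes[ones], ones)]
    position[ranked[seq.int(n_tags + 1L, k)]] <- 0L
  } else if (k < n_tags) {
    zeros <- which(position == 0)
    ranked <- zeros[order(-class_sizes[zeros], zeros)]
    position[ranked[seq_len(n_tags - k)]] <- 1L
  }
  position
}

# one velocity update for a single particle; rand()/Rand() are independent
# per-component uniforms
velocity_step <- function(v, x, pbest, gbest, cfg, phase) {
  r1 <- stats::runif(length(v))
  r2 <- stats::runif(length(v))
  v_new <- cfg$c1 * r1 * (pbest - x) + cfg$c2 * r2 * (gbest - x)
  if (phase == "early") v_new <- cfg$w * v + v_new
  pmin(pmax(v_new, -cfg$v_max), cfg$v_max)
}

# one position update for a single particle, after the velocity update
position_step <- function(x, v, phase) {
  u <- stats::runif(length(x))
  if (phase == "early") {
    return(as.integer(flip_probability(v, "early") >= u))
  }
  p <- flip_probability(v, "late")
  x_new <- x
  x_new[v < 0 & p >= u] <- 0L
  x_new[v > 0 & p >= u] <- 1L
  x_new   # v == 0: unchanged
}

#' Select a fixed-size tag-SNP set by constrained binary PSO
#'
#' Runs the phase-switched binary particle swarm over the candidate set of
#' an [ld_cluster()] result. Every particle is repaired to exactly
#' `n_tags` selected candidates after each move, the fitness is
#' [bpso_fitness()] (fraction of loci represented), and personal/global
#' bests update on strict improvement, so the incumbent fitness is
#' non-decreasing.
#'
#' @param clus An `ld_clustering` object (the candidate set).
#' @param n_tags Number of tag SNPs to select (S); must not exceed the
#'   number of candidate classes.
#' @param config A [swarm_config()].
#' @param seed Optional integer seed; fixing it makes the whole run
#'   reproducible bit-for-bit.
#' @return A `tag_selection` object with components `tags` (original locus
#'   indices, ascending), `tag_ids`, `fitness`, `history` (incumbent
#'   fitness per iteration, including the initial swarm), `position`
#'   (gbest over candidates), `n_tags`, `config`, `seed`, `clustering`.
#'   Use [tidy()] / [glance()] / [autoplot()].
#' @examples
#' sim <- simulate_haplotypes(n_haplotypes = 60, n_blocks = 3,
#'                            loci_per_block = 4, seed = 7)
#' clus <- ld_cluster(sim$haplotypes)
#' sel <- bpso_select(clus, n_tags = 3, seed = 7)
#' sel$tags
#' @export
bpso_select <- function(clus, n_tags, config = swarm_config(), seed = NULL) {
  stopifnot(inherits(clus, "ld_clustering"))
  sizes <- clus$class_size
  K <- length(sizes)
  n_tags <- as.integer(n_tags)
  if (n_tags < 1L) stop("n_tags must be at least 1", call. = FALSE)
  if (n_tags > K) {
    stop("n_tags = ", n_tags, " exceeds the ", K,
         " candidate tags; lower lambda to merge fewer classes",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- config
  pop <- cfg$pop_size

  # initial swarm: uniform random positions, repaired; velocities uniform
  # on [v_min, v_max]
  P <- matrix(0L, pop, K)
  V <- matrix(cfg$v_min + stats::runif(pop * K) * (cfg$v_max - cfg$v_min),
              pop, K)
  for (i in seq_len(pop)) {
    P[i, ] <- repair_position(as.integer(stats::runif(K) < 0.5),
                              n_tags, sizes)
  }
  fit <- apply(P, 1L, bpso_fitness, class_sizes = sizes, m_total = clus$m)
  pbest <- P
  pbest_fit <- fit
  g <- which.max(pbest_fit)
  gbest <- pbest[g, ]
  gbest_fit <- pbest_fit[g]
  history <- numeric(cfg$max_iter + 1L)
  history[1L] <- gbest_fit

  for (t in seq_len(cfg$max_iter)) {
    phase <- if ((t - 1L) < cfg$switch_fraction * cfg$max_iter) "early"
             else "late"
    for (i in seq_len(pop)) {
      V[i, ] <- velocity_step(V[i, ], P[i, ], pbest[i, ], gbest, cfg, phase)
      x <- position_step(P[i, ], V[i, ], phase)
      x <- repair_position(x, n_tags, sizes)
      P[i, ] <- x
      f <- bpso_fitness(x, sizes, clus$m)
      if (f > pbest_fit[i]) {
        pbest[i, ] <- x
        pbest_fit[i] <- f
        if (f > gbest_fit) {
          gbest <- x
          gbest_fit <- f
        }
      }
    }
    history[t + 1L] <- gbest_fit
  }

  tags <- sort(clus$centers[gbest == 1])
  out <- list(tags = tags,
              tag_ids = clus$locus_ids[tags],
              fitness = gbest_fit,
              history = history,
              position = gbest,
              n_tags = n_tags,
              config = cfg,
              seed = seed,
              clustering = clus)
  class(out) <- "tag_selection"
  out
}

#' @export
print.tag_selection <- function(x, ...) {
  cat(sprintf("<tag_selection> %d tags from %d candidates, fitness %.4f\n",
              x$n_tags, length(x$position), x$fitness))
  cat("tags:", paste(x$tag_ids, collapse = " "), "\n")
  invisible(x)
}
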