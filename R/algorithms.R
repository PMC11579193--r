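# Global search drivers. Each proposes a generation of candidate genomes:
# genetic algorithm on the GA bitstring, binary particle swarm on a [0,1]
# relaxation, surrogate-assisted proposals (random forest / gradient boosted
# trees / Gaussian process) scored by a lower-confidence-bound acquisition,
# and exhaustive enumeration.

# ---------------------------------------------------------------------------
# Genetic algorithm
# ---------------------------------------------------------------------------

#' One genetic-algorithm generation
#'
#' Produces the next generation from the current population: the
#' `elitist_num` best genomes are carried over unchanged; each remaining pair
#' of slots is filled by a mating event -- two tournaments of two (the model
#' with the better fitness wins each), single-point crossover of the parents'
#' GA bitstrings with probability `crossover_rate`, then per-child mutation:
#' with probability `mutation_rate` each of the child's bits flips
#' independently at rate `1/n_bits`. Offspring bitstrings decode by the
#' modulo rule, so every product of crossover/mutation is a valid model.
#'
#' Tournament members are drawn without replacement (four at a time); if the
#' population holds fewer than four distinct genomes they are drawn with
#' replacement instead. Uses the global RNG stream.
#'
#' @param genomes List of genomes (the current population).
#' @param fitnesses Numeric vector of their fitnesses.
#' @param space A [search_space()].
#' @param crossover_rate Probability a parent pair undergoes crossover.
#' @param elitist_num Number of best genomes carried over unchanged (must be
#'   smaller than the population).
#' @param mutation_rate Probability a new candidate undergoes mutation.
#' @return List of genomes, same length as `genomes`; the elites occupy the
#'   first positions.
#' @export
ga_step <- function(genomes, fitnesses, space, crossover_rate = 0.95,
                    elitist_num = 4L, mutation_rate = 0.95) {
  n <- length(genomes)
  if (n == 0L) stop("population is empty", call. = FALSE)
  if (length(fitnesses) != n)
    stop("'fitnesses' must match the population size", call. = FALSE)
  if (elitist_num >= n)
    stop("population (", n, ") is not larger than elitist_num (",
         elitist_num, ")", call. = FALSE)
  nbits <- space$n_bits
  ord <- order(fitnesses)
  elites <- genomes[ord[seq_len(elitist_num)]]
  n_distinct <- length(unique(vapply(genomes, genome_key, character(1))))
  bitpop <- lapply(genomes, encode_ga, space = space)

  tournament <- function(i, j)
    if (fitnesses[j] < fitnesses[i]) j else i  # tie: first drawn wins

  children <- list()
  while (length(children) < n - elitist_num) {
    idx <- if (n >= 4L && n_distinct >= 4L) sample.int(n, 4L)
           else sample.int(n, 4L, replace = TRUE)
    p1 <- bitpop[[tournament(idx[1], idx[2])]]
    p2 <- bitpop[[tournament(idx[3], idx[4])]]
    if (stats::runif(1) < crossover_rate && nbits >= 2L) {
      pt <- sample.int(nbits - 1L, 1L)
      c1 <- c(p1[seq_len(pt)], p2[seq.int(pt + 1L, nbits)])
      c2 <- c(p2[seq_len(pt)], p1[seq.int(pt + 1L, nbits)])
    } else {
      c1 <- p1; c2 <- p2
    }
    for (child in list(c1, c2)) {
      if (stats::runif(1) < mutation_rate) {
        flip <- stats::runif(nbits) < 1 / nbits
        child[flip] <- 1L - child[flip]
      }
      children[[length(children) + 1L]] <- decode_ga(child, space)
    }
  }
  c(elites, children[seq_len(n - elitist_num)])
}

# ---------------------------------------------------------------------------
# Particle swarm
# ---------------------------------------------------------------------------

#' Particle swarm velocity update
#'
#' The componentwise update
#' \deqn{V_{t+1} = w V_t + c_1 r_1 (pbest - x_t) + c_2 r_2 (best - x_t)}
#' where `best_ref` is the global or neighborhood best position.
#'
#' @param v_t Current velocity vector.
#' @param x_t Current position vector.
#' @param pbest Best position this particle has visited.
#' @param best_ref Reference best (global or local neighborhood best).
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social constants.
#' @param r1,r2 Random draws in `[0,1]` (scalar or per-component).
#' @return The new velocity vector.
#' @examples
#' pso_velocity(0.2, 0, 1, 1, w = 0.5, c1 = 0.9, c2 = 0.8, r1 = 1, r2 = 1)
#' @export
pso_velocity <- function(v_t, x_t, pbest, best_ref, w, c1, c2, r1, r2) {
  n <- length(x_t)
  lens <- c(length(v_t), length(pbest), length(best_ref))
  if (any(lens != n))
    stop("velocity/position/best vectors must have equal length",
         call. = FALSE)
  if (!all(length(r1) %in% c(1L, n), length(r2) %in% c(1L, n)))
    stop("'r1'/'r2' must be scalar or match the vector length", call. = FALSE)
  stopifnot(w >= 0, c1 >= 0, c2 >= 0)
  w * v_t + c1 * r1 * (pbest - x_t) + c2 * r2 * (best_ref - x_t)
}

#' Initialize a binary particle swarm
#'
#' Particles live in the continuous relaxation `[0,1]^n_bits` of the GA
#' bitstring space; a particle's genome is obtained by thresholding each
#' coordinate at 0.5 and decoding with the modulo rule. Initial positions are
#' uniform, initial velocities zero. Uses the global RNG stream.
#'
#' @param space A [search_space()].
#' @param swarm_size Number of particles.
#' @return An object of class `"pso_state"`.
#' @seealso [pso_step()], [pso_proposals()]
#' @export
pso_init <- function(space, swarm_size) {
  stopifnot(swarm_size >= 2L)
  n <- space$n_bits
  structure(list(
    positions = matrix(stats::runif(swarm_size * n), swarm_size, n),
    velocities = matrix(0, swarm_size, n),
    pbest_pos = NULL,
    pbest_fit = rep(Inf, swarm_size)),
    class = "pso_state")
}

#' Genomes currently proposed by a swarm
#'
#' @param state A [pso_init()] state.
#' @param space The search space.
#' @return List of genomes, one per particle (duplicates possible; the cache
#'   collapses them).
#' @export
pso_proposals <- function(state, space) {
  apply(state$positions, 1L, function(pos)
    decode_ga(as.integer(pos > 0.5), space), simplify = FALSE)
}

#' One particle-swarm step
#'
#' Given the fitnesses of the swarm's current proposals: updates each
#' particle's personal best, finds each particle's neighborhood best (the
#' best personal best among its `neighbor_num` nearest particles under the
#' `p_norm` Minkowski distance, plus itself), applies the velocity update
#' of [pso_velocity()] with fresh per-component random draws, moves
#' `x <- x + v` and clips to `[0,1]`.
#'
#' @param state A `"pso_state"`.
#' @param fitnesses Fitness of each particle's current proposal.
#' @param space The search space.
#' @param inertia,cognitive,social The `w`, `c1`, `c2` coefficients.
#' @param neighbor_num Number of nearest neighbors defining each particle's
#'   local neighborhood (must be smaller than the swarm).
#' @param p_norm Minkowski order for the neighbor distance (2 = Euclidean).
#' @return The updated `"pso_state"`.
#' @export
pso_step <- function(state, fitnesses, space, inertia = 0.5,
                     cognitive = 0.9, social = 0.8, neighbor_num = 2L,
                     p_norm = 2) {
  stopifnot(inherits(state, "pso_state"))
  m <- nrow(state$positions)
  if (length(fitnesses) != m)
    stop("'fitnesses' must have one entry per particle", call. = FALSE)
  if (neighbor_num >= m)
    stop("'neighbor_num' (", neighbor_num, ") must be smaller than the ",
         "swarm size (", m, ")", call. = FALSE)
  if (is.null(state$pbest_pos)) state$pbest_pos <- state$positions
  improved <- fitnesses < state$pbest_fit
  state$pbest_fit[improved] <- fitnesses[improved]
  state$pbest_pos[improved, ] <- state$positions[improved, , drop = FALSE]

  d <- as.matrix(stats::dist(state$positions, method = "minkowski",
                             p = p_norm))
  n <- ncol(state$positions)
  for (i in seq_len(m)) {
    nb <- order(d[i, -i])[seq_len(neighbor_num)]
    nb <- c(i, seq_len(m)[-i][nb])
    lbest <- nb[which.min(state$pbest_fit[nb])]
    state$velocities[i, ] <- pso_velocity(
      state$velocities[i, ], state$positions[i, ],
      state$pbest_pos[i, ], state$pbest_pos[lbest, ],
      w = inertia, c1 = cognitive, c2 = social,
      r1 = stats::runif(n), r2 = stats::runif(n))
  }
  state$positions <- pmin(pmax(state$positions + state$velocities, 0), 1)
  state
}

# ---------------------------------------------------------------------------
# Surrogate-assisted proposals
# ---------------------------------------------------------------------------

# strictly categorical treatment: full one-hot columns per dimension
one_hot <- function(genomes, space) {
  nc <- sum(space$option_counts)
  X <- matrix(0, length(genomes), nc)
  col0 <- c(0L, cumsum(space$option_counts))
  for (r in seq_along(genomes)) {
    g <- as.integer(genomes[[r]])
    X[r, col0[seq_along(g)] + g + 1L] <- 1
  }
  X
}

#' Surrogate-assisted candidate proposals
#'
#' Fits a regressor of fitness on one-hot-encoded genomes (the strictly
#' categorical treatment) over everything evaluated so far, then scores a
#' pool of not-yet-evaluated genomes by the lower confidence bound
#' `predicted mean - exploration_weight * predicted spread` and returns the
#' best-scoring distinct unseen genomes. The spread is the posterior SD for
#' the Gaussian process, the across-tree SD for the random forest, and 0 for
#' gradient boosted trees.
#'
#' When the space is small enough the pool is the full enumeration of unseen
#' genomes; otherwise it is a random sample of about `candidate_pool_size`.
#' If fewer unseen genomes exist than requested, all of them are returned.
#'
#' @param history A search history with at least one record.
#' @param space A [search_space()].
#' @param kind `"random_forest"`, `"gradient_boosted_trees"` or
#'   `"gaussian_process"`.
#' @param n_propose Number of genomes to return.
#' @param candidate_pool_size Size of the scored pool (at least
#'   `n_propose`).
#' @param exploration_weight Non-negative acquisition weight.
#' @return List of genomes (possibly shorter than `n_propose` when the space
#'   is nearly exhausted; empty when it is exhausted).
#' @export
surrogate_propose <- function(history, space,
                              kind = c("random_forest",
                                       "gradient_boosted_trees",
                                       "gaussian_process"),
                              n_propose, candidate_pool_size = 10L * n_propose,
                              exploration_weight = 1.0) {
  kind <- match.arg(kind)
  stopifnot(history_size(history) > 0L, n_propose >= 1L,
            candidate_pool_size >= n_propose, exploration_weight >= 0)
  recs <- history_records(history)
  gen_seen <- lapply(recs, `[[`, "genome")
  y <- vapply(recs, `[[`, numeric(1), "fitness")
  seen_keys <- vapply(gen_seen, genome_key, character(1))

  # unseen candidate pool
  card <- cardinality(space)
  if (card <= max(candidate_pool_size, 4096)) {
    all_g <- enumerate_genomes(space)
    keys <- apply(all_g, 1L, function(r) genome_key(r))
    keep <- !(keys %in% seen_keys)
    pool <- lapply(which(keep), function(r) as.integer(all_g[r, ]))
  } else {
    draws <- replicate(3L * candidate_pool_size, random_genome(space),
                       simplify = FALSE)
    keys <- vapply(draws, genome_key, character(1))
    keep <- !duplicated(keys) & !(keys %in% seen_keys)
    pool <- draws[keep]
    if (length(pool) > candidate_pool_size)
      pool <- pool[seq_len(candidate_pool_size)]
  }
  if (length(pool) == 0L) return(list())
  if (length(pool) <= n_propose) return(pool)

  X <- one_hot(gen_seen, space)
  Xp <- one_hot(pool, space)
  scored <- tryCatch(
    surrogate_score(kind, X, y, Xp, exploration_weight),
    error = function(e) rep(0, length(pool)))
  pool[order(scored)[seq_len(n_propose)]]
}

surrogate_score <- function(kind, X, y, Xp, w) {
  if (kind == "random_forest") {
    fit <- randomForest::randomForest(X, y,
                                      ntree = 200L,
                                      nodesize = 2L)
    pa <- stats::predict(fit, Xp, predict.all = TRUE)
    mu <- pa$aggregate
    sd_ <- apply(pa$individual, 1L, stats::sd)
    mu - w * sd_
  } else if (kind == "gradient_boosted_trees") {
    fit <- xgboost::xgboost(x = X, y = y, nrounds = 100L, max_depth = 3L,
                            learning_rate = 0.1, verbosity = 0)
    stats::predict(fit, Xp)
  } else {
    # center the response: gausspr's posterior mean reverts to a zero prior
    # mean away from data, which would distort the acquisition ranking on
    # raw -2LL-scale fitnesses
    ybar <- mean(y)
    fit <- NULL
    utils::capture.output(
      fit <- kernlab::gausspr(X, y - ybar, variance.model = TRUE,
                              scaled = FALSE))
    mu <- as.numeric(kernlab::predict(fit, Xp)) + ybar
    sd_ <- as.numeric(kernlab::predict(fit, Xp, type = "sdeviation"))
    mu - w * sd_
  }
}

# ---------------------------------------------------------------------------
# Exhaustive search
# ---------------------------------------------------------------------------

#' Exhaustive search over a space
#'
#' Evaluates every distinct genome exactly once, in odometer enumeration
#' order (last dimension fastest), and returns the best together with the
#' full history. Ties are broken by enumeration order. The gold standard the
#' heuristic drivers are judged against.
#'
#' @param space A [search_space()].
#' @param evaluator A `pk_evaluator`.
#' @param schedule A [penalty_schedule()].
#' @param template Optional template text for evaluators that consume
#'   rendered models.
#' @param limit Refuse to run on spaces larger than this.
#' @return List with `best` (the winning history record) and `history`.
#' @export
exhaustive_search <- function(space, evaluator,
                              schedule = penalty_schedule(),
                              template = NULL, limit = 1e6) {
  history <- new_search_history()
  eval_fn <- make_cached_evaluator(evaluator, space, history, schedule,
                                   template)
  gmat <- enumerate_genomes(space, limit = limit)
  for (r in seq_len(nrow(gmat)))
    eval_fn(as.integer(gmat[r, ]), generation = 0, phase = "exhaustive")
  list(best = history_best(history), history = history)
}
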