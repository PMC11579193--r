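test_that("GA elitism carries the best genomes over unchanged", {
  sp <- binary_space(6)
  set.seed(21)
  pop <- replicate(12, random_genome(sp), simplify = FALSE)
  fits <- sapply(pop, function(g) sum(g) + stats::runif(1, 0, 0.1))
  nxt <- ga_step(pop, fits, sp, crossover_rate = 0.9, elitist_num = 4L,
                 mutation_rate = 0.9)
  expect_length(nxt, 12L)
  elite_keys <- sapply(pop[order(fits)[1:4]], paste, collapse = ",")
  next_keys <- sapply(nxt, paste, collapse = ",")
  expect_true(all(elite_keys %in% next_keys))
  expect_error(ga_step(pop[1:3], fits[1:3], sp, elitist_num = 4L),
               "elitist_num")
})

test_that("with no crossover or mutation every child is a tournament winner", {
  sp <- binary_space(5)
  set.seed(31)
  pop <- replicate(10, random_genome(sp), simplify = FALSE)
  fits <- seq_len(10)
  pop_keys <- sapply(pop, paste, collapse = ",")
  for (rep in 1:5) {
    nxt <- ga_step(pop, fits, sp, crossover_rate = 0, elitist_num = 2L,
                   mutation_rate = 0)
    expect_true(all(sapply(nxt, paste, collapse = ",") %in% pop_keys))
  }
  # the worst genome can never win a tournament of two distinct members
  many <- replicate(40, ga_step(pop, fits, sp, crossover_rate = 0,
                                elitist_num = 2L, mutation_rate = 0),
                    simplify = FALSE)
  worst_key <- pop_keys[which.max(fits)]
  kids <- unlist(lapply(many, function(gen)
    sapply(gen[-(1:2)], paste, collapse = ",")))
  expect_false(worst_key %in% kids)
})

test_that("PSO velocity update follows the canonical equation exactly", {
  expect_equal(pso_velocity(0, 1, 1, 1, w = 0.5, c1 = 2, c2 = 2,
                            r1 = 0.5, r2 = 0.5), 0)
  expect_equal(pso_velocity(c(1, 2), c(0, 0), c(0, 0), c(0, 0),
                            w = 0.7, c1 = 0, c2 = 0, r1 = 1, r2 = 1),
               c(0.7, 1.4))
  expect_equal(pso_velocity(0.2, 0, 1, 1, w = 0.5, c1 = 0.9, c2 = 0.8,
                            r1 = 1, r2 = 1), 1.8)
  expect_error(pso_velocity(c(0, 0), 0, 1, 1, w = 1, c1 = 1, c2 = 1,
                            r1 = 1, r2 = 1), "equal length")
})

test_that("a converged swarm with equal fitness re-proposes its genomes", {
  sp <- binary_space(4)
  set.seed(41)
  st <- pso_init(sp, 5L)
  pos <- matrix(rep(c(0.8, 0.2, 0.8, 0.2), each = 5), 5, 4)
  st$positions <- pos
  st$velocities <- matrix(0, 5, 4)
  before <- pso_proposals(st, sp)
  st2 <- pso_step(st, rep(3, 5), sp, neighbor_num = 2L)
  expect_equal(st2$positions, pos)
  expect_identical(pso_proposals(st2, sp), before)
  expect_error(pso_step(st, rep(3, 5), sp, neighbor_num = 5L),
               "swarm size")
})

test_that("the swarm reference best is local to the nearest neighbors", {
  sp <- binary_space(2)
  st <- pso_init(sp, 3L)
  st$positions <- rbind(c(0, 0), c(0.1, 0), c(1, 1))
  st$velocities <- matrix(0, 3, 2)
  # particle 3 is the global best, but particle 1's single nearest neighbor
  # is particle 2
  set.seed(5)
  st2 <- pso_step(st, c(5, 1, 0), sp, inertia = 0, cognitive = 0,
                  social = 1, neighbor_num = 1L, p_norm = 2)
  # local best of particle 1 is particle 2's pbest (0.1, 0): the velocity
  # has no second component, which it would under a global-best topology
  expect_equal(st2$velocities[1, 2], 0)
  expect_gte(st2$velocities[1, 1], 0)
  # fixed seed reproduces the trajectory
  set.seed(77)
  a <- pso_step(st, c(5, 1, 0), sp)
  set.seed(77)
  b <- pso_step(st, c(5, 1, 0), sp)
  expect_equal(a, b)
})

test_that("surrogate proposals are unseen, distinct and reproducible", {
  sp <- make_space(c(2L, 2L, 2L))
  spec <- random_landscape(3, n_interactions = 2, seed = 9)
  ev <- landscape_evaluator(spec, sp)
  h <- new_search_history()
  efn <- make_cached_evaluator(ev, sp, h)
  gmat <- enumerate_genomes(sp)
  # evaluate all but one genome
  for (r in 1:7) efn(as.integer(gmat[r, ]))
  for (kind in c("random_forest", "gradient_boosted_trees",
                 "gaussian_process")) {
    set.seed(1)
    got <- surrogate_propose(h, sp, kind = kind, n_propose = 4L,
                             candidate_pool_size = 8L)
    expect_length(got, 1L)
    expect_identical(got[[1]], as.integer(gmat[8, ]))
  }
  # larger space: proposals distinct, unseen, seed-stable
  sp2 <- binary_space(8)
  ev2 <- landscape_evaluator(random_landscape(8, seed = 2), sp2)
  h2 <- new_search_history()
  efn2 <- make_cached_evaluator(ev2, sp2, h2)
  set.seed(3)
  for (k in 1:20) efn2(random_genome(sp2))
  seen <- sapply(pksearch:::history_records(h2), `[[`, "key")
  for (kind in c("random_forest", "gaussian_process")) {
    set.seed(10)
    p1 <- surrogate_propose(h2, sp2, kind = kind, n_propose = 10L)
    set.seed(10)
    p2 <- surrogate_propose(h2, sp2, kind = kind, n_propose = 10L)
    expect_identical(p1, p2)
    keys <- sapply(p1, paste, collapse = ",")
    expect_false(any(duplicated(keys)))
    expect_false(any(keys %in% seen))
  }
})

test_that("exhaustive search matches a naive brute-force oracle and tie rule", {
  sp <- binary_space(8)
  spec <- random_landscape(8, n_interactions = 6, seed = 33)
  ev <- landscape_evaluator(spec, sp)
  got <- exhaustive_search(sp, ev)
  oracle <- brute_force_landscape_min(spec)
  expect_equal(got$best$fitness, oracle$minimum)
  expect_identical(got$best$genome, oracle$bits)
  expect_equal(history_size(got$history), 256L)

  # constant fitness: first genome in enumeration order wins
  flat <- landscape_spec(3, main_effects = rep(0, 3), base = 7)
  sp3 <- binary_space(3)
  got3 <- exhaustive_search(sp3, landscape_evaluator(flat, sp3))
  expect_identical(got3$best$genome, c(0L, 0L, 0L))
  expect_equal(got3$best$ordinal, 1L)

  # cardinality-1 space
  one <- make_space(c(1L))
  ev1 <- new_evaluator_for_tests()
  got1 <- exhaustive_search(one, ev1)
  expect_identical(got1$best$genome, 0L)
})
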