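test_that("options validate up front and reject unknown or invalid fields", {
  expect_s3_class(search_options(), "search_options")
  expect_error(search_options(population_size = 1), "population_size")
  expect_error(search_options(elitist_num = 80), "elitist_num")
  expect_error(search_options(crossover_rate = 1.5), "crossover_rate")
  expect_error(search_options(nonsense = 1), "unknown option")
  # invalid options never reach the evaluator
  sp <- binary_space(4)
  ev <- new_evaluator_for_tests()
  expect_error(run_search(sp, ev, options = list(population_size = 10)),
               "search_options")
  # penalty block flows into the schedule
  o <- search_options(penalty = list(theta = 3.84))
  expect_equal(o$schedule$theta, 3.84)
})

test_that("the cache never re-evaluates and batches are order-independent", {
  sp <- binary_space(5)
  calls <- new.env(); calls$n <- 0L
  counting <- structure(list(
    fn = function(genome, space, rendered = NULL) {
      calls$n <- calls$n + 1L
      run_result(sum(genome), condition_number = 1)
    }, label = "counting", needs_render = FALSE), class = "pk_evaluator")
  h <- new_search_history()
  efn <- make_cached_evaluator(counting, sp, h)
  g1 <- c(0L, 0L, 0L, 0L, 0L); g2 <- c(1L, 0L, 0L, 0L, 0L)
  recs <- evaluate_batch(list(g1, g2, g1, g2, g1), efn, num_parallel = 4L)
  expect_length(recs, 5L)
  expect_equal(calls$n, 2L)
  expect_equal(history_size(h), 2L)
  # an all-duplicate batch adds nothing
  evaluate_batch(list(g1, g1), efn)
  expect_equal(calls$n, 2L)
  # num_parallel does not change results
  h1 <- new_search_history()
  e1 <- make_cached_evaluator(counting, sp, h1)
  evaluate_batch(list(g1, g2), e1, num_parallel = 1L)
  h32 <- new_search_history()
  e32 <- make_cached_evaluator(counting, sp, h32)
  evaluate_batch(list(g1, g2), e32, num_parallel = 32L)
  expect_equal(history_table(h1, sp), history_table(h32, sp))
})

test_that("evaluator errors become crashed records, not exceptions", {
  sp <- binary_space(3)
  flaky <- structure(list(
    fn = function(genome, space, rendered = NULL) {
      if (sum(genome) == 3L) stop("engine exploded")
      run_result(sum(genome), condition_number = 1)
    }, label = "flaky", needs_render = FALSE), class = "pk_evaluator")
  got <- exhaustive_search(sp, flaky)
  tab <- history_table(got$history, sp)
  expect_equal(sum(tab$crashed), 1L)
  expect_equal(tab$fitness[tab$crashed], penalty_schedule()$crash_value)
  expect_equal(got$best$fitness, 0)
})

test_that("exhaustive runs match the oracle and downhill phases land on schedule", {
  sp <- binary_space(10)
  spec <- random_landscape(10, seed = 55)
  ev <- landscape_evaluator(spec, sp)
  res_ex <- run_search(sp, ev, algorithm = "EX", seed = 1)
  oracle <- brute_force_landscape_min(spec)
  expect_equal(res_ex$best$fitness, oracle$minimum)
  expect_equal(res_ex$n_unique, 1024L)

  opts <- search_options(population_size = 10, num_generations = 20,
                         downhill_period = 5, elitist_num = 2)
  res <- run_search(sp, ev, algorithm = "GA", options = opts, seed = 2)
  dh <- res$trace$generation[res$trace$phase == "downhill"]
  expect_equal(dh, c(5.5, 10.5, 15.5, 20.5))
  # best fitness equals the history minimum; best-so-far is non-increasing
  expect_equal(res$best$fitness, min(res$history_table$fitness))
  expect_true(all(diff(res$trace$best_so_far) <= 0 + 1e-12))
  # unique-model ordinal marks the first attainment of the final best
  tab <- res$history_table
  expect_equal(res$unique_to_best,
               min(tab$ordinal[tab$fitness == res$best$fitness]))
})

test_that("a run is fully reproducible from (seed, options, evaluator)", {
  sp <- binary_space(8)
  ev <- landscape_evaluator(random_landscape(8, seed = 3), sp)
  opts <- search_options(population_size = 8, num_generations = 4,
                         downhill_period = 2, elitist_num = 2,
                         neighbor_num = 2)
  for (alg in c("GA", "PSO", "RF")) {
    a <- run_search(sp, ev, algorithm = alg, options = opts, seed = 9)
    b <- run_search(sp, ev, algorithm = alg, options = opts, seed = 9)
    expect_equal(a$history_table, b$history_table)
    expect_equal(a$best$fitness, b$best$fitness)
  }
  # different drivers share the same initial population at the same seed
  ga <- run_search(sp, ev, algorithm = "GA", options = opts, seed = 4)
  rf <- run_search(sp, ev, algorithm = "RF", options = opts, seed = 4)
  expect_equal(ga$history_table$genome[1:8], rf$history_table$genome[1:8])
})

test_that("results written to disk round-trip and re-render identically", {
  sp <- make_space(c(2L, 2L, 2L))
  tmpl <- "model: {D1[0]}-{D2[0]}-{D3[0]}"
  ev <- landscape_evaluator(random_landscape(3, n_interactions = 1,
                                             seed = 12), sp)
  opts <- search_options(population_size = 4, num_generations = 3,
                         downhill_period = 2, elitist_num = 1,
                         neighbor_num = 2)
  res <- run_search(sp, ev, algorithm = "GA", options = opts, seed = 6,
                    template = tmpl)
  out <- withr::local_tempdir()
  paths <- write_results(res, out)
  expect_true(all(file.exists(unlist(paths))))

  tab <- utils::read.csv(paths$history)
  expect_equal(nrow(tab), res$n_unique)
  expect_true(all(diff(tab$ordinal) > 0))
  expect_equal(min(tab$fitness), res$best$fitness)

  best_txt <- readLines(paths$best_model)
  expect_identical(paste(best_txt, collapse = "\n"),
                   render_template(tmpl, sp, res$best$genome))

  # the options snapshot re-runs to an identical search
  opts2 <- search_options(file = paths$options)
  res2 <- run_search(sp, ev, algorithm = "GA", options = opts2, seed = 6,
                     template = tmpl)
  expect_equal(res2$history_table, res$history_table)
})
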