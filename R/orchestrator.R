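# Full search orchestration: options, the generation loop alternating a
# global driver with downhill phases, unique-model accounting and reporting.

ALGORITHMS <- c("GA", "PSO", "RF", "GBRT", "GP", "EX")

#' Search options
#'
#' Assembles and validates the option set shared by all drivers plus the
#' driver-specific blocks, under the conventional field names. Defaults are
#' the standard schedule: population 80 run 32-wide in parallel, 2 niches of
#' radius 2, a downhill phase every 5 generations, 20 generations; GA
#' crossover 0.95 / 4 elites / mutation 0.95; PSO cognitive 0.9, social 0.8,
#' inertia 0.5, 2 neighbors under the Euclidean (p = 2) norm. The `penalty`
#' block takes the [penalty_schedule()] fields.
#'
#' @param ... Named options overriding the defaults. Unknown names are an
#'   error.
#' @param file Optional path of an options JSON document to load first;
#'   `...` overrides it.
#' @return A validated list of class `"search_options"`.
#' @export
search_options <- function(..., file = NULL) {
  defaults <- list(
    population_size = 80L, num_parallel = 32L, num_niches = 2L,
    niche_radius = 2L, downhill_period = 5L, num_generations = 20L,
    crossover_rate = 0.95, elitist_num = 4L, mutation_rate = 0.95,
    cognitive = 0.9, social = 0.8, inertia = 0.5, neighbor_num = 2L,
    p_norm = 2, two_bit_enabled = TRUE,
    candidate_pool_size = NULL, exploration_weight = 1.0,
    penalty = list())
  opts <- defaults
  if (!is.null(file)) {
    doc <- as.list(jsonlite::fromJSON(file, simplifyVector = TRUE))
    # snapshots may carry run metadata (algorithm, seed); options are the
    # known fields only
    opts <- utils::modifyList(opts, doc[intersect(names(doc),
                                                  names(defaults))])
  }
  extra <- list(...)
  if (length(extra) > 0) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("options must be named", call. = FALSE)
    unknown <- setdiff(names(extra), names(defaults))
    if (length(unknown) > 0)
      stop("unknown option(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    opts <- utils::modifyList(opts, extra)
  }
  if (is.null(opts$candidate_pool_size))
    opts$candidate_pool_size <- 10L * opts$population_size
  validate_options(opts)
  opts$schedule <- do.call(penalty_schedule, opts$penalty)
  class(opts) <- "search_options"
  opts
}

validate_options <- function(o) {
  chk <- function(cond, msg) if (!cond) stop("invalid options: ", msg,
                                             call. = FALSE)
  chk(o$population_size >= 2, "population_size must be at least 2")
  chk(o$num_parallel >= 1, "num_parallel must be at least 1")
  chk(o$num_niches >= 1, "num_niches must be at least 1")
  chk(o$niche_radius >= 1, "niche_radius must be at least 1")
  chk(o$downhill_period >= 1, "downhill_period must be at least 1")
  chk(o$num_generations >= 1, "num_generations must be at least 1")
  chk(o$crossover_rate >= 0 && o$crossover_rate <= 1,
      "crossover_rate must be in [0,1]")
  chk(o$mutation_rate >= 0 && o$mutation_rate <= 1,
      "mutation_rate must be in [0,1]")
  chk(o$elitist_num >= 0 && o$elitist_num < o$population_size,
      "elitist_num must be smaller than population_size")
  chk(o$neighbor_num >= 1 && o$neighbor_num < o$population_size,
      "neighbor_num must be smaller than population_size")
  chk(all(c(o$cognitive, o$social, o$inertia) >= 0),
      "PSO coefficients must be non-negative")
  chk(o$p_norm > 0, "p_norm must be positive")
  chk(o$candidate_pool_size >= o$population_size,
      "candidate_pool_size must be at least population_size")
  chk(o$exploration_weight >= 0, "exploration_weight must be non-negative")
  invisible(o)
}

#' Evaluate a batch of genomes through the shared cache
#'
#' Unseen genomes are evaluated (serially, but the reduction is
#' order-independent, so results are identical for any `num_parallel`);
#' duplicates and previously seen genomes are served from the cache and never
#' re-invoke the evaluator.
#'
#' @param genomes List of genomes.
#' @param eval_fn Caching closure from [make_cached_evaluator()].
#' @param generation,phase Provenance recorded with fresh evaluations.
#' @param num_parallel Declared parallel width (validated; evaluation is
#'   sequential, which trivially satisfies the at-most-`num_parallel`
#'   in-flight contract).
#' @return List of history records, one per input genome (in input order).
#' @export
evaluate_batch <- function(genomes, eval_fn, generation = NA_real_,
                           phase = "global", num_parallel = 1L) {
  stopifnot(num_parallel >= 1L)
  lapply(genomes, eval_fn, generation = generation, phase = phase)
}

#' Run a full model-structure search
#'
#' The main entry point: an initial random population, `num_generations`
#' generations of the chosen global driver with all evaluations cached, a
#' one-bit/two-bit downhill phase after every `downhill_period` generations
#' and once more after the final generation, and full reproducibility given
#' `(seed, options, evaluator)`. The best model found in a downhill phase is
#' injected into the next GA population (as an elite) or PSO swarm (replacing
#' the weakest particle), so the global driver restarts from the improved
#' incumbent.
#'
#' Exhaustive search (`"EX"`) evaluates every genome once in enumeration
#' order and runs no downhill phase.
#'
#' @param space A [search_space()].
#' @param evaluator A `pk_evaluator` (see [landscape_evaluator()],
#'   [external_evaluator()], [toy_pk_evaluator()]).
#' @param algorithm One of `"GA"`, `"PSO"`, `"RF"`, `"GBRT"`, `"GP"`,
#'   `"EX"`.
#' @param options A [search_options()] object.
#' @param seed Integer master seed; per-component streams (population
#'   initialization, driver operations) are derived from it, so every driver
#'   starts from the same initial population at the same seed.
#' @param template Optional template text; required by evaluators that
#'   consume rendered model files.
#' @return An object of class `"pk_search"`: a list with `best` (winning
#'   history record), `unique_to_best` (evaluation ordinal at which the final
#'   best fitness was first attained), `trace` (per-generation minima,
#'   downhill phases as fractional generations), `history` /
#'   `history_table`, and the run metadata. Methods: `print`, `summary`,
#'   `plot`.
#' @examples
#' sp <- binary_space(6)
#' ev <- landscape_evaluator(random_landscape(6, seed = 42), sp)
#' fit <- run_search(sp, ev, algorithm = "GA",
#'                   options = search_options(population_size = 10,
#'                                            num_generations = 4,
#'                                            elitist_num = 2,
#'                                            downhill_period = 2),
#'                   seed = 1)
#' fit
#' @export
run_search <- function(space, evaluator,
                       algorithm = c("GA", "PSO", "RF", "GBRT", "GP", "EX"),
                       options = search_options(), seed = 1L,
                       template = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(space, "search_space"),
            inherits(evaluator, "pk_evaluator"))
  if (!inherits(options, "search_options"))
    stop("'options' must come from search_options()", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  history <- new_search_history()
  eval_fn <- make_cached_evaluator(evaluator, space, history,
                                   options$schedule, template)
  set.seed(seed)
  streams <- sample.int(.Machine$integer.max - 1L, 2L)
  trace <- list()
  note <- function(generation, phase, recs) {
    fits <- vapply(recs, `[[`, numeric(1), "fitness")
    best <- history_best(history)
    trace[[length(trace) + 1L]] <<- data.frame(
      generation = generation, phase = phase,
      n_evaluated = length(recs),
      gen_min = if (length(fits)) min(fits) else NA_real_,
      best_so_far = best$fitness)
  }

  if (algorithm == "EX") {
    gmat <- enumerate_genomes(space)
    recs <- evaluate_batch(
      lapply(seq_len(nrow(gmat)), function(r) as.integer(gmat[r, ])),
      eval_fn, generation = 1, phase = "exhaustive",
      num_parallel = options$num_parallel)
    note(1, "exhaustive", recs)
    return(finish_search(space, history, trace, options, algorithm, seed,
                         template, t0))
  }

  # shared initial population
  set.seed(streams[1])
  pop <- replicate(options$population_size, random_genome(space),
                   simplify = FALSE)
  set.seed(streams[2])
  recs <- evaluate_batch(pop, eval_fn, generation = 1, phase = "init",
                         num_parallel = options$num_parallel)
  note(1, "init", recs)
  pop_fit <- vapply(recs, `[[`, numeric(1), "fitness")

  pso <- NULL
  if (algorithm == "PSO") {
    pso <- pso_init(space, options$population_size)
    pso$positions <- do.call(rbind, lapply(pop, function(g)
      as.numeric(encode_ga(g, space))))
  }

  run_downhill <- function(g) {
    n_before <- history_size(history)
    best <- downhill_phase(history, space, eval_fn,
                           num_niches = options$num_niches,
                           niche_radius = options$niche_radius,
                           two_bit_enabled = options$two_bit_enabled,
                           generation = g + 0.5)
    recs <- history_records(history)
    note(g + 0.5, "downhill",
         recs[seq.int(n_before + 1L, length.out = history_size(history) -
                        n_before)])
    best
  }

  inject <- function(best_rec) {
    # seed the driver's population with the downhill incumbent
    if (algorithm == "GA") {
      worst <- which.max(pop_fit)
      pop[[worst]] <<- best_rec$genome
      pop_fit[worst] <<- best_rec$fitness
    } else if (algorithm == "PSO") {
      worst <- which.max(pop_fit)
      bits <- as.numeric(encode_ga(best_rec$genome, space))
      pso$positions[worst, ] <<- bits
      pso$velocities[worst, ] <<- 0
      if (!is.null(pso$pbest_pos)) {
        pso$pbest_pos[worst, ] <<- bits
        pso$pbest_fit[worst] <<- best_rec$fitness
      }
      pop_fit[worst] <<- best_rec$fitness
    }
  }

  last_downhill_gen <- NA_real_
  if (options$num_generations > 1L && 1L %% options$downhill_period == 0L) {
    inject(run_downhill(1))
    last_downhill_gen <- 1
  }

  g <- 1L
  while (g < options$num_generations) {
    g <- g + 1L
    if (algorithm == "GA") {
      proposals <- ga_step(pop, pop_fit, space,
                           crossover_rate = options$crossover_rate,
                           elitist_num = options$elitist_num,
                           mutation_rate = options$mutation_rate)
    } else if (algorithm == "PSO") {
      pso <- pso_step(pso, pop_fit, space,
                      inertia = options$inertia,
                      cognitive = options$cognitive,
                      social = options$social,
                      neighbor_num = options$neighbor_num,
                      p_norm = options$p_norm)
      proposals <- pso_proposals(pso, space)
    } else {
      proposals <- surrogate_propose(
        history, space,
        kind = switch(algorithm,
                      RF = "random_forest",
                      GBRT = "gradient_boosted_trees",
                      GP = "gaussian_process"),
        n_propose = options$population_size,
        candidate_pool_size = options$candidate_pool_size,
        exploration_weight = options$exploration_weight)
    }
    if (length(proposals) == 0L) break  # space exhausted
    recs <- evaluate_batch(proposals, eval_fn, generation = g,
                           phase = "global",
                           num_parallel = options$num_parallel)
    note(g, algorithm, recs)
    pop <- lapply(recs, `[[`, "genome")
    pop_fit <- vapply(recs, `[[`, numeric(1), "fitness")
    if (g %% options$downhill_period == 0L) {
      inject(run_downhill(g))
      last_downhill_gen <- g
    }
  }
  if (!isTRUE(last_downhill_gen == g))
    run_downhill(g)

  finish_search(space, history, trace, options, algorithm, seed, template,
                t0)
}

finish_search <- function(space, history, trace, options, algorithm, seed,
                          template, t0) {
  best <- history_best(history)
  tab <- history_table(history, space)
  unique_to_best <- min(tab$ordinal[tab$fitness == best$fitness])
  structure(list(
    best = best,
    unique_to_best = unique_to_best,
    n_unique = history_size(history),
    trace = do.call(rbind, trace),
    history = history,
    history_table = tab,
    options = options,
    algorithm = algorithm,
    seed = seed,
    space = space,
    template = template,
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "pk_search")
}

#' @export
print.pk_search <- function(x, ...) {
  cat(sprintf("Model-structure search (%s), seed %d\n", x$algorithm,
              x$seed))
  cat(sprintf("  %s unique models evaluated (space: %s candidates)\n",
              format(x$n_unique, big.mark = ","),
              format(cardinality(x$space), big.mark = ",")))
  cat(sprintf("  best fitness %.4f (-2LL %.4f) at genome [%s]\n",
              x$best$fitness, x$best$result$minus2LL, x$best$key))
  cat(sprintf("  first attained at unique model #%d; elapsed %.1f s\n",
              x$unique_to_best, x$elapsed))
  invisible(x)
}

#' @export
summary.pk_search <- function(object, ...) {
  res <- object$best$result
  out <- list(
    algorithm = object$algorithm, seed = object$seed,
    best_fitness = object$best$fitness,
    best_minus2LL = res$minus2LL,
    penalty_total = object$best$fitness - res$minus2LL,
    n_theta = res$n_theta, n_omega = res$n_omega, n_sigma = res$n_sigma,
    best_genome = object$best$genome,
    unique_models = object$n_unique,
    unique_to_best = object$unique_to_best,
    trace = object$trace)
  class(out) <- "summary.pk_search"
  out
}

#' @export
print.summary.pk_search <- function(x, ...) {
  cat(sprintf("Search summary (%s, seed %d)\n", x$algorithm, x$seed))
  cat(sprintf("  best fitness %.4f = -2LL %.4f + penalties %.4f\n",
              x$best_fitness, x$best_minus2LL, x$penalty_total))
  cat(sprintf("  parameters: %d theta, %d omega, %d sigma\n",
              x$n_theta, x$n_omega, x$n_sigma))
  cat(sprintf("  best genome: [%s]\n", paste(x$best_genome,
                                             collapse = ",")))
  cat(sprintf("  unique models: %d (best first attained at #%d)\n",
              x$unique_models, x$unique_to_best))
  cat("\nMinimum fitness by generation (downhill phases at half steps):\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pk_search <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$generation, tr$best_so_far, type = "s",
                 xlab = "generation",
                 ylab = "minimum fitness so far",
                 main = sprintf("%s search: fitness vs generation",
                                x$algorithm), ...)
  dh <- tr$phase == "downhill"
  if (any(dh))
    graphics::points(tr$generation[dh], tr$best_so_far[dh], pch = 8)
  invisible(x)
}

#' Write a finished search to disk
#'
#' Writes the history table as CSV, the best model's rendered text (when the
#' run had a template), a plain-text log of per-generation minima and the
#' resolved options snapshot as JSON.
#'
#' @param result A `"pk_search"` object.
#' @param output_dir Directory (created if needed; must be writable).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, output_dir) {
  stopifnot(inherits(result, "pk_search"))
  ok <- dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir))
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  paths <- list(history = file.path(output_dir, "history.csv"),
                log = file.path(output_dir, "run_log.txt"),
                options = file.path(output_dir, "options.json"))
  utils::write.csv(result$history_table, paths$history, row.names = FALSE)
  tr <- result$trace
  lines <- c(sprintf("algorithm %s seed %d", result$algorithm, result$seed),
             sprintf("unique models %d; best fitness %.6f at #%d",
                     result$n_unique, result$best$fitness,
                     result$unique_to_best),
             sprintf("gen %-6s phase %-10s evaluated %4d min %12.4f best %12.4f",
                     format(tr$generation), tr$phase, tr$n_evaluated,
                     tr$gen_min, tr$best_so_far))
  writeLines(lines, paths$log)
  opts <- result$options
  opts$schedule <- NULL
  jsonlite::write_json(
    c(opts, list(algorithm = result$algorithm, seed = result$seed)),
    paths$options, auto_unbox = TRUE, pretty = TRUE, digits = NA,
    null = "null")
  if (!is.null(result$template)) {
    paths$best_model <- file.path(output_dir, "best_model.txt")
    writeLines(render_template(result$template, result$space,
                               result$best$genome),
               paths$best_model)
  }
  invisible(paths)
}
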