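# Shared cache of every unique genome evaluated during a search, with
# provenance. One record per canonical genome (the integer index vector, so
# redundant bit codes hit the same record); evaluation ordinals are strictly
# increasing and every evaluator invocation creates exactly one record.

#' Create an empty search history
#'
#' The history is the run's model cache and audit trail: a map from canonical
#' genome to its evaluation record (run result, fitness, generation, search
#' phase, evaluation ordinal). Duplicate proposals are served from the cache
#' and never re-evaluated, so the record count equals the number of unique
#' models run.
#'
#' @return An object of class `"search_history"` (environment-backed;
#'   mutated in place by [history_add()]).
#' @export
new_search_history <- function() {
  h <- new.env(parent = emptyenv())
  h$map <- new.env(parent = emptyenv())
  h$keys <- character(0)   # in ordinal order
  h$n <- 0L
  class(h) <- "search_history"
  h
}

history_has <- function(history, genome)
  !is.null(history$map[[genome_key(genome)]])

history_get <- function(history, genome)
  history$map[[genome_key(genome)]]

#' Add an evaluation record to a history
#'
#' @param history A [new_search_history()].
#' @param genome The evaluated genome.
#' @param result Its [run_result()].
#' @param fitness Its penalized fitness.
#' @param generation Generation number (may be fractional for downhill
#'   phases, e.g. `5.5`).
#' @param phase Character tag (`"init"`, `"global"`, `"downhill1"`,
#'   `"downhill2"`, ...).
#' @return The stored record (a list with `genome`, `result`, `fitness`,
#'   `generation`, `phase`, `ordinal`), invisibly.
#' @export
history_add <- function(history, genome, result, fitness,
                        generation = NA_real_, phase = "manual") {
  key <- genome_key(genome)
  if (!is.null(history$map[[key]]))
    stop("genome already evaluated: ", key, call. = FALSE)
  history$n <- history$n + 1L
  rec <- list(genome = as.integer(genome), key = key, result = result,
              fitness = fitness, generation = generation, phase = phase,
              ordinal = history$n)
  history$map[[key]] <- rec
  history$keys <- c(history$keys, key)
  invisible(rec)
}

#' Number of unique models evaluated
#' @param history A search history.
#' @return Integer count.
#' @export
history_size <- function(history) history$n

history_records <- function(history)
  lapply(history$keys, function(k) history$map[[k]])

#' Best record in a history
#'
#' Minimal fitness; ties broken by evaluation order (the earlier record
#' wins).
#'
#' @param history A search history.
#' @return A record list, or `NULL` for an empty history.
#' @export
history_best <- function(history) {
  if (history$n == 0L) return(NULL)
  recs <- history_records(history)
  fits <- vapply(recs, `[[`, numeric(1), "fitness")
  recs[[which.min(fits)]]
}

#' History as a data frame
#'
#' One row per unique model in evaluation order: ordinal, genome (comma-joined
#' option indices and minimal-binary bitstring), fitness and its components,
#' diagnostics, generation and phase.
#'
#' @param history A search history.
#' @param space The [search_space()] the genomes belong to (for the
#'   bitstring column).
#' @return A data frame.
#' @export
history_table <- function(history, space = NULL) {
  recs <- history_records(history)
  if (length(recs) == 0L)
    return(data.frame(ordinal = integer(0), genome = character(0),
                      bits = character(0), fitness = numeric(0)))
  df <- do.call(rbind, lapply(recs, function(r) {
    res <- r$result
    data.frame(
      ordinal = r$ordinal,
      genome = r$key,
      bits = if (is.null(space)) NA_character_
             else paste(encode_ga(r$genome, space), collapse = ""),
      fitness = r$fitness,
      minus2LL = res$minus2LL,
      n_theta = res$n_theta, n_omega = res$n_omega, n_sigma = res$n_sigma,
      converged = res$converged, covariance_ok = res$covariance_ok,
      correlation_ok = res$correlation_ok,
      condition_number = res$condition_number,
      crashed = res$crashed,
      generation = r$generation, phase = r$phase,
      stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Build a caching evaluation function
#'
#' Binds an evaluator, a space, a penalty schedule, an optional template and
#' a history into a single closure `f(genome, generation, phase)` that serves
#' repeats from the cache and records every fresh evaluation. This is the
#' function the global drivers and the downhill search share, so "number of
#' unique models" accounting is automatic.
#'
#' @param evaluator A `pk_evaluator` (see e.g. [landscape_evaluator()]).
#' @param space A [search_space()].
#' @param history A [new_search_history()] (mutated in place).
#' @param schedule A [penalty_schedule()].
#' @param template Optional template text, rendered per model when the
#'   evaluator needs it.
#' @return `function(genome, generation = NA, phase = "manual")` returning
#'   the history record.
#' @export
make_cached_evaluator <- function(evaluator, space, history,
                                  schedule = penalty_schedule(),
                                  template = NULL) {
  stopifnot(inherits(evaluator, "pk_evaluator"),
            inherits(space, "search_space"),
            inherits(history, "search_history"))
  if (isTRUE(evaluator$needs_render) && is.null(template))
    stop("this evaluator requires a template to render models from",
         call. = FALSE)
  function(genome, generation = NA_real_, phase = "manual") {
    hit <- history_get(history, genome)
    if (!is.null(hit)) return(hit)
    rendered <- if (!is.null(template))
      render_template(template, space, genome) else NULL
    result <- tryCatch(evaluator$fn(genome, space, rendered),
                       error = function(e) run_result(crashed = TRUE))
    if (!inherits(result, "run_result")) result <- run_result(crashed = TRUE)
    history_add(history, genome, result,
                fitness = compute_fitness(result, schedule),
                generation = generation, phase = phase)
  }
}
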