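# Local one-bit / two-bit downhill search with Hamming-distance niching.
# Works in the minimal-binary geometry: flips that decode to an out-of-range
# option (possible when a dimension's option count is not a power of two) are
# simply not neighbors.

#' One-bit neighborhood of a genome
#'
#' Every genome reachable by flipping exactly one bit of the minimal-binary
#' representation, excluding flips whose pattern does not decode to a valid
#' option. Ordered by flipped bit position (lowest first); for a fully valid
#' code of `n` bits there are exactly `n` neighbors.
#'
#' @param genome A genome (0-based option index vector).
#' @param space A [search_space()].
#' @return List of genomes.
#' @seealso [two_bit_neighbors()], [one_bit_descent()]
#' @export
one_bit_neighbors <- function(genome, space) {
  bits <- encode_ga(genome, space)
  out <- list()
  for (k in seq_along(bits)) {
    b <- bits
    b[k] <- 1L - b[k]
    g <- decode_minimal(b, space)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

#' Two-bit neighborhood of a genome
#'
#' Every genome reachable by flipping exactly two distinct bits, excluding
#' invalid decodings. For an `n`-bit fully valid code the count is
#' `n * (n - 1) / 2`. Pairs are ordered lexicographically by (lower bit,
#' higher bit). Two-bit moves are what escape the one-bit-wide ridges of
#' worse models that feature interactions create around a local minimum.
#'
#' @inheritParams one_bit_neighbors
#' @return List of genomes.
#' @export
two_bit_neighbors <- function(genome, space) {
  bits <- encode_ga(genome, space)
  n <- length(bits)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      b <- bits
      b[i] <- 1L - b[i]
      b[j] <- 1L - b[j]
      g <- decode_minimal(b, space)
      if (!is.null(g)) out[[length(out) + 1L]] <- g
    }
  }
  out
}

#' Select niche seeds for parallel downhill descents
#'
#' Walks the evaluated models in ascending fitness (ties by evaluation
#' order), greedily keeping a model as a seed only if its minimal-binary
#' Hamming distance from every already-kept seed is at least `niche_radius`
#' -- so parallel descents do not start from near-identical models and
#' collapse into the same (possibly local) minimum. Returns fewer than
#' `num_niches` seeds if the history cannot supply them.
#'
#' @param history A search history.
#' @param space A [search_space()].
#' @param num_niches Maximum number of seeds.
#' @param niche_radius Minimum pairwise Hamming distance between seeds.
#' @return List of history records (best first).
#' @export
select_niche_seeds <- function(history, space, num_niches = 2L,
                               niche_radius = 2L) {
  stopifnot(num_niches >= 1L, niche_radius >= 1L)
  recs <- history_records(history)
  if (length(recs) == 0L) return(list())
  fits <- vapply(recs, `[[`, numeric(1), "fitness")
  ords <- vapply(recs, `[[`, numeric(1), "ordinal")
  recs <- recs[order(fits, ords)]
  seeds <- list()
  for (r in recs) {
    if (length(seeds) >= num_niches) break
    ok <- all(vapply(seeds, function(s)
      hamming(s$genome, r$genome, space) >= niche_radius, logical(1)))
    if (ok) seeds[[length(seeds) + 1L]] <- r
  }
  seeds
}

#' One-bit steepest descent
#'
#' From `start`, evaluates the full one-bit neighborhood, moves to the best
#' strictly better neighbor (ties broken by lowest flipped bit position), and
#' repeats until no neighbor improves. Strict improvement plus a finite space
#' guarantees termination. All evaluations go through `eval_fn`, so they are
#' cached and counted.
#'
#' @param start Starting genome.
#' @param space A [search_space()].
#' @param eval_fn A caching evaluation closure from
#'   [make_cached_evaluator()] (or any `function(genome, generation, phase)`
#'   returning a record with `genome` and `fitness`).
#' @param generation Generation tag recorded with fresh evaluations.
#' @return The best record found (the descent's terminus).
#' @export
one_bit_descent <- function(start, space, eval_fn,
                            generation = NA_real_) {
  current <- eval_fn(start, generation, "downhill1")
  repeat {
    nbs <- one_bit_neighbors(current$genome, space)
    if (length(nbs) == 0L) return(current)
    recs <- lapply(nbs, eval_fn, generation = generation,
                   phase = "downhill1")
    fits <- vapply(recs, `[[`, numeric(1), "fitness")
    best <- which.min(fits)
    if (fits[best] < current$fitness) current <- recs[[best]]
    else return(current)
  }
}

#' Full downhill phase: niched one-bit descents plus two-bit escape
#'
#' Runs a one-bit descent from each niche seed; then, if `two_bit_enabled`,
#' evaluates the entire two-bit neighborhood of the single best result. If
#' any two-bit neighbor improves, the one-bit descent resumes from it and the
#' alternation repeats until neither a one-bit nor a two-bit move improves.
#'
#' @param history A search history (supplies the niche seeds; grows as the
#'   phase evaluates models).
#' @param space A [search_space()].
#' @param eval_fn Caching evaluation closure (see [make_cached_evaluator()]).
#' @param num_niches,niche_radius Niching controls (see
#'   [select_niche_seeds()]).
#' @param two_bit_enabled Whether to run the two-bit stage.
#' @param generation Generation tag for records created by this phase.
#' @return The best record at the end of the phase.
#' @export
downhill_phase <- function(history, space, eval_fn, num_niches = 2L,
                           niche_radius = 2L, two_bit_enabled = TRUE,
                           generation = NA_real_) {
  seeds <- select_niche_seeds(history, space, num_niches, niche_radius)
  if (length(seeds) == 0L)
    stop("downhill phase requires a non-empty history", call. = FALSE)
  results <- lapply(seeds, function(s)
    one_bit_descent(s$genome, space, eval_fn, generation))
  fits <- vapply(results, `[[`, numeric(1), "fitness")
  best <- results[[which.min(fits)]]
  if (!two_bit_enabled) return(best)
  repeat {
    nbs <- two_bit_neighbors(best$genome, space)
    if (length(nbs) == 0L) return(best)
    recs <- lapply(nbs, eval_fn, generation = generation,
                   phase = "downhill2")
    fits <- vapply(recs, `[[`, numeric(1), "fitness")
    k <- which.min(fits)
    if (fits[k] >= best$fitness) return(best)
    best <- one_bit_descent(recs[[k]]$genome, space, eval_fn, generation)
  }
}
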