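# Discrete model-structure search space: named dimensions of mutually
# exclusive options, genome codecs (GA bitstring, minimal binary) and
# Hamming geometry.

#' Construct a model-structure search space
#'
#' A search space is an ordered list of named dimensions. Each dimension is a
#' set of mutually exclusive options; a candidate model (a *genome*) picks
#' exactly one option per dimension. Options carry the text fragments that the
#' template engine substitutes into the model template (see
#' [render_template()]); for purely numerical work the fragments may be empty
#' strings.
#'
#' Each dimension with `k` options is represented in bitstring form with
#' `max(1, ceiling(log2(k)))` bits, the option index written most-significant
#' bit first. Two bit-level representations share this layout:
#'
#' * the **GA bitstring**, in which every bit pattern is a valid model --
#'   patterns whose value exceeds the option count wrap around via
#'   `value %% k` (so crossover and mutation never produce an invalid model);
#' * the **minimal binary** code used by the downhill search, in which
#'   out-of-range patterns are simply invalid (no two patterns denote the same
#'   model), keeping the code redundancy-free.
#'
#' @param dimensions A list. Each element describes one dimension and must have
#'   a `name` (unique character scalar) and `options`, a list with one element
#'   per option; every option is a character vector of text fragments
#'   (fragment `0`, `1`, ... as addressed by the template).
#' @return An object of class `"search_space"` with elements `dimensions`,
#'   `names`, `option_counts`, `widths` (bits per dimension), `offsets`
#'   (0-based bit offset of each dimension) and `n_bits`.
#' @seealso [load_search_space()], [cardinality()], [random_genome()]
#' @examples
#' sp <- search_space(list(
#'   list(name = "NCOMP", options = list("ADVAN1", "ADVAN3", "ADVAN11")),
#'   list(name = "V_WT",  options = list("", "*(WT/70)**THETA(4)"))
#' ))
#' cardinality(sp)
#' @export
search_space <- function(dimensions) {
  if (!is.list(dimensions) || length(dimensions) == 0L)
    stop("'dimensions' must be a non-empty list", call. = FALSE)
  dims <- lapply(seq_along(dimensions), function(i) {
    d <- dimensions[[i]]
    if (is.null(d$name) || !is.character(d$name) || length(d$name) != 1L ||
        !nzchar(d$name))
      stop("dimension ", i, " has no valid 'name'", call. = FALSE)
    if (is.null(d$options) || length(d$options) == 0L)
      stop("dimension '", d$name, "' has an empty option list", call. = FALSE)
    opts <- lapply(d$options, function(o) {
      o <- as.character(o)
      if (length(o) == 0L)
        stop("dimension '", d$name, "' has an option with no fragments",
             call. = FALSE)
      o
    })
    list(name = d$name, options = opts)
  })
  nms <- vapply(dims, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate dimension name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  counts <- vapply(dims, function(d) length(d$options), integer(1))
  widths <- vapply(counts, bit_width, integer(1))
  structure(
    list(dimensions = dims, names = nms, option_counts = counts,
         widths = widths, offsets = c(0L, cumsum(widths))[seq_along(widths)],
         n_bits = sum(widths)),
    class = "search_space")
}

# number of bits needed for k options (minimum 1)
bit_width <- function(k) {
  w <- 1L
  while (bitwShiftL(1L, w) < k) w <- w + 1L
  w
}

#' Load a search space from a tokens document
#'
#' The tokens document is JSON: a top-level object mapping dimension name to an
#' array of options, each option an array of text fragments (addressed from the
#' template by 0-based index). Document order defines dimension order and bit
#' concatenation order.
#'
#' @param tokens Path to a JSON file, or a JSON string.
#' @return A [search_space()].
#' @examples
#' js <- '{"NCOMP": [["one"], ["two"]], "V_WT": [[""], ["*WT"]]}'
#' sp <- load_search_space(js)
#' sp$names
#' @export
load_search_space <- function(tokens) {
  doc <- tryCatch(
    jsonlite::fromJSON(tokens, simplifyVector = FALSE),
    error = function(e) stop("tokens document failed to parse: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(doc) || is.null(names(doc)) || any(!nzchar(names(doc))))
    stop("tokens document must be an object mapping dimension names to ",
         "option arrays", call. = FALSE)
  dims <- lapply(names(doc), function(nm) {
    grp <- doc[[nm]]
    if (!is.list(grp) || length(grp) == 0L)
      stop("dimension group '", nm, "' has no options", call. = FALSE)
    opts <- lapply(seq_along(grp), function(j) {
      frag <- grp[[j]]
      if (is.list(frag)) frag <- unlist(frag, use.names = FALSE)
      if (length(frag) == 0L)
        stop("dimension group '", nm, "', option ", j,
             ": empty fragment list", call. = FALSE)
      if (!is.character(frag))
        stop("dimension group '", nm, "', option ", j,
             ": fragments must be strings", call. = FALSE)
      frag
    })
    list(name = nm, options = opts)
  })
  search_space(dims)
}

#' Number of candidate models in a search space
#'
#' The exact product of per-dimension option counts. Exact as long as the
#' product stays below 2^53 (the double-precision integer limit), which covers
#' any space one could conceivably search.
#'
#' @param space A [search_space()].
#' @return A numeric scalar count.
#' @examples
#' sp <- search_space(list(
#'   list(name = "A", options = list("a", "b", "c")),
#'   list(name = "B", options = list("x", "y"))
#' ))
#' cardinality(sp)  # 6
#' @export
cardinality <- function(space) {
  stopifnot(inherits(space, "search_space"))
  prod(as.numeric(space$option_counts))
}

assert_genome <- function(genome, space, arg = "genome") {
  if (!is.numeric(genome) || length(genome) != length(space$option_counts))
    stop("'", arg, "' must have one index per dimension (",
         length(space$option_counts), ")", call. = FALSE)
  g <- as.integer(genome)
  if (any(g < 0L) || any(g >= space$option_counts))
    stop("'", arg, "' has out-of-range option index", call. = FALSE)
  g
}

# MSB-first bit expansion of a non-negative integer at fixed width
int_to_bits <- function(v, width) {
  bits <- integer(width)
  for (b in seq_len(width)) bits[b] <- bitwAnd(bitwShiftR(v, width - b), 1L)
  bits
}

bits_to_int <- function(bits) {
  v <- 0L
  for (b in bits) v <- bitwOr(bitwShiftL(v, 1L), as.integer(b))
  v
}

#' Genome bitstring codecs
#'
#' `encode_ga()` writes a genome (0-based option index per dimension) as a
#' concatenated bitstring, each dimension's index in binary, most-significant
#' bit first, at that dimension's width. The identical layout serves both the
#' GA bitstring and the minimal binary code; the two differ only in decoding:
#'
#' * `decode_ga()` maps every pattern to a valid model, wrapping out-of-range
#'   values by `value %% option_count` (redundant patterns are thereby
#'   tolerated, so GA crossover/mutation products are never discarded);
#' * `decode_minimal()` returns `NULL` for any pattern with an out-of-range
#'   dimension value, keeping the downhill code redundancy-free.
#'
#' @param genome Integer vector of 0-based option indices, one per dimension.
#' @param bits Integer 0/1 vector of length `space$n_bits`.
#' @param space A [search_space()].
#' @return `encode_ga()`: an integer 0/1 vector. `decode_ga()`: a genome.
#'   `decode_minimal()`: a genome or `NULL`.
#' @examples
#' sp <- search_space(list(list(name = "A", options = list("a", "b", "c"))))
#' decode_ga(c(1L, 1L), sp)      # pattern 11 -> 3 %% 3 = 0
#' decode_minimal(c(1L, 1L), sp) # NULL: invalid in the minimal code
#' @export
encode_ga <- function(genome, space) {
  g <- assert_genome(genome, space)
  unlist(lapply(seq_along(g), function(i)
    int_to_bits(g[i], space$widths[i])), use.names = FALSE)
}

#' @rdname encode_ga
#' @export
decode_ga <- function(bits, space) {
  vals <- split_bits(bits, space)
  as.integer(vals %% space$option_counts)
}

#' @rdname encode_ga
#' @export
decode_minimal <- function(bits, space) {
  vals <- split_bits(bits, space)
  if (any(vals >= space$option_counts)) return(NULL)
  as.integer(vals)
}

split_bits <- function(bits, space) {
  if (length(bits) != space$n_bits)
    stop("bit vector has length ", length(bits), ", expected ",
         space$n_bits, call. = FALSE)
  if (any(!(bits %in% c(0L, 1L))))
    stop("bit vector must contain only 0/1", call. = FALSE)
  vapply(seq_along(space$widths), function(i) {
    idx <- space$offsets[i] + seq_len(space$widths[i])
    bits_to_int(bits[idx])
  }, integer(1))
}

#' Hamming distance between two genomes
#'
#' The number of differing bits in the minimal-binary representation -- the
#' geometry in which the one-/two-bit downhill search and niche radii are
#' defined.
#'
#' @param a,b Genomes (0-based option index vectors) from `space`.
#' @param space A [search_space()].
#' @return Non-negative integer.
#' @examples
#' sp <- search_space(list(
#'   list(name = "D1", options = as.list(letters[1:4])),
#'   list(name = "D2", options = as.list(letters[1:4]))
#' ))
#' hamming(c(1, 0), c(3, 0), sp)  # [0,1;0,0] vs [1,1;0,0] -> 1
#' @export
hamming <- function(a, b, space) {
  sum(encode_ga(a, space) != encode_ga(b, space))
}

#' Draw a uniform random genome
#'
#' Each dimension's option index is uniform over its options. Uses R's global
#' RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param space A [search_space()].
#' @return A genome (integer vector of 0-based indices).
#' @export
random_genome <- function(space) {
  vapply(space$option_counts, function(k) sample.int(k, 1L) - 1L, integer(1))
}

#' Enumerate every genome in a space
#'
#' Odometer order: the last dimension varies fastest. Intended for exhaustive
#' search and for brute-force verification on small spaces.
#'
#' @param space A [search_space()].
#' @param limit Refuse to enumerate more than this many genomes.
#' @return Integer matrix, one genome per row.
#' @export
enumerate_genomes <- function(space, limit = 1e6) {
  n <- cardinality(space)
  if (n > limit)
    stop("space has ", format(n, big.mark = ","),
         " genomes; enumeration limit is ", format(limit, big.mark = ","),
         call. = FALSE)
  grids <- lapply(rev(space$option_counts), function(k) seq_len(k) - 1L)
  m <- as.matrix(rev(expand.grid(grids, KEEP.OUT.ATTRS = FALSE)))
  dimnames(m) <- list(NULL, space$names)
  storage.mode(m) <- "integer"
  m
}

# canonical cache key: the integer index vector, not the bitstring, so
# redundant GA codes hit the same record
genome_key <- function(genome) paste(as.integer(genome), collapse = ",")

#' A space of n binary dimensions
#'
#' Convenience constructor for benchmark landscapes: `n_bits` dimensions of two
#' options each, so the minimal-binary code is the genome itself.
#'
#' @param n_bits Number of binary dimensions.
#' @return A [search_space()].
#' @export
binary_space <- function(n_bits) {
  search_space(lapply(seq_len(n_bits), function(i)
    list(name = paste0("BIT", i), options = list("0", "1"))))
}

#' @export
print.search_space <- function(x, ...) {
  cat("Model-structure search space:", length(x$names), "dimensions,",
      format(cardinality(x), big.mark = ","), "candidate models,",
      x$n_bits, "bits\n")
  for (i in seq_along(x$names))
    cat(sprintf("  %-12s %d option%s (%d bit%s)\n", x$names[i],
                x$option_counts[i], if (x$option_counts[i] > 1) "s" else "",
                x$widths[i], if (x$widths[i] > 1) "s" else ""))
  invisible(x)
}
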