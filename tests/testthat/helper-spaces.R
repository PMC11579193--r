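# shared fixtures: small spaces and an independent brute-force landscape
# oracle

# a space with the given option counts, options named o1, o2, ...
make_space <- function(counts, prefix = "D") {
  search_space(lapply(seq_along(counts), function(i)
    list(name = paste0(prefix, i),
         options = as.list(paste0("o", seq_len(counts[i]))))))
}

# the Table-1-style fixture: two dimensions of four options (2 bits each),
# so genomes are written [b1,b2;b3,b4]
table1_space <- function() make_space(c(4L, 4L))

bitstr <- function(genome, space) paste(encode_ga(genome, space), collapse = "")

genome_set <- function(genomes, space)
  sort(vapply(genomes, bitstr, character(1), space = space))

# a constant-fitness evaluator built from package primitives
new_evaluator_for_tests <- function(value = 42) {
  spec_env <- list(value = value)
  structure(list(
    fn = function(genome, space, rendered = NULL)
      run_result(spec_env$value, condition_number = 1),
    label = "constant", needs_render = FALSE),
    class = "pk_evaluator")
}

# independent brute-force minimum of a landscape over all bit vectors:
# re-derives the objective directly from the spec fields, without
# landscape_evaluate() or enumerate_genomes()
brute_force_landscape_min <- function(spec) {
  n <- spec$n_bits
  best <- Inf
  best_bits <- NULL
  for (v in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(v)[1:n])
    obj <- spec$base + sum(spec$main_effects * bits)
    if (nrow(spec$interactions) > 0) {
      for (r in seq_len(nrow(spec$interactions))) {
        if (bits[spec$interactions$i[r]] == spec$interactions$a[r] &&
            bits[spec$interactions$j[r]] == spec$interactions$b[r])
          obj <- obj + spec$interactions$value[r]
      }
    }
    if (obj < best) {
      best <- obj
      best_bits <- bits
    }
  }
  list(minimum = best, bits = best_bits)
}
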