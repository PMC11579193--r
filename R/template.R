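# Render candidate model definition text from a template and a genome.
# Placeholders have the form {DimensionName[k]} and select fragment k
# (0-based) of the option the genome picked in that dimension. Fragments may
# themselves contain placeholders; these are resolved recursively up to a
# fixed depth.

PLACEHOLDER_RE <- "\\{([^{}\\[\\]]+)\\[([0-9]+)\\]\\}"

#' Render a candidate model definition
#'
#' Substitutes every `{Name[k]}` placeholder in the template with fragment `k`
#' of the option selected by `genome` in dimension `Name`. Substitution is
#' pure text replacement, repeated until no placeholders remain (fragments may
#' reference other dimensions' tokens), up to `max_depth` rounds. No
#' model-language validation is attempted: syntactic correctness of the
#' rendered control stream is the template author's contract.
#'
#' @param template Character scalar, the template body (may span lines).
#' @param space A [search_space()].
#' @param genome Integer vector of 0-based option indices.
#' @param max_depth Maximum recursive substitution rounds (default 4).
#' @return Character scalar: the rendered model text, free of placeholders.
#' @examples
#' sp <- search_space(list(list(name = "COV", options = list("", "*WT"))))
#' render_template("CL=THETA(1){COV[0]}", sp, 1L)
#' @export
render_template <- function(template, space, genome, max_depth = 4L) {
  stopifnot(is.character(template), length(template) == 1L)
  g <- assert_genome(genome, space)
  text <- template
  for (round in seq_len(max_depth)) {
    m <- gregexpr(PLACEHOLDER_RE, text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(text)
    tokens <- regmatches(text, list(m))[[1]]
    repl <- vapply(tokens, function(tok) {
      parts <- regmatches(tok, regexec(PLACEHOLDER_RE, tok, perl = TRUE))[[1]]
      nm <- parts[2]; k <- as.integer(parts[3])
      di <- match(nm, space$names)
      if (is.na(di))
        stop("template references undefined dimension '", nm, "'",
             call. = FALSE)
      frags <- space$dimensions[[di]]$options[[g[di] + 1L]]
      if (k + 1L > length(frags))
        stop("fragment index ", k, " out of range for dimension '", nm,
             "' (selected option has ", length(frags), " fragment",
             if (length(frags) > 1) "s" else "", ")", call. = FALSE)
      frags[k + 1L]
    }, character(1))
    regmatches(text, list(m)) <- list(repl)
  }
  if (grepl(PLACEHOLDER_RE, text, perl = TRUE)) {
    left <- regmatches(text, regexpr(PLACEHOLDER_RE, text, perl = TRUE))
    stop("unresolved placeholder after ", max_depth,
         " substitution rounds: ", left, call. = FALSE)
  }
  text
}

#' Validate a template against a search space
#'
#' Static checks, returned as a data frame of issues rather than raised:
#' placeholders naming unknown dimensions (`error`), fragment indices out of
#' range for at least one option of the dimension (`error`), and dimensions
#' defined in the space but never referenced by the template (`warning` --
#' such dimensions multiply the search-space cardinality without changing any
#' rendered model, so distinct genomes become duplicate models).
#'
#' Only top-level placeholders are examined; references nested inside
#' fragments are exercised at render time.
#'
#' @param template Character scalar template body.
#' @param space A [search_space()].
#' @return A data frame with columns `severity` (`"error"`/`"warning"`),
#'   `dimension` and `message`; zero rows when the pair is clean.
#' @export
validate_template <- function(template, space) {
  stopifnot(is.character(template), length(template) == 1L)
  issues <- list()
  add <- function(severity, dimension, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, dimension = dimension, message = message,
      stringsAsFactors = FALSE)

  m <- gregexpr(PLACEHOLDER_RE, template, perl = TRUE)[[1]]
  seen <- character(0)
  if (m[1] != -1L) {
    for (tok in regmatches(template, list(m))[[1]]) {
      parts <- regmatches(tok, regexec(PLACEHOLDER_RE, tok, perl = TRUE))[[1]]
      nm <- parts[2]; k <- as.integer(parts[3])
      di <- match(nm, space$names)
      if (is.na(di)) {
        add("error", nm, paste0("unknown dimension in placeholder ", tok))
        next
      }
      seen <- c(seen, nm)
      nfrag <- vapply(space$dimensions[[di]]$options, length, integer(1))
      if (any(k + 1L > nfrag))
        add("error", nm,
            paste0("fragment index ", k, " out of range: option(s) ",
                   paste(which(k + 1L > nfrag), collapse = ", "),
                   " of '", nm, "' have fewer fragments"))
    }
  }
  for (nm in setdiff(space$names, unique(seen)))
    add("warning", nm,
        paste0("dimension '", nm, "' is never referenced by the template; ",
               "its options produce duplicate models"))
  if (length(issues) == 0L)
    return(data.frame(severity = character(0), dimension = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
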