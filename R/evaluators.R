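# Pluggable fitness backends. An evaluator is an object with an `fn` element:
#   fn(genome, space, rendered = NULL) -> run_result
# The orchestrator never sees what is behind `fn`: an external estimation
# engine, a synthetic landscape, or the toy pooled PK fitter.

new_evaluator <- function(fn, label, needs_render = FALSE) {
  structure(list(fn = fn, label = label, needs_render = needs_render),
            class = "pk_evaluator")
}

#' @export
print.pk_evaluator <- function(x, ...) {
  cat("Fitness evaluator:", x$label, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Synthetic epistatic landscapes
# ---------------------------------------------------------------------------

#' Synthetic epistatic fitness landscape
#'
#' A deterministic benchmark objective over bit vectors:
#' \deqn{-2\log L(g) = base + \sum_k m_k g_k + \sum_{(i,j)} v_{ij}
#'   [g_i = a_{ij}][g_j = b_{ij}]}
#' i.e. additive per-bit main effects plus pairwise epistatic interactions
#' that fire only when both bits take their required values. Interactions
#' between model features are exactly what creates the ridge-shaped local
#' minima that defeat purely local (one-bit) search, so these landscapes make
#' honest desk-scale stand-ins for a population-PK fitness surface.
#'
#' Bits listed in `parameter_bits` count as an estimated fixed effect when
#' set, so the parameter-count penalty of [penalty_schedule()] applies.
#'
#' @param n_bits Genome length in bits.
#' @param main_effects Numeric vector of length `n_bits`; contribution of each
#'   set bit.
#' @param interactions A data frame with columns `i`, `j` (distinct bit
#'   positions), `a`, `b` (required bit values, 0/1) and `value`; or `NULL`.
#' @param parameter_bits Integer positions counted into `n_theta` when set.
#' @param base Offset added to every genome.
#' @return An object of class `"landscape_spec"`.
#' @seealso [landscape_evaluate()], [random_landscape()],
#'   [make_ridge_landscape()]
#' @export
landscape_spec <- function(n_bits, main_effects = numeric(n_bits),
                           interactions = NULL,
                           parameter_bits = integer(0), base = 0) {
  stopifnot(n_bits >= 1, length(main_effects) == n_bits)
  if (!is.null(interactions)) {
    stopifnot(is.data.frame(interactions),
              all(c("i", "j", "value") %in% names(interactions)))
    if (is.null(interactions$a)) interactions$a <- 1L
    if (is.null(interactions$b)) interactions$b <- 1L
    with(interactions, stopifnot(all(i != j), all(i >= 1), all(j >= 1),
                                 all(i <= n_bits), all(j <= n_bits),
                                 all(a %in% 0:1), all(b %in% 0:1)))
  } else {
    interactions <- data.frame(i = integer(0), j = integer(0),
                               a = integer(0), b = integer(0),
                               value = numeric(0))
  }
  stopifnot(all(parameter_bits >= 1), all(parameter_bits <= n_bits))
  structure(list(n_bits = as.integer(n_bits),
                 main_effects = as.numeric(main_effects),
                 interactions = interactions,
                 parameter_bits = as.integer(parameter_bits),
                 base = as.numeric(base)),
            class = "landscape_spec")
}

#' Evaluate a bit genome on a synthetic landscape
#'
#' Pure and total: the same spec and genome always give an identical
#' [run_result()] with all diagnostics passing.
#'
#' @param spec A [landscape_spec()].
#' @param bits Integer 0/1 vector of length `spec$n_bits`.
#' @return A [run_result()].
#' @export
landscape_evaluate <- function(spec, bits) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (length(bits) != spec$n_bits)
    stop("genome has ", length(bits), " bits, landscape expects ",
         spec$n_bits, call. = FALSE)
  bits <- as.integer(bits)
  obj <- spec$base + sum(spec$main_effects * bits)
  if (nrow(spec$interactions) > 0) {
    hit <- bits[spec$interactions$i] == spec$interactions$a &
           bits[spec$interactions$j] == spec$interactions$b
    obj <- obj + sum(spec$interactions$value[hit])
  }
  run_result(minus2LL = obj,
             n_theta = sum(bits[spec$parameter_bits]),
             condition_number = 1)
}

#' Wrap a landscape as a search evaluator
#'
#' Genomes are mapped to bits through the minimal-binary code of `space`
#' before evaluation, so the landscape can sit behind any space whose total
#' bit length matches `spec$n_bits`.
#'
#' @param spec A [landscape_spec()].
#' @param space A [search_space()] with `space$n_bits == spec$n_bits`.
#' @return A `pk_evaluator`.
#' @export
landscape_evaluator <- function(spec, space) {
  stopifnot(inherits(spec, "landscape_spec"), inherits(space, "search_space"))
  if (space$n_bits != spec$n_bits)
    stop("space has ", space$n_bits, " bits, landscape expects ",
         spec$n_bits, call. = FALSE)
  new_evaluator(
    fn = function(genome, space, rendered = NULL)
      landscape_evaluate(spec, encode_ga(genome, space)),
    label = sprintf("synthetic landscape (%d bits, %d interactions)",
                    spec$n_bits, nrow(spec$interactions)))
}

#' Random epistatic benchmark landscape
#'
#' Draws an NK-style landscape: Gaussian main effects and `n_interactions`
#' pairwise interaction terms on random bit pairs with random required
#' patterns. Defaults give moderate epistasis -- enough to create off-axis
#' local minima, not so much that the surface is pure noise.
#'
#' @param n_bits Genome length.
#' @param n_interactions Number of pairwise interaction terms.
#' @param base Offset (think of it as the best model's -2LL scale).
#' @param main_sd,interaction_sd Standard deviations of effect draws.
#' @param seed Integer seed; the landscape is a pure function of its
#'   arguments.
#' @return A [landscape_spec()].
#' @export
random_landscape <- function(n_bits = 12L, n_interactions = 12L, base = 1000,
                             main_sd = 10, interaction_sd = 15, seed = 1L) {
  stopifnot(n_bits >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  main <- stats::rnorm(n_bits, 0, main_sd)
  pairs <- t(replicate(n_interactions, sample.int(n_bits, 2L)))
  inter <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      a = sample(0:1, n_interactions, replace = TRUE),
                      b = sample(0:1, n_interactions, replace = TRUE),
                      value = stats::rnorm(n_interactions, 0, interaction_sd))
  landscape_spec(n_bits, main_effects = main, interactions = inter,
                 base = base)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Construct a ridge landscape around a local-minimum trap
#'
#' Builds a landscape on which `trap` is a one-bit local minimum surrounded by
#' a one-bit-wide ridge of worse models, while `escape` -- exactly two bit
#' flips away -- is strictly better. A one-bit descent started at the trap
#' must terminate there; only the two-bit neighborhood reaches the escape.
#' This is the canonical feature-interaction failure mode of local model
#' search.
#'
#' Construction: fitness rises by `step` per bit of Hamming distance from the
#' trap, and a single pairwise interaction on the two differing bits (firing
#' at the escape's values) subtracts `3 * step / 2 + step` so the escape ends
#' `step/2` below the trap. The required ordering
#' `f(escape) < f(trap) < f(one-bit neighbors of trap)` is verified by
#' enumeration before the spec is returned; the escape is the unique global
#' minimum of the space.
#'
#' @param space A [search_space()].
#' @param trap,escape Genomes at minimal-binary Hamming distance exactly 2.
#' @param base Fitness of the trap itself.
#' @param step Ridge height per differing bit (default 10).
#' @return A [landscape_spec()].
#' @export
make_ridge_landscape <- function(space, trap, escape, base = 1000,
                                 step = 10) {
  stopifnot(inherits(space, "search_space"), step > 0)
  d <- hamming(trap, escape, space)
  if (d != 2L)
    stop("'escape' must be exactly 2 bits from 'trap' (got ", d, ")",
         call. = FALSE)
  tb <- encode_ga(trap, space)
  eb <- encode_ga(escape, space)
  diff_bits <- which(tb != eb)
  n <- space$n_bits
  # main effect of bit k being 1: +step if trap has 0, -step if trap has 1;
  # offset so f(trap) = base
  main <- ifelse(tb == 0L, step, -step)
  offset <- base + step * sum(tb)
  inter <- data.frame(i = diff_bits[1], j = diff_bits[2],
                      a = eb[diff_bits[1]], b = eb[diff_bits[2]],
                      value = -(2 * step + step / 2))
  spec <- landscape_spec(n, main_effects = main, interactions = inter,
                         base = offset)
  f <- function(bits) landscape_evaluate(spec, bits)$minus2LL
  f_trap <- f(tb); f_escape <- f(eb)
  nb1 <- lapply(seq_len(n), function(k) { b <- tb; b[k] <- 1L - b[k]; b })
  worse <- vapply(nb1, function(b) f(b) > f_trap, logical(1))
  if (!(f_escape < f_trap) || !all(worse))
    stop("ridge construction failed verification", call. = FALSE)
  spec
}

# ---------------------------------------------------------------------------
# External command adapter
# ---------------------------------------------------------------------------

#' Specification for an external fitness command
#'
#' Mirrors the workflow in which each rendered model definition is written to
#' its own working directory and executed by an external estimation engine.
#' The command template must contain the placeholder `{model_file}`; it is
#' replaced with the path of the rendered model file. The command's standard
#' output is parsed by the reference key-value parser (see Details). A
#' nonzero exit status, a timeout or unparseable output yields a crashed
#' [run_result()] -- a crash is a value, never an exception.
#'
#' The reference output dialect is flat `KEY value` lines:
#' `OBJ` (-2LL, required), `NTHETA`, `NOMEGA`, `NSIGMA` (counts, default 0),
#' `CONVERGED`, `COV_OK`, `CORR_OK` (0/1, default 1), `COND_NUM` (optional).
#' Lines `CORR i j value` may list off-diagonal parameter-estimate
#' correlations; if any magnitude exceeds `corr_threshold` the correlation
#' diagnostic fails (overriding `CORR_OK`).
#'
#' @param command Character scalar command template containing
#'   `{model_file}`.
#' @param workdir Directory under which per-model run directories are
#'   created (default [tempdir()]).
#' @param timeout Seconds before the run is declared crashed.
#' @param corr_threshold Magnitude bound for the correlation diagnostic.
#' @return An object of class `"external_run_spec"`.
#' @export
external_run_spec <- function(command, workdir = tempdir(), timeout = 60,
                              corr_threshold = 0.95) {
  stopifnot(is.character(command), length(command) == 1L)
  if (!grepl("{model_file}", command, fixed = TRUE))
    stop("'command' must contain the {model_file} placeholder", call. = FALSE)
  structure(list(command = command, workdir = workdir, timeout = timeout,
                 corr_threshold = corr_threshold),
            class = "external_run_spec")
}

#' Run one rendered model through the external command
#'
#' @param spec An [external_run_spec()].
#' @param rendered Character scalar: the rendered model definition text.
#' @param tag Optional label used for the per-model run directory.
#' @return A [run_result()]; crashed on any failure.
#' @export
external_evaluate <- function(spec, rendered, tag = "model") {
  stopifnot(inherits(spec, "external_run_spec"), is.character(rendered))
  dir <- file.path(spec$workdir,
                   paste0("run_", gsub("[^A-Za-z0-9_.-]", "_", tag)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model_file <- file.path(dir, "model.txt")
  writeLines(rendered, model_file)
  cmd <- gsub("{model_file}", shQuote(model_file), spec$command, fixed = TRUE)
  out <- tryCatch(
    suppressWarnings(system(cmd, intern = TRUE, timeout = spec$timeout)),
    error = function(e) NULL)
  status <- attr(out, "status")
  if (is.null(out) || (!is.null(status) && status != 0))
    return(run_result(crashed = TRUE))
  parse_external_output(out, spec$corr_threshold)
}

parse_external_output <- function(lines, corr_threshold = 0.95) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  kv <- list()
  corr_vals <- numeric(0)
  for (tk in toks) {
    if (length(tk) == 2L) {
      kv[[tk[1]]] <- suppressWarnings(as.numeric(tk[2]))
    } else if (length(tk) == 4L && identical(tk[1], "CORR")) {
      corr_vals <- c(corr_vals, suppressWarnings(as.numeric(tk[4])))
    }
  }
  obj <- kv[["OBJ"]]
  if (is.null(obj) || is.na(obj)) return(run_result(crashed = TRUE))
  num <- function(key, default) {
    v <- kv[[key]]
    if (is.null(v) || is.na(v)) default else v
  }
  corr_ok <- num("CORR_OK", 1) != 0
  if (length(corr_vals) > 0 && any(abs(corr_vals) > corr_threshold))
    corr_ok <- FALSE
  run_result(minus2LL = obj,
             n_theta = num("NTHETA", 0), n_omega = num("NOMEGA", 0),
             n_sigma = num("NSIGMA", 0),
             converged = num("CONVERGED", 1) != 0,
             covariance_ok = num("COV_OK", 1) != 0,
             correlation_ok = corr_ok,
             condition_number = num("COND_NUM", NA_real_))
}

#' Wrap an external command as a search evaluator
#'
#' @param spec An [external_run_spec()].
#' @return A `pk_evaluator` that requires rendered model text (so
#'   [run_search()] must be given a template).
#' @export
external_evaluator <- function(spec) {
  stopifnot(inherits(spec, "external_run_spec"))
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  new_evaluator(
    fn = function(genome, space, rendered = NULL) {
      if (is.null(rendered))
        stop("external evaluator needs rendered model text", call. = FALSE)
      counter$n <- counter$n + 1L
      external_evaluate(spec, rendered, tag = sprintf("%06d", counter$n))
    },
    label = paste("external command:", spec$command),
    needs_render = TRUE)
}

# ---------------------------------------------------------------------------
# Toy pooled PK fitter
# ---------------------------------------------------------------------------

#' Reduced pharmacokinetic model-structure space for the toy fitter
#'
#' Six binary-flavoured dimensions spanning the kinds of hypotheses a
#' population-PK search asks: compartment count, a weight power on central
#' volume, a weight power on clearance, between-subject variability on
#' clearance, between-occasion variability on clearance, and the residual
#' error model (combined additive+proportional first, proportional-only
#' second). With the default two compartment options this is a 64-model
#' space.
#'
#' @param ncomp Integer vector of compartment-count options (subset of 1:3).
#' @return A [search_space()] whose option fragments name the selected
#'   feature; [toy_pk_evaluator()] interprets them.
#' @export
toy_pk_space <- function(ncomp = c(1L, 2L)) {
  stopifnot(all(ncomp %in% 1:3), length(ncomp) >= 1)
  search_space(list(
    list(name = "NCOMP",  options = as.list(as.character(ncomp))),
    list(name = "V_WT",   options = list("none", "power")),
    list(name = "CL_WT",  options = list("none", "power")),
    list(name = "BSV_CL", options = list("none", "bsv")),
    list(name = "IOV_CL", options = list("none", "bov")),
    list(name = "RESERR", options = list("combined", "proportional"))))
}

# closed-form central-compartment bolus disposition, superposed over doses.
# p: list with CL, V1 (+ Q2, V2 for 2 cpt; + Q3, V3 for 3 cpt), each a
# per-subject vector. times/subj index observation rows; doses at dose_times.
pk_profile <- function(times, subj, dose, dose_times, ncomp, p) {
  n_sub <- length(p$CL)
  pred <- numeric(length(times))
  if (ncomp == 1L) {
    k <- p$CL / p$V1
    for (td in dose_times) {
      dt <- times - td
      on <- dt >= 0
      pred[on] <- pred[on] +
        (dose / p$V1[subj[on]]) * exp(-k[subj[on]] * dt[on])
    }
  } else if (ncomp == 2L) {
    k10 <- p$CL / p$V1; k12 <- p$Q2 / p$V1; k21 <- p$Q2 / p$V2
    s <- k10 + k12 + k21
    disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
    al <- (s + disc) / 2; be <- (s - disc) / 2
    denom <- al - be
    denom[denom == 0] <- .Machine$double.eps
    cA <- (al - k21) / denom; cB <- (k21 - be) / denom
    for (td in dose_times) {
      dt <- times - td
      on <- dt >= 0
      i <- subj[on]
      pred[on] <- pred[on] + (dose / p$V1[i]) *
        (cA[i] * exp(-al[i] * dt[on]) + cB[i] * exp(-be[i] * dt[on]))
    }
  } else {
    # 3 compartments: eigendecomposition of the micro-rate matrix per subject
    for (sidx in seq_len(n_sub)) {
      k10 <- p$CL[sidx] / p$V1[sidx]
      k12 <- p$Q2[sidx] / p$V1[sidx]; k21 <- p$Q2[sidx] / p$V2[sidx]
      k13 <- p$Q3[sidx] / p$V1[sidx]; k31 <- p$Q3[sidx] / p$V3[sidx]
      K <- matrix(c(-(k10 + k12 + k13), k21, k31,
                    k12, -k21, 0,
                    k13, 0, -k31), 3, 3, byrow = TRUE)
      ev <- eigen(K)
      w <- solve(ev$vectors, c(1, 0, 0))
      coefs <- ev$vectors[1, ] * w  # A1(t)/Dose = sum coefs * exp(lambda t)
      rows <- which(subj == sidx)
      for (td in dose_times) {
        dt <- times[rows] - td
        on <- dt >= 0
        if (!any(on)) next
        a1 <- Re(vapply(dt[on], function(tt)
          sum(coefs * exp(ev$values * tt)), complex(1)))
        pred[rows[on]] <- pred[rows[on]] + dose * a1 / p$V1[sidx]
      }
    }
  }
  pred
}

#' Simulate a synthetic concentration-time dataset
#'
#' Intravenous bolus dosing into a 1-, 2- or 3-compartment linear model with
#' covariate effects on clearance and central volume, superposed over the
#' dose schedule, with proportional and/or additive residual noise. Columns
#' follow the usual estimation-engine conventions: `ID`, `TIME`, `AMT`
#' (positive on dose rows, 0 on observations), `DV` (`NA` on dose rows),
#' `WT`, `AGE`, `SEX`.
#'
#' @param design List: `n_subjects`, `dose` (amount per bolus), `dose_times`,
#'   `sample_times` (times of observations, shared by subjects).
#' @param params List: `ncomp` (1/2/3), `CL`, `V1` and, as needed, `Q2`,
#'   `V2`, `Q3`, `V3` (typical values, positive); optional covariate effects
#'   `wt_v_power`, `wt_cl_power` (powers of weight/70 on V1 and CL),
#'   `age_v_power` (power of age/40 on V1), `sex_cl` (log-scale shift of CL
#'   for SEX == 1).
#' @param noise List: `prop` (proportional SD, e.g. 0.1 for 10%), `add`
#'   (additive SD in concentration units).
#' @param seed Integer seed (covariates and noise).
#' @return A data frame; attribute `"truth"` records the generating
#'   structure.
#' @export
toy_pk_simulate <- function(design = list(), params, noise = list(),
                            seed = 1L) {
  des <- utils::modifyList(list(n_subjects = 12L, dose = 100,
                                dose_times = 0,
                                sample_times = c(0.5, 1, 2, 4, 8, 12, 24)),
                           design)
  noi <- utils::modifyList(list(prop = 0.1, add = 0), noise)
  p <- utils::modifyList(list(wt_v_power = 0, wt_cl_power = 0,
                              age_v_power = 0, sex_cl = 0), params)
  stopifnot(p$ncomp %in% 1:3, p$CL > 0, p$V1 > 0,
            all(des$sample_times >= 0), all(des$dose_times >= 0),
            des$dose > 0)
  if (p$ncomp >= 2L) stopifnot(p$Q2 > 0, p$V2 > 0)
  if (p$ncomp == 3L) stopifnot(p$Q3 > 0, p$V3 > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ns <- des$n_subjects
  WT <- stats::runif(ns, 50, 100)
  AGE <- stats::runif(ns, 20, 80)
  SEX <- stats::rbinom(ns, 1, 0.5)
  ind <- list(CL = p$CL * (WT / 70)^p$wt_cl_power * exp(p$sex_cl * SEX),
              V1 = p$V1 * (WT / 70)^p$wt_v_power * (AGE / 40)^p$age_v_power)
  if (p$ncomp >= 2L) { ind$Q2 <- rep(p$Q2, ns); ind$V2 <- rep(p$V2, ns) }
  if (p$ncomp == 3L) { ind$Q3 <- rep(p$Q3, ns); ind$V3 <- rep(p$V3, ns) }
  nt <- length(des$sample_times)
  subj <- rep(seq_len(ns), each = nt)
  times <- rep(des$sample_times, ns)
  conc <- pk_profile(times, subj, des$dose, des$dose_times, p$ncomp, ind)
  dv <- conc * (1 + stats::rnorm(length(conc), 0, noi$prop)) +
    stats::rnorm(length(conc), 0, noi$add)
  obs <- data.frame(ID = subj, TIME = times, AMT = 0, DV = dv,
                    WT = WT[subj], AGE = AGE[subj], SEX = SEX[subj])
  dose_rows <- data.frame(ID = rep(seq_len(ns), each = length(des$dose_times)),
                          TIME = rep(des$dose_times, ns),
                          AMT = des$dose, DV = NA_real_,
                          WT = WT[rep(seq_len(ns),
                                      each = length(des$dose_times))],
                          AGE = AGE[rep(seq_len(ns),
                                        each = length(des$dose_times))],
                          SEX = SEX[rep(seq_len(ns),
                                        each = length(des$dose_times))])
  out <- rbind(dose_rows, obs)
  out <- out[order(out$ID, out$TIME, -out$AMT), ]
  rownames(out) <- NULL
  attr(out, "truth") <- p
  out
}

# map a toy-space genome to the structure it selects
toy_pk_structure <- function(genome, space) {
  g <- assert_genome(genome, space)
  pick <- function(nm) {
    di <- match(nm, space$names)
    if (is.na(di)) return(NULL)
    space$dimensions[[di]]$options[[g[di] + 1L]][1]
  }
  list(ncomp = as.integer(pick("NCOMP")),
       v_wt = identical(pick("V_WT"), "power"),
       cl_wt = identical(pick("CL_WT"), "power"),
       n_bsv = sum(identical(pick("BSV_CL"), "bsv")),
       n_iov = sum(identical(pick("IOV_CL"), "bov")),
       combined_error = identical(pick("RESERR"), "combined"))
}

#' Fit one toy PK model structure to a simulated dataset
#'
#' Desk-scale stand-in for a mixed-effect estimation run: the structural
#' model selected by the genome (compartment count, weight powers on central
#' volume and clearance) is fitted to the *pooled* data by maximising a
#' normal likelihood with the selected residual-variance model
#' (proportional-only or combined additive+proportional). There are no random
#' effects: between-subject and between-occasion variability dimensions
#' contribute estimated-parameter counts only. This preserves the search
#' space's semantics while staying far from a real nonlinear mixed-effect
#' estimator -- it is a test harness, not a population fitter.
#'
#' `minus2LL` is the pooled normal deviance at the optimum; `n_theta` counts
#' structural plus covariate fixed effects, `n_omega` the selected
#' variability terms, `n_sigma` the residual terms. A failed or non-finite
#' optimisation yields a crashed result.
#'
#' @param genome Genome over a [toy_pk_space()]-shaped space.
#' @param space The search space.
#' @param dataset A [toy_pk_simulate()] data frame.
#' @return A [run_result()].
#' @export
toy_pk_evaluate <- function(genome, space, dataset) {
  st <- toy_pk_structure(genome, space)
  obs <- dataset[dataset$AMT == 0, ]
  dose_rows <- dataset[dataset$AMT > 0, ]
  dose <- dose_rows$AMT[1]
  dose_times <- sort(unique(dose_rows$TIME))
  ids <- sort(unique(obs$ID))
  subj <- match(obs$ID, ids)
  wt_s <- obs$WT[match(ids, obs$ID)]
  ns <- length(ids)

  # crude data-driven starting values
  cmax <- tapply(obs$DV, obs$ID, max)
  v1_0 <- max(dose / stats::median(cmax), 1e-3)
  k_0 <- 0.1
  cl_0 <- max(k_0 * v1_0, 1e-3)

  theta_names <- c("lCL", "lV1")
  start <- c(lCL = log(cl_0), lV1 = log(v1_0))
  if (st$ncomp >= 2L) {
    theta_names <- c(theta_names, "lQ2", "lV2")
    start <- c(start, lQ2 = log(cl_0), lV2 = log(2 * v1_0))
  }
  if (st$ncomp == 3L) {
    theta_names <- c(theta_names, "lQ3", "lV3")
    start <- c(start, lQ3 = log(cl_0 / 2), lV3 = log(4 * v1_0))
  }
  if (st$v_wt)  start <- c(start, pow_v = 0)
  if (st$cl_wt) start <- c(start, pow_cl = 0)
  start <- c(start, lsp = log(0.2))
  if (st$combined_error)
    start <- c(start, lsa = log(max(0.05 * stats::median(obs$DV), 1e-4)))

  times <- obs$TIME; dv <- obs$DV
  objective <- function(par) {
    pv <- if ("pow_v" %in% names(par)) par[["pow_v"]] else 0
    pc <- if ("pow_cl" %in% names(par)) par[["pow_cl"]] else 0
    ind <- list(CL = exp(par[["lCL"]]) * (wt_s / 70)^pc,
                V1 = exp(par[["lV1"]]) * (wt_s / 70)^pv)
    if (st$ncomp >= 2L) {
      ind$Q2 <- rep(exp(par[["lQ2"]]), ns); ind$V2 <- rep(exp(par[["lV2"]]), ns)
    }
    if (st$ncomp == 3L) {
      ind$Q3 <- rep(exp(par[["lQ3"]]), ns); ind$V3 <- rep(exp(par[["lV3"]]), ns)
    }
    pred <- pk_profile(times, subj, dose, dose_times, st$ncomp, ind)
    pred <- pmax(pred, 1e-9)
    sp2 <- exp(2 * par[["lsp"]])
    var <- sp2 * pred^2
    if (st$combined_error) var <- var + exp(2 * par[["lsa"]])
    sum(log(2 * pi * var) + (dv - pred)^2 / var)
  }

  fit <- tryCatch(
    stats::optim(start, objective, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value))
    return(run_result(crashed = TRUE))
  n_theta <- length(theta_names) + st$v_wt + st$cl_wt
  run_result(minus2LL = fit$value,
             n_theta = n_theta,
             n_omega = st$n_bsv + st$n_iov,
             n_sigma = 1L + st$combined_error,
             converged = fit$convergence == 0,
             condition_number = 1)
}

#' Wrap the toy PK fitter as a search evaluator
#'
#' @param dataset A [toy_pk_simulate()] data frame.
#' @return A `pk_evaluator` usable with any [toy_pk_space()]-shaped space.
#' @export
toy_pk_evaluator <- function(dataset) {
  new_evaluator(
    fn = function(genome, space, rendered = NULL)
      toy_pk_evaluate(genome, space, dataset),
    label = sprintf("toy pooled PK fitter (%d observations)",
                    sum(dataset$AMT == 0)))
}
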