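# Penalized fitness: -2LL plus additive penalties for estimated parameter
# counts and failed run diagnostics.

#' Penalty schedule for the fitness function
#'
#' Additive penalty points applied on top of a run's \eqn{-2\log L} (the
#' objective function value). Defaults are the conventional schedule: 10
#' points per estimated THETA/OMEGA/SIGMA element and 100 points for each
#' failed diagnostic (non-convergence, covariance-step failure, parameter
#' correlation above bound, condition number above `condition_number_threshold`).
#' Crashed runs receive the sentinel `crash_value` outright.
#'
#' @param theta,omega,sigma Points per estimated fixed-effect, random-effect
#'   and residual-error parameter.
#' @param convergence,covariance,correlation,condition_number Points for each
#'   failed diagnostic.
#' @param condition_number_threshold Condition numbers above this incur the
#'   penalty (default 1000).
#' @param crash_value Fitness assigned to crashed/unparseable runs; must
#'   exceed any plausible fitness.
#' @return An object of class `"penalty_schedule"`.
#' @examples
#' penalty_schedule()          # the default 10/10/10/100... schedule
#' penalty_schedule(theta = 3.84)  # likelihood-ratio-test flavoured
#' @export
penalty_schedule <- function(theta = 10, omega = 10, sigma = 10,
                             convergence = 100, covariance = 100,
                             correlation = 100, condition_number = 100,
                             condition_number_threshold = 1000,
                             crash_value = 99999999) {
  vals <- c(theta = theta, omega = omega, sigma = sigma,
            convergence = convergence, covariance = covariance,
            correlation = correlation, condition_number = condition_number)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all penalties must be finite and non-negative", call. = FALSE)
  if (!is.finite(condition_number_threshold) || condition_number_threshold <= 0)
    stop("'condition_number_threshold' must be positive", call. = FALSE)
  structure(c(as.list(vals),
              list(condition_number_threshold = condition_number_threshold,
                   crash_value = crash_value)),
            class = "penalty_schedule")
}

#' Outcome of one candidate-model evaluation
#'
#' The parsed result of running one candidate model: objective function value,
#' estimated-parameter counts and diagnostic flags. Evaluators that cannot
#' produce a result (nonzero exit, timeout, unparseable output, failed fit)
#' return `crashed = TRUE`; downstream the run gets the schedule's crash
#' sentinel as fitness.
#'
#' If the covariance step did not run, set `covariance_ok = FALSE`,
#' `correlation_ok = FALSE` and leave `condition_number` as `NA`: all three
#' diagnostic penalties then apply (the conservative reading).
#'
#' @param minus2LL Objective function value (\eqn{-2\log L}); `NA` on crash.
#' @param n_theta,n_omega,n_sigma Counts of *estimated* parameters (fixed
#'   effects, random-effect variances, residual-error terms).
#' @param converged,covariance_ok,correlation_ok Diagnostic flags.
#' @param condition_number Condition number of the estimation covariance
#'   (`NA` when unavailable).
#' @param crashed Whether the run failed outright.
#' @return An object of class `"run_result"`.
#' @export
run_result <- function(minus2LL = NA_real_, n_theta = 0L, n_omega = 0L,
                       n_sigma = 0L, converged = TRUE, covariance_ok = TRUE,
                       correlation_ok = TRUE, condition_number = NA_real_,
                       crashed = FALSE) {
  counts <- c(n_theta, n_omega, n_sigma)
  if (any(counts < 0)) stop("parameter counts must be non-negative",
                            call. = FALSE)
  if (!crashed && !is.finite(minus2LL))
    stop("'minus2LL' must be finite unless the run crashed", call. = FALSE)
  structure(list(minus2LL = as.numeric(minus2LL),
                 n_theta = as.integer(n_theta),
                 n_omega = as.integer(n_omega),
                 n_sigma = as.integer(n_sigma),
                 converged = isTRUE(converged),
                 covariance_ok = isTRUE(covariance_ok),
                 correlation_ok = isTRUE(correlation_ok),
                 condition_number = as.numeric(condition_number),
                 crashed = isTRUE(crashed)),
            class = "run_result")
}

#' Penalized fitness of a run
#'
#' The quantity minimized over the search space:
#' \deqn{F = -2\log L + p_\theta n_\theta + p_\omega n_\omega + p_\sigma
#'   n_\sigma + \sum \textrm{diagnostic penalties}.}
#' The condition-number penalty applies when the condition number exceeds the
#' threshold, and also when it is absent (`NA`) -- so a run whose covariance
#' step never produced one is penalized. Crashed runs return `crash_value`.
#' Total function: never raises.
#'
#' @param result A [run_result()].
#' @param schedule A [penalty_schedule()].
#' @return Numeric fitness.
#' @examples
#' compute_fitness(run_result(8041.271, n_theta = 7, n_omega = 7, n_sigma = 2,
#'                            condition_number = 50), penalty_schedule())
#' @export
compute_fitness <- function(result, schedule = penalty_schedule()) {
  stopifnot(inherits(result, "run_result"),
            inherits(schedule, "penalty_schedule"))
  if (result$crashed) return(schedule$crash_value)
  f <- result$minus2LL +
    schedule$theta * result$n_theta +
    schedule$omega * result$n_omega +
    schedule$sigma * result$n_sigma
  if (!result$converged)      f <- f + schedule$convergence
  if (!result$covariance_ok)  f <- f + schedule$covariance
  if (!result$correlation_ok) f <- f + schedule$correlation
  cn <- result$condition_number
  if (is.na(cn) || cn > schedule$condition_number_threshold)
    f <- f + schedule$condition_number
  f
}

#' @export
print.penalty_schedule <- function(x, ...) {
  cat("Penalty schedule (points added to -2LL):\n")
  cat(sprintf("  per THETA/OMEGA/SIGMA: %g / %g / %g\n",
              x$theta, x$omega, x$sigma))
  cat(sprintf("  convergence %g, covariance %g, correlation %g,\n",
              x$convergence, x$covariance, x$correlation))
  cat(sprintf("  condition number > %g: %g; crash sentinel %g\n",
              x$condition_number_threshold, x$condition_number,
              x$crash_value))
  invisible(x)
}

#' @export
print.run_result <- function(x, ...) {
  if (x$crashed) {
    cat("Run result: crashed\n")
  } else {
    cat(sprintf(paste0("Run result: -2LL %.3f; %d theta, %d omega, %d sigma; ",
                       "converged %s, covariance %s, correlation %s, ",
                       "condition number %s\n"),
                x$minus2LL, x$n_theta, x$n_omega, x$n_sigma,
                x$converged, x$covariance_ok, x$correlation_ok,
                if (is.na(x$condition_number)) "NA"
                else format(x$condition_number)))
  }
  invisible(x)
}
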