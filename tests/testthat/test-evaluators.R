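test_that("landscape evaluation is the exact sum of main effects and interactions", {
  spec <- landscape_spec(2, main_effects = c(3, 5),
                         interactions = data.frame(i = 1, j = 2,
                                                   value = -50),
                         base = 100)
  f <- function(bits) landscape_evaluate(spec, bits)$minus2LL
  expect_equal(f(c(0, 0)), 100)
  expect_equal(f(c(1, 0)), 103)
  expect_equal(f(c(0, 1)), 105)
  expect_equal(f(c(1, 1)), 100 + 3 + 5 - 50)
  # pure function: identical results on repeat
  expect_identical(landscape_evaluate(spec, c(1, 1)),
                   landscape_evaluate(spec, c(1, 1)))
  expect_error(landscape_evaluate(spec, c(1, 1, 1)), "bits")
  # parameter bits feed the theta count
  spec2 <- landscape_spec(3, parameter_bits = c(2L, 3L), base = 10)
  expect_equal(landscape_evaluate(spec2, c(1, 1, 1))$n_theta, 2L)
  expect_equal(landscape_evaluate(spec2, c(1, 0, 0))$n_theta, 0L)
})

test_that("ridge construction holds for arbitrary distance-2 pairs", {
  set.seed(61)
  for (trial in 1:12) {
    n_dims <- sample(2:4, 1)
    sp <- make_space(sample(c(2L, 2L, 4L), n_dims, replace = TRUE))
    if (sp$n_bits > 16) next
    trap <- random_genome(sp)
    # flip two random bits so that the result is still a valid genome
    repeat {
      bits <- encode_ga(trap, sp)
      flip <- sample(length(bits), 2L)
      bits[flip] <- 1L - bits[flip]
      esc <- decode_minimal(bits, sp)
      if (!is.null(esc) && hamming(trap, esc, sp) == 2L) break
    }
    spec <- make_ridge_landscape(sp, trap, esc)
    f <- function(g) landscape_evaluate(spec, encode_ga(g, sp))$minus2LL
    expect_lt(f(esc), f(trap))
    for (nb in one_bit_neighbors(trap, sp)) expect_gt(f(nb), f(trap))
    # the escape is the exhaustive minimum of the whole space
    gmat <- enumerate_genomes(sp)
    fits <- apply(gmat, 1, function(r) f(as.integer(r)))
    expect_equal(min(fits), f(esc))
  }
  sp <- table1_space()
  expect_error(make_ridge_landscape(sp, c(1L, 0L), c(1L, 1L)), "2 bits")
})

test_that("the external adapter parses well-formed output and flags failures", {
  good <- c("OBJ 8041.271", "NTHETA 7", "NOMEGA 7", "NSIGMA 2",
            "CONVERGED 1", "COV_OK 1", "CORR_OK 1", "COND_NUM 42")
  r <- pksearch:::parse_external_output(good)
  expect_equal(r$minus2LL, 8041.271)
  expect_equal(r$n_theta, 7L)
  expect_false(r$crashed)
  expect_equal(compute_fitness(r, penalty_schedule()), 8201.271)

  # condition number above the bound is penalized downstream
  high <- pksearch:::parse_external_output(c("OBJ 100", "COND_NUM 2000"))
  expect_equal(compute_fitness(high, penalty_schedule()), 200)

  # off-diagonal correlation beyond the threshold fails the diagnostic
  corr <- pksearch:::parse_external_output(
    c("OBJ 100", "COND_NUM 5", "CORR 1 2 0.99"))
  expect_false(corr$correlation_ok)
  ok <- pksearch:::parse_external_output(
    c("OBJ 100", "COND_NUM 5", "CORR 1 2 0.50"))
  expect_true(ok$correlation_ok)

  # missing objective means the run is unusable
  expect_true(pksearch:::parse_external_output(c("NTHETA 3"))$crashed)
})

test_that("external commands run, and nonzero exits become crashed results", {
  dir <- withr::local_tempdir()
  ok_script <- file.path(dir, "mock_ok.sh")
  writeLines(c("#!/bin/sh", "echo OBJ 123.5", "echo NTHETA 2",
               "echo COND_NUM 10"), ok_script)
  bad_script <- file.path(dir, "mock_bad.sh")
  writeLines(c("#!/bin/sh", "exit 3"), bad_script)

  spec <- external_run_spec(paste("sh", ok_script, "{model_file}"),
                            workdir = dir)
  r <- external_evaluate(spec, "THE MODEL TEXT", tag = "t1")
  expect_false(r$crashed)
  expect_equal(r$minus2LL, 123.5)
  expect_equal(r$n_theta, 2L)
  # the rendered model really was written
  expect_true(file.exists(file.path(dir, "run_t1", "model.txt")))

  bad <- external_run_spec(paste("sh", bad_script, "{model_file}"),
                           workdir = dir)
  rb <- external_evaluate(bad, "x", tag = "t2")
  expect_true(rb$crashed)
  expect_equal(compute_fitness(rb, penalty_schedule()), 99999999)

  expect_error(external_run_spec("no placeholder"), "model_file")
})

test_that("simulated concentrations follow the closed-form disposition", {
  # one compartment, single bolus, no noise: C(t) = D/V * exp(-CL/V t)
  p <- list(ncomp = 1, CL = 5, V1 = 30)
  d <- toy_pk_simulate(design = list(n_subjects = 4),
                       params = p, noise = list(prop = 0, add = 0),
                       seed = 7)
  obs <- d[d$AMT == 0, ]
  expect_equal(obs$DV, (100 / 30) * exp(-(5 / 30) * obs$TIME),
               tolerance = 1e-12)
  # identical seeds give identical datasets
  d2 <- toy_pk_simulate(design = list(n_subjects = 4), params = p,
                        noise = list(prop = 0, add = 0), seed = 7)
  expect_identical(d, d2)
  # invalid parameters refuse to simulate
  expect_error(toy_pk_simulate(params = list(ncomp = 1, CL = -1, V1 = 30)))
})

test_that("multiple daily doses superpose shifted single-dose profiles", {
  p <- list(ncomp = 2, CL = 5, V1 = 30, Q2 = 10, V2 = 70)
  times <- c(49, 52, 60, 71)
  multi <- toy_pk_simulate(design = list(n_subjects = 3,
                                         dose_times = c(0, 24, 48),
                                         sample_times = times),
                           params = p, noise = list(prop = 0), seed = 5)
  mobs <- multi[multi$AMT == 0, ]
  # independent superposition from three single-dose simulations
  single <- function(shift) {
    d <- toy_pk_simulate(design = list(n_subjects = 3, dose_times = 0,
                                       sample_times = times - shift),
                         params = p, noise = list(prop = 0), seed = 5)
    d[d$AMT == 0, "DV"]
  }
  expect_equal(mobs$DV, single(0) + single(24) + single(48),
               tolerance = 1e-10)
})

test_that("the toy fitter recovers a noise-free generating model nearly exactly", {
  sp <- toy_pk_space()
  truth <- list(ncomp = 2, CL = 5, V1 = 30, Q2 = 10, V2 = 70,
                wt_v_power = 1)
  d <- toy_pk_simulate(params = truth, noise = list(prop = 1e-4), seed = 3)
  # generating structure: 2 compartments, V~WT power, proportional error
  g_true <- c(1L, 1L, 0L, 0L, 0L, 1L)
  r_true <- toy_pk_evaluate(g_true, sp, d)
  expect_false(r_true$crashed)
  expect_equal(r_true$n_theta, 5L)   # CL, V1, Q2, V2, power
  expect_equal(r_true$n_sigma, 1L)
  # a one-compartment structure misfits by orders of magnitude
  g_1c <- c(0L, 1L, 0L, 0L, 0L, 1L)
  r_1c <- toy_pk_evaluate(g_1c, sp, d)
  expect_gt(r_1c$minus2LL - r_true$minus2LL, 100)
  # dropping the true covariate also costs far more than its penalty
  g_nocov <- c(1L, 0L, 0L, 0L, 0L, 1L)
  r_nocov <- toy_pk_evaluate(g_nocov, sp, d)
  expect_gt(r_nocov$minus2LL - r_true$minus2LL, 10)
  # variability dimensions only add parameter counts
  g_bsv <- c(1L, 1L, 0L, 1L, 1L, 1L)
  r_bsv <- toy_pk_evaluate(g_bsv, sp, d)
  expect_equal(r_bsv$n_omega, 2L)
  expect_equal(r_bsv$minus2LL, r_true$minus2LL)
})

test_that("a spurious covariate loses to the generating model under penalty", {
  sp <- toy_pk_space()
  truth <- list(ncomp = 2, CL = 5, V1 = 30, Q2 = 10, V2 = 70,
                wt_v_power = 1)
  sched <- penalty_schedule()
  wins <- 0L
  for (s in 1:5) {
    d <- toy_pk_simulate(params = truth, noise = list(prop = 0.1),
                         seed = 500 + s)
    f_true <- compute_fitness(
      toy_pk_evaluate(c(1L, 1L, 0L, 0L, 0L, 1L), sp, d), sched)
    f_spur <- compute_fitness(
      toy_pk_evaluate(c(1L, 1L, 1L, 0L, 0L, 1L), sp, d), sched)
    if (f_true < f_spur) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
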