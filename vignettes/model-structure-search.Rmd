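---
title: "Hybrid machine-learning and downhill search for model structure selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid machine-learning and downhill search for model structure selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksearch)
```

## The problem

Choosing a population pharmacokinetic (or pharmacodynamic) model is usually
done by forward addition / backward elimination: start from a trivial model,
test one feature at a time, keep what improves the objective. That procedure
is a greedy local search, and it inherits the two classic failure modes of
local search: it starts far from the optimum, and it tests hypotheses one at
a time, so it is blind to interactions between model features (a covariate
may only help once a second compartment is present, and vice versa).

`pksearch` treats structure selection as an explicit discrete optimization.
The modeller enumerates the hypotheses up front as a **search space**: an
ordered list of dimensions, each a set of mutually exclusive options
(compartment count; each covariate relationship present/absent; each
random-effect term present/absent; the residual-error form). A candidate
model -- a **genome** -- picks exactly one option per dimension, and the
space's cardinality is the product of the option counts. A 20-dimension
space with one 3-option dimension and nineteen binary ones holds
$3 \times 2^{19} = 1{,}572{,}864$ candidate models, far beyond what stepwise
habits actually explore.

## Fitness

Each candidate is scored by a penalized objective,

$$F = -2\log L \;+\; p_\theta n_\theta + p_\omega n_\omega + p_\sigma n_\sigma
\;+\; \sum \text{diagnostic penalties},$$

minimized over the space. Defaults are 10 points per estimated
fixed-effect, random-effect and residual parameter and 100 points for each
failed diagnostic: non-convergence, covariance-step failure, an
off-diagonal parameter-estimate correlation beyond 0.95, or a condition
number above 1000. Two deliberate edge rules:

* if the condition number is *absent* the penalty applies -- a run that
  produced no condition number has not demonstrated a well-conditioned fit;
* if the covariance step did not run at all, evaluators should clear the
  covariance and correlation flags and leave the condition number `NA`, so
  all three penalties apply. This is the conservative reading; the
  alternative (no penalty when no information) would reward models that
  break the covariance step.

Crashed runs (nonzero exit, timeout, unparseable output, failed fit)
receive a sentinel fitness of 99,999,999 rather than an exception, so a
search continues over a partially hostile space. A per-parameter penalty of
10 is roughly twice the 3.84 of a 5% likelihood-ratio test: the schedule is
intentionally parsimony-favouring, and it is fully configurable through the
`penalty` block of the options.

## Representations and geometry

Genomes have three faces:

* **integer vector** -- one 0-based option index per dimension; the
  canonical identity under which the evaluation cache deduplicates models;
* **GA bitstring** -- each dimension written in `ceiling(log2(k))` bits
  (minimum 1), most-significant bit first. Crossover and mutation can
  produce patterns whose value exceeds the option count; these decode by
  `value %% k`, so every bitstring is a valid model and no offspring is
  discarded. The wrap rule is this package's choice at a genuinely open
  design point; because canonical identity is the index vector, the
  redundant codes collapse into one cached model;
* **minimal binary** -- the same bit layout, but out-of-range patterns are
  simply invalid. This keeps the code redundancy-free (no two valid
  patterns denote the same model), which is the property the downhill
  search needs: flipping a bit either reaches a distinct valid model or is
  not a move at all.

Hamming distance -- and with it the niche radius -- is defined on the
minimal-binary representation.

## Global drivers

All drivers start from the same uniformly random initial population under
the run's master seed (the master seed derives per-component streams, so
driver comparisons share their starting point), and all of them propose
genomes only; evaluation and caching are shared machinery.

**Genetic algorithm.** Tournament selection as two pairs of two (the better
fitness of each pair becomes a parent), single-point crossover on the GA
bitstring with probability `crossover_rate` (default 0.95), then a
per-model mutation gate at `mutation_rate` (default 0.95) behind which each
bit flips at rate `1/n_bits`, and `elitist_num` (default 4) elites carried
over unchanged. The crossover operator and the per-bit rate behind the
per-model gate are implementation choices; elitism makes the best-so-far
trace non-increasing.

**Binary particle swarm.** Particles live in the continuous relaxation
$[0,1]^{n}$ of the bitstring space; a particle's genome is each coordinate
thresholded at 0.5. Velocities follow the canonical update
$V_{t+1} = wV_t + c_1 r_1 (pbest - x_t) + c_2 r_2 (lbest - x_t)$ with
inertia 0.5, cognitive 0.9, social 0.8, and a *local*-best topology: each
particle's reference best is the best personal best among its
`neighbor_num` (default 2) nearest particles under the `p_norm` (default
Euclidean) distance, plus itself. Positions are clipped to $[0,1]$ after
each move. The continuous relaxation with thresholding is the package's
discrete mapping choice.

**Surrogate-assisted search** (random forest, gradient boosted trees,
Gaussian process). The regressor is fit to fitness on *one-hot encoded*
genomes -- the strictly categorical treatment; option indices are labels,
not magnitudes -- over everything evaluated so far. A pool of unseen
genomes (the full unseen set when the space is small, a random sample of
`candidate_pool_size` otherwise) is scored by the lower confidence bound
$\hat\mu - w\,\hat s$ with exploration weight $w$ (default 1.0), and the
best-scoring distinct unseen genomes become the next generation. The
spread $\hat s$ is the across-tree standard deviation for the forest, the
posterior standard deviation for the Gaussian process, and 0 for boosted
trees (a pure exploitation driver). One numerical point matters for the
Gaussian process: the response is centered before fitting, because a
zero-mean prior on raw $-2\log L$-scale values (around $10^3$) makes the
posterior mean revert to 0 away from data and corrupts the acquisition
ranking. Forest size (200 trees), boosting depth/rounds (3/100) and the
radial-basis kernel are documented defaults of this package, not claims
about any other implementation.

**Exhaustive search** evaluates every genome once in odometer order (last
dimension fastest; ties go to the earlier genome) and is the gold standard
the others are judged against.

## The downhill search and why two bits

After every `downhill_period` global generations (default 5), and once more
after the final generation, a local phase runs:

1. **Niche seeds.** Walk the evaluated models in ascending fitness,
   greedily keeping up to `num_niches` (default 2) seeds that are pairwise
   at least `niche_radius` (default 2) bits apart, so parallel descents do
   not start from near-identical models.
2. **One-bit descent** from each seed: evaluate the full one-bit
   neighborhood, move to the best strictly better neighbor (ties: lowest
   flipped bit position, making runs deterministic), repeat until no
   neighbor improves. Strict improvement on a finite space guarantees
   termination.
3. **Two-bit stage** from the single best descent result: evaluate all
   $n(n-1)/2$ two-bit flips; if any improves, resume the one-bit descent
   from it and alternate until neither stage improves.

The two-bit stage exists because feature interactions create *ridges*: a
model can be strictly better than every one-bit neighbor yet strictly
worse than a model two flips away (drop covariate A, add compartment B).
`make_ridge_landscape()` constructs exactly this situation -- a trap genome
whose entire one-bit neighborhood is worse while a distance-2 escape is the
global minimum -- and the construction is verified by enumeration at build
time. On such a landscape a one-bit-only search provably stalls; the
two-bit phase escapes. Three-bit search is omitted: the neighborhood grows
as $\binom{n}{3}$ and the cost outruns the benefit.

The best model found by a downhill phase is injected into the next GA
population (replacing the worst member) or PSO swarm (replacing the worst
particle, velocity zeroed), so the global driver restarts from the
improved incumbent. Surrogate drivers need no injection -- they always
condition on the full history. Whether to reseed the global driver at all
was an open design point; injection was chosen because it preserves the
non-increasing best-so-far trace and costs nothing.

## Evaluators

**External command.** Mirrors the estimation-engine workflow: the rendered
model text is written to a per-model directory, a user command runs it, and
a flat `KEY value` output (`OBJ`, `NTHETA`, `NOMEGA`, `NSIGMA`,
`CONVERGED`, `COV_OK`, `CORR_OK`, `COND_NUM`, optional `CORR i j r` lines)
is parsed into a run result. Anything unparseable is a crash value, not an
error.

**Synthetic landscapes.** A deterministic objective over bit vectors: base
plus per-bit main effects plus pairwise interaction terms that fire when
both bits take required values. `random_landscape()` draws a moderate
NK-style instance: 12 bits, main effects $N(0, 10)$, 12 interactions
$N(0, 15)$ on random bit pairs with random required patterns, base 1000
(so values sit on a plausible $-2\log L$ scale). These defaults were fixed
once as a realistic difficulty -- enough epistasis to create off-axis local
minima, not pure noise. Landscapes emulate the *topology* of a model-search
fitness surface (additivity plus pairwise feature interaction); they do not
emulate estimation noise, crashes, or diagnostic failures, so passing
recovery tests on them demonstrates search behaviour, not estimator
behaviour.

**Toy pooled PK fitter.** An end-to-end stand-in exercising real
pharmacokinetic semantics at desk scale. `toy_pk_simulate()` generates
intravenous-bolus concentration-time data from analytic 1/2/3-compartment
disposition (superposed over the dose schedule) with covariate effects
(powers of weight on volume and clearance, among others) and
proportional/additive noise. `toy_pk_evaluate()` fits the structure a
genome selects by maximising a *pooled* normal likelihood -- structural and
residual-variance parameters jointly, by Nelder--Mead on log scales -- so
the residual-error dimension (combined vs proportional-only) is genuinely
data-driven rather than penalty-only. There are no random effects:
between-subject and between-occasion dimensions contribute parameter
counts (and hence penalties) only. This is loudly a test harness, not a
nonlinear mixed-effect estimator; it preserves the search space's meaning
while keeping one model fit in the tens of milliseconds. Default study
conditions, chosen once as a small-but-identifiable design: 12 subjects,
weights uniform on 50--100 kg, a single 100 mg bolus, sampling at 0.5, 1,
2, 4, 8, 12 and 24 h, 10% proportional noise; the default generating truth
used in examples is two compartments (CL 5 L/h, V1 30 L, Q2 10 L/h, V2
70 L) with a weight power of 1 on central volume.

## Orchestration and accounting

`run_search()` validates options before any evaluation, runs the initial
population as generation 1 and driver proposals as generations 2 onward,
and alternates in downhill phases recorded at half-step generations (5.5,
10.5, ...), since they happen between global generations. Every evaluator
invocation creates exactly one history record; duplicate proposals are
cache hits and are never re-run, so "unique models evaluated" is simply
the history size and "unique models to the best" is the ordinal at which
the final best fitness first appeared. `num_parallel` is accepted and
validated for interface compatibility, but evaluation is sequential: the
results contract (identical histories at any parallel width) makes
sequential execution an implementation detail, and it keeps runs exactly
reproducible.

Reproducibility is a hard contract: identical `(seed, options, evaluator)`
give identical history tables, and the written options snapshot re-runs to
an identical search.

## Problem sizes used by the test suite

The suite exercises the drivers on 12-bit landscapes (4,096 models, small
enough for an independent brute-force oracle) with population 20, 10
generations and downhill period 5 over 10 seeded replicates per driver,
and the toy PK recovery on the 64-model reduced space over 10 simulation
replicates. These sizes are the package's own verification design: large
enough that global-vs-local differences show, small enough that the oracle
is exact.

## Known limitations

* No real mixed-effect estimation is performed anywhere in the package;
  conclusions about real datasets require an external estimation engine
  behind the external-command adapter.
* The toy fitter pools subjects; variability dimensions are penalty-only,
  so it cannot detect when random effects are truly needed.
* Surrogate hyperparameters (kernel, tree counts, pool size, exploration
  weight) are sensible defaults, not tuned recommendations.
* Dimensions a template never references multiply cardinality without
  changing models; `validate_template()` warns, but the search will happily
  waste evaluations on such spaces if the warning is ignored.
* Fitness ties are broken by evaluation order; on landscapes with large
  flat plateaus the reported "unique models to best" depends on that
  order.
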