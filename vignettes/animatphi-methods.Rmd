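---
title: "Integrated information and surprisal in evolved animats: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated information and surprisal in evolved animats: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`animatphi` simulates small embodied agents ("animats") evolving on a
perceptual categorization task, and measures two quantities on them at
every within-trial timestep: the integrated conceptual information
$\Phi$ of the agent's internal network (IIT 3.0), and the surprisal
$\Im(o) = -\ln P(o)$ of its sensory state under an empirical goal
prior. This vignette documents the models, the conventions the
implementation commits to, the tunable parameters, and the limits of
what the package's synthetic fixtures can show.

## The task world

The arena is 16 columns wide (laterally wrapped, so column arithmetic
is modulo 16) and 36 rows tall. Each trial, a horizontally contiguous
block of length 1–6 falls from row 0, moving one row down and one
column left or right per timestep, reaching the bottom row after 35
timesteps. The animat occupies 3 contiguous bottom-row columns and may
move one column per timestep. A trial is a *catch* if animat and block
columns overlap when the block lands, otherwise an *avoid*. Two tasks
are provided: *easy* (catch length 1, avoid length 3; 64 distinct
trials) and *hard* (catch lengths 3 and 6, avoid 4 and 5; 128 distinct
trials). Trials enumerate every (length, direction, starting column)
combination; the animat always starts at columns {0,1,2}, which under
the lateral wraparound is equivalent to varying the agent's start
instead.

The first timestep initializes the network in the all-off state and
the last is the win-or-lose step, so analyses use the 33 timesteps in
between. Within a timestep the order of operations is fixed: sensors
are read from the world, the network updates synchronously, the motors
move the animat, the block advances. The simulation is deterministic
and bitwise reproducible; a compiled fast path and a plain-R reference
loop are kept in exact agreement by the test suite.

## Markov-brain animats

A brain has 8 binary nodes: 2 sensors (each on iff a block cell is
directly above the corresponding outermost animat cell; the middle
cell is blind), 4 hidden nodes and 2 motors (left/right; the animat
moves only when exactly one motor is on). Each non-sensor node owns a
gate: an ordered input list (sensors and hidden nodes only — motors
have no outputs) and a full truth table, with the first listed input as
the least significant table bit. A gate with no inputs emits a stored
constant, initialized off, so the ancestral unconnected brain is inert.
Updates are synchronous.

## Evolution

A generation holds 100 animats (package default for scaled runs: 50).
The next generation is sampled with replacement with probability
proportional to $1.02^{\,k}$, where $k$ is the number of correct
trials, and every child is mutated: per node, with probability
`p_rewire` = 0.05 one wiring change (replace, add or remove an input,
arity capped at 4), and each truth-table bit flips with probability
`p_flip` = 0.01. Adding an input duplicates the table (the new input
starts silent); removing one keeps the slice where that input is off.
There is no elitism and no crossover. The exact mutation operators and
rates of the original study framework are not published; these are this
package's own explicit stand-ins, chosen once so that runs of a few
thousand generations show fitness gains, and all configurable.

The line of descent (LOD) is traced from the best final animat (ties:
lowest index) back to generation 0, with genomes recorded every
`interval` generations; at the production scale of 60,000 generations
and interval 500 this yields 121 records, which the suite verifies on
a synthetic full-scale history rather than by running one.

## The IIT 3.0 engine

$\Phi$ is computed per network state. For a candidate subset of the 6
non-sensor nodes (sensors are always background; motors are eligible
but, having no outputs, never belong to a complex), all other nodes
are clamped to their current state on both the input and output side
of the transition, giving a candidate-only node-form TPM.

*Mechanism level.* The effect repertoire of a mechanism over a purview
is the product over purview nodes of each node's next-state
distribution with the mechanism clamped and all other candidate inputs
marginalized uniformly; the cause repertoire is the per-mechanism-node
Bayesian inversion under a uniform perturbation prior, combined as a
normalized product. Integrated information $\varphi$ of a purview is
the earth mover's distance (Hamming ground metric) between the whole
repertoire and the best factored repertoire over all
mechanism/purview bipartitions (each part must retain a mechanism or a
purview); the core cause/effect maximizes $\varphi$ per direction, and
a concept exists iff $\min(\varphi_{cause}, \varphi_{effect}) > 0$.

*System level.* Every unidirectional cut (sever all connections from
one part of the candidate to the rest, severed inputs replaced by
maximum-entropy noise) is applied, the conceptual structure is
recomputed under the cut TPM, and $\Phi$ is the extended EMD between
intact and cut structures: concepts transport their $\varphi$ mass,
with ground cost the Hamming EMD between expanded cause repertoires
plus that between expanded effect repertoires, and surplus mass routed
through the null concept (the unconstrained repertoires of the intact
candidate, used for both sides). The candidate with maximal $\Phi$ is
the main complex; ties prefer the larger candidate, then enumeration
order.

Numerical and convention choices, applied consistently and documented
here because the formalism leaves them open:

* State indexing: the first node of an ordering is the least
  significant bit of the state index.
* Partition and cut enumeration is by ascending bit mask;
  minimum-information ties keep the first partition encountered.
  Core-purview ties prefer the larger purview.
* $\varphi$ or $\Phi$ below $10^{-8}$ is treated as exactly 0 (the
  transportation solver's noise floor).
* A mechanism state that is unreachable under the deterministic TPM
  constrains nothing: $\varphi_{cause} = 0$.
* A single-node candidate cannot be system-partitioned; its $\Phi$ is
  the distance from its conceptual structure to the empty structure.
* Effect repertoires (and their factored partitions) are product
  distributions, for which the Hamming EMD equals the summed absolute
  marginal differences; the engine uses this closed form on the effect
  side and the exact transportation solver (successive shortest paths,
  written in C++) on the cause side and for concept transport.
* Candidates containing a node with no incoming or outgoing
  connection inside the candidate are reducible with $\Phi = 0$ and
  are skipped analytically; the same connectivity reasoning prunes
  irrelevant purviews. These short cuts are exactness-preserving and
  are validated against a naive reference that does not use them.

The whole engine is checked, value by value (per-mechanism $\varphi$,
concept sets, $\Phi$, complexes), against an independent naive
implementation that works on explicit state-by-state matrices and
solves every EMD as a linear program, on a fixture library of small
networks and on randomly generated ones. Main-complex results are
memoized by (genome, state), which is what makes per-timestep $\Phi$
series affordable: an animat visits few distinct states. A dense
6-node candidate evaluates in well under a minute on one CPU; evolved
sparse brains are much faster.

## Goal priors and surprisal

The goal prior approximates what a well-adapted agent expects to
sense. For each perfect-fitness source animat, separately per trial
type (catch/avoid), block direction and analyzed timestep — pooling
block lengths and starting columns — the four sensory states are
counted across that animat's trials and add-one smoothed:
$P(o) = (c_o + 1)/(n + 4)$. With the hard task's 32 trials per
condition this bounds surprisal to $[-\ln(33/36), -\ln(1/36)] =
[0.087, 3.584]$ nats, matching the reported extremes (0.09 and 3.58 at
two decimals); the smoothing constant is configurable and this
analytic correspondence is why add-one is the default. Each scored
animat is assigned the source whose priors minimize its mean surprisal
over all trials and timesteps (averaging over the full
trials-by-timesteps set is this package's reading of the
per-animat-per-generation selection rule), so surprisal is always
relative to the nearest perfect strategy. Priors are task-matched.

At scales where evolution has not produced perfect animats, scripted
omniscient controllers stand in as prior sources: a *follow* policy
that steers under (catch) or beside (avoid) the block and a
*pass-over* policy that lets the block cross the animat once on catch
trials. Both achieve fitness 1.0 on every trial of both tasks by
construction, and their records are produced by the same world loop as
brain records, so their sensor streams are physically legitimate. They
are stand-ins for evolved perfect animats, not claims about evolved
strategies.

## Analyses

*Evolutionary time.* Per LOD record, fitness, mean $\Phi$ and mean
surprisal are averaged over all trials and timesteps, smoothed with a
trailing window of the record and up to 5 preceding records (truncated
at the series start — the smoothing operates on the recorded LOD grid,
the only series that exists), then averaged across LODs with standard
errors.

*Trial time.* Per-timestep series are aggregated directly or after
centering each trial at its first block observation (trials with no
observation are excluded; counts necessarily thin away from relative
time 0).

*Covariation.* Pearson cross-correlations at lags $-16..16$ with
$\Phi$ as the lagging variable: negative lags relate $\Phi$ to future
surprisal. Trials with $\Phi$ constant at 0 are excluded; zero-variance
windows yield missing values rather than zeros. Lag-0 coefficients are
classified into negative / neutral / positive profiles with the
neutral band $[-0.1, 0.1]$ closed at both ends (the boundary's
inclusiveness is this package's documented convention). Fluctuations
are related by regressing $|\Delta\Phi|$ on $|\Delta\Im|$ (first
timestep of each trial dropped): the native estimator demeans within
trials (absorbing animat and trial intercepts), fits one slope per
animat, and pools by averaging; a full mixed model (random animat and
trial intercepts, random animat slope, via `lme4`) is available for
side-by-side comparison.

## Synthetic fixtures and what passing tests show

The surrogate-series generator produces paired 33-step series with a
shared unit step at a random observation time: the surprisal-like
series is the clean step, the phi-like series is `coupling` times the
step plus white noise. It exists to give the analysis stack a known
ground truth: slope recovery holds in the low-noise regime (the
absolute-difference transform makes additive noise a first-order
downward bias, so recovery is asserted at noise well below the step
size), zero coupling centers the lag-0 distribution at zero, and
positive coupling right-shifts it. None of this emulates real animat
series, whose $\Phi$ steps are state-dependent and asymmetric.

Scaled study conditions used by the acceptance suite: 10 easy-task
runs, population 50, 2,000 generations, recording interval 100. At
this scale animats improve markedly over the unconnected baseline but
rarely reach perfect fitness, which is why the fixture controllers
supply the goal priors there. The production-scale quantities (150
LODs, 60,000 generations, final-generation distribution statistics,
the pooled regression estimate) are out of reach of a desk run and are
not claimed; the package verifies the analytic anchors (trial counts,
timestep counts, LOD record counts, surprisal bounds) and the
qualitative signatures (fitness rises, surprisal falls, and the two
are negatively rank-correlated along scaled LODs).

## Known limitations

* Deterministic gates only; probabilistic TPMs arise solely from
  system cuts.
* IIT 3.0 only; no spatial or temporal coarse-graining, no later
  formalisms.
* The main-complex search treats sensors as background
  unconditionally; whether motors should be candidate-eligible in the
  reference analyses is not documented there, so eligibility is a
  config switch (motors, having no outputs, never end up in a complex
  either way).
* The easy task has 64 distinct trial configurations although the
  production study reports 128 trials per animat for both tasks;
  fitness is a fraction, so the denominator difference is immaterial,
  and no doubling is guessed.
* Cross-correlation and regression operate on 33-point series;
  per-trial coefficients are accordingly noisy, which is inherent to
  the design rather than to this implementation.
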