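# animatphi

Integrated information and surprisal in evolved animats.

`animatphi` is an R toolkit for a question at the junction of
Integrated Information Theory (IIT) and the Free Energy Principle
(FEP): when small embodied agents evolve to do a task, how does the
integrated conceptual information Φ of their internal network relate
to the surprisal of what they sense? It is written for computational
neuroscience / artificial-life researchers who want a self-contained,
fully testable re-implementation of that style of study at desk scale.

The package provides:

* a deterministic **block-catching world** (16×36, laterally wrapped):
  a block of length 1–6 falls for 35 timesteps while drifting left or
  right; a 3-cell animat must catch or avoid it depending on its
  length. Two tasks: *easy* (catch 1 / avoid 3; 64 trials) and *hard*
  (catch 3,6 / avoid 4,5; 128 trials). The 33 timesteps between
  initialization and the win-or-lose step are analyzed.
* **Markov-brain animats**: 8 binary nodes (2 sensors, 4 hidden,
  2 motors), each non-sensor node a truth-table gate; synchronous
  deterministic updates; compiled simulation core.
* a **genetic algorithm** with fitness-proportionate sampling
  (weight `1.02^#correct`), clone-and-mutate reproduction, and
  line-of-descent (LOD) recording.
* a complete **IIT 3.0 engine** for small binary networks:
  cause/effect repertoires, mechanism-level φ over all purviews and
  partitions, concepts, unidirectional system cuts, system-level Φ via
  the extended earth mover's distance, and the main-complex search —
  with exact EMDs solved as transportation problems in compiled code,
  and every value cross-checked in the test suite against an
  independent naive implementation.
* **empirical goal priors and surprisal**: per perfect-fitness source
  animat, per trial type, block direction and timestep, the four
  sensory states are counted and add-one smoothed,
  `P(o) = (count(o)+1)/(n+4)`, and observations are scored as
  `ℑ(o) = −ln P(o)` against the best-matching source.
* the **covariation analyses**: evolutionary-time aggregation with
  trailing smoothing, trial-time series centered on the first block
  observation, lagged cross-correlations (Φ lagging, lags −16..16),
  correlation profiles (negative / neutral / positive at ±0.1), and
  the |ΔΦ| ~ |Δℑ| fluctuation regression.
* **fixtures**: scripted omniscient controllers ("follow",
  "pass-over") that are perfect on every trial of both tasks and stand
  in as goal-prior sources at scales where evolution has not produced
  perfect animats, a toy-network suite with oracle-computed φ/Φ
  reference values, and surrogate coupled series with known ground
  truth.

## Worked example

Build goal priors from a perfect agent on the hard task and score
surprisal:

```r
library(animatphi)

ctl     <- make_perfect_controller("hard", "follow")
records <- run_controller_trials(ctl)         # 128 trials x 33 timesteps
mean(records$correct[records$t == 1])
#> [1] 1

priors <- build_goal_priors(list(follow = records))
priors[priors$t == 33 & priors$trial_type == "catch" &
         priors$direction == "right",
       c("state", "count", "n", "p")]
#> # A tibble: 4 × 4
#>   state count     n      p
#>   <chr> <int> <int>  <dbl>
#> 1 00        0    32 0.0278
#> 2 10        0    32 0.0278
#> 3 01        0    32 0.0278
#> 4 11       32    32 0.917
```

By the end of a catch trial the follower keeps the block above a
sensor, so the prior concentrates on state `11` (both sensors on). A
state never seen in the 32 trials of a condition costs
`−ln(1/36) = 3.58` nats; a state seen in all of them costs
`−ln(33/36) = 0.09`:

```r
round(surprisal("01", priors, "catch", "right", t = 33), 2)
#> [1] 3.58
round(surprisal("11", priors, "catch", "right", t = 33), 2)
#> [1] 0.09
```

Integrated information of a two-node reciprocal copy loop, both nodes
on:

```r
net <- logic_network(list(list(inputs = 2L, table = c(0L, 1L)),
                          list(inputs = 1L, table = c(0L, 1L))))
main_complex(net, c(1L, 1L))
#> Phi = 1 over nodes { 1,2 } in state 11 with 2 concepts
```

Each node's state pins down both its cause and its effect (φ = 0.5
per mechanism), no unidirectional cut can sever the loop without
destroying concepts, and the whole two-node system is the main
complex.

A full scaled pipeline — evolution, LOD extraction, surprisal scoring,
Φ time series, correlations, profiles and regression — runs from one
configuration:

```r
run_pipeline(list(task = "easy", generations = 2000, pop_size = 50,
                  n_lods = 5, seed = 1),
             out_dir = "out")
```

or from a shell via the wrapper script:

```sh
Rscript inst/cli/animatphi.R all --config run.yaml --out out/
```

Outputs are plain CSV/JSON files with a metadata header (config hash,
seed); reruns with the same config and seed are byte-identical.

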