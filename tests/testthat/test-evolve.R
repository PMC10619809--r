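# Genetic algorithm, mutation operators and line-of-descent extraction.

test_that("selection samples proportionally to base^(correct trials)", {
  set.seed(1)
  cfg <- evolve_config(pop_size = 40L, selection_base = 1.05)
  # population with known fitness spread; count parent picks over many
  # seeded selections and compare with the multinomial expectation
  fit <- c(rep(0.25, 20), rep(0.75, 20))
  pop <- list(brains = rep(list(empty_brain()), 40L), fitness = fit)
  n_trials <- 64L
  w <- cfg$selection_base^(fit * n_trials)
  expected <- w / sum(w)
  picks <- integer(40)
  for (i in 1:200) {
    nxt <- select_next_generation(pop, cfg, n_trials)
    picks <- picks + tabulate(nxt$parent, 40L)
  }
  freq <- picks / sum(picks)
  grp <- tapply(freq, rep(1:2, each = 20), sum)
  exp_grp <- tapply(expected, rep(1:2, each = 20), sum)
  expect_lt(max(abs(grp - exp_grp)), 0.02)
  # equal fitness: sampling is uniform across the population
  pop_eq <- list(brains = rep(list(empty_brain()), 40L),
                 fitness = rep(0.5, 40))
  picks <- integer(40)
  for (i in 1:200) picks <- picks +
      tabulate(select_next_generation(pop_eq, cfg, n_trials)$parent, 40L)
  expect_lt(max(abs(picks / sum(picks) - 1 / 40)), 0.01)
})

test_that("mutation respects rates and structural legality", {
  b <- random_test_brain(3)
  set.seed(1)
  expect_identical(mutate_brain(b, p_rewire = 0, p_flip = 0)$gates,
                   b$gates)
  # forced flip complements a 1-input gate's table
  b1 <- markov_brain(list(list(inputs = 1L, table = c(0L, 1L))))
  m1 <- mutate_brain(b1, p_rewire = 0, p_flip = 1)
  expect_equal(m1$gates[[1]]$table, c(1L, 0L))
  # empirical flip frequency tracks p_flip
  set.seed(7)
  flips <- 0L; bits <- 0L
  for (i in 1:300) {
    m <- mutate_brain(b, p_rewire = 0, p_flip = 0.1)
    for (g in 1:6) {
      flips <- flips + sum(m$gates[[g]]$table != b$gates[[g]]$table)
      bits <- bits + length(b$gates[[g]]$table)
    }
  }
  expect_lt(abs(flips / bits - 0.1), 0.015)
  # heavy rewiring keeps brains legal (validate_brain does not error)
  set.seed(11)
  mb <- b
  for (i in 1:200) mb <- mutate_brain(mb, p_rewire = 0.5, p_flip = 0.05)
  expect_silent(validate_brain(mb))
  expect_true(all(vapply(mb$gates, function(g)
    length(g$inputs) <= 4L, logical(1))))
})

test_that("evolution is reproducible and conserves population size", {
  cfg <- evolve_config(task = "easy", generations = 40L, pop_size = 15L,
                       interval = 20L, seed = 99L)
  h1 <- run_evolution(cfg)
  h2 <- run_evolution(cfg)
  expect_identical(h1, h2)
  expect_equal(dim(h1$fitness), c(41L, 15L))
  expect_true(all(!is.na(h1$fitness)))
  # generation 0 is all unconnected animats with identical fitness
  expect_equal(length(unique(h1$fitness[1L, ])), 1L)
  expect_true(all(vapply(h1$snapshots[["0"]], function(b)
    identical(b$gates, empty_brain()$gates), logical(1))))
  # G = 0: a single all-unconnected population
  h0 <- run_evolution(evolve_config(generations = 0L, pop_size = 5L))
  expect_equal(nrow(h0$fitness), 1L)
  expect_equal(length(unique(h0$fitness[1L, ])), 1L)
})

test_that("LOD extraction returns ancestor snapshots at the interval", {
  cfg <- evolve_config(task = "easy", generations = 60L, pop_size = 12L,
                       interval = 20L, seed = 5L)
  h <- run_evolution(cfg)
  lod <- extract_lod(h)
  expect_equal(vapply(lod, `[[`, integer(1), "generation"),
               c(0L, 20L, 40L, 60L))
  # independent ancestry walk reproduces the recorded genomes
  chain <- integer(61)
  chain[61] <- which.max(h$fitness[61L, ])
  for (g in 60:1) chain[g] <- h$parents[g + 1L, chain[g + 1L]]
  for (rec in lod) {
    g <- rec$generation
    expect_identical(rec$brain$gates,
                     h$snapshots[[as.character(g)]][[chain[g + 1L]]]$gates)
  }
  # JSON-lines round trip
  f <- withr::local_tempfile(fileext = ".jsonl")
  lod_to_jsonl(lod, f)
  lod2 <- lod_from_jsonl(f)
  expect_equal(length(lod2), length(lod))
  for (i in seq_along(lod)) {
    expect_identical(lod2[[i]]$brain$gates, lod[[i]]$brain$gates)
    expect_equal(lod2[[i]]$fitness, lod[[i]]$fitness)
  }
})

test_that("production-scale recording yields 121 records per LOD", {
  # synthetic history at the full scale: 60,000 generations, interval 500
  G <- 60000L
  brains <- list(empty_brain(), empty_brain())
  snaps <- setNames(rep(list(brains), length(seq(0L, G, by = 500L))),
                    as.character(seq(0L, G, by = 500L)))
  hist <- structure(list(
    config = evolve_config(generations = G, pop_size = 2L,
                           interval = 500L),
    fitness = matrix(0.5, nrow = G + 1L, ncol = 2L),
    parents = matrix(1L, nrow = G + 1L, ncol = 2L),
    snapshots = snaps, recorded = seq(0L, G, by = 500L)),
    class = "evolution_history")
  lod <- extract_lod(hist)
  expect_equal(length(lod), 121L)
  expect_equal(lod[[1L]]$generation, 0L)
  expect_equal(lod[[121L]]$generation, 60000L)
})
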