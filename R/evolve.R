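#' Evolution run configuration
#'
#' Bundles every knob of the genetic algorithm. Defaults are the scaled
#' study conditions used throughout the package's tests and examples; the
#' selection scheme is exponential fitness-proportionate sampling with
#' weight `selection_base ^ (number of correct trials)`, clone-and-mutate
#' reproduction, no elitism, no crossover.
#'
#' @param task `"easy"` or `"hard"`.
#' @param generations number of selection-mutation steps `G`.
#' @param pop_size animats per generation.
#' @param interval line-of-descent recording interval (generations).
#' @param p_rewire per-node probability of one wiring mutation (replace,
#'   add or remove an input, within `max_arity`).
#' @param p_flip per-truth-table-bit flip probability.
#' @param max_arity maximum number of gate inputs.
#' @param selection_base base of the exponential selection weight.
#' @param seed RNG seed; (config, seed) fully determines the run.
#' @return an `evolve_config` list.
#' @export
evolve_config <- function(task = "easy", generations = 2000L,
                          pop_size = 50L, interval = 500L,
                          p_rewire = 0.05, p_flip = 0.01,
                          max_arity = 4L, selection_base = 1.02,
                          seed = 1L) {
  stopifnot(pop_size >= 2L, generations >= 0L, interval >= 1L,
            p_rewire >= 0, p_rewire <= 1, p_flip >= 0, p_flip <= 1,
            max_arity >= 1L, selection_base > 1)
  task_blocks(task) # validates the task id
  structure(list(task = task, generations = as.integer(generations),
                 pop_size = as.integer(pop_size),
                 interval = as.integer(interval),
                 p_rewire = p_rewire, p_flip = p_flip,
                 max_arity = as.integer(max_arity),
                 selection_base = selection_base,
                 seed = as.integer(seed)),
            class = "evolve_config")
}

#' Mutate a brain
#'
#' Independently per non-sensor node: with probability `p_rewire` one
#' wiring change is applied (replace an input with a uniformly chosen
#' legal node -- sensors or hidden, duplicates allowed -- or add/remove an
#' input within the arity cap); then every truth-table bit flips with
#' probability `p_flip`. Adding an input appends it as the new most
#' significant table bit with the table duplicated, so the new input is
#' initially silent; removing an input keeps the table slice where that
#' input is off. Uses R's global RNG.
#'
#' @param brain a `markov_brain`.
#' @param p_rewire,p_flip,max_arity see [evolve_config()].
#' @return the mutated `markov_brain`.
#' @export
mutate_brain <- function(brain, p_rewire = 0.05, p_flip = 0.01,
                         max_arity = 4L) {
  gates <- brain$gates
  for (i in seq_along(gates)) {
    g <- gates[[i]]
    k <- length(g$inputs)
    if (runif(1) < p_rewire) {
      ops <- c(if (k > 0L) "replace", if (k < max_arity) "add",
               if (k > 0L) "remove")
      op <- if (length(ops) == 1L) ops else sample(ops, 1L)
      if (op == "replace") {
        j <- if (k == 1L) 1L else sample.int(k, 1L)
        g$inputs[j] <- sample(LEGAL_INPUT_NODES, 1L)
      } else if (op == "add") {
        g$inputs <- c(g$inputs, sample(LEGAL_INPUT_NODES, 1L))
        g$table <- c(g$table, g$table) # new MSB, initially silent
      } else { # remove
        j <- if (k == 1L) 1L else sample.int(k, 1L)
        keep_idx <- which(state_matrix(k)[, j] == 0L)
        g$inputs <- g$inputs[-j]
        g$table <- g$table[keep_idx]
      }
    }
    flips <- runif(length(g$table)) < p_flip
    if (any(flips)) g$table[flips] <- 1L - g$table[flips]
    gates[[i]] <- g
  }
  # mutations preserve structural legality; skip re-validation
  structure(list(gates = gates), class = "markov_brain")
}

# Evaluate fitness for a list of brains with a persistent genome cache.
eval_fitness <- function(brains, task, cache) {
  vapply(brains, function(b) {
    key <- brain_key(b)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- fitness(b, task)
      cache[[key]] <- v
    }
    v
  }, numeric(1))
}

#' Selection-and-mutation step
#'
#' Samples the next generation with replacement, with probability
#' proportional to `selection_base ^ n_correct` (so an all-incorrect
#' animat still has weight 1), then mutates every child.
#'
#' @param pop a population list with elements `brains` and `fitness`.
#' @param config an [evolve_config()].
#' @param n_trials number of trials in the task (to convert the fitness
#'   fraction back to a correct-trial count).
#' @return a population list with `brains`, `parent` (index into `pop`)
#'   and unevaluated `fitness`.
#' @export
select_next_generation <- function(pop, config, n_trials) {
  n <- length(pop$brains)
  w <- config$selection_base^(pop$fitness * n_trials)
  parent <- sample.int(n, n, replace = TRUE, prob = w)
  brains <- lapply(parent, function(p)
    mutate_brain(pop$brains[[p]], config$p_rewire, config$p_flip,
                 config$max_arity))
  list(brains = brains, parent = parent, fitness = rep(NA_real_, n))
}

#' Run an evolutionary simulation
#'
#' Generation 0 is a population of unconnected brains; `G` clone-mutate-
#' select steps follow. Fitness is cached per unique genome. Population
#' genomes are snapshotted at every multiple of the recording interval
#' (plus the final generation); parent indices are kept for every
#' generation so any ancestry can be reconstructed.
#'
#' @param config an [evolve_config()].
#' @param progress print a progress line every 500 generations.
#' @return an `evolution_history`: list with `config`, `fitness` matrix
#'   (`G+1` rows, one per generation), `parents` matrix, and `snapshots`
#'   (named list of brain lists at recorded generations).
#' @export
run_evolution <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "evolve_config"))
  set.seed(config$seed)
  n_trials <- nrow(enumerate_trials(config$task))
  cache <- new.env(parent = emptyenv())
  G <- config$generations
  n <- config$pop_size
  pop <- list(brains = rep(list(empty_brain()), n),
              parent = rep(NA_integer_, n),
              fitness = rep(NA_real_, n))
  pop$fitness <- eval_fitness(pop$brains, config$task, cache)
  fit_mat <- matrix(NA_real_, nrow = G + 1L, ncol = n)
  par_mat <- matrix(NA_integer_, nrow = G + 1L, ncol = n)
  fit_mat[1L, ] <- pop$fitness
  rec_gens <- unique(c(seq(0L, G, by = config$interval), G))
  snapshots <- list()
  snapshots[["0"]] <- pop$brains
  for (g in seq_len(G)) {
    pop <- select_next_generation(pop, config, n_trials)
    pop$fitness <- eval_fitness(pop$brains, config$task, cache)
    fit_mat[g + 1L, ] <- pop$fitness
    par_mat[g + 1L, ] <- pop$parent
    if (g %in% rec_gens) snapshots[[as.character(g)]] <- pop$brains
    if (progress && g %% 500L == 0L)
      message(sprintf("generation %d: best fitness %.3f", g,
                      max(pop$fitness)))
  }
  structure(list(config = config, fitness = fit_mat, parents = par_mat,
                 snapshots = snapshots, recorded = rec_gens),
            class = "evolution_history")
}

#' Extract the line of descent
#'
#' Walks ancestry backwards from the best-performing final animat (ties:
#' lowest index) and returns its ancestral genome at every recorded
#' generation (`0, interval, 2*interval, ..., G` inclusive). 60,000
#' generations at interval 500 yield 121 records.
#'
#' @param history an `evolution_history` from [run_evolution()].
#' @param interval recording interval; defaults to the run's own.
#' @return a `lod` object: list of records, each with `generation`,
#'   `brain`, `fitness`.
#' @export
extract_lod <- function(history, interval = NULL) {
  stopifnot(inherits(history, "evolution_history"))
  interval <- interval %||% history$config$interval
  G <- history$config$generations
  gens <- unique(c(seq(0L, G, by = interval), G))
  if (!all(as.character(gens) %in% names(history$snapshots)))
    stop("requested interval was not recorded in this history",
         call. = FALSE)
  # ancestor index of the best final animat at every generation
  idx <- integer(G + 1L)
  idx[G + 1L] <- which.max(history$fitness[G + 1L, ])
  if (G > 0L)
    for (g in G:1L) idx[g] <- history$parents[g + 1L, idx[g + 1L]]
  records <- lapply(gens, function(g) {
    list(generation = g,
         brain = history$snapshots[[as.character(g)]][[idx[g + 1L]]],
         fitness = history$fitness[g + 1L, idx[g + 1L]])
  })
  structure(records, class = "lod")
}

#' Write a line of descent as JSON lines
#'
#' One JSON object per recorded generation with fields `generation`,
#' `fitness` and the genome (per-gate inputs and truth-table bit string).
#'
#' @param lod a `lod` from [extract_lod()].
#' @param path output file.
#' @export
lod_to_jsonl <- function(lod, path) {
  lines <- vapply(lod, function(rec) {
    jsonlite::toJSON(list(
      generation = rec$generation, fitness = rec$fitness,
      gates = lapply(rec$brain$gates, function(g)
        list(inputs = g$inputs, table = paste(g$table, collapse = "")))
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname lod_to_jsonl
#' @param path file of JSON lines written by [lod_to_jsonl()].
#' @export
lod_from_jsonl <- function(path) {
  records <- lapply(readLines(path), function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    list(generation = as.integer(obj$generation),
         fitness = as.numeric(obj$fitness),
         brain = markov_brain(lapply(obj$gates, function(g)
           list(inputs = as.integer(unlist(g$inputs)),
                table = as.integer(strsplit(g$table, "")[[1]])))))
  })
  structure(records, class = "lod")
}
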