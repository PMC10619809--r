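#' Scripted controllers
#'
#' Deterministic policies that stand in for evolved animats wherever
#' perfect-fitness agents are needed (goal priors, baselines) at scales
#' where evolution has not produced any. Policies may read the full
#' world state ("omniscient"), but their recorded sensor streams are
#' computed by [read_sensors()] along the actual trajectory, so the
#' records are physically consistent and pass the same validators as
#' brain-driven ones (hidden nodes are recorded as all-off).
#'
#' Kinds:
#' * `follow` (= `omniscient_optimal`): steers the animat to a target
#'   offset under (catch) or beside (avoid) the block and tracks it --
#'   the strategy of following behind/underneath the block. Perfect on
#'   every trial of both tasks.
#' * `pass_over`: on catch trials travels one extra lap of the cylinder
#'   so the block passes over the animat once before it settles
#'   underneath; behaves like `follow` on avoid trials. Also perfect.
#' * `motionless`: never moves; the geometric baseline.
#'
#' @name controllers
NULL

# Offset dynamics: let r = (animat_anchor - block_anchor) mod 16 and
# s = +/-1 the block drift. A move m in {-1,0,+1} changes r by m - s, so
# r can be driven at up to 2 columns/step against the drift and held
# with m = s. The block overlaps the animat at the bottom iff
# r in {14, 15} union {0, ..., L-1}.
target_offset <- function(trial_type, L) {
  if (trial_type == "catch") {
    # overlap with the block kept above a *sensor* cell, so the follower
    # sees the block for the rest of the trial once in position (a
    # length-1 block centered on the animat would sit over the blind
    # middle cell)
    if (L == 1L) 0L else (floor((L - 3) / 2)) %% 16L
  } else (L + 3L) %% 16L # mid safe zone, block never seen again
}

#' Create a scripted controller
#'
#' @param task_id `"easy"` or `"hard"`.
#' @param kind `"follow"`, `"pass_over"`, `"motionless"` or
#'   `"omniscient_optimal"` (alias of `"follow"`).
#' @return an `animat_controller` with fields `kind`, `task_id`,
#'   `access`, and the action rule.
#' @export
make_perfect_controller <- function(task_id,
                                    kind = c("follow", "pass_over",
                                             "motionless",
                                             "omniscient_optimal")) {
  kind <- match.arg(kind)
  task_blocks(task_id) # validate
  access <- if (kind == "motionless") "sensors_only" else "world_state"
  structure(list(task_id = task_id, kind = kind, access = access),
            class = "animat_controller")
}

# Returns a fresh per-trial policy closure: called with the world each
# timestep, returns motor pair c(mL, mR).
controller_policy <- function(controller, spec) {
  kind <- controller$kind
  if (kind == "motionless") return(function(world) c(0L, 0L))
  rstar <- target_offset(spec$trial_type, spec$block_length)
  s <- if (spec$direction == "right") 1L else -1L
  # pass_over travels one extra lap of the cylinder on catch trials, so
  # the block crosses over the animat once before it settles underneath
  extra <- if (kind == "pass_over" && spec$trial_type == "catch") 16L else 0L
  env <- new.env(parent = emptyenv())
  env$remaining <- NA_integer_ # distance still to travel, set on first call
  function(world) {
    if (is.na(env$remaining)) {
      r <- wrap_col(world$animat_anchor - world$block_anchor)
      g0 <- if (s == 1L) wrap_col(r - rstar) else wrap_col(rstar - r)
      env$remaining <- g0 + extra
    }
    m <- if (env$remaining >= 2L) -s else if (env$remaining == 1L) 0L else s
    env$remaining <- max(0L, env$remaining - (if (m == -s) 2L else if (m == 0L) 1L else 0L))
    if (m == -1L) c(1L, 0L) else if (m == 1L) c(0L, 1L) else c(0L, 0L)
  }
}

#' Run a scripted controller over trials
#'
#' Identical world loop and record format as [run_trial()]; hidden and
#' motor node columns hold the controller's actions (hidden all-off).
#'
#' @param controller from [make_perfect_controller()].
#' @param spec a single trial spec row.
#' @param animat_anchor initial leftmost animat column.
#' @return a 33-row trial-record tibble.
#' @export
run_controller_trial <- function(controller, spec, animat_anchor = 0L) {
  spec <- as.list(spec)
  policy <- controller_policy(controller, spec)
  world <- world_new(spec$init_col, spec$block_length, spec$direction,
                     animat_anchor = animat_anchor)
  world <- advance_block(world)
  rec <- matrix(0L, nrow = N_ANALYZED, ncol = N_NODES + 3L)
  for (t in 2:N_TIMESTEPS) {
    sens <- read_sensors(world)
    motors <- policy(world)
    world <- apply_motors(world, motors)
    if (t <= N_TIMESTEPS - 1L)
      rec[t - 1L, ] <- c(sens, integer(4), motors, world$animat_anchor,
                         world$block_row, world$block_anchor)
    world <- advance_block(world)
  }
  caught <- any(world$animat_cols %in% world$block_cols)
  correct <- caught == (spec$trial_type == "catch")
  tibble::tibble(
    trial_id = spec$trial_id %||% NA_integer_,
    task_id = spec$task_id %||% controller$task_id,
    block_length = as.integer(spec$block_length),
    trial_type = spec$trial_type, direction = spec$direction,
    init_col = as.integer(spec$init_col), t = seq_len(N_ANALYZED),
    sL = rec[, 1L], sR = rec[, 2L],
    h1 = rec[, 3L], h2 = rec[, 4L], h3 = rec[, 5L], h4 = rec[, 6L],
    mL = rec[, 7L], mR = rec[, 8L],
    animat_col = rec[, 9L], block_row = rec[, 10L], block_col0 = rec[, 11L],
    caught = caught, correct = correct)
}

#' @rdname run_controller_trial
#' @param trials task id or trial-spec tibble.
#' @export
run_controller_trials <- function(controller, trials = controller$task_id,
                                  animat_anchor = 0L) {
  if (is.character(trials)) trials <- enumerate_trials(trials)
  dplyr::bind_rows(lapply(seq_len(nrow(trials)), function(i)
    run_controller_trial(controller, trials[i, ], animat_anchor)))
}

#' Task fitness of a controller
#' @inheritParams run_controller_trials
#' @return fraction of trials correct.
#' @export
controller_fitness <- function(controller, trials = controller$task_id,
                               animat_anchor = 0L) {
  recs <- run_controller_trials(controller, trials, animat_anchor)
  mean(recs$correct[recs$t == 1L])
}

#' The toy network suite
#'
#' Small fixture networks with reference phi values computed by the
#' naive exhaustive oracle and stored in
#' `inst/extdata/toy_networks.json` (regenerated programmatically, never
#' hand-edited; see the file's provenance field).
#'
#' @return a named list; each entry holds `network` (a
#'   [logic_network()]), `state` (bit vector), and the stored references
#'   `phi_mechanisms` (named by mechanism, e.g. `"1,2"`), `big_phi` (of
#'   the full candidate) and `main_complex` (`nodes`, `phi`).
#' @export
toy_network_suite <- function() {
  path <- system.file("extdata", "toy_networks.json",
                      package = "animatphi", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(raw$networks, function(ent) {
    gates <- lapply(ent$gates, function(g) {
      if (length(g$inputs) == 0L && identical(g$table, "0")) return(NULL)
      list(inputs = as.integer(unlist(g$inputs)),
           table = as.integer(strsplit(g$table, "")[[1]]))
    })
    list(name = ent$name,
         network = logic_network(gates),
         state = as.integer(unlist(ent$state)),
         phi_mechanisms = setNames(
           vapply(ent$phi_mechanisms, function(x) as.numeric(x$phi),
                  numeric(1)),
           vapply(ent$phi_mechanisms, function(x) x$mechanism,
                  character(1))),
         big_phi = as.numeric(ent$big_phi),
         main_complex = list(
           nodes = as.integer(unlist(ent$main_complex$nodes)),
           phi = as.numeric(ent$main_complex$phi)))
  })
  setNames(out, vapply(out, `[[`, character(1), "name"))
}

# Gate definitions of the toy suite (single source of truth for both the
# shipped JSON and its regeneration).
toy_network_gates <- function() {
  list(
    unconnected2 = list(gates = list(NULL, NULL), state = c(0L, 0L)),
    selfcopy = list(gates = list(list(inputs = 1L, table = c(0L, 1L))),
                    state = 1L),
    copyloop2 = list(gates = list(list(inputs = 2L, table = c(0L, 1L)),
                                  list(inputs = 1L, table = c(0L, 1L))),
                     state = c(1L, 1L)),
    and_loop3 = list(gates = list(
      # ring with an AND: 1 <- 2 AND 3, 2 <- copy(1), 3 <- copy(2)
      list(inputs = c(2L, 3L), table = c(0L, 0L, 0L, 1L)),
      list(inputs = 1L, table = c(0L, 1L)),
      list(inputs = 2L, table = c(0L, 1L))), state = c(1L, 1L, 1L)))
}

#' Coupled surrogate series
#'
#' Paired 33-step "phi-like" and "surprisal-like" series for exercising
#' the covariation analyses with a known ground truth. Each trial has a
#' unit step in the surprisal-like series at a random observation time
#' (drawn in 5..20); the phi-like series is `coupling` times that step
#' plus white noise of standard deviation `noise`. With `noise = 0` and
#' `coupling = 1` the two series are identical; with `coupling = 0` they
#' are independent.
#'
#' @param n_trials number of trials.
#' @param coupling shared-step coefficient in `[-1, 1]`.
#' @param noise standard deviation of the white noise on the phi-like
#'   series.
#' @param seed RNG seed.
#' @return tibble `trial_id`, `t` (1..33), `obs_t`, `surprisal`, `phi`.
#' @export
coupled_surrogate_series <- function(n_trials, coupling, noise, seed) {
  stopifnot(coupling >= -1, coupling <= 1, noise >= 0)
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_trials), function(i) {
    t0 <- sample(5:20, 1L)
    step <- as.numeric(seq_len(N_ANALYZED) >= t0)
    tibble::tibble(trial_id = i, t = seq_len(N_ANALYZED), obs_t = t0,
                   surprisal = step,
                   phi = coupling * step +
                     noise * stats::rnorm(N_ANALYZED))
  }))
}
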