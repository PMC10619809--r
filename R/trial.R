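#' Run one trial
#'
#' Simulates the 35-timestep fall of a block. The first timestep is the
#' initialization step: the network is in the all-off state, the animat
#' does not move and the block advances. On each later timestep the
#' sensors are read from the world, the brain updates synchronously, the
#' motors move the animat and the block advances. Timesteps 2--34 are
#' recorded as analyzed steps 1--33 (the final win-or-lose step is
#' dropped). The trial counts as caught iff the animat and block columns
#' overlap once the block reaches the bottom row; it is correct iff caught
#' matches the trial type.
#'
#' Recorded per analyzed step: the full network state after the update,
#' the animat anchor after moving, and the block row/anchor at sensing
#' time.
#'
#' @param brain a `markov_brain`.
#' @param spec one trial: a single row of [enumerate_trials()] (or a list
#'   with fields `block_length`, `trial_type`, `direction`, `init_col`,
#'   optionally `trial_id`, `task_id`).
#' @param animat_anchor initial leftmost animat column (default 0; trial
#'   variety is carried by the 16 initial block columns).
#' @return a 33-row tibble, one row per analyzed timestep, with columns
#'   `trial_id`, `task_id`, `block_length`, `trial_type`, `direction`,
#'   `init_col`, `t`, `sL`, `sR`, `h1`..`h4`, `mL`, `mR`, `animat_col`,
#'   `block_row`, `block_col0`, `caught`, `correct`.
#' @export
run_trial <- function(brain, spec, animat_anchor = 0L) {
  spec <- as.list(spec)
  world <- world_new(spec$init_col, spec$block_length, spec$direction,
                     animat_anchor = animat_anchor)
  state <- integer(N_NODES)
  world <- advance_block(world) # initialization timestep (t = 1)
  rec <- matrix(0L, nrow = N_ANALYZED, ncol = N_NODES + 3L)
  for (t in 2:N_TIMESTEPS) {
    sens <- read_sensors(world)
    state[SENSOR_NODES] <- sens
    state <- update_brain(brain, state)
    world <- apply_motors(world, state[MOTOR_NODES])
    if (t <= N_TIMESTEPS - 1L)
      rec[t - 1L, ] <- c(state, world$animat_anchor, world$block_row,
                         world$block_anchor)
    world <- advance_block(world)
  }
  caught <- any(world$animat_cols %in% world$block_cols)
  correct <- caught == (spec$trial_type == "catch")
  tibble::tibble(
    trial_id = spec$trial_id %||% NA_integer_,
    task_id = spec$task_id %||% NA_character_,
    block_length = as.integer(spec$block_length),
    trial_type = spec$trial_type,
    direction = spec$direction,
    init_col = as.integer(spec$init_col),
    t = seq_len(N_ANALYZED),
    sL = rec[, 1L], sR = rec[, 2L],
    h1 = rec[, 3L], h2 = rec[, 4L], h3 = rec[, 5L], h4 = rec[, 6L],
    mL = rec[, 7L], mR = rec[, 8L],
    animat_col = rec[, 9L], block_row = rec[, 10L], block_col0 = rec[, 11L],
    caught = caught, correct = correct
  )
}

#' Run a brain over a whole trial set
#'
#' @param brain a `markov_brain`.
#' @param trials a task id (`"easy"`/`"hard"`) or a tibble of trial specs
#'   as from [enumerate_trials()].
#' @param animat_anchor initial leftmost animat column.
#' @param engine `"cpp"` (compiled fast path) or `"r"` (reference loop);
#'   the two are bitwise identical.
#' @return row-bound trial records (33 rows per trial).
#' @export
run_trials <- function(brain, trials, animat_anchor = 0L,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.character(trials)) trials <- enumerate_trials(trials)
  if (engine == "r") {
    recs <- lapply(seq_len(nrow(trials)), function(i)
      run_trial(brain, trials[i, ], animat_anchor))
    return(dplyr::bind_rows(recs))
  }
  sim <- sim_trials_cpp(
    lapply(brain$gates, function(g) g$inputs - 1L),
    lapply(brain$gates, function(g) g$table),
    trials$block_length,
    ifelse(trials$direction == "right", 1L, -1L),
    trials$init_col, as.integer(animat_anchor), TRUE)
  nt <- nrow(trials)
  caught <- rep(sim$caught, each = N_ANALYZED)
  st <- sim$states
  tibble::tibble(
    trial_id = rep(trials$trial_id %||% seq_len(nt), each = N_ANALYZED),
    task_id = rep(trials$task_id %||% NA_character_, each = N_ANALYZED),
    block_length = rep(trials$block_length, each = N_ANALYZED),
    trial_type = rep(trials$trial_type, each = N_ANALYZED),
    direction = rep(trials$direction, each = N_ANALYZED),
    init_col = rep(trials$init_col, each = N_ANALYZED),
    t = rep(seq_len(N_ANALYZED), nt),
    sL = st[, 1L], sR = st[, 2L],
    h1 = st[, 3L], h2 = st[, 4L], h3 = st[, 5L], h4 = st[, 6L],
    mL = st[, 7L], mR = st[, 8L],
    animat_col = st[, 9L], block_row = st[, 10L], block_col0 = st[, 11L],
    caught = caught,
    correct = caught == (rep(trials$trial_type, each = N_ANALYZED) == "catch")
  )
}

#' Task fitness of a brain
#'
#' Fraction of the task's enumerated trials the brain gets correct
#' (catching catch-blocks, avoiding avoid-blocks). Deterministic.
#'
#' @inheritParams run_trials
#' @param task_id `"easy"` or `"hard"`.
#' @return a number in `[0, 1]`.
#' @export
fitness <- function(brain, task_id, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  trials <- enumerate_trials(task_id)
  if (engine == "cpp") {
    sim <- sim_trials_cpp(
      lapply(brain$gates, function(g) g$inputs - 1L),
      lapply(brain$gates, function(g) g$table),
      trials$block_length,
      ifelse(trials$direction == "right", 1L, -1L),
      trials$init_col, 0L, FALSE)
    return(mean(sim$caught == (trials$trial_type == "catch")))
  }
  recs <- run_trials(brain, trials, engine = "r")
  mean(dplyr::summarise(dplyr::group_by(recs, .data$trial_id),
                        ok = .data$correct[1])$ok)
}

#' Export trial records as CSV
#'
#' One row per (trial, analyzed timestep), with a `#`-prefixed metadata
#' header line carrying provenance.
#'
#' @param records trial-record tibble from [run_trials()].
#' @param path output file.
#' @param meta optional named character vector written into the header.
#' @export
write_trial_records <- function(records, path, meta = NULL) {
  write_csv_meta(records, path, meta)
}
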