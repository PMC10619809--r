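#' The block-catching world
#'
#' A two-dimensional toroidal-width arena, 16 columns wide and 36 rows tall.
#' A laterally contiguous block of length 1--6 falls from the top row (0),
#' moving one row down and one column sideways per timestep, wrapping around
#' the lateral edges. An animat occupies exactly 3 contiguous columns on the
#' bottom row. Columns are 0-based (`0:15`) and all column arithmetic is
#' modulo 16; rows run top-down from 0 to 35.
#'
#' @name world
NULL

WORLD_WIDTH <- 16L
WORLD_HEIGHT <- 36L
ANIMAT_WIDTH <- 3L
N_TIMESTEPS <- 35L # falls from row 0 to row 35
N_ANALYZED <- 33L  # timesteps 2..34, re-indexed 1..33

# Block lengths per task: which lengths must be caught vs avoided.
task_blocks <- function(task_id) {
  switch(task_id,
    easy = list(catch = 1L, avoid = 3L),
    hard = list(catch = c(3L, 6L), avoid = c(4L, 5L)),
    stop("unknown task id: '", task_id, "' (expected 'easy' or 'hard')",
         call. = FALSE)
  )
}

wrap_col <- function(x) ((as.integer(x)) %% WORLD_WIDTH)

block_cols_of <- function(anchor, len) wrap_col(anchor + 0:(len - 1L))
animat_cols_of <- function(anchor) wrap_col(anchor + 0:(ANIMAT_WIDTH - 1L))

#' Construct a world state
#'
#' @param block_anchor leftmost block column (0-based, modulo 16).
#' @param block_length block length, 1--6.
#' @param direction `"left"` or `"right"`; the block's lateral drift.
#' @param animat_anchor leftmost animat column (default 0).
#' @param block_row current row of the block (top = 0).
#' @return a `world_state` list with fields `block_row`, `block_anchor`,
#'   `block_length`, `block_cols`, `direction`, `animat_anchor`,
#'   `animat_cols`, `timestep`.
#' @export
world_new <- function(block_anchor, block_length, direction,
                      animat_anchor = 0L, block_row = 0L) {
  stopifnot(block_length >= 1L, block_length <= 6L,
            direction %in% c("left", "right"),
            block_row >= 0L, block_row <= WORLD_HEIGHT - 1L)
  structure(list(
    block_row = as.integer(block_row),
    block_anchor = wrap_col(block_anchor),
    block_length = as.integer(block_length),
    block_cols = block_cols_of(block_anchor, block_length),
    direction = direction,
    animat_anchor = wrap_col(animat_anchor),
    animat_cols = animat_cols_of(animat_anchor),
    timestep = 0L
  ), class = "world_state")
}

#' Advance the falling block one timestep
#'
#' Moves the block one row down and one column sideways (wrapping).
#'
#' @param world a `world_state`.
#' @return the updated `world_state`.
#' @export
advance_block <- function(world) {
  if (world$block_row >= WORLD_HEIGHT - 1L)
    stop("block is already at the bottom row", call. = FALSE)
  shift <- if (world$direction == "right") 1L else -1L
  world$block_row <- world$block_row + 1L
  world$block_anchor <- wrap_col(world$block_anchor + shift)
  world$block_cols <- block_cols_of(world$block_anchor, world$block_length)
  world$timestep <- world$timestep + 1L
  world
}

#' Read the animat's sensors
#'
#' The left (right) sensor is on iff some block column lies directly above
#' the animat's leftmost (rightmost) column; the middle column carries no
#' sensor.
#'
#' @param world a `world_state`.
#' @return integer vector `c(sL, sR)` of 0/1.
#' @export
read_sensors <- function(world) {
  ac <- world$animat_cols
  c(as.integer(ac[1L] %in% world$block_cols),
    as.integer(ac[ANIMAT_WIDTH] %in% world$block_cols))
}

#' Move the animat according to its motor state
#'
#' With exactly one motor on the animat shifts one column in that motor's
#' direction (wrapping); with both motors off or both on it stays put.
#'
#' @param world a `world_state`.
#' @param motors integer vector `c(mL, mR)` of 0/1.
#' @return the updated `world_state`.
#' @export
apply_motors <- function(world, motors) {
  stopifnot(length(motors) == 2L, all(motors %in% c(0L, 1L)))
  shift <- if (motors[1L] == 1L && motors[2L] == 0L) -1L
           else if (motors[1L] == 0L && motors[2L] == 1L) 1L
           else 0L
  world$animat_anchor <- wrap_col(world$animat_anchor + shift)
  world$animat_cols <- animat_cols_of(world$animat_anchor)
  world
}

#' Enumerate the trial set of a task
#'
#' Every distinct combination of block length, drift direction and initial
#' block column. The hard task (catch lengths 3 and 6, avoid lengths 4 and
#' 5) yields 128 trials; the easy task (catch 1, avoid 3) yields 64.
#'
#' @param task_id `"easy"` or `"hard"`.
#' @return a tibble with columns `trial_id`, `task_id`, `block_length`,
#'   `trial_type`, `direction`, `init_col`, ordered by length, direction,
#'   column.
#' @examples
#' nrow(enumerate_trials("hard")) # 128
#' @export
enumerate_trials <- function(task_id) {
  cached <- .trial_table_cache[[task_id]]
  if (!is.null(cached)) return(cached)
  blocks <- task_blocks(task_id)
  specs <- dplyr::bind_rows(
    tidyr::expand_grid(block_length = blocks$catch, trial_type = "catch"),
    tidyr::expand_grid(block_length = blocks$avoid, trial_type = "avoid")
  )
  out <- tidyr::expand_grid(specs, direction = c("left", "right"),
                            init_col = 0:(WORLD_WIDTH - 1L))
  out <- dplyr::arrange(out, .data$block_length, .data$direction,
                        .data$init_col)
  out <- tibble::tibble(trial_id = seq_len(nrow(out)), task_id = task_id,
                        out[, c("block_length", "trial_type", "direction",
                                "init_col")])
  assign(task_id, out, envir = .trial_table_cache)
  out
}

.trial_table_cache <- new.env(parent = emptyenv())
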