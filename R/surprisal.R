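#' Empirical goal priors and surprisal
#'
#' A goal prior is the empirical distribution over the four sensory
#' states `00, 10, 01, 11` (left bit first) observed in a perfect-fitness
#' animat's trials, kept separately per source animat, per trial type
#' (catch/avoid), per block direction (left/right) and per analyzed
#' timestep; block lengths and starting columns within a condition are
#' pooled. Counts are add-one (Laplace) smoothed over the 4 states:
#' `P(o) = (count(o) + alpha) / (n + 4 alpha)` with `alpha = 1`, so with
#' `n = 32` trials per condition the surprisal `-ln P(o)` ranges from
#' `-ln(33/36) = 0.087` (state seen in every trial) to `-ln(1/36) =
#' 3.584` nats (state never seen).
#'
#' @name goal_priors
NULL

SENSOR_STATES <- c("00", "10", "01", "11")

sensor_state_of <- function(sL, sR) paste0(sL, sR)

#' Build empirical goal priors from perfect-animat trial records
#'
#' @param records trial records from [run_trials()] or
#'   [run_controller_trials()], for one or more source animats: either a
#'   single tibble with a `source_id` column, or a named list of record
#'   tibbles (names become source ids).
#' @param alpha smoothing constant added to each state count (default 1).
#' @return a `goal_prior` tibble: `source_id`, `trial_type`, `direction`,
#'   `t`, `state`, `count`, `n`, `p`, with all four states present for
#'   every key and `sum(p) = 1` within each key.
#' @export
build_goal_priors <- function(records, alpha = 1) {
  if (is.list(records) && !is.data.frame(records)) {
    stopifnot(!is.null(names(records)), all(nzchar(names(records))))
    records <- dplyr::bind_rows(records, .id = "source_id")
  }
  stopifnot("source_id" %in% names(records))
  counts <- records |>
    dplyr::mutate(state = sensor_state_of(.data$sL, .data$sR)) |>
    dplyr::count(.data$source_id, .data$trial_type, .data$direction,
                 .data$t, .data$state, name = "count") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("source_id"), !!rlang::sym("trial_type"),
                     !!rlang::sym("direction"), !!rlang::sym("t")),
      state = SENSOR_STATES, fill = list(count = 0L))
  out <- counts |>
    dplyr::group_by(.data$source_id, .data$trial_type, .data$direction,
                    .data$t) |>
    dplyr::mutate(n = sum(.data$count),
                  p = (.data$count + alpha) / (.data$n + 4 * alpha)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$source_id, .data$trial_type, .data$direction,
                   .data$t, match(.data$state, SENSOR_STATES))
  class(out) <- c("goal_prior", class(out))
  out
}

#' Surprisal of one observation under a goal prior
#'
#' `-ln P(o)` in nats; never infinite thanks to the smoothing.
#'
#' @param o sensory state, one of `"00"`, `"10"`, `"01"`, `"11"` (left
#'   sensor first).
#' @param prior a `goal_prior` tibble (one source).
#' @param trial_type,direction,t the condition key.
#' @return surprisal in nats.
#' @examples
#' \dontrun{
#' surprisal("11", prior, "catch", "left", t = 10)
#' }
#' @export
surprisal <- function(o, prior, trial_type, direction, t) {
  stopifnot(o %in% SENSOR_STATES)
  if (length(unique(prior$source_id)) != 1L)
    stop("prior must be filtered to a single source animat", call. = FALSE)
  row <- prior[prior$trial_type == trial_type &
                 prior$direction == direction &
                 prior$t == t & prior$state == o, ]
  if (nrow(row) != 1L)
    stop("no goal-prior entry for (", trial_type, ", ", direction,
         ", t=", t, ", ", o, ")", call. = FALSE)
  -log(row$p)
}

# Per-timestep surprisal of every record row against every source in the
# prior set; internal workhorse shared by the selection and scoring ops.
score_against_priors <- function(records, priors) {
  obs <- records |>
    dplyr::mutate(state = sensor_state_of(.data$sL, .data$sR)) |>
    dplyr::select("trial_id", "trial_type", "direction", "t", "state")
  dplyr::inner_join(
    obs, dplyr::select(priors, "source_id", "trial_type", "direction",
                       "t", "state", "p"),
    by = c("trial_type", "direction", "t", "state"),
    relationship = "many-to-many") |>
    dplyr::mutate(surprisal = -log(.data$p))
}

#' Choose the reference prior source for an animat
#'
#' Scores the animat's full set of trials and analyzed timesteps against
#' each perfect source's goal priors and returns the source with the
#' lowest mean surprisal (so surprisal is always evaluated relative to
#' the perfect strategy closest to the animat's own); ties go to the
#' first source id in sort order.
#'
#' @param records one animat's trial records.
#' @param priors a `goal_prior` tibble (one or more sources).
#' @return the selected `source_id` (character scalar).
#' @export
select_reference_prior <- function(records, priors) {
  stopifnot(nrow(priors) > 0L)
  scored <- score_against_priors(records, priors)
  means <- scored |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(mean_surprisal = mean(.data$surprisal)) |>
    dplyr::arrange(.data$mean_surprisal, .data$source_id)
  means$source_id[1L]
}

#' Surprisal time series for an animat
#'
#' One value per (trial, analyzed timestep), scored against the selected
#' reference source (chosen once per animat via
#' [select_reference_prior()] unless given).
#'
#' @param records one animat's trial records.
#' @param priors a `goal_prior` tibble.
#' @param source_id optional source to use; default selects the
#'   best-matching one.
#' @return tibble `trial_id`, `trial_type`, `direction`, `t`, `state`,
#'   `surprisal`, `source_id`.
#' @export
surprisal_timeseries <- function(records, priors, source_id = NULL) {
  source_id <- source_id %||% select_reference_prior(records, priors)
  scored <- score_against_priors(
    records, priors[priors$source_id == source_id, ])
  dplyr::arrange(
    dplyr::mutate(scored, source_id = source_id),
    .data$trial_id, .data$t)
}

#' Export goal priors as CSV
#'
#' Columns `source_id, trial_type, direction, t, state, count, p`,
#' directly renderable as per-condition heatmaps (timestep x state).
#'
#' @param priors a `goal_prior` tibble.
#' @param path output file.
#' @param meta optional named character vector for the metadata header.
#' @export
write_goal_priors <- function(priors, path, meta = NULL) {
  write_csv_meta(
    priors[, c("source_id", "trial_type", "direction", "t", "state",
               "count", "p")], path, meta)
}
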