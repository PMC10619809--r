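#' Aggregation and covariation analyses
#'
#' Tools for the two timescales of the study: evolutionary time (per-LOD
#' series of fitness, mean Phi and mean surprisal over recorded
#' generations, trailing-smoothed and averaged across LODs) and trial
#' time (per-timestep series, optionally centered on the animat's first
#' observation of the block, lagged cross-correlations, correlation
#' profiles, and the fluctuation regression).
#'
#' @name analyze
NULL

#' Evolutionary-time aggregation
#'
#' Input is one row per (LOD, recorded generation) with the animat-level
#' means (each variable already averaged over all trials x timesteps for
#' that animat). Each LOD's series is smoothed with a trailing window of
#' the current and up to 5 preceding recorded generations (truncated at
#' the series start), then LODs are averaged per generation with
#' standard errors.
#'
#' @param per_animat tibble with columns `lod_id`, `generation`, and one
#'   or more value columns (e.g. `fitness`, `phi`, `surprisal`).
#' @param vars value columns to aggregate (default: all numeric columns
#'   besides the keys).
#' @param window trailing window length in recorded generations
#'   (default 6 = current + 5 previous).
#' @return list with `by_lod` (smoothed per-LOD series, columns
#'   `<var>_smooth`) and `by_generation` (cross-LOD `mean_<var>`,
#'   `se_<var>`, `n_lods` per generation, computed on the smoothed
#'   series).
#' @export
evolutionary_aggregate <- function(per_animat, vars = NULL, window = 6L) {
  keys <- c("lod_id", "generation")
  stopifnot(all(keys %in% names(per_animat)))
  vars <- vars %||% setdiff(names(per_animat)[vapply(per_animat,
                                                     is.numeric,
                                                     logical(1))],
                            keys)
  smooth_trailing <- function(x) {
    vapply(seq_along(x), function(i)
      mean(x[max(1L, i - window + 1L):i]), numeric(1))
  }
  by_lod <- per_animat |>
    dplyr::arrange(.data$lod_id, .data$generation) |>
    dplyr::group_by(.data$lod_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vars), smooth_trailing,
                                .names = "{.col}_smooth")) |>
    dplyr::ungroup()
  by_generation <- by_lod |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(
      n_lods = dplyr::n(),
      dplyr::across(dplyr::all_of(paste0(vars, "_smooth")),
                    list(mean = mean,
                         se = ~ sd(.x) / sqrt(dplyr::n())),
                    .names = "{.fn}_{.col}")) |>
    dplyr::rename_with(~ sub("_smooth$", "", .x))
  list(by_lod = by_lod, by_generation = by_generation)
}

#' Center trial time on the first block observation
#'
#' Adds `rel_t = t - t_first` where `t_first` is the first analyzed
#' timestep with any sensor on. Trials in which the animat never
#' observes the block are excluded.
#'
#' @param df tibble with columns `trial_id`, `t`, `sL`, `sR` (plus any
#'   value columns, carried through).
#' @return the centered tibble (a subset of rows of `df`, plus `t_first`
#'   and `rel_t`).
#' @export
center_on_first_observation <- function(df) {
  df |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::mutate(t_first = if (any(.data$sL + .data$sR > 0))
      min(.data$t[.data$sL + .data$sR > 0]) else NA_integer_) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$t_first)) |>
    dplyr::mutate(rel_t = .data$t - .data$t_first)
}

#' Lagged cross-correlation of two trial-time series
#'
#' Pearson correlations at lags `-max_lag..max_lag` with Phi as the
#' lagging variable: at negative lags the coefficient relates Phi to
#' *future* surprisal, at positive lags to past surprisal
#' (`r(l) = cor(phi_t, surprisal_{t-l})` over the overlapping window).
#' Lags where either windowed series has zero variance give `NA`.
#'
#' @param phi,surprisal numeric vectors of equal length (33 for analyzed
#'   trials).
#' @param max_lag maximum absolute lag (default 16).
#' @return tibble with columns `lag`, `r`.
#' @export
cross_correlation <- function(phi, surprisal, max_lag = 16L) {
  n <- length(phi)
  stopifnot(length(surprisal) == n, max_lag < n)
  r <- vapply(-max_lag:max_lag, function(l) {
    if (l >= 0L) { x <- phi[(1L + l):n]; y <- surprisal[1:(n - l)] }
    else { x <- phi[1:(n + l)]; y <- surprisal[(1L - l):n] }
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  tibble::tibble(lag = -max_lag:max_lag, r = r)
}

#' Cross-correlations for every trial of an animat
#'
#' Trials whose Phi series is constant at 0 are excluded (their
#' coefficient is undefined).
#'
#' @param df tibble with columns `trial_id`, `t`, `phi`, `surprisal`.
#' @param max_lag maximum absolute lag.
#' @return tibble `trial_id`, `lag`, `r`.
#' @export
trial_cross_correlations <- function(df, max_lag = 16L) {
  kept <- df |>
    dplyr::arrange(.data$trial_id, .data$t) |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::filter(any(.data$phi != 0)) |>
    dplyr::ungroup()
  if (nrow(kept) == 0L)
    return(tibble::tibble(trial_id = integer(0), lag = integer(0),
                          r = numeric(0)))
  kept |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::reframe(cross_correlation(.data$phi, .data$surprisal,
                                     max_lag))
}

#' Classify a correlation profile
#'
#' Neutral iff `-0.1 <= r0 <= 0.1` (closed interval -- documented
#' convention), negative below, positive above. `NA` stays unclassified.
#'
#' @param r0 lag-0 correlation coefficient(s).
#' @return character vector in `{"negative", "neutral", "positive"}`
#'   (with `NA` for missing input).
#' @export
classify_profile <- function(r0) {
  dplyr::case_when(
    is.na(r0) ~ NA_character_,
    r0 < -0.1 ~ "negative",
    r0 > 0.1 ~ "positive",
    TRUE ~ "neutral")
}

#' Fluctuation regression of |dPhi| on |dSurprisal|
#'
#' Relates the absolute timestep-to-timestep changes of the two series
#' at lag 0, excluding each trial's first timestep (no change is defined
#' there). The native estimator is two-stage: within every trial both
#' difference series are mean-centered (absorbing animat- and
#' trial-level intercepts), a slope is fit per animat by OLS over its
#' pooled centered series, and the pooled slope is the mean of the
#' per-animat slopes with its standard error. Animats whose centered
#' regressor has zero variance are dropped from the pooling. A full
#' mixed-model fit (random intercepts for animat and trial, random slope
#' per animat, via lme4) can be requested for comparison.
#'
#' @param df tibble with columns `animat_id`, `trial_id`, `t`, `phi`,
#'   `surprisal`.
#' @param method `"two_stage"` (native) or `"lmer"` (requires lme4).
#' @return list with `beta1` (pooled slope), `se`, `sd_slope` (between-
#'   animat dispersion), `n_animats`, and `slopes` (per-animat tibble).
#'   For `"lmer"`, also the fitted model in `$fit`.
#' @export
fluctuation_regression <- function(df, method = c("two_stage", "lmer")) {
  method <- match.arg(method)
  stopifnot(all(c("animat_id", "trial_id", "t", "phi", "surprisal") %in%
                  names(df)))
  d <- df |>
    dplyr::arrange(.data$animat_id, .data$trial_id, .data$t) |>
    dplyr::group_by(.data$animat_id, .data$trial_id) |>
    dplyr::mutate(dphi = abs(.data$phi - dplyr::lag(.data$phi)),
                  dsur = abs(.data$surprisal -
                               dplyr::lag(.data$surprisal))) |>
    dplyr::filter(!is.na(.data$dphi)) |>
    dplyr::mutate(dphi_c = .data$dphi - mean(.data$dphi),
                  dsur_c = .data$dsur - mean(.data$dsur)) |>
    dplyr::ungroup()
  if (nrow(d) < 2L) stop("fewer than 2 usable timesteps", call. = FALSE)
  if (method == "lmer") {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("method 'lmer' requires the lme4 package", call. = FALSE)
    fit <- lme4::lmer(
      dphi ~ dsur + (1 + dsur | animat_id) + (1 | animat_id:trial_id),
      data = d)
    beta1 <- unname(lme4::fixef(fit)["dsur"])
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_slope <- vc$sdcor[vc$grp == "animat_id" & vc$var1 == "dsur" &
                           is.na(vc$var2)]
    return(list(beta1 = beta1, se = summary(fit)$coefficients["dsur", 2],
                sd_slope = sd_slope, n_animats = dplyr::n_distinct(
                  d$animat_id), fit = fit))
  }
  slopes <- d |>
    dplyr::group_by(.data$animat_id) |>
    dplyr::summarise(
      sxx = sum(.data$dsur_c^2),
      slope = ifelse(.data$sxx > 0,
                     sum(.data$dsur_c * .data$dphi_c) / .data$sxx,
                     NA_real_)) |>
    dplyr::select("animat_id", "slope")
  sl <- slopes$slope[!is.na(slopes$slope)]
  list(beta1 = mean(sl),
       se = if (length(sl) > 1L) sd(sl) / sqrt(length(sl)) else NA_real_,
       sd_slope = if (length(sl) > 1L) sd(sl) else NA_real_,
       n_animats = length(sl), slopes = slopes)
}
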