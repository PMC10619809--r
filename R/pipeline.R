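#' Reproducible pipeline
#'
#' Chains the stages -- fixture priors, evolution, surprisal scoring,
#' Phi time series, covariation analyses -- on a scaled configuration,
#' writing plain-text artifacts (CSV with metadata headers, JSON,
#' JSON-lines) plus an execution log into one output directory. A run is
#' fully determined by (config, seed): every per-LOD evolution seed is
#' derived from the master seed, and each output file's header carries
#' the config hash and seed.
#'
#' @name pipeline
NULL

pipeline_defaults <- function() {
  list(task = "easy", generations = 200L, pop_size = 30L,
       interval = 100L, p_rewire = 0.05, p_flip = 0.01, max_arity = 4L,
       selection_base = 1.02, n_lods = 2L, seed = 1L,
       alpha = 1, phi_trials = 4L, include_motors = TRUE,
       phi_evolution = TRUE, max_lag = 16L, plots = FALSE)
}

#' Load a pipeline configuration
#'
#' YAML file with any subset of the fields of `pipeline_defaults()`;
#' missing fields take the defaults. Unknown fields are an error.
#'
#' @param path YAML file path, or a named list.
#' @return the resolved config list.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, cfg)
  for (f in c("generations", "pop_size", "interval", "max_arity",
              "n_lods", "seed", "phi_trials", "max_lag"))
    out[[f]] <- as.integer(out[[f]])
  task_blocks(out$task)
  out
}

#' Run the full pipeline
#'
#' @param config a config list (see [load_run_config()]), a YAML path,
#'   or `NULL` for the defaults.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the main in-memory results:
#'   `evolution` (per-LOD per-generation tibble), `aggregate`,
#'   `trial_series`, `correlations`, `profiles`, `regression`, `priors`.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- load_run_config(config %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(cfg)
  meta <- c(config_hash = cfg_hash, seed = cfg$seed)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "",
                            sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  writeLines(jsonlite::toJSON(c(cfg, list(config_hash = cfg_hash)),
                              auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_config.json"))
  logf("pipeline start: task=%s generations=%d n_lods=%d seed=%d",
       cfg$task, cfg$generations, cfg$n_lods, cfg$seed)

  # -- fixture stage: perfect-controller goal priors ----------------------
  sources <- list(
    follow = run_controller_trials(
      make_perfect_controller(cfg$task, "follow")),
    pass_over = run_controller_trials(
      make_perfect_controller(cfg$task, "pass_over")))
  priors <- build_goal_priors(sources, alpha = cfg$alpha)
  write_goal_priors(priors, file.path(out_dir, "goal_priors.csv"), meta)
  logf("fixture priors built from %d perfect sources", length(sources))

  # -- evolution + per-record scoring -------------------------------------
  evo_rows <- list()
  final_series <- list()
  trials <- enumerate_trials(cfg$task)
  phi_trial_ids <- trials$trial_id[seq_len(min(cfg$phi_trials,
                                               nrow(trials)))]
  for (i in seq_len(cfg$n_lods)) {
    ecfg <- evolve_config(task = cfg$task, generations = cfg$generations,
                          pop_size = cfg$pop_size,
                          interval = cfg$interval,
                          p_rewire = cfg$p_rewire, p_flip = cfg$p_flip,
                          max_arity = cfg$max_arity,
                          selection_base = cfg$selection_base,
                          seed = derive_seed(cfg$seed, paste0("lod", i)))
    hist <- run_evolution(ecfg)
    lod <- extract_lod(hist)
    lod_to_jsonl(lod, file.path(out_dir, sprintf("lod_%02d.jsonl", i)))
    for (rec in lod) {
      recs <- run_trials(rec$brain, trials)
      ss <- surprisal_timeseries(recs, priors)
      is_final <- rec$generation == cfg$generations
      ph <- if (cfg$phi_evolution || is_final) {
        sub <- recs[recs$trial_id %in% phi_trial_ids, ]
        phi_timeseries(rec$brain, sub,
                       include_motors = cfg$include_motors)
      }
      evo_rows[[length(evo_rows) + 1L]] <- tibble::tibble(
        lod_id = i, generation = rec$generation, fitness = rec$fitness,
        surprisal = mean(ss$surprisal),
        phi = if (is.null(ph)) NA_real_ else mean(ph$phi))
      if (is_final) {
        joined <- dplyr::inner_join(
          ph, ss[, c("trial_id", "t", "surprisal")],
          by = c("trial_id", "t"))
        joined$lod_id <- i
        final_series[[i]] <- joined
      }
    }
    logf("LOD %d done: final fitness %.3f", i,
         lod[[length(lod)]]$fitness)
  }
  evolution <- dplyr::bind_rows(evo_rows)
  # mean Phi per recorded animat uses the phi_trials trial subset; with
  # phi_evolution = FALSE it is only available at the final generation
  agg <- evolutionary_aggregate(
    evolution,
    vars = c("fitness", "surprisal",
             if (cfg$phi_evolution) "phi"))
  write_csv_meta(agg$by_generation,
                 file.path(out_dir, "fig3_evolution.csv"), meta)

  # -- trial-time analyses at the final generation ------------------------
  series <- dplyr::bind_rows(final_series)
  centered <- center_on_first_observation(series)
  write_csv_meta(
    dplyr::select(centered, "lod_id", "trial_id", "t", "t_first",
                  "rel_t", "phi", "surprisal"),
    file.path(out_dir, "fig4_trialtime.csv"), meta)
  series$animat_id <- series$lod_id
  series$trial_key <- paste(series$lod_id, series$trial_id, sep = ":")
  cc <- series |>
    dplyr::group_by(.data$animat_id) |>
    dplyr::group_modify(~ trial_cross_correlations(
      .x, max_lag = cfg$max_lag)) |>
    dplyr::ungroup()
  write_csv_meta(cc, file.path(out_dir, "fig6_correlations.csv"), meta)
  lag0 <- cc[cc$lag == 0L, ]
  profiles <- tibble::tibble(
    animat_id = lag0$animat_id, trial_id = lag0$trial_id, r0 = lag0$r,
    profile = classify_profile(lag0$r))
  write_csv_meta(profiles, file.path(out_dir, "fig7_8_profiles.csv"),
                 meta)
  regression <- tryCatch(
    fluctuation_regression(series[, c("animat_id", "trial_id", "t",
                                      "phi", "surprisal")]),
    error = function(e) list(beta1 = NA_real_, error = conditionMessage(e)))
  writeLines(jsonlite::toJSON(
    c(list(config_hash = cfg_hash, seed = cfg$seed),
      regression[c("beta1", "se", "sd_slope", "n_animats", "error")]),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE),
    file.path(out_dir, "regression.json"))

  if (isTRUE(cfg$plots)) {
    ggplot2::ggsave(file.path(out_dir, "fig3_fitness.png"),
                    plot_evolution(agg, "fitness"), width = 6, height = 4)
    ggplot2::ggsave(file.path(out_dir, "fig3_surprisal.png"),
                    plot_evolution(agg, "surprisal"), width = 6,
                    height = 4)
    ggplot2::ggsave(file.path(out_dir, "fig10_goal_priors.png"),
                    plot_goal_priors(priors), width = 10, height = 5)
  }
  logf("pipeline done")
  invisible(list(evolution = evolution, aggregate = agg,
                 trial_series = series, correlations = cc,
                 profiles = profiles, regression = regression,
                 priors = priors))
}

#' Command-line interface
#'
#' Subcommands: `evolve`, `phi`, `surprisal`, `analyze`, `fixtures`,
#' `all`. See the repository script `inst/cli/animatphi.R` for the
#' executable wrapper. Flags are `--key value` pairs; every subcommand
#' accepts `--out <dir>`.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
animat_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) < 1L)
      stop("usage: animatphi <evolve|phi|surprisal|analyze|fixtures|all> ",
           "[--key value ...]", call. = FALSE)
    cmd <- argv[1L]
    opts <- list()
    args <- argv[-1L]
    while (length(args) >= 2L) {
      if (!startsWith(args[1L], "--"))
        stop("expected --flag, got: ", args[1L], call. = FALSE)
      opts[[sub("^--", "", args[1L])]] <- args[2L]
      args <- args[-(1:2)]
    }
    need <- function(k) opts[[k]] %||%
      stop("missing required flag --", k, call. = FALSE)
    switch(cmd,
      all = {
        run_pipeline(if (!is.null(opts$config)) opts$config else NULL,
                     out_dir = need("out"))
      },
      evolve = {
        cfg <- load_run_config(if (!is.null(opts$config)) opts$config
                               else list())
        out <- need("out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_len(cfg$n_lods)) {
          ecfg <- evolve_config(
            task = cfg$task, generations = cfg$generations,
            pop_size = cfg$pop_size, interval = cfg$interval,
            p_rewire = cfg$p_rewire, p_flip = cfg$p_flip,
            max_arity = cfg$max_arity,
            selection_base = cfg$selection_base,
            seed = derive_seed(cfg$seed, paste0("lod", i)))
          lod <- extract_lod(run_evolution(ecfg))
          lod_to_jsonl(lod, file.path(out, sprintf("lod_%02d.jsonl", i)))
        }
        cat("wrote", cfg$n_lods, "LOD file(s) to", out, "\n")
      },
      phi = {
        tpm <- tpm_read(need("tpm"))
        st <- as.integer(need("state"))
        res <- big_phi(tpm, st)
        cat(sprintf("Phi = %.6f (nodes {%s}, state %d, %d concepts)\n",
                    res$phi, paste(res$nodes, collapse = ","), st,
                    res$n_concepts))
      },
      surprisal = {
        recs <- tibble::as_tibble(read_csv_meta(need("records")))
        pri <- tibble::as_tibble(read_csv_meta(need("priors")))
        ss <- surprisal_timeseries(recs, pri)
        write_csv_meta(ss, need("out"))
        cat("wrote", nrow(ss), "surprisal rows to", opts$out, "\n")
      },
      fixtures = {
        out <- need("out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        task <- opts$task %||% "hard"
        sources <- list(
          follow = run_controller_trials(
            make_perfect_controller(task, "follow")),
          pass_over = run_controller_trials(
            make_perfect_controller(task, "pass_over")))
        write_trial_records(dplyr::bind_rows(sources, .id = "source_id"),
                            file.path(out, "perfect_records.csv"))
        write_goal_priors(build_goal_priors(sources),
                          file.path(out, "goal_priors.csv"))
        file.copy(system.file("extdata", "toy_networks.json",
                              package = "animatphi"),
                  file.path(out, "toy_networks.json"), overwrite = TRUE)
        cat("wrote fixture records, priors and toy networks to", out,
            "\n")
      },
      analyze = {
        inp <- need("records") # joined phi+surprisal series CSV
        df <- tibble::as_tibble(read_csv_meta(inp))
        out <- need("out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        cc <- trial_cross_correlations(df)
        write_csv_meta(cc, file.path(out, "correlations.csv"))
        r0 <- cc[cc$lag == 0L, ]
        write_csv_meta(
          tibble::tibble(trial_id = r0$trial_id, r0 = r0$r,
                         profile = classify_profile(r0$r)),
          file.path(out, "profiles.csv"))
        cat("wrote correlation analyses to", out, "\n")
      },
      stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
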