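# Aggregation, centering, cross-correlation, profiles, regression.

test_that("trailing smoothing averages the current and 5 previous records", {
  df <- tibble::tibble(lod_id = 1L, generation = seq(0, 3000, 500),
                       fitness = c(1, 2, 3, 4, 5, 6, 7))
  agg <- evolutionary_aggregate(df, vars = "fitness")
  sm <- agg$by_lod$fitness_smooth
  expect_equal(sm[7], mean(2:7))  # full window
  expect_equal(sm[1], 1)          # truncated window: itself
  expect_equal(sm[3], mean(1:3))
  # constant series unchanged
  dfc <- tibble::tibble(lod_id = 1L, generation = seq(0, 2000, 500),
                        fitness = rep(2.5, 5))
  expect_equal(evolutionary_aggregate(dfc,
                                      vars = "fitness")$by_lod$fitness_smooth,
               rep(2.5, 5))
  # cross-LOD mean and standard error
  df2 <- dplyr::bind_rows(
    tibble::tibble(lod_id = 1L, generation = c(0, 500), fitness = c(1, 1)),
    tibble::tibble(lod_id = 2L, generation = c(0, 500), fitness = c(3, 3)))
  bg <- evolutionary_aggregate(df2, vars = "fitness")$by_generation
  expect_equal(bg$mean_fitness, c(2, 2))
  expect_equal(bg$se_fitness, c(1, 1))
  expect_equal(bg$n_lods, c(2L, 2L))
})

test_that("centering maps the first observation to relative time 0", {
  df <- dplyr::bind_rows(
    tibble::tibble(trial_id = 1L, t = 1:6, sL = c(0, 0, 0, 0, 1, 0),
                   sR = 0, v = 1:6),
    tibble::tibble(trial_id = 2L, t = 1:6, sL = 0, sR = 0, v = 1:6))
  cen <- center_on_first_observation(df)
  expect_equal(unique(cen$trial_id), 1L) # never-seen trial excluded
  expect_equal(cen$t_first, rep(5L, 6))
  expect_equal(cen$rel_t, -4:1)
  expect_equal(cen$v[cen$rel_t == 0], 5L)
  # centering is lossless for the kept trials
  expect_equal(sort(cen$v), sort(df$v[df$trial_id == 1L]))
  # counts per relative timestep never exceed the count at 0
  set.seed(4)
  many <- dplyr::bind_rows(lapply(1:40, function(i) {
    tf <- sample(3:30, 1)
    tibble::tibble(trial_id = i, t = 1:33,
                   sL = as.integer(1:33 >= tf), sR = 0L)
  }))
  cen2 <- center_on_first_observation(many)
  counts <- table(cen2$rel_t)
  expect_equal(max(counts), unname(counts["0"]))
})

test_that("cross-correlation obeys the stated lag sign convention", {
  set.seed(10)
  x <- cumsum(rnorm(33))
  cc <- cross_correlation(x, x)
  expect_equal(nrow(cc), 33L)
  expect_equal(cc$r[cc$lag == 0], 1)
  expect_true(all(abs(cc$r) <= 1 + 1e-12, na.rm = TRUE))
  # surprisal trailing phi by k (phi leads): peak at negative lag -k,
  # i.e. phi correlates with *future* surprisal
  k <- 3L
  phi <- c(rep(0, 10), 1, rep(0, 22)) + rnorm(33, sd = 1e-3)
  surp <- c(rep(0, 10 + k), 1, rep(0, 22 - k)) + rnorm(33, sd = 1e-3)
  cc2 <- cross_correlation(phi, surp)
  expect_equal(cc2$lag[which.max(cc2$r)], -k)
  # and the mirrored construction peaks at +k
  cc3 <- cross_correlation(surp, phi)
  expect_equal(cc3$lag[which.max(cc3$r)], k)
  # zero-variance windows give NA, not 0
  cc4 <- cross_correlation(rep(0, 33), rnorm(33))
  expect_true(all(is.na(cc4$r)))
})

test_that("per-trial correlations exclude constant-zero phi trials", {
  df <- dplyr::bind_rows(
    tibble::tibble(trial_id = 1L, t = 1:33, phi = 0,
                   surprisal = rnorm(33)),
    tibble::tibble(trial_id = 2L, t = 1:33,
                   phi = c(rep(0, 16), rep(1, 17)) + rnorm(33, sd = 1e-2),
                   surprisal = rnorm(33)))
  cc <- trial_cross_correlations(df)
  expect_equal(unique(cc$trial_id), 2L)
  expect_equal(nrow(cc), 33L)
  # all trials constant-zero: empty result, no error
  cc0 <- trial_cross_correlations(
    tibble::tibble(trial_id = 1L, t = 1:33, phi = 0, surprisal = 1))
  expect_equal(nrow(cc0), 0L)
})

test_that("profile classification partitions at the +/-0.1 thresholds", {
  expect_equal(classify_profile(c(0.05, -0.5, 0.1, -0.1, 0.11, NA)),
               c("neutral", "negative", "neutral", "neutral",
                 "positive", NA))
  set.seed(5)
  r <- runif(100, -1, 1)
  cls <- classify_profile(r)
  expect_true(all(cls %in% c("negative", "neutral", "positive")))
  expect_equal(cls == "neutral", r >= -0.1 & r <= 0.1)
})

test_that("fluctuation regression recovers known couplings", {
  # identical difference series: slope exactly 1
  set.seed(20)
  df <- coupled_surrogate_series(40, coupling = 1, noise = 0, seed = 21)
  df$animat_id <- 1L
  fit <- fluctuation_regression(df)
  expect_equal(fit$beta1, 1, tolerance = 1e-9)
  # independent series: pooled slope within 2 SE of zero
  df0 <- dplyr::bind_rows(lapply(1:8, function(a) {
    d <- coupled_surrogate_series(30, coupling = 0, noise = 0.5,
                                  seed = 100 + a)
    d$animat_id <- a
    d$trial_id <- paste(a, d$trial_id)
    d
  }))
  fit0 <- fluctuation_regression(df0)
  expect_lt(abs(fit0$beta1), 2 * fit0$se + 1e-9)
  # the two-stage and mixed-model estimators broadly agree
  dfc <- dplyr::bind_rows(lapply(1:4, function(a) {
    d <- coupled_surrogate_series(40, coupling = 0.5, noise = 0.02,
                                  seed = 200 + a)
    d$animat_id <- a
    d$trial_id <- paste(a, d$trial_id)
    d
  }))
  f2 <- fluctuation_regression(dfc, method = "two_stage")
  fl <- fluctuation_regression(dfc, method = "lmer")
  expect_equal(f2$beta1, 0.5, tolerance = 0.1)
  expect_equal(fl$beta1, f2$beta1, tolerance = 0.1)
  expect_error(fluctuation_regression(dfc[1, ]), "fewer than 2")
})
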