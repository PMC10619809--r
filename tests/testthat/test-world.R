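# World geometry, trial enumeration and trial execution.

test_that("trial enumeration yields the full distinct trial sets", {
  hard <- enumerate_trials("hard")
  expect_equal(nrow(hard), 128L)
  easy <- enumerate_trials("easy")
  expect_equal(nrow(easy), 64L)
  # distinctness and 16 starting columns per (length, direction)
  key <- paste(hard$block_length, hard$direction, hard$init_col)
  expect_equal(anyDuplicated(key), 0L)
  one <- hard[hard$block_length == 6L & hard$direction == "left", ]
  expect_equal(nrow(one), 16L)
  expect_equal(sort(one$init_col), 0:15)
  # catch/avoid assignment follows the task definition
  expect_setequal(unique(hard$block_length[hard$trial_type == "catch"]),
                  c(3L, 6L))
  expect_setequal(unique(hard$block_length[hard$trial_type == "avoid"]),
                  c(4L, 5L))
  expect_error(enumerate_trials("medium"), "unknown task")
})

test_that("block advance moves one down, one sideways, with wraparound", {
  w <- world_new(15L, 1L, "right")
  w2 <- advance_block(w)
  expect_equal(w2$block_cols, 0L)
  expect_equal(w2$block_row, 1L)
  wl <- advance_block(world_new(0L, 1L, "left"))
  expect_equal(wl$block_cols, 15L)
  # 35 successive advances reach the bottom row, a 36th is an error
  w <- world_new(4L, 3L, "right")
  for (i in 1:35) w <- advance_block(w)
  expect_equal(w$block_row, 35L)
  expect_error(advance_block(w), "bottom")
})

test_that("sensors see the block only above the outermost animat cells", {
  # length-3 block exactly above the animat: both sensors on
  w <- world_new(0L, 3L, "right", animat_anchor = 0L)
  expect_equal(read_sensors(w), c(1L, 1L))
  # length-1 block above the middle cell: both off
  w <- world_new(1L, 1L, "right", animat_anchor = 0L)
  expect_equal(read_sensors(w), c(0L, 0L))
  # disjoint block: both off
  w <- world_new(8L, 4L, "left", animat_anchor = 0L)
  expect_equal(read_sensors(w), c(0L, 0L))
  # one-sided overlap under wraparound
  w <- world_new(14L, 3L, "right", animat_anchor = 0L)
  expect_equal(read_sensors(w), c(1L, 0L))
})

test_that("motors move the animat only when exactly one is on", {
  w <- world_new(5L, 1L, "right", animat_anchor = 4L)
  expect_equal(apply_motors(w, c(1L, 0L))$animat_anchor, 3L)
  expect_equal(apply_motors(w, c(0L, 1L))$animat_anchor, 5L)
  expect_equal(apply_motors(w, c(1L, 1L))$animat_anchor, 4L)
  expect_equal(apply_motors(w, c(0L, 0L))$animat_anchor, 4L)
  # wraparound on both sides
  expect_equal(apply_motors(world_new(0L, 1L, "left"),
                            c(1L, 0L))$animat_anchor, 15L)
})

test_that("trials run for 33 analyzed timesteps and are reproducible", {
  b <- random_test_brain(1)
  spec <- enumerate_trials("easy")[10, ]
  r1 <- run_trial(b, spec)
  expect_equal(nrow(r1), 33L)
  expect_equal(r1$t, 1:33)
  expect_identical(r1, run_trial(b, spec))
  # compiled and reference engines agree bitwise on a full trial set
  r_all <- run_trials(b, "easy", engine = "r")
  c_all <- run_trials(b, "easy", engine = "cpp")
  expect_identical(as.data.frame(r_all), as.data.frame(c_all))
})

test_that("an unconnected brain never moves and geometry is conserved", {
  recs <- run_trials(empty_brain(), "easy")
  expect_true(all(recs$animat_col == 0L))
  expect_true(all(recs[c("h1", "h2", "h3", "h4", "mL", "mR")] == 0L))
  # block row recorded at sensing time equals the analyzed step index
  expect_equal(recs$block_row, rep(1:33, 64))
})

test_that("motionless fitness equals the geometric overlap baseline", {
  # independent geometric oracle: the final block anchor after 35 steps
  for (task in c("easy", "hard")) {
    trials <- enumerate_trials(task)
    shift <- ifelse(trials$direction == "right", 35L, -35L)
    final_anchor <- (trials$init_col + shift) %% 16L
    caught <- mapply(function(a, l) {
      any(((a + 0:(l - 1L)) %% 16L) %in% 0:2)
    }, final_anchor, trials$block_length)
    expected <- mean(caught == (trials$trial_type == "catch"))
    expect_equal(fitness(empty_brain(), task), expected)
  }
  expect_gte(fitness(empty_brain(), "easy"), 0)
  expect_lte(fitness(empty_brain(), "easy"), 1)
})

test_that("mirroring brain, trial and start position mirrors the record", {
  for (seed in 1:3) {
    b <- random_test_brain(seed)
    mb <- mirror_brain(b)
    spec <- enumerate_trials("hard")[7L * seed, ]
    mspec <- spec
    mspec$direction <- ifelse(spec$direction == "right", "left", "right")
    mspec$init_col <- (16L - spec$init_col - spec$block_length) %% 16L
    r <- run_trial(b, spec, animat_anchor = 0L)
    mr <- run_trial(mb, mspec, animat_anchor = 13L)
    expect_identical(r$sL, mr$sR)
    expect_identical(r$sR, mr$sL)
    expect_identical(r$mL, mr$mR)
    expect_identical(r$caught, mr$caught)
    expect_identical(r$correct, mr$correct)
  }
})
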