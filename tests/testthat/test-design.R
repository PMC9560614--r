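test_that("default design reproduces the task structure", {
  d <- generate_experiment_design(seed = 1)
  expect_length(d$blocks, 11)
  n2 <- vapply(d$blocks, `[[`, integer(1), "n2")
  expect_identical(sum(n2 == 0), 2L)
  for (bl in d$blocks) {
    expect_length(bl$cs_ids, 5)
    expect_identical(length(unique(bl$cs_means)), 4L)
    expect_identical(sum(duplicated(bl$cs_means)), 1L)
    expect_identical(bl$n1 + bl$n2 + bl$n3, 27L)
    expect_true(bl$n1 %in% c(9L, 12L, 15L, 18L))
    expect_true(bl$n2 %in% c(0L, 5L, 10L, 15L))
    expect_identical(nrow(bl$pair_schedule), 27L)
    # four equally spaced levels centred on the block mean level
    lv <- sort(unique(bl$cs_means))
    expect_equal(mean(lv), bl$mean_level)
    expect_equal(unique(diff(lv)), bl$difficulty)
  }
  types <- vapply(d$blocks, `[[`, integer(1), "stimulus_type")
  expect_identical(as.integer(sort(table(types))), c(5L, 6L))
})

test_that("designs are reproducible and condition factors balanced", {
  d1 <- generate_experiment_design(seed = 42)
  d2 <- generate_experiment_design(seed = 42)
  expect_identical(design_trials(d1), design_trials(d2))
  expect_false(identical(design_trials(d1),
                         design_trials(generate_experiment_design(seed = 43))))

  for (seed in 1:25) {
    d <- generate_experiment_design(seed = seed)
    means <- vapply(d$blocks, `[[`, numeric(1), "mean_level")
    diffs <- vapply(d$blocks, `[[`, numeric(1), "difficulty")
    expect_true(max(table(means)) - min(table(means)) <= 1)
    expect_true(max(table(diffs)) - min(table(diffs)) <= 1)
    for (bl in d$blocks) {
      sched <- bl$pair_schedule
      expect_false(any(sched$left_cs == sched$right_cs))
      for (ph in unique(sched$phase)) {
        apps <- table(factor(
          c(sched$left_cs[sched$phase == ph],
            sched$right_cs[sched$phase == ph]),
          levels = bl$cs_ids
        ))
        expect_lte(max(apps) - min(apps), 2)
      }
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(design_config(n_blocks = 3, n_control = 5), "n_control")
  expect_error(
    generate_block_design(list(block_index = 1, stimulus_type = 0,
                               mean_level = 23, difficulty = 3,
                               n1 = 18, n2 = 15), seed = 1),
    "exceeds"
  )
  expect_error(build_pair_schedule("A", 5, 0, 0), "two CS")
  expect_error(draw_reward(55), "within")
  expect_error(draw_reward(0), "within")
})

test_that("block designs honour phase arithmetic and spacing modes", {
  bp <- list(block_index = 2, stimulus_type = 1, mean_level = 23,
             difficulty = 3, n1 = 18, n2 = 5)
  bl <- generate_block_design(bp, seed = 7)
  expect_identical(bl$n3, 4L)
  expect_setequal(sort(unique(bl$cs_means)), c(18.5, 21.5, 24.5, 27.5))

  ctrl <- generate_block_design(
    list(block_index = 1, stimulus_type = 0, mean_level = 18,
         difficulty = 6, n1 = 9, n2 = 0),
    seed = 3
  )
  expect_setequal(unique(ctrl$pair_schedule$phase), c(1L, 3L))

  # mean-pairwise interpretation: mean |pairwise difference| of the four
  # levels equals the difficulty
  cfg <- design_config(value_spacing = "mean_pairwise")
  bl2 <- generate_block_design(bp, seed = 7, config = cfg)
  lv <- sort(unique(bl2$cs_means))
  expect_equal(mean(abs(c(dist(lv)))), 3)
})

test_that("scratch-card rewards follow the truncated normal", {
  r <- draw_reward(23, n = 1e5, seed = 11)
  expect_true(all(r >= 0 & r <= 50))
  expect_true(all(r == round(r)))
  expect_lt(abs(mean(r) - 23), 0.5)
  # at mean 18 the lower truncation at 0 sits 1.8 SD away, biasing the
  # truncated mean upward by ~0.8 EUR; at 28 the bias is symmetric-small
  for (m in c(18, 28)) {
    expect_lt(abs(mean(draw_reward(m, n = 1e5, seed = m)) - m), 1.0)
  }
  expect_identical(draw_reward(23, n = 10, seed = 5),
                   draw_reward(23, n = 10, seed = 5))
})

test_that("pair schedules balance appearances within each phase", {
  sched <- build_pair_schedule(LETTERS[1:5], 0, 10, 0, seed = 9)
  apps <- table(factor(c(sched$left_cs, sched$right_cs),
                       levels = LETTERS[1:5]))
  expect_identical(sum(apps), 20L)
  expect_true(all(apps >= 3 & apps <= 5))
  expect_identical(build_pair_schedule(LETTERS[1:5], 9, 5, 13, seed = 2),
                   build_pair_schedule(LETTERS[1:5], 9, 5, 13, seed = 2))
})
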