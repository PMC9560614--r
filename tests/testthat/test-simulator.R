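test_that("model confidence maps choice probability to the rating scale", {
  expect_equal(model_confidence(0.5), 0)
  expect_equal(model_confidence(1), 1)
  expect_equal(model_confidence(0.3), 0)
  expect_equal(model_confidence(0.75), 0.5)
  expect_error(model_confidence(1.2), "probability")
})

test_that("simulated subjects honour the trial-record contract", {
  design <- generate_experiment_design(seed = 5)
  p <- list(alpha_r = 0.2, beta = 0.2, alpha_c = 0.5, gamma = 8)
  s <- simulate_subject("ConfUnspec", p, design, seed = 6,
                        keep_latents = TRUE)
  expect_identical(nrow(s), 11L * 27L)
  expect_true(all(s$reward_observed[s$phase %in% c(1, 3)]))
  expect_false(any(s$reward_observed[s$phase == 2]))
  expect_true(all(is.finite(s$reward)))       # drawn on every trial
  expect_true(all(s$reward >= 0 & s$reward <= 50))
  expect_true(all(s$confidence >= 0 & s$confidence <= 1))
  expect_equal(s$confidence_raw, s$confidence * 10)
  # confidence is 0 whenever the sampled choice went against the model
  expect_true(all(s$confidence[s$p_chosen <= 0.5] == 0))
  expect_equal(s$confidence, model_confidence(s$p_chosen))
  # correctness undefined exactly for equal-value pairs
  expect_identical(is.na(s$correct), s$left_value == s$right_value)

  s2 <- simulate_subject("ConfUnspec", p, design, seed = 6,
                         keep_latents = TRUE)
  expect_identical(s, s2)
  expect_identical(attr(s, "latents"), attr(s2, "latents"))
})

test_that("choice sampling is calibrated to the softmax probabilities", {
  # with beta = 0 every choice probability is 0.5; the sampled right-rate
  # over many trials must match
  design <- generate_experiment_design(seed = 8)
  s <- purrr::map_dfr(1:40, function(i) {
    simulate_subject("Static", list(alpha_r = 0.3, beta = 0),
                     design, seed = 100 + i)
  })
  expect_true(all(s$p_right == 0.5))
  expect_lt(abs(mean(s$chosen_side == "right") - 0.5), 0.01)
})

test_that("cohorts derive distinct, reproducible subjects", {
  p <- list(alpha_r = 0.2, beta = 0.2)
  co <- simulate_cohort("Static", p, 3, config = small_design_config(),
                        seed = 7)
  expect_identical(dplyr::n_distinct(co$subject_id), 3L)
  pairs <- split(paste(co$left_cs, co$right_cs, co$trial), co$subject_id)
  expect_gt(length(unique(pairs)), 1)
  co2 <- simulate_cohort("Static", p, 3, config = small_design_config(),
                         seed = 7)
  expect_identical(co, co2)
  expect_error(simulate_cohort("Static", p, 0, seed = 1), "at least 1")
})

test_that("self-reinforcement raises confidence across phase 2", {
  co <- simulate_cohort(
    "ConfUnspec",
    list(alpha_r = 0.2, beta = 0.2, alpha_c = 0.5, gamma = 30),
    100, seed = 21
  )
  p2 <- co |>
    dplyr::filter(phase == 2, n2 >= 10) |>
    dplyr::group_by(subject_id, block) |>
    dplyr::mutate(idx = dplyr::row_number(), third = cut(
      idx, breaks = c(0, dplyr::n() / 3, 2 * dplyr::n() / 3, dplyr::n()),
      labels = c("first", "mid", "last")
    )) |>
    dplyr::ungroup()
  m <- tapply(p2$confidence, p2$third, mean)
  expect_gt(m[["last"]], m[["first"]])
})

test_that("positive transfer keeps the phase-2 value spread growing", {
  co <- simulate_cohort(
    "ConfUnspec",
    list(alpha_r = 0.2, beta = 0.2, alpha_c = 0.5, gamma = 8),
    60, seed = 31, keep_latents = TRUE
  )
  lat <- attr(co, "latents") |>
    dplyr::filter(phase == 2, n2 >= 10) |>
    dplyr::group_by(subject_id, block, trial) |>
    dplyr::summarise(spread = max(v_bar) - min(v_bar),
                     idx = trial[1] - n1[1], .groups = "drop") |>
    dplyr::group_by(subject_id, block) |>
    dplyr::summarise(first = spread[which.min(idx)],
                     last = spread[which.max(idx)], .groups = "drop")
  expect_gt(mean(lat$last), mean(lat$first))
})

test_that("latent time courses reduce to raw latents for one block", {
  cfg <- design_config(n_blocks = 1, n_control = 0,
                       phase1_lengths = 9L, phase2_lengths = 10L)
  design <- generate_experiment_design(cfg, seed = 3)
  s <- simulate_subject("Static", list(alpha_r = 0.3, beta = 0.4), design,
                        seed = 4, keep_latents = TRUE)
  tc <- latent_timecourses(s)
  lat <- attr(s, "latents")
  one <- tc$values[tc$values$value_rank == 2 & tc$values$time == 0, ]
  raw <- lat |>
    dplyr::group_by(trial) |>
    dplyr::mutate(rank = dplyr::dense_rank(cs_value)) |>
    dplyr::filter(rank == 2, trial == n1)
  expect_equal(one$v_bar, mean(raw$v_bar))

  # static values: v_bar constant across phase 2
  p2 <- lat[lat$phase == 2, ]
  expect_true(all(tapply(p2$v_bar, p2$cs, function(v) max(v) - min(v)) == 0))
  expect_error(latent_timecourses(s[0, ]), "empty")
})
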