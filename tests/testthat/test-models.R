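test_that("softmax choice rule matches direct evaluation", {
  expect_equal(softmax_choice_prob(0.7, 5, 5), 0.5)
  expect_equal(softmax_choice_prob(0, 40, -3), 0.5)
  expect_equal(softmax_choice_prob(0.2, 6, 0), 1 / (1 + exp(-1.2)))
  # numerically stable far into the tails
  expect_equal(softmax_choice_prob(2, 350, 0), 1)
  expect_gt(softmax_choice_prob(2, 0, 350), 0)
  expect_error(softmax_choice_prob(0.2, Inf, 0), "finite")
  expect_error(softmax_choice_prob(-1, 1, 0), "non-negative")
})

test_that("perseveration rule adds the previous-choice bias", {
  expect_equal(perseveration_choice_prob(0.3, 0, 4, 1, 1, 0),
               softmax_choice_prob(0.3, 4, 1))
  expect_equal(perseveration_choice_prob(0.3, 1.5, 2, 2, 0, 0), 0.5)
  expect_equal(perseveration_choice_prob(0.2, 0.73, 3, 3, 1, 0),
               1 / (1 + exp(-0.146)))
  expect_error(perseveration_choice_prob(0.2, 0.5, 1, 1, 1, 1),
               "previous-choice")
})

test_that("reward update follows the Rescorla-Wagner rule", {
  st <- learner_state(c("A", "B"))
  expect_identical(update_value_reward(st, "A", 20, 0)$v_bar, st$v_bar)
  st5 <- update_value_reward(st, "A", 20, 0.25)
  expect_equal(unname(st5$v_bar["A"]), 5)
  expect_equal(unname(st5$v_bar["B"]), 0)
  expect_equal(update_value_reward(st5, "A", 5, 0.9)$v_bar[["A"]], 5)
  expect_error(update_value_reward(st, "C", 1, 0.1), "Unknown CS")
})

test_that("expected-confidence update returns the pre-update CPE", {
  st <- learner_state(c("A", "B"), conf_specific = TRUE)
  st$c_bar["A"] <- 0.5
  up <- update_expected_confidence(st, "A", 0.8, 0.14, "per-CS")
  expect_equal(up$delta_c, 0.3)
  expect_equal(unname(up$state$c_bar["A"]), 0.542)
  expect_equal(unname(up$state$c_bar["B"]), 0)

  g <- learner_state(c("A", "B"))
  up0 <- update_expected_confidence(g, "A", 0.7, 0, "global")
  expect_equal(up0$delta_c, 0.7)
  expect_equal(up0$state$c_bar, 0)
  same <- update_expected_confidence(g, "B", 0, 0.5, "global")
  expect_equal(same$delta_c, 0)
  expect_equal(same$state$c_bar, 0)
  expect_error(update_expected_confidence(g, "A", 1.2, 0.1), "\\[0, 1\\]")
})

test_that("no-feedback value updates match their closed forms", {
  st <- learner_state(c("A", "B"))
  st$v_bar["A"] <- 3

  expect_equal(
    transfer_confidence_to_value(st, "A", 0.3, 8)$v_bar[["A"]], 5.4
  )
  expect_equal(transfer_confidence_to_value(st, "A", 0, 8)$v_bar[["A"]], 3)
  expect_equal(transfer_confidence_to_value(st, "A", 0.3, 0)$v_bar[["A"]], 3)
  expect_error(transfer_confidence_to_value(st, "A", 0.3, 8, phase = 1),
               "phase 2")

  expect_equal(update_value_choice(st, "A", 0.97)$v_bar[["A"]], 3.97)
  twice <- update_value_choice(update_value_choice(st, "A", 0.97), "A", 0.97)
  expect_equal(twice$v_bar[["A"]], 3 + 2 * 0.97)
  expect_error(update_value_choice(st, "A", 1, phase = 3), "phase 2")

  st$v_bar["A"] <- 10
  expect_equal(update_value_deval(st, "A", 0.1)$v_bar[["A"]], 9)
  expect_equal(update_value_deval(st, "A", 0)$v_bar[["A"]], 10)
  st$v_bar["A"] <- 0
  expect_equal(update_value_deval(st, "A", 0.7)$v_bar[["A"]], 0)
})

test_that("step_trial composes the equations per model and phase", {
  ctx2 <- list(phase = 2, left_cs = "A", right_cs = "B", mode = "generative")
  obs <- list(chosen_cs = "A", confidence = 0.8, reward = NA,
              reward_observed = FALSE)

  st <- learner_state(c("A", "B"))
  out <- step_trial("Static", c(alpha_r = 0.3, beta = 0.5), st, ctx2, obs)
  expect_identical(out$state$v_bar, st$v_bar)

  # composed confidence transfer: c_bar 0.5, confidence 0.8, gamma 8
  st$c_bar <- 0.5
  st$v_bar["A"] <- 3
  out <- step_trial(
    "ConfUnspec",
    c(alpha_r = 0.3, beta = 0.5, alpha_c = 0.14, gamma = 8),
    st, ctx2, obs
  )
  expect_equal(out$delta_c, 0.3)
  expect_equal(unname(out$state$v_bar["A"]), 5.4)
  expect_equal(out$state$c_bar, 0.542)

  # feedback phases require an observed reward and apply the reward rule
  ctx1 <- list(phase = 1, left_cs = "A", right_cs = "B", mode = "generative")
  expect_error(step_trial("Static", c(alpha_r = 0.3, beta = 0.5),
                          learner_state(c("A", "B")), ctx1, obs),
               "observed reward")
  expect_error(
    step_trial("Static", c(alpha_r = 0.3, beta = 0.5),
               learner_state(c("A", "B")), ctx2,
               list(chosen_cs = "A", confidence = 0.5, reward = 10,
                    reward_observed = TRUE)),
    "Phase-2"
  )
})

test_that("models with zeroed extra parameters collapse onto Static", {
  nested <- list(
    Deval = list(alpha_d = 0),
    Choice = list(lambda = 0),
    ConfSpec = list(alpha_c = 0.3, gamma = 0),
    ConfUnspec = list(alpha_c = 0.3, gamma = 0),
    Perseveration = list(eta = 0)
  )
  set.seed(101)
  for (i in 1:10) {
    base <- list(alpha_r = runif(1), beta = runif(1, 0, 2))
    trials <- small_subject("Static", base, seed = 300 + i)
    ref <- negative_log_likelihood(trials, "Static", base)
    for (m in names(nested)) {
      expect_identical(
        negative_log_likelihood(trials, m, c(base, nested[[m]])), ref
      )
    }
  }
})

test_that("specific and unspecific confidence agree when one CS is chosen", {
  trials <- fixture_trials()
  trials$chosen_cs <- rep("A", 4)
  trials$chosen_value <- trials$left_value * (trials$left_cs == "A") +
    trials$right_value * (trials$right_cs == "A")
  p <- list(alpha_r = 0.3, beta = 0.4, alpha_c = 0.5, gamma = 4)
  expect_equal(negative_log_likelihood(trials, "ConfSpec", p),
               negative_log_likelihood(trials, "ConfUnspec", p))
})

test_that("expected confidence stays in [0,1] and values stay finite", {
  set.seed(77)
  for (m in c("ConfSpec", "ConfUnspec")) {
    p <- random_params(m)
    trials <- small_subject(m, p, seed = 555)
    st <- learner_state(unique(c(trials$left_cs, trials$right_cs)),
                        conf_specific = m == "ConfSpec")
    for (i in which(trials$block == trials$block[1])) {
      fb <- trials$phase[i] %in% c(1, 3)
      out <- step_trial(
        m, unlist(p), st,
        list(phase = trials$phase[i], left_cs = trials$left_cs[i],
             right_cs = trials$right_cs[i], mode = "generative"),
        list(chosen_cs = trials$chosen_cs[i],
             confidence = trials$confidence[i],
             reward = if (fb) trials$reward[i] else NA,
             reward_observed = fb)
      )
      st <- out$state
      expect_true(all(st$c_bar >= 0 & st$c_bar <= 1))
      expect_true(all(is.finite(st$v_bar)))
      expect_true(out$p_right > 0 && out$p_right < 1)
    }
  }
})

test_that("parameter sets are validated against their bounds", {
  expect_identical(length(active_params("Static")), 2L)
  expect_identical(length(active_params("Deval")), 3L)
  expect_identical(length(active_params("Choice")), 3L)
  expect_identical(length(active_params("Perseveration")), 3L)
  expect_identical(length(active_params("ConfSpec")), 4L)
  expect_identical(length(active_params("ConfUnspec")), 4L)

  expect_error(validate_params("Static", list(alpha_r = 0.5)), "Missing")
  expect_error(validate_params("Static", list(alpha_r = 1.5, beta = 1)),
               "out of bounds")
  expect_error(validate_params("Perseveration",
                               list(alpha_r = 0.5, beta = 1, eta = 9)),
               "out of bounds")
  # inactive extras are dropped
  ok <- validate_params("Static", list(alpha_r = 0.5, beta = 1, gamma = 3))
  expect_named(ok, c("alpha_r", "beta"))
})
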