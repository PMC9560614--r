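# Minimal hand-built phase-2 trial tables for closed-form checks.
p2_table <- function(correct, confidence, chosen = NULL, pairs = NULL,
                     values = NULL) {
  n <- max(length(correct), length(confidence))
  tibble::tibble(
    subject_id = "S1",
    block = 1L,
    trial = seq_len(n) - 1L,
    phase = 2L,
    left_cs = if (is.null(pairs)) "A" else pairs$left,
    right_cs = if (is.null(pairs)) "B" else pairs$right,
    chosen_cs = if (is.null(chosen)) "A" else chosen,
    chosen_value = if (is.null(values)) 20 else values,
    left_value = 20, right_value = 25,
    correct = correct,
    confidence = confidence
  )
}

test_that("performance slope matches closed-form least squares", {
  t1 <- p2_table(correct = c(FALSE, FALSE, TRUE, TRUE),
                 confidence = rep(0.5, 4))
  expect_equal(performance_effect(t1)$estimate, 0.4)
  t2 <- p2_table(correct = rep(TRUE, 4), confidence = rep(0.5, 4))
  expect_equal(performance_effect(t2)$estimate, 0)
  expect_error(performance_effect(dplyr::mutate(t1, phase = 1L)),
               "phase-2")
})

test_that("confidence slope matches closed-form least squares", {
  t1 <- p2_table(correct = rep(TRUE, 3),
                 confidence = c(0.2, 0.4, 0.6))
  expect_equal(confidence_effect(t1)$estimate, 0.2)
  t2 <- p2_table(correct = rep(TRUE, 3), confidence = rep(0.7, 3))
  expect_equal(confidence_effect(t2)$estimate, 0)
})

test_that("confidence-by-value interaction matches a direct regression", {
  # four CS with confidence slopes 0, .01, .02, .03 at values
  # 18.5, 21.5, 24.5, 27.5 -> regression coefficient .01/3 per euro
  slopes <- c(0, 0.01, 0.02, 0.03)
  values <- c(18.5, 21.5, 24.5, 27.5)
  rows <- purrr::map_dfr(1:4, function(i) {
    tibble::tibble(
      chosen_cs = LETTERS[i],
      chosen_value = values[i],
      confidence = 0.5 + slopes[i] * (0:2)
    )
  })
  n <- nrow(rows)
  tab <- tibble::tibble(
    subject_id = "S1", block = 1L, trial = seq_len(n) - 1L, phase = 2L,
    left_cs = rows$chosen_cs, right_cs = "Z",
    chosen_cs = rows$chosen_cs, chosen_value = rows$chosen_value,
    left_value = rows$chosen_value, right_value = 99,
    correct = TRUE, confidence = rows$confidence
  )
  # CS-wise slopes are computed on the global phase-2 index, so interleave
  # the rows so that each CS's choices are consecutive index triples
  tab <- tab[order(rep(1:4, each = 3)), ]
  tab$trial <- seq_len(n) - 1L
  res <- confidence_value_effect(tab)
  # each CS occupies indices (3k, 3k+1, 3k+2): its slope is unchanged
  expect_equal(res$estimate, 0.01 / 3)

  flat <- dplyr::mutate(tab, confidence = 0.5)
  expect_equal(confidence_value_effect(flat)$estimate, 0)
  one_each <- tab[c(1, 4, 7, 10), ]
  expect_error(confidence_value_effect(one_each), "at least two")
})

test_that("consistency effect counts pair-repetition transitions", {
  mk <- function(chosen) {
    p2_table(correct = rep(TRUE, length(chosen)),
             confidence = rep(0.5, length(chosen)), chosen = chosen)
  }
  expect_equal(consistency_effect(mk(c("A", "A", "B")))$estimate, -1)
  expect_equal(consistency_effect(mk(c("A", "A", "A", "A")))$estimate, 0)
  two <- mk(c("A", "B"))
  expect_error(consistency_effect(two), "three times")
})

test_that("effect_estimates stacks all four statistics", {
  co <- simulate_cohort(
    "ConfUnspec",
    list(alpha_r = 0.2, beta = 0.2, alpha_c = 0.5, gamma = 8),
    12, seed = 71
  )
  est <- effect_estimates(co)
  expect_identical(est$effect,
                   c("performance", "confidence", "confidence_value",
                     "consistency"))
  expect_true(all(is.finite(est$estimate)))
  expect_true(all(est$sem >= 0))
})

test_that("sweep grids have the documented shapes", {
  expect_identical(nrow(default_sweep("ConfUnspec")), 24L)
  expect_identical(nrow(default_sweep("ConfSpec")), 24L)
  expect_identical(nrow(default_sweep("Choice")), 7L)
  expect_identical(nrow(default_sweep("Perseveration")), 7L)
  sw <- run_generative_sweep("Perseveration", n_datasets = 4, seed = 3,
                             sweep = tibble::tibble(eta = c(0, 1)))
  expect_identical(nrow(sw), 8L)  # 2 nodes x 4 effects
  expect_true(all(c("eta", "effect", "estimate", "sem") %in% names(sw)))
})

test_that("power analysis validates its inputs and degenerate level", {
  expect_error(power_analysis(n_replications = 0), "at least 1")
  expect_error(power_analysis(model = "Static"), "non-static")
  pw <- power_analysis(
    n_subjects = 4, n_replications = 2, alpha = 1, seed = 5,
    config = small_design_config(),
    params = list(alpha_r = 0.1, alpha_c = 0.1, beta = 1 / 3, gamma = 1)
  )
  expect_equal(pw$power, 1)
  expect_identical(nrow(pw$replications), 2L)
})
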