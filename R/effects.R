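# Behavioral/generative effect statistics, parameter sweeps and power
# simulation.

# Add the 0-based within-phase-2 trial index per (subject, block).
add_phase2_index <- function(trials) {
  if (!"subject_id" %in% names(trials)) trials$subject_id <- "S1"
  trials |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::mutate(
      p2_index = dplyr::if_else(
        .data$phase == 2L,
        cumsum(.data$phase == 2L) - 1L, NA_integer_
      )
    ) |>
    dplyr::ungroup()
}

phase2_or_die <- function(trials) {
  trials <- add_phase2_index(trials)
  p2 <- dplyr::filter(trials, .data$phase == 2L)
  if (nrow(p2) == 0) abort("No phase-2 trials in the table.")
  p2
}

# Mean of per-subject values with SEM across subjects, as a one-row tibble.
effect_row <- function(effect, per_subject) {
  x <- per_subject[is.finite(per_subject)]
  tibble::tibble(effect = effect, estimate = mean(x), sem = sem(x),
                 n = length(x))
}

#' Performance effect
#'
#' Average least-squares slope of the correctness of choices (0/1) on the
#' within-phase-2 trial index: computed per block, averaged over blocks per
#' subject and then over subjects. Trials pairing two equal-valued CS are
#' excluded (correctness undefined).
#'
#' @param trials A trial tibble with phase-2 trials.
#' @return A one-row tibble: `effect`, `estimate` (slope, proportion correct
#'   per trial), `sem` (across subjects/datasets), `n`.
#' @export
performance_effect <- function(trials) {
  p2 <- phase2_or_die(trials) |> dplyr::filter(!is.na(.data$correct))
  per_subject <- p2 |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::summarise(
      slope = ols_slope(.data$p2_index, as.numeric(.data$correct)),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(value = mean(.data$slope, na.rm = TRUE),
                     .groups = "drop")
  effect_row("performance", per_subject$value)
}

#' Confidence effect
#'
#' As [performance_effect()] but for normalized confidence: the average
#' least-squares slope of confidence across phase-2 trials.
#'
#' @inheritParams performance_effect
#' @return A one-row tibble (slope in confidence units per trial).
#' @export
confidence_effect <- function(trials) {
  p2 <- phase2_or_die(trials)
  per_subject <- p2 |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::summarise(
      slope = ols_slope(.data$p2_index, .data$confidence),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(value = mean(.data$slope, na.rm = TRUE),
                     .groups = "drop")
  effect_row("confidence", per_subject$value)
}

#' Confidence-by-value effect
#'
#' Within each block, the confidence slope across phase-2 trials is computed
#' per chosen CS (requiring at least two choices of that CS); those CS-wise
#' slopes are regressed on the CS mean values, and the regression coefficient
#' is averaged over blocks and subjects. A positive effect means confidence
#' rises faster for more valuable CS.
#'
#' @inheritParams performance_effect
#' @return A one-row tibble (slope units per euro).
#' @export
confidence_value_effect <- function(trials) {
  p2 <- phase2_or_die(trials)
  cs_slopes <- p2 |>
    dplyr::group_by(.data$subject_id, .data$block, .data$chosen_cs) |>
    dplyr::summarise(
      slope = ols_slope(.data$p2_index, .data$confidence),
      value = .data$chosen_value[1],
      n_choices = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_choices >= 2, is.finite(.data$slope))
  if (nrow(cs_slopes) == 0) {
    abort("No CS with at least two phase-2 choices.")
  }
  per_subject <- cs_slopes |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::summarise(coef = ols_slope(.data$value, .data$slope),
                     .groups = "drop_last") |>
    dplyr::summarise(value = mean(.data$coef, na.rm = TRUE),
                     .groups = "drop")
  effect_row("confidence_value", per_subject$value)
}

#' Consistency effect
#'
#' For every unordered CS pair encountered at least three times within a
#' block's phase 2, the choice is compared between the pair's first and
#' second occurrence and between its second and third occurrence. The effect
#' is `p23 - p12`: the change in the proportion of consistently repeated
#' choices from the first to the second transition, averaged over subjects.
#'
#' @inheritParams performance_effect
#' @return A one-row tibble (difference of proportions).
#' @export
consistency_effect <- function(trials) {
  p2 <- phase2_or_die(trials) |>
    dplyr::mutate(pair = pair_key(.data$left_cs, .data$right_cs))
  reps <- p2 |>
    dplyr::arrange(.data$subject_id, .data$block, .data$trial) |>
    dplyr::group_by(.data$subject_id, .data$block, .data$pair) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(
      cons12 = .data$chosen_cs[1] == .data$chosen_cs[2],
      cons23 = .data$chosen_cs[2] == .data$chosen_cs[3],
      .groups = "drop"
    )
  if (nrow(reps) == 0) {
    abort("No CS pair occurs three times within a block's phase 2.")
  }
  per_subject <- reps |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(value = mean(.data$cons23) - mean(.data$cons12),
                     .groups = "drop")
  effect_row("consistency", per_subject$value)
}

#' All four effect statistics at once
#'
#' @inheritParams performance_effect
#' @return A four-row tibble stacking [performance_effect()],
#'   [confidence_effect()], [confidence_value_effect()] and
#'   [consistency_effect()].
#' @export
effect_estimates <- function(trials) {
  dplyr::bind_rows(
    performance_effect(trials),
    confidence_effect(trials),
    confidence_value_effect(trials),
    consistency_effect(trials)
  )
}

#' Default generative sweep grids
#'
#' The parameter grids over which generative performance is assessed:
#' `alpha_c` in \{0, 0.5, 1\} crossed with `log(gamma)` in 8 equidistant
#' steps over \[0, 4\] for the confidence models; `lambda` over 7 exponential
#' steps in \[0.5, 10\] for `Choice`; `eta` from -1.5 to 1.5 in steps of 0.5
#' for `Perseveration`.
#'
#' @param model A model name (one of the four dynamic phase-2 models).
#' @return A tibble of sweep nodes (one column per swept parameter).
#' @export
default_sweep <- function(model) {
  model <- match.arg(model, c("ConfUnspec", "ConfSpec", "Choice",
                              "Perseveration"))
  switch(model,
    ConfUnspec = ,
    ConfSpec = tidyr::expand_grid(
      alpha_c = c(0, 0.5, 1),
      gamma = exp(seq(0, 4, length.out = 8))
    ),
    Choice = tibble::tibble(
      lambda = exp(seq(log(0.5), log(10), length.out = 7))
    ),
    Perseveration = tibble::tibble(eta = seq(-1.5, 1.5, by = 0.5))
  )
}

#' Generative-performance parameter sweep
#'
#' Simulates cohorts at every node of a sweep grid (reward learning rate and
#' inverse decision noise fixed at 0.2, which shape only the feedback phases)
#' and computes the four effect statistics with SEM across simulated
#' datasets.
#'
#' @param model One of `ConfUnspec`, `ConfSpec`, `Choice`, `Perseveration`.
#' @param n_datasets Simulated datasets (subjects) per node.
#' @param seed Master seed.
#' @param sweep Sweep grid; defaults to [default_sweep()].
#' @param alpha_r,beta Fixed feedback-phase parameters.
#' @param config A [design_config()].
#' @return A tibble with one row per node and effect: the node's swept
#'   parameters plus `effect`, `estimate`, `sem`, `n`.
#' @export
run_generative_sweep <- function(model, n_datasets = 250, seed = 1L,
                                 sweep = default_sweep(model),
                                 alpha_r = 0.2, beta = 0.2,
                                 config = design_config()) {
  model <- match.arg(model, c("ConfUnspec", "ConfSpec", "Choice",
                              "Perseveration"))
  seeds <- derive_seeds(seed, nrow(sweep))
  purrr::map_dfr(seq_len(nrow(sweep)), function(i) {
    params <- c(list(alpha_r = alpha_r, beta = beta),
                as.list(sweep[i, , drop = FALSE]))
    trials <- simulate_cohort(model, params, n_datasets, config = config,
                              seed = seeds[i])
    dplyr::bind_cols(sweep[i, ], effect_estimates(trials))
  })
}

#' Forward power simulation for model dissociation
#'
#' Repeatedly simulates cohorts from a generative model, fits both the
#' generative model and the static reference model to every subject, and
#' tests whether a two-tailed paired t-test on per-subject AIC separates the
#' two at level `alpha`. Returns the fraction of significant replications.
#' Default parameters are the educated guesses used when planning the sample
#' size: `alpha_r = 0.1`, `alpha_c = 0.1`, `beta = 1/3`, `gamma = 1`.
#'
#' @param n_subjects Subjects per replication.
#' @param model Generative (non-static) model.
#' @param params Generative parameters.
#' @param n_replications Number of replications (`>= 1`).
#' @param alpha Test level.
#' @param seed Master seed.
#' @param config A [design_config()].
#' @param fit_config A [fitting_config()].
#' @return A list of class `confrl_power`: `power` (fraction significant),
#'   `replications` (per-replication tibble with `t`, `p`, `mean_aic_diff`),
#'   `alpha`.
#' @export
power_analysis <- function(n_subjects = 64, model = "ConfUnspec",
                           params = list(alpha_r = 0.1, alpha_c = 0.1,
                                         beta = 1 / 3, gamma = 1),
                           n_replications = 10, alpha = 0.05, seed = 1L,
                           config = design_config(),
                           fit_config = fitting_config()) {
  if (n_replications < 1) abort("`n_replications` must be at least 1.")
  if (model == "Static") abort("The generative model must be non-static.")
  seeds <- derive_seeds(seed, n_replications)
  reps <- purrr::map_dfr(seq_len(n_replications), function(r) {
    trials <- simulate_cohort(model, params, n_subjects, config = config,
                              seed = seeds[r])
    fits <- fit_models(trials, models = c(model, "Static"),
                       config = fit_config)
    wide <- fits |>
      dplyr::select("subject_id", "model", "aic") |>
      tidyr::pivot_wider(names_from = "model", values_from = "aic")
    d <- wide[[model]] - wide[["Static"]]
    tt <- t.test(d)
    tibble::tibble(replication = r, t = unname(tt$statistic),
                   p = tt$p.value, mean_aic_diff = mean(d))
  })
  structure(
    list(power = mean(reps$p < alpha), replications = reps, alpha = alpha,
         model = model, n_subjects = n_subjects),
    class = "confrl_power"
  )
}

#' @export
print.confrl_power <- function(x, ...) {
  cat(sprintf(
    "<confrl_power> %s vs Static, n = %d: power %.2f (alpha %.2f, %d reps)\n",
    x$model, x$n_subjects, x$power, x$alpha, nrow(x$replications)
  ))
  invisible(x)
}
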