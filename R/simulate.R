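# Forward simulation of synthetic subjects from any model and parameter set.

#' Model-derived confidence
#'
#' Maps the choice probability of the chosen CS to the normalized confidence
#' scale: `max(0, 2 * (p_chosen - 0.5))`. A sampled choice made against the
#' model's preference (`p_chosen < 0.5`) yields confidence 0 (guessing).
#'
#' @param p_chosen Probability the model assigned to the chosen CS.
#' @return Normalized confidence in \[0, 1\].
#' @export
model_confidence <- function(p_chosen) {
  if (any(!is.finite(p_chosen)) || any(p_chosen < 0) || any(p_chosen > 1)) {
    abort("`p_chosen` must be a probability.")
  }
  pmax(0, 2 * (p_chosen - 0.5))
}

#' Simulate one subject
#'
#' Plays a full experiment from a generative model: on each trial the choice
#' probability is computed from the current state (perseveration bias in
#' phase 2 for the `Perseveration` model), a choice is sampled, confidence is
#' set to the model confidence of the sampled choice, a reward is drawn for
#' the chosen CS (observed only in feedback phases) and the state is advanced
#' with [step_trial()] in generative mode (phase-2 updates target the sampled
#' choice). Latent variables are logged before the update.
#'
#' @param model A model name from [model_kinds()].
#' @param params Named parameters for the model.
#' @param design A `confrl_design` from [generate_experiment_design()].
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param subject_id Subject identifier stored in the table.
#' @param keep_latents Attach a per-trial, per-CS latent table as the
#'   `"latents"` attribute.
#' @param discretize_confidence Round confidence to the 11-point 0-10 scale.
#'
#' @return A tibble with one row per trial (columns `subject_id`, `block`,
#'   `trial`, `phase`, `left_cs`, `right_cs`, `left_value`, `right_value`,
#'   `chosen_side`, `chosen_cs`, `chosen_value`, `reward`, `reward_observed`,
#'   `confidence_raw`, `confidence`, `correct`, `p_right`, `p_chosen`,
#'   `delta_c`, `c_bar`, `n1`, `n2`). When `keep_latents = TRUE` the
#'   `"latents"` attribute holds a long tibble of pre-update expected values
#'   (and per-CS expected confidence for `ConfSpec`).
#' @export
simulate_subject <- function(model, params, design, seed = NULL,
                             subject_id = "S1", keep_latents = FALSE,
                             discretize_confidence = FALSE) {
  model <- match.arg(model, model_kinds())
  params <- validate_params(model, params)
  stopifnot(inherits(design, "confrl_design"))
  cfg <- design$config

  local_seed(seed, {
    n_total <- sum(vapply(design$blocks, function(b) nrow(b$pair_schedule),
                          integer(1)))
    out <- list(
      block = integer(n_total), trial = integer(n_total),
      phase = integer(n_total),
      left_cs = character(n_total), right_cs = character(n_total),
      left_value = numeric(n_total), right_value = numeric(n_total),
      chosen_side = character(n_total), chosen_cs = character(n_total),
      chosen_value = numeric(n_total),
      reward = numeric(n_total), reward_observed = logical(n_total),
      confidence = numeric(n_total),
      p_right = numeric(n_total), p_chosen = numeric(n_total),
      delta_c = numeric(n_total), c_bar = numeric(n_total),
      n1 = integer(n_total), n2 = integer(n_total)
    )
    lat <- if (keep_latents) vector("list", length(design$blocks)) else NULL

    i <- 0L
    for (bl in design$blocks) {
      state <- learner_state(bl$cs_ids, conf_specific = model == "ConfSpec")
      sched <- bl$pair_schedule
      if (keep_latents) {
        nb <- nrow(sched)
        lv <- matrix(NA_real_, nb, length(bl$cs_ids))
        lc <- matrix(NA_real_, nb, length(bl$cs_ids))
      }
      for (t in seq_len(nrow(sched))) {
        i <- i + 1L
        left <- sched$left_cs[t]
        right <- sched$right_cs[t]
        phase <- sched$phase[t]

        if (keep_latents) {
          lv[t, ] <- state$v_bar
          lc[t, ] <- if (model == "ConfSpec") state$c_bar else state$c_bar[[1]]
        }

        key <- pair_key(left, right)
        p_right <- if (model == "Perseveration" && phase == 2 &&
                         key %in% names(state$prev_choice)) {
          prev <- state$prev_choice[[key]]
          perseveration_choice_prob(
            params[["beta"]], params[["eta"]],
            state$v_bar[[right]], state$v_bar[[left]],
            as.numeric(prev == right), as.numeric(prev == left)
          )
        } else {
          softmax_choice_prob(params[["beta"]], state$v_bar[[right]],
                              state$v_bar[[left]])
        }

        go_right <- runif(1) < p_right
        chosen <- if (go_right) right else left
        p_chosen <- if (go_right) p_right else 1 - p_right
        conf <- model_confidence(p_chosen)
        if (discretize_confidence) conf <- round(conf * 10) / 10
        reward <- draw_reward(bl$cs_means[[chosen]], sd = cfg$reward_sd,
                              range = cfg$reward_range)
        observed <- phase %in% c(1L, 3L)

        st <- step_trial(
          model, params, state,
          context = list(phase = phase, left_cs = left, right_cs = right,
                         mode = "generative"),
          observation = list(chosen_cs = chosen, confidence = conf,
                             reward = if (observed) reward else NA_real_,
                             reward_observed = observed)
        )
        cb_pre <- if (model == "ConfSpec") {
          state$c_bar[[chosen]]
        } else if (model == "ConfUnspec") {
          state$c_bar[[1]]
        } else {
          NA_real_
        }
        state <- st$state

        out$block[i] <- bl$block_index
        out$trial[i] <- sched$trial[t]
        out$phase[i] <- phase
        out$left_cs[i] <- left
        out$right_cs[i] <- right
        out$left_value[i] <- bl$cs_means[[left]]
        out$right_value[i] <- bl$cs_means[[right]]
        out$chosen_side[i] <- if (go_right) "right" else "left"
        out$chosen_cs[i] <- chosen
        out$chosen_value[i] <- bl$cs_means[[chosen]]
        out$reward[i] <- reward
        out$reward_observed[i] <- observed
        out$confidence[i] <- conf
        out$p_right[i] <- p_right
        out$p_chosen[i] <- p_chosen
        out$delta_c[i] <- st$delta_c
        out$c_bar[i] <- cb_pre
        out$n1[i] <- bl$n1
        out$n2[i] <- bl$n2
      }
      if (keep_latents) {
        lat[[bl$block_index]] <- tibble::tibble(
          subject_id = subject_id,
          block = bl$block_index,
          trial = rep(sched$trial, each = length(bl$cs_ids)),
          phase = rep(sched$phase, each = length(bl$cs_ids)),
          cs = rep(bl$cs_ids, nrow(sched)),
          cs_value = rep(unname(bl$cs_means), nrow(sched)),
          v_bar = as.vector(t(lv)),
          c_bar_cs = as.vector(t(lc)),
          n1 = bl$n1, n2 = bl$n2
        )
      }
    }

    trials <- tibble::tibble(
      subject_id = subject_id, model = model, !!!out
    )
    trials$confidence_raw <- trials$confidence * 10
    trials$correct <- dplyr::if_else(
      trials$left_value == trials$right_value, NA,
      trials$chosen_value > pmin(trials$left_value, trials$right_value)
    )
    trials <- dplyr::relocate(trials, "confidence_raw", .before = "confidence")
    if (keep_latents) {
      attr(trials, "latents") <- dplyr::bind_rows(lat)
    }
    trials
  })
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived from the master seed; each subject receives a
#' freshly generated design from the same configuration, mirroring how designs
#' were sampled anew for every synthetic dataset.
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects (`>= 1`).
#' @param config A [design_config()] used to generate each subject's design.
#' @param seed Master integer seed.
#'
#' @return A tibble of all subjects' trials (latents attached as a combined
#'   `"latents"` attribute when `keep_latents = TRUE`).
#' @export
simulate_cohort <- function(model, params, n_subjects,
                            config = design_config(), seed = 1L,
                            keep_latents = FALSE,
                            discretize_confidence = FALSE) {
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  seeds <- derive_seeds(seed, 2L * n_subjects)
  subjects <- purrr::map(seq_len(n_subjects), function(s) {
    design <- generate_experiment_design(config, seed = seeds[2L * s - 1L])
    simulate_subject(model, params, design, seed = seeds[2L * s],
                     subject_id = sprintf("S%03d", s),
                     keep_latents = keep_latents,
                     discretize_confidence = discretize_confidence)
  })
  trials <- dplyr::bind_rows(subjects)
  if (keep_latents) {
    attr(trials, "latents") <-
      dplyr::bind_rows(purrr::map(subjects, attr, "latents"))
  }
  trials
}

#' Average latent time courses aligned to phase-2 onset
#'
#' Aggregates simulated latent variables and posterior-predictive quantities
#' across blocks and subjects, aligned so that time 0 is the first phase-2
#' trial (for control blocks, the first phase-3 trial), split by phase-1 and
#' phase-2 duration. Expected values (and per-CS expected confidence, if
#' present) are averaged per CS value rank within block; trial-level
#' quantities -- model performance (probability assigned to the objectively
#' higher-valued CS), model confidence, expected confidence, confidence
#' prediction error and its absolute value -- are averaged per time point.
#'
#' @param trials A trial tibble from [simulate_subject()]/[simulate_cohort()].
#' @param latents The matching latent table; defaults to the `"latents"`
#'   attribute of `trials`.
#' @return A list of class `confrl_timecourses` with tibbles `values`
#'   (per `n1`, `n2`, value rank and aligned time) and `trialwise`
#'   (per `n1`, `n2` and aligned time).
#' @export
latent_timecourses <- function(trials, latents = attr(trials, "latents")) {
  if (is.null(trials) || nrow(trials) == 0) {
    abort("`trials` is empty.")
  }
  tw <- trials |>
    dplyr::mutate(
      time = .data$trial - .data$n1,
      p_better = dplyr::case_when(
        .data$right_value > .data$left_value ~ .data$p_right,
        .data$right_value < .data$left_value ~ 1 - .data$p_right,
        TRUE ~ NA_real_
      )
    ) |>
    dplyr::group_by(.data$n1, .data$n2, .data$time) |>
    dplyr::summarise(
      performance = mean(.data$p_better, na.rm = TRUE),
      model_confidence = mean(.data$confidence),
      c_bar = mean(.data$c_bar),
      delta_c = mean(.data$delta_c),
      abs_delta_c = mean(abs(.data$delta_c)),
      n = dplyr::n(),
      .groups = "drop"
    )

  values <- NULL
  if (!is.null(latents)) {
    values <- latents |>
      dplyr::group_by(.data$subject_id, .data$block) |>
      dplyr::mutate(value_rank = dplyr::dense_rank(.data$cs_value)) |>
      dplyr::ungroup() |>
      dplyr::mutate(time = .data$trial - .data$n1) |>
      dplyr::group_by(.data$n1, .data$n2, .data$value_rank, .data$time) |>
      dplyr::summarise(
        v_bar = mean(.data$v_bar),
        c_bar_cs = mean(.data$c_bar_cs),
        n = dplyr::n(),
        .groups = "drop"
      )
  }
  structure(list(values = values, trialwise = tw),
            class = "confrl_timecourses")
}
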