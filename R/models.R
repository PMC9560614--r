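# Learning models: parameter sets, state, update equations and choice rules.
# All transition functions are pure: they return a new state and never modify
# their input.

#' The six candidate learning models
#'
#' All models learn CS values from reward prediction errors in feedback phases
#' (Rescorla-Wagner rule with learning rate `alpha_r`) and choose via a
#' softmax with inverse decision noise `beta`. They differ in what happens on
#' no-feedback (phase 2) trials:
#' * `Static` - values are unchanged;
#' * `Deval` - the chosen CS is devalued as if an effective reward of zero had
#'   been received (rate `alpha_d`);
#' * `Choice` - the chosen CS gains a fixed increment `lambda` from the mere
#'   act of choosing;
#' * `ConfSpec` - the chosen CS's value moves in proportion (`gamma`) to the
#'   confidence prediction error against a per-CS expected confidence
#'   (learning rate `alpha_c`);
#' * `ConfUnspec` - as `ConfSpec` but with a single stimulus-unspecific
#'   expected confidence;
#' * `Perseveration` - values are unchanged but phase-2 choice probabilities
#'   carry an additive bias `eta` toward (positive) or away from (negative)
#'   the CS chosen at the pair's previous encounter.
#'
#' @return Character vector of model names.
#' @export
model_kinds <- function() {
  c("Static", "Deval", "Choice", "ConfSpec", "ConfUnspec", "Perseveration")
}

#' Free parameters of a model
#'
#' @param model A model name from [model_kinds()].
#' @return Character vector of the model's free parameter names (its length is
#'   the parameter count k used by AIC/BIC).
#' @export
active_params <- function(model) {
  model <- match.arg(model, model_kinds())
  switch(model,
    Static = c("alpha_r", "beta"),
    Deval = c("alpha_r", "beta", "alpha_d"),
    Choice = c("alpha_r", "beta", "lambda"),
    ConfSpec = c("alpha_r", "beta", "alpha_c", "gamma"),
    ConfUnspec = c("alpha_r", "beta", "alpha_c", "gamma"),
    Perseveration = c("alpha_r", "beta", "eta")
  )
}

#' Parameter bounds
#'
#' Fitting bounds for every parameter: learning rates in \[0, 1\], `beta` in
#' \[0, 2\], `eta` in \[-5, 5\]; `gamma` and `lambda` have no natural upper
#' bound and receive a practical cap.
#'
#' @param model A model name.
#' @param cap Practical upper bound for `gamma` and `lambda`.
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
param_bounds <- function(model, cap = 100) {
  all <- tibble::tribble(
    ~param,    ~lower, ~upper,
    "alpha_r", 0,      1,
    "beta",    0,      2,
    "alpha_c", 0,      1,
    "alpha_d", 0,      1,
    "gamma",   0,      cap,
    "lambda",  0,      cap,
    "eta",     -5,     5
  )
  dplyr::filter(all, .data$param %in% active_params(model))
}

#' Validate a parameter set
#'
#' @param model A model name.
#' @param params Named numeric vector (or list) covering the model's
#'   [active_params()]; extra entries are dropped.
#' @param cap Practical upper bound for `gamma`/`lambda`.
#' @return The validated parameters as a named numeric vector in canonical
#'   order.
#' @export
validate_params <- function(model, params, cap = Inf) {
  act <- active_params(model)
  params <- unlist(params)
  missing <- setdiff(act, names(params))
  if (length(missing) > 0) {
    abort(paste0("Missing parameter(s) for ", model, ": ",
                 paste(missing, collapse = ", ")))
  }
  params <- params[act]
  b <- param_bounds(model, cap = cap)
  bad <- params < b$lower[match(names(params), b$param)] |
    params > b$upper[match(names(params), b$param)]
  if (any(!is.finite(params)) || any(bad)) {
    abort(paste0("Parameter(s) out of bounds for ", model, ": ",
                 paste(names(params)[!is.finite(params) | bad],
                       collapse = ", ")))
  }
  params
}

#' Initial learner state for a block
#'
#' Expected values and expected confidence start at zero for every new block
#' (new CS appear in each block), and the previous-choice memory is empty.
#'
#' @param cs_ids CS identifiers of the block.
#' @param conf_specific Logical: per-CS expected confidence (`TRUE`,
#'   stimulus-specific) or a single scalar (`FALSE`, stimulus-unspecific).
#' @return A list of class `confrl_state` with fields `v_bar`, `c_bar`,
#'   `prev_choice`.
#' @export
learner_state <- function(cs_ids, conf_specific = FALSE) {
  structure(
    list(
      v_bar = stats::setNames(rep(0, length(cs_ids)), cs_ids),
      c_bar = if (conf_specific) {
        stats::setNames(rep(0, length(cs_ids)), cs_ids)
      } else {
        0
      },
      prev_choice = character(0)
    ),
    class = "confrl_state"
  )
}

#' Softmax choice probability
#'
#' Probability of choosing the right-hand CS under the logistic softmax
#' `p_right = 1 / (1 + exp(-beta * (v_right - v_left)))`; `beta = 0` yields
#' random choice.
#'
#' @param beta Inverse decision noise, `>= 0`.
#' @param v_right,v_left Expected values of the right and left CS (euros).
#' @return `p_right` in (0, 1).
#' @export
softmax_choice_prob <- function(beta, v_right, v_left) {
  if (any(!is.finite(c(beta, v_right, v_left)))) {
    abort("Non-finite inputs to softmax_choice_prob().")
  }
  if (any(beta < 0)) abort("`beta` must be non-negative.")
  plogis(beta * (v_right - v_left))
}

#' Choice probability with perseveration bias
#'
#' Extends the softmax with an additive bias applied to the value difference:
#' `p_right = 1 / (1 + exp(-beta * ((v_right - v_left) +
#' eta * (c_prev_right - c_prev_left))))`, where the previous-choice
#' indicators mark which side's CS was chosen at the pair's most recent
#' encounter (both 0 when the pair has not been seen before).
#'
#' @param beta Inverse decision noise, `>= 0`.
#' @param eta Perseveration bias (positive repeats, negative alternates).
#' @param v_right,v_left Expected values of the two CS.
#' @param c_prev_right,c_prev_left Previous-choice indicators in \{0, 1\};
#'   at most one may be 1.
#' @return `p_right` in (0, 1).
#' @export
perseveration_choice_prob <- function(beta, eta, v_right, v_left,
                                      c_prev_right, c_prev_left) {
  if (any(c_prev_right + c_prev_left > 1)) {
    abort("At most one previous-choice indicator may be 1.")
  }
  if (any(!is.finite(c(beta, eta, v_right, v_left)))) {
    abort("Non-finite inputs to perseveration_choice_prob().")
  }
  if (any(beta < 0)) abort("`beta` must be non-negative.")
  plogis(beta * ((v_right - v_left) + eta * (c_prev_right - c_prev_left)))
}

#' Reward-based value update (Rescorla-Wagner)
#'
#' `v_bar_chosen <- v_bar_chosen + alpha_r * (reward - v_bar_chosen)`.
#'
#' @param state A `confrl_state`.
#' @param chosen_cs CS that was chosen (must exist in the state).
#' @param reward Obtained reward (euros).
#' @param alpha_r Reward learning rate in \[0, 1\].
#' @return The updated state.
#' @export
update_value_reward <- function(state, chosen_cs, reward, alpha_r) {
  if (!chosen_cs %in% names(state$v_bar)) {
    abort(paste0("Unknown CS: ", chosen_cs))
  }
  state$v_bar[chosen_cs] <- state$v_bar[chosen_cs] +
    alpha_r * (reward - state$v_bar[chosen_cs])
  state
}

#' Expected-confidence update
#'
#' Maintains the running average of experienced confidence: the confidence
#' prediction error `delta_c = confidence - c_bar(reference)` is computed
#' before the update and `c_bar(reference) <- c_bar(reference) +
#' alpha_c * delta_c`. Applied on every trial of every phase. In `"global"`
#' mode a single scalar is tracked and `reference_cs` is ignored.
#'
#' @param state A `confrl_state`.
#' @param reference_cs CS whose expected confidence is referenced
#'   (`"per-CS"` mode).
#' @param confidence Normalized confidence in \[0, 1\].
#' @param alpha_c Confidence learning rate in \[0, 1\].
#' @param specificity `"per-CS"` or `"global"`.
#' @return A list with elements `state` (updated) and `delta_c` (the
#'   pre-update confidence prediction error).
#' @export
update_expected_confidence <- function(state, reference_cs, confidence,
                                       alpha_c,
                                       specificity = c("global", "per-CS")) {
  specificity <- match.arg(specificity)
  if (!is.finite(confidence) || confidence < 0 || confidence > 1) {
    abort("`confidence` must lie in [0, 1].")
  }
  if (specificity == "per-CS") {
    if (!reference_cs %in% names(state$c_bar)) {
      abort(paste0("Unknown CS: ", reference_cs))
    }
    delta_c <- confidence - unname(state$c_bar[reference_cs])
    state$c_bar[reference_cs] <- state$c_bar[reference_cs] + alpha_c * delta_c
  } else {
    delta_c <- confidence - unname(state$c_bar[1])
    state$c_bar[1] <- state$c_bar[1] + alpha_c * delta_c
  }
  list(state = state, delta_c = delta_c)
}

check_no_feedback <- function(phase) {
  if (!identical(as.integer(phase), 2L)) {
    abort("No-feedback value updates apply only in phase 2.")
  }
}

#' Confidence-to-value transfer
#'
#' On no-feedback trials the target CS's value moves in proportion to the
#' confidence prediction error: `v_bar_target <- v_bar_target +
#' gamma * delta_c`.
#'
#' @param state A `confrl_state`.
#' @param target_cs CS receiving the update.
#' @param delta_c Confidence prediction error of the trial.
#' @param gamma Confidence transfer parameter, `>= 0`.
#' @param phase Phase of the calling trial; must be 2.
#' @return The updated state.
#' @export
transfer_confidence_to_value <- function(state, target_cs, delta_c, gamma,
                                         phase = 2L) {
  check_no_feedback(phase)
  if (!target_cs %in% names(state$v_bar)) {
    abort(paste0("Unknown CS: ", target_cs))
  }
  state$v_bar[target_cs] <- state$v_bar[target_cs] + gamma * delta_c
  state
}

#' Choice-induced value reinforcement
#'
#' On no-feedback trials the target CS gains a fixed increment:
#' `v_bar_target <- v_bar_target + lambda`.
#'
#' @inheritParams transfer_confidence_to_value
#' @param lambda Choice reinforcement increment, `>= 0`.
#' @return The updated state.
#' @export
update_value_choice <- function(state, target_cs, lambda, phase = 2L) {
  check_no_feedback(phase)
  if (!target_cs %in% names(state$v_bar)) {
    abort(paste0("Unknown CS: ", target_cs))
  }
  state$v_bar[target_cs] <- state$v_bar[target_cs] + lambda
  state
}

#' Devaluation update
#'
#' On no-feedback trials the target CS is updated as if an effective reward of
#' zero had been received: `v_bar_target <- (1 - alpha_d) * v_bar_target`.
#'
#' @inheritParams transfer_confidence_to_value
#' @param alpha_d Devaluation learning rate in \[0, 1\].
#' @return The updated state.
#' @export
update_value_deval <- function(state, target_cs, alpha_d, phase = 2L) {
  check_no_feedback(phase)
  if (!target_cs %in% names(state$v_bar)) {
    abort(paste0("Unknown CS: ", target_cs))
  }
  state$v_bar[target_cs] <- (1 - alpha_d) * state$v_bar[target_cs]
  state
}

#' Advance the learner state by one trial
#'
#' Dispatcher composing the update equations per model and phase. Feedback
#' phases (1 and 3) apply the reward update to the applied choice; phase 2
#' applies the model-specific no-feedback update. The update target in phase 2
#' depends on the mode: in `"generative"` mode it is the applied (sampled)
#' choice; in `"fitting"` mode it is the model-predicted CS (right CS if
#' `p_right >= 0.5`, else left), so the model never conditions on the choice
#' it is asked to predict. Confidence models track expected confidence on
#' every trial (referenced, for `ConfSpec`, to the applied choice);
#' `Perseveration` records the applied choice for the pair on every trial and
#' applies the `eta` bias only in phase 2.
#'
#' @param model A model name.
#' @param params Named parameters (see [active_params()]).
#' @param state A `confrl_state` for the current block.
#' @param context List with `phase`, `left_cs`, `right_cs` and `mode`
#'   (`"generative"` or `"fitting"`).
#' @param observation List with `chosen_cs`, `confidence` (normalized) and,
#'   on feedback phases, `reward` with `reward_observed = TRUE`.
#' @return A list with `state` (updated), `p_right` (the choice probability
#'   used for the trial) and `delta_c` (confidence prediction error; `NA` for
#'   non-confidence models).
#' @export
step_trial <- function(model, params, state, context, observation) {
  model <- match.arg(model, model_kinds())
  phase <- as.integer(context$phase)
  mode <- match.arg(context$mode, c("generative", "fitting"))
  left <- context$left_cs
  right <- context$right_cs
  chosen <- observation$chosen_cs
  if (!chosen %in% c(left, right)) {
    abort("`chosen_cs` must be one of the trial's two CS.")
  }
  if (phase == 2 && isTRUE(observation$reward_observed)) {
    abort("Phase-2 observations cannot carry an observed reward.")
  }

  key <- pair_key(left, right)
  if (model == "Perseveration" && phase == 2 && key %in%
        names(state$prev_choice)) {
    prev <- state$prev_choice[[key]]
    p_right <- perseveration_choice_prob(
      params[["beta"]], params[["eta"]],
      state$v_bar[[right]], state$v_bar[[left]],
      as.numeric(prev == right), as.numeric(prev == left)
    )
  } else {
    p_right <- softmax_choice_prob(params[["beta"]],
                                   state$v_bar[[right]],
                                   state$v_bar[[left]])
  }

  delta_c <- NA_real_
  conf_model <- model %in% c("ConfSpec", "ConfUnspec")
  if (conf_model) {
    spec <- if (model == "ConfSpec") "per-CS" else "global"
    cb <- if (model == "ConfSpec") state$c_bar[[chosen]] else state$c_bar[[1]]
    delta_c <- observation$confidence - cb
  }

  if (phase %in% c(1L, 3L)) {
    if (!isTRUE(observation$reward_observed)) {
      abort("Feedback-phase observations require an observed reward.")
    }
    state <- update_value_reward(state, chosen, observation$reward,
                                 params[["alpha_r"]])
  } else {
    target <- if (mode == "fitting") {
      if (p_right >= 0.5) right else left
    } else {
      chosen
    }
    state <- switch(model,
      Static = state,
      Perseveration = state,
      Deval = update_value_deval(state, target, params[["alpha_d"]]),
      Choice = update_value_choice(state, target, params[["lambda"]]),
      ConfSpec = ,
      ConfUnspec = transfer_confidence_to_value(state, target, delta_c,
                                                params[["gamma"]])
    )
  }

  if (conf_model) {
    upd <- update_expected_confidence(state, chosen, observation$confidence,
                                      params[["alpha_c"]], specificity = spec)
    state <- upd$state
  }
  if (model == "Perseveration") {
    state$prev_choice[[key]] <- chosen
  }

  list(state = state, p_right = unname(p_right), delta_c = unname(delta_c))
}
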