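# Independent per-trial likelihood oracle: re-derives the learner state from
# scratch with explicit arithmetic, deliberately sharing no code with the
# package's step_trial()/C++ paths.

oracle_nll <- function(trials, model, params) {
  trials <- trials[order(trials$block, trials$trial), ]
  total <- 0
  for (b in unique(trials$block)) {
    tb <- trials[trials$block == b, ]
    cs <- sort(unique(c(tb$left_cs, tb$right_cs)))
    v <- setNames(rep(0, length(cs)), cs)
    cb <- setNames(rep(0, length(cs)), cs)  # per-CS expected confidence
    cg <- 0                                  # global expected confidence
    prev <- list()                           # pair -> last chosen cs
    for (i in seq_len(nrow(tb))) {
      L <- tb$left_cs[i]; R <- tb$right_cs[i]
      ph <- tb$phase[i]
      chosen <- tb$chosen_cs[i]
      conf <- tb$confidence[i]
      key <- paste(sort(c(L, R)), collapse = "~")

      drive <- v[[R]] - v[[L]]
      if (model == "Perseveration" && ph == 2 && !is.null(prev[[key]])) {
        bias <- if (prev[[key]] == R) 1 else -1
        drive <- drive + params$eta * bias
      }
      p_right <- 1 / (1 + exp(-params$beta * drive))
      p_obs <- if (chosen == R) p_right else 1 - p_right
      total <- total - log(max(p_obs, 1e-12))

      if (ph %in% c(1, 3)) {
        v[[chosen]] <- v[[chosen]] + params$alpha_r * (tb$reward[i] -
                                                         v[[chosen]])
      } else {
        tgt <- if (p_right >= 0.5) R else L
        if (model == "Deval") {
          v[[tgt]] <- (1 - params$alpha_d) * v[[tgt]]
        } else if (model == "Choice") {
          v[[tgt]] <- v[[tgt]] + params$lambda
        } else if (model == "ConfSpec") {
          v[[tgt]] <- v[[tgt]] + params$gamma * (conf - cb[[chosen]])
        } else if (model == "ConfUnspec") {
          v[[tgt]] <- v[[tgt]] + params$gamma * (conf - cg)
        }
      }
      if (model == "ConfSpec") {
        cb[[chosen]] <- cb[[chosen]] + params$alpha_c * (conf - cb[[chosen]])
      } else if (model == "ConfUnspec") {
        cg <- cg + params$alpha_c * (conf - cg)
      }
      if (model == "Perseveration") prev[[key]] <- chosen
    }
  }
  total
}

# Random parameters within each model's fitting bounds.
random_params <- function(model) {
  p <- list(alpha_r = runif(1), beta = runif(1, 0, 2))
  extra <- switch(model,
    Static = list(),
    Deval = list(alpha_d = runif(1)),
    Choice = list(lambda = runif(1, 0, 5)),
    ConfSpec = ,
    ConfUnspec = list(alpha_c = runif(1), gamma = runif(1, 0, 20)),
    Perseveration = list(eta = runif(1, -3, 3))
  )
  c(p, extra)
}

# Small simulated subject on a reduced design for fast property checks.
small_design_config <- function() {
  design_config(
    n_blocks = 3, n_control = 1,
    phase1_lengths = c(9L, 12L), phase2_lengths = c(5L, 10L)
  )
}

small_subject <- function(model, params, seed) {
  design <- generate_experiment_design(small_design_config(), seed = seed)
  simulate_subject(model, params, design, seed = seed + 1)
}

# Hand-built two-CS trial table (values in euros, confidence normalized).
fixture_trials <- function() {
  tibble::tibble(
    subject_id = "F1",
    block = 1L,
    trial = 0:3,
    phase = c(1L, 1L, 2L, 3L),
    left_cs = c("A", "B", "A", "B"),
    right_cs = c("B", "A", "B", "A"),
    chosen_cs = c("B", "B", "A", "A"),
    chosen_side = c("right", "left", "left", "right"),
    reward = c(20, 10, NA, 30),
    reward_observed = c(TRUE, TRUE, FALSE, TRUE),
    confidence = c(0.2, 0.4, 0.6, 0.8),
    confidence_raw = c(2, 4, 6, 8),
    left_value = c(20, 25, 20, 25),
    right_value = c(25, 20, 25, 20),
    chosen_value = c(25, 25, 20, 20),
    correct = c(TRUE, TRUE, FALSE, FALSE)
  )
}
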