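# Per-subject maximum-likelihood fitting and model comparison.

model_code <- function(model) {
  match(match.arg(model, model_kinds()), model_kinds())
}

# Canonical length-4 parameter vector in the layout of the likelihood core.
par_vector <- function(model, params) {
  act <- active_params(model)
  p <- c(params[["alpha_r"]], params[["beta"]], 0, 0)
  extras <- setdiff(act, c("alpha_r", "beta"))
  if (length(extras) > 0) p[3] <- params[[extras[1]]]
  if (length(extras) > 1) p[4] <- params[[extras[2]]]
  p
}

# Validate and index a single subject's trial table for the likelihood core.
prepare_fit_data <- function(trials) {
  req <- c("block", "trial", "phase", "left_cs", "right_cs", "chosen_cs",
           "reward", "confidence")
  missing <- setdiff(req, names(trials))
  if (length(missing) > 0) {
    abort(paste0("Trial table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if ("subject_id" %in% names(trials) &&
        dplyr::n_distinct(trials$subject_id) > 1) {
    abort("Likelihoods are per subject; got multiple subjects.")
  }
  trials <- dplyr::arrange(trials, .data$block, .data$trial)
  if (any(!is.finite(trials$confidence)) ||
        any(trials$confidence < 0 | trials$confidence > 1)) {
    abort("Every trial needs a normalized confidence in [0, 1].")
  }
  fb <- trials$phase %in% c(1L, 3L)
  if (any(!is.finite(trials$reward[fb]))) {
    abort("Feedback-phase trials need an observed reward.")
  }
  # 0-based CS indices within block, shared between the two sides
  left <- integer(nrow(trials))
  right <- integer(nrow(trials))
  for (ix in split(seq_len(nrow(trials)), trials$block)) {
    cs <- sort(unique(c(trials$left_cs[ix], trials$right_cs[ix])))
    left[ix] <- match(trials$left_cs[ix], cs) - 1L
    right[ix] <- match(trials$right_cs[ix], cs) - 1L
  }
  # chosen side from ids (robust even if chosen_side column is absent)
  choice_right <- as.integer(trials$chosen_cs == trials$right_cs)
  if (any(trials$chosen_cs != trials$left_cs &
            trials$chosen_cs != trials$right_cs)) {
    abort("`chosen_cs` must match `left_cs` or `right_cs` on every trial.")
  }
  list(
    block = as.integer(trials$block), phase = as.integer(trials$phase),
    left = as.integer(left), right = as.integer(right),
    choice_right = choice_right,
    reward = ifelse(is.finite(trials$reward), trials$reward, 0),
    confidence = trials$confidence,
    n_cs = max(c(left, right)) + 1L,
    n_trials = nrow(trials)
  )
}

#' Negative log-likelihood of a subject's choices
#'
#' Sums `-log p(observed choice)` over all trials of all blocks, with the
#' learner state reset to zeros at every block start. In feedback phases the
#' reward update uses the participant's actual choice and observed reward; in
#' phase 2 the no-feedback value update targets the model-predicted CS (the
#' right CS if `p_right >= 0.5`, else the left), so the model cannot exploit
#' the choice it is predicting. Expected-confidence updates use the reported
#' normalized confidence (referenced, for `ConfSpec`, to the actually chosen
#' CS). Per-trial probabilities are floored at 1e-12 before the log.
#'
#' @param trials A single subject's trial tibble.
#' @param model A model name.
#' @param params Named parameters for the model.
#' @param engine `"cpp"` (compiled core) or `"r"` (pure-R [step_trial()]
#'   chain); both give identical results.
#' @return The negative log-likelihood (non-negative scalar).
#' @export
negative_log_likelihood <- function(trials, model, params, engine = "cpp") {
  model <- match.arg(model, model_kinds())
  engine <- match.arg(engine, c("cpp", "r"))
  params <- validate_params(model, params)
  if (engine == "cpp") {
    d <- prepare_fit_data(trials)
    return(nll_trials_cpp(d$block, d$phase, d$left, d$right, d$choice_right,
                          d$reward, d$confidence, model_code(model),
                          par_vector(model, params), d$n_cs))
  }
  trials <- dplyr::arrange(trials, .data$block, .data$trial)
  nll <- 0
  state <- NULL
  last_block <- NA
  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    if (!identical(row$block, last_block)) {
      cs <- sort(unique(c(
        trials$left_cs[trials$block == row$block],
        trials$right_cs[trials$block == row$block]
      )))
      state <- learner_state(cs, conf_specific = model == "ConfSpec")
      last_block <- row$block
    }
    fb <- row$phase %in% c(1L, 3L)
    st <- step_trial(
      model, params, state,
      context = list(phase = row$phase, left_cs = row$left_cs,
                     right_cs = row$right_cs, mode = "fitting"),
      observation = list(chosen_cs = row$chosen_cs,
                         confidence = row$confidence,
                         reward = if (fb) row$reward else NA_real_,
                         reward_observed = fb)
    )
    p_obs <- if (row$chosen_cs == row$right_cs) st$p_right else 1 - st$p_right
    nll <- nll - log(max(p_obs, 1e-12))
    state <- st$state
  }
  nll
}

#' Fitting configuration
#'
#' Grid and optimizer settings for [fit_subject()]. The default coarse grid
#' uses 5 equidistant points for each learning rate, 5 log-spaced points for
#' `beta`, `gamma` and `lambda`, and 7 equidistant points for `eta`; `gamma`
#' and `lambda` are capped at `cap` during optimization.
#'
#' @param cap Practical upper bound for `gamma` and `lambda`.
#' @param grid Optional named list of per-parameter grid values overriding
#'   the defaults.
#' @param maxit Iteration cap handed to both local optimizers.
#' @return A list of class `confrl_fit_config`.
#' @export
fitting_config <- function(cap = 100, grid = NULL, maxit = 500) {
  default <- list(
    alpha_r = seq(0.1, 0.9, length.out = 5),
    alpha_c = seq(0.1, 0.9, length.out = 5),
    alpha_d = seq(0.1, 0.9, length.out = 5),
    beta = exp(seq(log(0.05), log(2), length.out = 5)),
    gamma = exp(seq(log(0.1), log(cap), length.out = 5)),
    lambda = exp(seq(log(0.1), log(cap), length.out = 5)),
    eta = seq(-3, 3, length.out = 7)
  )
  if (!is.null(grid)) default[names(grid)] <- grid
  structure(list(cap = cap, grid = default, maxit = maxit),
            class = "confrl_fit_config")
}

#' Coarse grid search for starting values
#'
#' Exhaustively evaluates the likelihood on the Cartesian product of the
#' per-parameter grids and returns the best point.
#'
#' @param trials A single subject's trial tibble.
#' @param model A model name.
#' @param config A [fitting_config()] (its `grid` entries for the model's
#'   active parameters form the grid).
#' @return A list with `params` (named vector of the best grid point) and
#'   `nll`.
#' @export
grid_search_init <- function(trials, model, config = fitting_config()) {
  model <- match.arg(model, model_kinds())
  act <- active_params(model)
  grids <- config$grid[act]
  if (any(vapply(grids, length, integer(1)) == 0)) {
    abort("Empty grid for at least one active parameter.")
  }
  points <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  d <- prepare_fit_data(trials)
  mat <- t(apply(points, 1, function(p) par_vector(model, as.list(p))))
  nll <- nll_batch_cpp(d$block, d$phase, d$left, d$right, d$choice_right,
                       d$reward, d$confidence, model_code(model), mat,
                       d$n_cs)
  best <- which.min(nll)
  list(params = unlist(points[best, , drop = TRUE])[act], nll = nll[best])
}

# Box transform used by the derivative-free optimizer: unconstrained z to
# bounded x and back.
box_to_z <- function(x, lower, upper) {
  f <- pmin(pmax((x - lower) / (upper - lower), 1e-6), 1 - 1e-6)
  qlogis(f)
}
z_to_box <- function(z, lower, upper) {
  lower + (upper - lower) * plogis(z)
}

#' Fit one model to one subject
#'
#' Maximum-likelihood estimation: a coarse grid search picks starting values,
#' then two local optimizers run from that point -- bounded quasi-Newton
#' (`L-BFGS-B`) on the raw scale and derivative-free Nelder-Mead on a
#' box-transformed unconstrained scale -- and the better solution is kept
#' (never worse than the grid optimum).
#'
#' @param trials A single subject's trial tibble.
#' @param model A model name.
#' @param config A [fitting_config()].
#' @return An object of class `confrl_fit`: a list with `model`, `params`
#'   (named vector), `nll`, `aic`, `bic`, `n_trials`, `k`, `grid_init_nll`
#'   and `optimizer`.
#' @export
fit_subject <- function(trials, model, config = fitting_config()) {
  model <- match.arg(model, model_kinds())
  act <- active_params(model)
  b <- param_bounds(model, cap = config$cap)
  lower <- b$lower[match(act, b$param)]
  upper <- b$upper[match(act, b$param)]
  d <- prepare_fit_data(trials)
  obj <- function(x) {
    nll_trials_cpp(d$block, d$phase, d$left, d$right, d$choice_right,
                   d$reward, d$confidence, model_code(model),
                   par_vector(model, as.list(stats::setNames(x, act))),
                   d$n_cs)
  }

  init <- grid_search_init(trials, model, config)
  candidates <- list(list(params = init$params, nll = init$nll,
                          optimizer = "grid"))

  lb <- tryCatch(
    optim(init$params, obj, method = "L-BFGS-B", lower = lower,
          upper = upper, control = list(maxit = config$maxit)),
    error = function(e) NULL
  )
  if (!is.null(lb)) {
    candidates <- c(candidates, list(list(
      params = stats::setNames(pmin(pmax(lb$par, lower), upper), act),
      nll = lb$value, optimizer = "L-BFGS-B"
    )))
  }

  nm <- tryCatch({
    z0 <- box_to_z(init$params, lower, upper)
    fit <- optim(z0, function(z) obj(z_to_box(z, lower, upper)),
                 method = "Nelder-Mead",
                 control = list(maxit = 4 * config$maxit))
    list(params = stats::setNames(z_to_box(fit$par, lower, upper), act),
         nll = fit$value, optimizer = "Nelder-Mead")
  }, error = function(e) NULL)
  if (!is.null(nm)) candidates <- c(candidates, list(nm))

  if (length(candidates) == 1) {
    abort("Both local optimizers failed; grid fallback available in message.")
  }
  best <- candidates[[which.min(vapply(candidates, `[[`, numeric(1), "nll"))]]
  k <- length(act)
  structure(
    list(
      model = model,
      params = best$params,
      nll = best$nll,
      aic = 2 * k + 2 * best$nll,
      bic = k * log(d$n_trials) + 2 * best$nll,
      n_trials = d$n_trials,
      k = k,
      grid_init_nll = init$nll,
      optimizer = best$optimizer
    ),
    class = "confrl_fit"
  )
}

#' @export
print.confrl_fit <- function(x, ...) {
  cat(sprintf("<confrl_fit> %s: nll %.2f, AIC %.2f, BIC %.2f (%s)\n",
              x$model, x$nll, x$aic, x$bic, x$optimizer))
  print(round(x$params, 4))
  invisible(x)
}

#' @rdname fit_subject
#' @param x A `confrl_fit`.
#' @param ... Unused.
#' @export
tidy.confrl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_subject
#' @export
glance.confrl_fit <- function(x, ...) {
  tibble::tibble(model = x$model, nll = x$nll, aic = x$aic, bic = x$bic,
                 n_trials = x$n_trials, k = x$k,
                 grid_init_nll = x$grid_init_nll, optimizer = x$optimizer)
}

#' Fit several models to every subject of a trial table
#'
#' @param trials A (possibly multi-subject) trial tibble.
#' @param models Model names to fit.
#' @param config A [fitting_config()].
#' @return A tibble with one row per subject and model: identifiers, fitted
#'   parameters (NA where inactive), `nll`, `aic`, `bic`, `k`, `n_trials`,
#'   `optimizer`.
#' @export
fit_models <- function(trials, models = model_kinds(),
                       config = fitting_config()) {
  if (!"subject_id" %in% names(trials)) trials$subject_id <- "S1"
  all_par <- c("alpha_r", "beta", "alpha_c", "alpha_d", "gamma", "lambda",
               "eta")
  purrr::map_dfr(split(trials, trials$subject_id), function(tt) {
    purrr::map_dfr(models, function(m) {
      fit <- fit_subject(tt, m, config)
      row <- stats::setNames(rep(NA_real_, length(all_par)), all_par)
      row[names(fit$params)] <- fit$params
      dplyr::bind_cols(
        tibble::tibble(subject_id = tt$subject_id[1], model = m),
        tibble::as_tibble(as.list(row)),
        tibble::tibble(nll = fit$nll, aic = fit$aic, bic = fit$bic,
                       k = fit$k, n_trials = fit$n_trials,
                       optimizer = fit$optimizer)
      )
    })
  })
}

#' Cohort-level model comparison
#'
#' Summarises per-subject information criteria per model (mean and SEM),
#' declares the model with the minimal mean criterion the winner, and runs
#' two-tailed paired t-tests on the per-subject criteria for the requested
#' model pairs.
#'
#' @param fits A tibble from [fit_models()]; every subject must carry a fit
#'   for every model.
#' @param criterion `"aic"` or `"bic"`.
#' @param pairs List of length-2 character vectors of models to test; by
#'   default the winner is tested against every other model.
#' @return A list of class `confrl_comparison` with `summary`, `winner`,
#'   `tests` and `criterion`.
#' @export
compare_models <- function(fits, criterion = c("aic", "bic"), pairs = NULL) {
  criterion <- match.arg(criterion)
  wide <- fits |>
    dplyr::select("subject_id", "model", dplyr::all_of(criterion)) |>
    tidyr::pivot_wider(names_from = "model",
                       values_from = dplyr::all_of(criterion))
  if (anyNA(wide)) {
    abort("Every subject must be fitted under every model.")
  }
  models <- setdiff(names(wide), "subject_id")
  summary <- fits |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      mean = mean(.data[[criterion]]),
      sem = sem(.data[[criterion]]),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean)
  winner <- summary$model[1]
  if (is.null(pairs)) {
    pairs <- purrr::map(setdiff(models, winner), ~ c(winner, .x))
  }
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- wide[[pr[1]]]
    b <- wide[[pr[2]]]
    if (length(a) < 2) {
      tibble::tibble(model_a = pr[1], model_b = pr[2],
                     t = NA_real_, df = 0, p = NA_real_,
                     mean_diff = mean(a - b))
    } else if (isTRUE(all.equal(a, b)) || sd(a - b) == 0) {
      tibble::tibble(model_a = pr[1], model_b = pr[2],
                     t = 0, df = length(a) - 1, p = 1,
                     mean_diff = mean(a - b))
    } else {
      tt <- t.test(a, b, paired = TRUE)
      tibble::tibble(model_a = pr[1], model_b = pr[2],
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, mean_diff = unname(tt$estimate))
    }
  })
  structure(list(summary = summary, winner = winner, tests = tests,
                 criterion = criterion),
            class = "confrl_comparison")
}

#' @export
print.confrl_comparison <- function(x, ...) {
  cat(sprintf("<confrl_comparison> criterion %s, winner: %s\n",
              toupper(x$criterion), x$winner))
  print(x$summary)
  invisible(x)
}

#' @rdname compare_models
#' @param x A `confrl_comparison`.
#' @param ... Unused.
#' @export
tidy.confrl_comparison <- function(x, ...) {
  x$summary
}
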