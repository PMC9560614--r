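# Model-recovery confusion matrices and parameter-recovery correlations.

#' Recovery parameter grids
#'
#' The coarse per-parameter grids used to span generative parameter regimes
#' in recovery studies: learning rates over 5 equidistant values in
#' \[0.1, 1\]; `beta` over 5 doubling values in \[0.1, 1.6\]; `gamma` over 5
#' exponential values in \[1, 100\]; `lambda` over 5 exponential values in
#' \[0.5, 5\]; `eta` over 6 equidistant values in \[-1.5, 1.5\].
#'
#' @return Named list of grid vectors.
#' @export
recovery_grid <- function() {
  list(
    alpha_r = seq(0.1, 1, length.out = 5),
    alpha_c = seq(0.1, 1, length.out = 5),
    alpha_d = seq(0.1, 1, length.out = 5),
    beta = 0.1 * 2^(0:4),
    gamma = exp(seq(log(1), log(100), length.out = 5)),
    lambda = exp(seq(log(0.5), log(5), length.out = 5)),
    eta = seq(-1.5, 1.5, length.out = 6)
  )
}

#' Full parameter-configuration grid for a model
#'
#' Expands the per-parameter recovery grids over a model's active parameters
#' (k^N configurations for N parameters with k values each).
#'
#' @param model A model name.
#' @param grid A [recovery_grid()]-style named list.
#' @return A tibble of parameter configurations.
#' @export
model_param_grid <- function(model, grid = recovery_grid()) {
  act <- active_params(model)
  tidyr::expand_grid(!!!grid[act])
}

#' Mid-grid parameter configuration
#'
#' The middle value of each active parameter's recovery grid; used by the
#' scaled recovery preset.
#'
#' @inheritParams model_param_grid
#' @return Named numeric vector.
#' @export
mid_grid_params <- function(model, grid = recovery_grid()) {
  act <- active_params(model)
  vapply(grid[act], function(v) v[ceiling((length(v) + 1) / 2)], numeric(1))
}

#' Scaled recovery preset: one mid-panel per model
#'
#' The full recovery study spans every combination of the per-parameter
#' grids; the scaled preset mirrors one panel of that study: the parameters
#' shared by all models (`alpha_r`, `beta`) are fixed at their mid-grid
#' values, while each model's own phase-2 parameters span their grid
#' (paired along the grid diagonal for the two-parameter confidence
#' models). This keeps configurations from every regime of the
#' model-defining parameter in the scaled run; the central configuration
#' alone would make several models near-indistinguishable from the static
#' reference by construction (e.g. a perseveration bias of
#' `beta * eta = 0.12` in the logit).
#'
#' @inheritParams model_param_grid
#' @return A tibble of parameter configurations.
#' @export
model_recovery_configs <- function(model, grid = recovery_grid()) {
  model <- match.arg(model, model_kinds())
  mid <- function(p) {
    v <- grid[[p]]
    v[ceiling((length(v) + 1) / 2)]
  }
  extras <- setdiff(active_params(model), c("alpha_r", "beta"))
  specific <- if (length(extras) == 0) {
    tibble::tibble(.rows = 1)
  } else if (length(extras) == 1) {
    tibble::as_tibble(stats::setNames(list(grid[[extras]]), extras))
  } else {
    tibble::as_tibble(stats::setNames(lapply(extras, function(p) {
      grid[[p]]
    }), extras))
  }
  dplyr::bind_cols(
    tibble::tibble(alpha_r = rep(mid("alpha_r"), nrow(specific)),
                   beta = mid("beta")),
    specific
  )
}

#' Model-recovery confusion matrices
#'
#' For each generative model, simulates datasets (one synthetic subject per
#' dataset, each on a freshly generated design), fits every candidate model,
#' and tallies which model attains the lowest information criterion. Reports
#' `p_fit_given_gen` (rows: generative model; probability each candidate best
#' fits its datasets) and `p_gen_given_fit` (rows: best-fitting model;
#' probability the dataset came from each generative model, computed after
#' equalizing generation base rates by seeded subsampling without
#' replacement).
#'
#' @param models Candidate (and generative) model set.
#' @param n_datasets Datasets per generative model, split as evenly as
#'   possible across that model's configurations.
#' @param params Named list mapping each generative model to a tibble of
#'   parameter configurations; defaults to the scaled
#'   [model_recovery_configs()] diagonal preset.
#' @param config A [design_config()].
#' @param fit_config A [fitting_config()].
#' @param seed Master seed.
#' @param criterion `"aic"` or `"bic"`.
#' @return A list of class `confrl_confusion` with `counts` (gen x fit),
#'   `p_fit_given_gen`, `p_gen_given_fit`, `criterion`, `n_datasets`.
#' @export
run_model_recovery <- function(models = model_kinds(), n_datasets = 20,
                               params = NULL, config = design_config(),
                               fit_config = fitting_config(), seed = 1L,
                               criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (n_datasets < 1) abort("`n_datasets` must be at least 1.")
  if (is.null(params)) {
    params <- purrr::map(
      stats::setNames(models, models),
      ~ model_recovery_configs(.x)
    )
  }
  seeds <- derive_seeds(seed, length(models) + 1L)
  best_fits <- purrr::imap_dfr(
    stats::setNames(models, models),
    function(gen_model, nm) {
      cfg_tbl <- params[[gen_model]]
      gi <- match(gen_model, models)
      cfg_seeds <- derive_seeds(seeds[gi], nrow(cfg_tbl))
      # split the per-model dataset budget across configurations
      n_cfg <- nrow(cfg_tbl)
      n_each <- diff(round(seq(0, n_datasets, length.out = n_cfg + 1)))
      purrr::map_dfr(seq_len(n_cfg), function(ci) {
        if (n_each[ci] == 0) {
          return(NULL)
        }
        trials <- simulate_cohort(gen_model, as.list(cfg_tbl[ci, ]),
                                  n_each[ci], config = config,
                                  seed = cfg_seeds[ci])
        fits <- fit_models(trials, models = models, config = fit_config)
        fits |>
          dplyr::group_by(.data$subject_id) |>
          dplyr::slice_min(.data[[criterion]], n = 1, with_ties = FALSE) |>
          dplyr::ungroup() |>
          dplyr::transmute(gen = gen_model, fit = .data$model)
      })
    }
  )

  lv <- factor(best_fits$gen, levels = models)
  counts <- table(gen = lv, fit = factor(best_fits$fit, levels = models))
  counts <- unclass(counts)
  p_fit_given_gen <- counts / rowSums(counts)

  # equalize base rates before conditioning on the best-fitting model
  n_min <- min(table(lv))
  eq <- local_seed(seeds[length(models) + 1L], {
    dplyr::bind_rows(lapply(split(best_fits, best_fits$gen), function(d) {
      d[sample.int(nrow(d), n_min), ]
    }))
  })
  eq_counts <- unclass(table(gen = factor(eq$gen, levels = models),
                             fit = factor(eq$fit, levels = models)))
  fit_totals <- colSums(eq_counts)
  p_gen_given_fit <- t(sweep(eq_counts, 2, pmax(fit_totals, 1), "/"))
  p_gen_given_fit[fit_totals == 0, ] <- NA_real_

  structure(
    list(counts = counts, p_fit_given_gen = p_fit_given_gen,
         p_gen_given_fit = p_gen_given_fit, criterion = criterion,
         n_datasets = n_datasets),
    class = "confrl_confusion"
  )
}

#' @export
print.confrl_confusion <- function(x, ...) {
  cat(sprintf("<confrl_confusion> criterion %s, %d datasets/model\n",
              toupper(x$criterion), x$n_datasets))
  cat("p(fit | gen):\n")
  print(round(x$p_fit_given_gen, 3))
  invisible(x)
}

#' Parameter-recovery correlations
#'
#' For each varied parameter, simulates one synthetic subject per value
#' (equidistant values across the parameter's recovery range, the other
#' parameters held at the anchor), fits the model, and correlates the
#' generative values of the varied parameter against every fitted parameter
#' (product-moment). Degenerate inputs (constant generative or fitted values)
#' yield `NA` correlations.
#'
#' @param model Model to recover (default the stimulus-unspecific confidence
#'   model).
#' @param n_values Number of varied values per parameter (`>= 3`).
#' @param ranges Named list of (lo, hi) ranges for the varied parameters;
#'   defaults to `alpha_r` 0.01-1, `beta` 0.02-2, `alpha_c` 0-1, `gamma`
#'   0-10.
#' @param anchor Named vector of anchor parameter values; defaults to
#'   [mid_grid_params()].
#' @param varied Which parameters to vary (defaults to all in `ranges` that
#'   are active).
#' @param config A [design_config()].
#' @param fit_config A [fitting_config()].
#' @param seed Master seed.
#' @return A list of class `confrl_precovery` with `correlations` (tibble:
#'   `varied`, one column per fitted parameter), `fits` (per-dataset
#'   generative value and fitted parameters) and `anchor`.
#' @export
run_parameter_recovery <- function(model = "ConfUnspec", n_values = 250,
                                   ranges = list(alpha_r = c(0.01, 1),
                                                 beta = c(0.02, 2),
                                                 alpha_c = c(0, 1),
                                                 gamma = c(0, 10)),
                                   anchor = mid_grid_params(model),
                                   varied = NULL,
                                   config = design_config(),
                                   fit_config = fitting_config(),
                                   seed = 1L) {
  if (n_values < 3) abort("`n_values` must be at least 3.")
  act <- active_params(model)
  if (is.null(varied)) varied <- intersect(names(ranges), act)
  stopifnot(all(varied %in% act), all(varied %in% names(ranges)))
  seeds <- derive_seeds(seed, length(varied))

  fits <- purrr::imap_dfr(
    stats::setNames(varied, varied),
    function(vp, nm) {
      vals <- seq(ranges[[vp]][1], ranges[[vp]][2], length.out = n_values)
      sub_seeds <- derive_seeds(seeds[match(vp, varied)], 2L * n_values)
      purrr::map_dfr(seq_along(vals), function(i) {
        params <- as.list(anchor)
        params[[vp]] <- vals[i]
        design <- generate_experiment_design(config,
                                             seed = sub_seeds[2L * i - 1L])
        trials <- simulate_subject(model, params, design,
                                   seed = sub_seeds[2L * i])
        fit <- fit_subject(trials, model, fit_config)
        dplyr::bind_cols(
          tibble::tibble(varied = vp, gen_value = vals[i]),
          tibble::as_tibble(as.list(fit$params))
        )
      })
    }
  )

  correlations <- fits |>
    dplyr::group_by(.data$varied) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(act),
      ~ if (sd(.x) == 0 || sd(.data$gen_value) == 0) NA_real_ else {
        cor(.data$gen_value, .x)
      }
    ), .groups = "drop")

  structure(list(correlations = correlations, fits = fits, anchor = anchor,
                 model = model),
            class = "confrl_precovery")
}

#' @export
print.confrl_precovery <- function(x, ...) {
  cat(sprintf("<confrl_precovery> %s, anchor: %s\n", x$model,
              paste(names(x$anchor), round(x$anchor, 3),
                    sep = "=", collapse = ", ")))
  print(x$correlations)
  invisible(x)
}
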