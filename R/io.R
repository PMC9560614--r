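# Trial-table CSV interchange.

trial_table_columns <- c(
  "subject_id", "block", "trial", "phase", "left_cs", "right_cs",
  "left_value", "right_value", "chosen_side", "chosen_cs", "chosen_value",
  "reward", "reward_observed", "confidence_raw", "confidence", "correct"
)

#' Write a trial table to CSV
#'
#' Writes the canonical trial-table columns in fixed order, sorted by
#' subject, block and trial. Rewards are blanked in rows where the reward was
#' not observed (no-feedback trials); values are written at fixed precision.
#'
#' @param trials A trial tibble (e.g. from [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  missing <- setdiff(setdiff(trial_table_columns, "reward_observed"),
                     names(trials))
  if (length(missing) > 0) {
    abort(paste0("Trial table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"reward_observed" %in% names(trials)) {
    trials$reward_observed <- is.finite(trials$reward)
  }
  out <- trials |>
    dplyr::arrange(.data$subject_id, .data$block, .data$trial) |>
    dplyr::mutate(
      reward = dplyr::if_else(.data$reward_observed, .data$reward, NA_real_),
      dplyr::across(dplyr::where(is.double), ~ round(.x, 6))
    ) |>
    dplyr::select(dplyr::all_of(trial_table_columns))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads and validates a trial-table CSV: required columns present, phases in
#' 1-3, raw confidence within the 0-10 scale, trial indices 0-based and
#' contiguous within each block. The normalized confidence is derived from
#' `confidence_raw` when absent.
#'
#' @param path CSV file path.
#' @return A validated trial tibble sorted by subject, block and trial.
#' @export
read_trial_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- setdiff(trial_table_columns,
                      c("confidence", "reward_observed", "correct"))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  bad_phase <- which(!tab$phase %in% 1:3)
  if (length(bad_phase) > 0) {
    abort(paste0("Invalid phase in row(s): ",
                 paste(utils::head(bad_phase, 5), collapse = ", ")))
  }
  bad_conf <- which(!is.finite(tab$confidence_raw) |
                      tab$confidence_raw < 0 | tab$confidence_raw > 10)
  if (length(bad_conf) > 0) {
    abort(paste0("confidence_raw outside [0, 10] in row(s): ",
                 paste(utils::head(bad_conf, 5), collapse = ", ")))
  }
  if (!"confidence" %in% names(tab)) {
    tab$confidence <- tab$confidence_raw / 10
  }
  if (!"reward_observed" %in% names(tab)) {
    tab$reward_observed <- is.finite(tab$reward)
  }
  if (!"correct" %in% names(tab)) {
    tab$correct <- dplyr::if_else(
      tab$left_value == tab$right_value, NA,
      tab$chosen_value > pmin(tab$left_value, tab$right_value)
    )
  }
  tab <- dplyr::arrange(tab, .data$subject_id, .data$block, .data$trial)
  gaps <- tab |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::summarise(
      ok = identical(as.integer(.data$trial),
                     seq(0L, length.out = dplyr::n())),
      .groups = "drop"
    )
  if (any(!gaps$ok)) {
    bad <- gaps[!gaps$ok, ]
    abort(paste0("Non-contiguous trial indices for subject/block: ",
                 paste(bad$subject_id, bad$block, sep = "/",
                       collapse = ", ")))
  }
  tab
}
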