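# Task-design generator: block structure, CS values, pair schedules, rewards.

#' Design configuration for the conditioning task
#'
#' Collects the tunable constants of the experimental design: an experiment of
#' 11 blocks of 27 trials, five conditioned stimuli (CS) per block assigned to
#' four distinct monetary value levels (one level duplicated), a feedback phase
#' 1 of 9/12/15/18 trials, a no-feedback phase 2 of 5/10/15 trials (omitted in
#' two control blocks) and a closing feedback phase 3 filling the block to 27
#' trials. Rewards are integer euro amounts drawn from a normal distribution
#' (SD 10) truncated to the 0-50 range of a 50-field scratch card.
#'
#' @param n_blocks Number of blocks per experiment.
#' @param n_control Number of control blocks in which phase 2 is omitted.
#' @param trials_per_block Trials per block.
#' @param n_cs Conditioned stimuli per block.
#' @param n_value_levels Distinct CS value levels per block.
#' @param phase1_lengths Admissible phase-1 lengths (trials).
#' @param phase2_lengths Admissible phase-2 lengths for non-control blocks.
#' @param mean_levels Admissible block mean reward levels (euros).
#' @param difficulties Admissible block difficulties (euros): the value
#'   separation between CS within a block.
#' @param reward_sd Standard deviation of the reward distribution (euros).
#' @param reward_range Truncation bounds of the reward distribution (euros).
#' @param value_spacing How the `n_value_levels` CS means are derived from
#'   `mean_level` and `difficulty`: `"adjacent"` places equally spaced levels
#'   with adjacent spacing equal to the difficulty; `"mean_pairwise"` chooses
#'   the spacing so that the mean absolute pairwise value difference equals the
#'   difficulty.
#' @param min_phase3 Minimum number of phase-3 trials per block.
#'
#' @return A list of class `confrl_design_config`.
#' @export
design_config <- function(n_blocks = 11L,
                          n_control = 2L,
                          trials_per_block = 27L,
                          n_cs = 5L,
                          n_value_levels = 4L,
                          phase1_lengths = c(9L, 12L, 15L, 18L),
                          phase2_lengths = c(5L, 10L, 15L),
                          mean_levels = c(18, 23, 28),
                          difficulties = c(3, 6),
                          reward_sd = 10,
                          reward_range = c(0, 50),
                          value_spacing = c("adjacent", "mean_pairwise"),
                          min_phase3 = 1L) {
  value_spacing <- match.arg(value_spacing)
  cfg <- list(
    n_blocks = as.integer(n_blocks), n_control = as.integer(n_control),
    trials_per_block = as.integer(trials_per_block), n_cs = as.integer(n_cs),
    n_value_levels = as.integer(n_value_levels),
    phase1_lengths = as.integer(phase1_lengths),
    phase2_lengths = as.integer(phase2_lengths),
    mean_levels = mean_levels, difficulties = difficulties,
    reward_sd = reward_sd, reward_range = reward_range,
    value_spacing = value_spacing, min_phase3 = as.integer(min_phase3)
  )
  if (cfg$n_control > cfg$n_blocks) {
    abort("`n_control` cannot exceed `n_blocks`.")
  }
  if (cfg$n_value_levels > cfg$n_cs) {
    abort("`n_value_levels` cannot exceed `n_cs`.")
  }
  if (any(cfg$phase1_lengths + min(cfg$phase2_lengths) >
            cfg$trials_per_block - cfg$min_phase3) &&
      !any(cfg$phase1_lengths + min(cfg$phase2_lengths) <=
             cfg$trials_per_block - cfg$min_phase3)) {
    abort("No admissible phase-1/phase-2 combination leaves room for phase 3.")
  }
  structure(cfg, class = "confrl_design_config")
}

# Spacing between adjacent CS value levels for a given difficulty.
level_spacing <- function(difficulty, n_levels, mode) {
  if (mode == "adjacent") {
    return(difficulty)
  }
  # mean absolute pairwise difference of n equally spaced values with
  # spacing s is s * (n + 1) / 3; solve for s
  difficulty * 3 / (n_levels + 1)
}

#' Generate the design of a single block
#'
#' Builds one block: CS identities, CS mean values (four equally spaced levels
#' centred on the block mean level, one level assigned to two CS), phase
#' lengths and a balanced pair schedule.
#'
#' @param block_params A list with elements `block_index`, `stimulus_type`
#'   (0 or 1), `mean_level`, `difficulty`, `n1`, `n2`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as when called from [generate_experiment_design()]).
#' @param config A [design_config()].
#'
#' @return A list of class `confrl_block` with fields `block_index`,
#'   `stimulus_type`, `cs_ids`, `cs_means` (named euros), `mean_level`,
#'   `difficulty`, `n1`, `n2`, `n3` and `pair_schedule` (a tibble with one row
#'   per trial: `trial`, `phase`, `left_cs`, `right_cs`).
#' @export
generate_block_design <- function(block_params, seed = NULL,
                                  config = design_config()) {
  p <- block_params
  needed <- c("block_index", "stimulus_type", "mean_level", "difficulty",
              "n1", "n2")
  if (!all(needed %in% names(p))) {
    abort(paste0("`block_params` must name: ", paste(needed, collapse = ", ")))
  }
  n1 <- as.integer(p$n1)
  n2 <- as.integer(p$n2)
  if (n1 + n2 > config$trials_per_block) {
    abort(sprintf("n1 + n2 = %d exceeds the %d trials of a block.",
                  n1 + n2, config$trials_per_block))
  }
  n3 <- config$trials_per_block - n1 - n2

  local_seed(seed, {
    cs_ids <- sprintf("B%02d_CS%d", p$block_index, seq_len(config$n_cs))
    s <- level_spacing(p$difficulty, config$n_value_levels,
                       config$value_spacing)
    offsets <- (seq_len(config$n_value_levels) -
                  (config$n_value_levels + 1) / 2) * s
    levels <- p$mean_level + offsets
    dup <- sample.int(config$n_value_levels, config$n_cs -
                        config$n_value_levels, replace = FALSE)
    cs_means <- sample(c(levels, levels[dup]))
    names(cs_means) <- cs_ids

    sched <- build_pair_schedule(cs_ids, n1, n2, n3)

    structure(
      list(
        block_index = as.integer(p$block_index),
        stimulus_type = as.integer(p$stimulus_type),
        cs_ids = cs_ids, cs_means = cs_means,
        mean_level = p$mean_level, difficulty = p$difficulty,
        n1 = n1, n2 = n2, n3 = n3,
        pair_schedule = sched
      ),
      class = "confrl_block"
    )
  })
}

#' Build a balanced pair schedule
#'
#' Schedules trials phase by phase so that within each phase every CS appears
#' a near-equal number of times (appearance counts differ by at most 2), with
#' randomized left/right placement and no CS paired with itself. Each trial
#' greedily pairs the two CS with the fewest appearances so far, with random
#' tie-breaking.
#'
#' @param cs_ids Character vector of at least two CS identifiers.
#' @param n1,n2,n3 Trial counts of phases 1-3 (any may be 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#'
#' @return A tibble with columns `trial` (0-based within block), `phase`,
#'   `left_cs`, `right_cs`.
#' @export
build_pair_schedule <- function(cs_ids, n1, n2, n3, seed = NULL) {
  if (length(cs_ids) < 2) {
    abort("At least two CS are required to build a pair schedule.")
  }
  lens <- c(n1, n2, n3)
  if (any(lens < 0)) abort("Phase lengths must be non-negative.")
  local_seed(seed, {
    rows <- vector("list", sum(lens))
    idx <- 0L
    trial <- 0L
    for (ph in 1:3) {
      counts <- stats::setNames(rep(0L, length(cs_ids)), cs_ids)
      for (t in seq_len(lens[ph])) {
        ord <- order(counts + runif(length(counts), 0, 0.999))
        pick <- cs_ids[ord[1:2]]
        if (runif(1) < 0.5) pick <- rev(pick)
        counts[pick] <- counts[pick] + 1L
        idx <- idx + 1L
        rows[[idx]] <- list(trial = trial, phase = ph,
                            left_cs = pick[1], right_cs = pick[2])
        trial <- trial + 1L
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Draw scratch-card rewards
#'
#' Rewards are whole 1-euro amounts on a 50-field scratch card: draws from a
#' normal distribution with the CS mean and SD `sd`, truncated to
#' `range`, rounded to the nearest integer.
#'
#' @param cs_mean Mean reward of the CS (euros), strictly inside `range`.
#' @param n Number of draws.
#' @param sd Standard deviation before truncation (euros).
#' @param range Truncation bounds (euros).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#'
#' @return Numeric vector of `n` integer-valued rewards within `range`.
#' @export
draw_reward <- function(cs_mean, n = 1, sd = 10, range = c(0, 50),
                        seed = NULL) {
  if (!is.finite(cs_mean) || cs_mean <= range[1] || cs_mean >= range[2]) {
    abort(sprintf("`cs_mean` must lie strictly within [%g, %g].",
                  range[1], range[2]))
  }
  local_seed(seed, {
    lo <- stats::pnorm(range[1], cs_mean, sd)
    hi <- stats::pnorm(range[2], cs_mean, sd)
    round(qnorm(runif(n, lo, hi), cs_mean, sd))
  })
}

# Assign phase lengths jointly so every block keeps >= min_phase3 trials for
# phase 3. Long phase-2 blocks are matched to short phase-1 blocks first.
assign_phase_lengths <- function(config) {
  n <- config$n_blocks
  cap <- config$trials_per_block - config$min_phase3
  n_active <- n - config$n_control
  # the longest phase 2 can require the shortest phase 1; make sure the
  # short phase-1 level is plentiful enough
  active_pool <- balanced_assign(config$phase2_lengths, n_active)
  n1_pool <- balanced_assign(config$phase1_lengths, n,
                             force_extra = min(config$phase1_lengths))
  control <- if (config$n_control > 0) {
    sample.int(n, config$n_control)
  } else {
    integer(0)
  }
  n2 <- integer(n)
  n2[setdiff(seq_len(n), control)] <- active_pool

  # randomized assignment of the n1 pool, most constrained n2 first
  n1 <- integer(n)
  remaining <- n1_pool
  for (b in order(-n2)) {
    ok <- which(remaining + n2[b] <= cap)
    if (length(ok) == 0) {
      abort("Phase-length pools admit no valid assignment; relax the config.")
    }
    pick <- if (length(ok) == 1) ok else sample(ok, 1)
    n1[b] <- remaining[pick]
    remaining <- remaining[-pick]
  }
  list(n1 = n1, n2 = n2, control = sort(control))
}

#' Generate a full experiment design
#'
#' Generates the block sequence of one synthetic experiment: condition factors
#' (mean level, difficulty, stimulus type, phase lengths) are cycled through
#' shuffled balanced pools so that each level appears as evenly as the block
#' count allows, two control blocks omit phase 2, and each block receives CS
#' values and a balanced pair schedule via [generate_block_design()]. The same
#' configuration and seed always reproduce the identical design.
#'
#' @param config A [design_config()].
#' @param seed Integer seed.
#'
#' @return A list of class `confrl_design` with fields `blocks` (list of
#'   `confrl_block`), `seed` and `config`.
#' @export
generate_experiment_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "confrl_design_config"))
  local_seed(seed, {
    ph <- assign_phase_lengths(config)
    # stimulus types: half/half, the odd block's type decided by the RNG
    n_half <- config$n_blocks %/% 2
    counts <- c(n_half, config$n_blocks - n_half)
    if (runif(1) < 0.5) counts <- rev(counts)
    stim <- sample(rep(0:1, counts))
    mean_level <- balanced_assign(config$mean_levels, config$n_blocks)
    difficulty <- balanced_assign(config$difficulties, config$n_blocks)

    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      generate_block_design(
        list(block_index = b, stimulus_type = stim[b],
             mean_level = mean_level[b], difficulty = difficulty[b],
             n1 = ph$n1[b], n2 = ph$n2[b]),
        seed = NULL, config = config
      )
    })
    structure(list(blocks = blocks, seed = as.integer(seed), config = config),
              class = "confrl_design")
  })
}

#' Flatten a design into a scheduled trial tibble
#'
#' @param design A `confrl_design`.
#' @return A tibble with one row per scheduled trial: `block`, `trial`
#'   (0-based within block), `phase`, `left_cs`, `right_cs`, `left_value`,
#'   `right_value`, `stimulus_type`, `mean_level`, `difficulty`, `n1`, `n2`.
#' @export
design_trials <- function(design) {
  stopifnot(inherits(design, "confrl_design"))
  purrr::map_dfr(design$blocks, function(bl) {
    sched <- bl$pair_schedule
    tibble::tibble(
      block = bl$block_index,
      trial = sched$trial,
      phase = sched$phase,
      left_cs = sched$left_cs,
      right_cs = sched$right_cs,
      left_value = unname(bl$cs_means[sched$left_cs]),
      right_value = unname(bl$cs_means[sched$right_cs]),
      stimulus_type = bl$stimulus_type,
      mean_level = bl$mean_level,
      difficulty = bl$difficulty,
      n1 = bl$n1, n2 = bl$n2
    )
  })
}

#' @export
print.confrl_design <- function(x, ...) {
  n2 <- vapply(x$blocks, `[[`, integer(1), "n2")
  cat(sprintf(
    "<confrl_design> %d blocks (%d control), %d trials each, seed %d\n",
    length(x$blocks), sum(n2 == 0),
    x$config$trials_per_block, x$seed
  ))
  invisible(x)
}
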