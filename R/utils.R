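# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# When seed is NULL the current RNG stream is used (callers inside an outer
# seeded scope pass NULL to keep a single reproducible stream).
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive n child seeds (< 2^31) from a master seed, reproducibly.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# sample() treats a length-1 numeric as 1:x; guard against that.
shuffle <- function(x) {
  if (length(x) <= 1) x else sample(x)
}

# Distribute `levels` over n slots as evenly as possible, in shuffled order.
# `force_extra` guarantees a given level is among those receiving the extra
# slot (used to keep joint phase-length constraints satisfiable).
balanced_assign <- function(levels, n, force_extra = NULL) {
  k <- length(levels)
  base <- rep(levels, n %/% k)
  n_extra <- n %% k
  extra <- if (n_extra > 0) levels[sample.int(k, n_extra)] else levels[0]
  if (!is.null(force_extra) && n_extra > 0 && !(force_extra %in% extra)) {
    extra[1] <- force_extra
  }
  shuffle(c(base, extra))
}

# OLS slope of y on x (NA when fewer than 2 points or x is constant).
ols_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2 || var(x) == 0) {
    return(NA_real_)
  }
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    return(NA_real_)
  }
  sd(x) / sqrt(length(x))
}

# Canonical key for an unordered CS pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
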