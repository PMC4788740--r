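# internal helpers

# Run code under a temporary RNG seed without clobbering the caller's stream.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    abs(x - round(x)) < sqrt(.Machine$double.eps)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

check_proportion <- function(x, name) {
  if (!is_proportion(x)) {
    abort(paste0("`", name, "` must be a single value in [0, 1]."))
  }
  invisible(x)
}

# guarded binomial success probability num / (num + alt); returns 0 when both
# components vanish (degenerate conditional, documented epsilon guard)
safe_odds <- function(num, alt) {
  den <- num + alt
  if (!is.finite(den) || den <= 0) {
    if (num > 0) return(1)
    return(0)
  }
  min(max(num / den, 0), 1)
}
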