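## Run code with a fixed RNG seed, restoring the caller's RNG state on exit.
## All stochastic operations in the package funnel through this so that a
## (params, seed) pair is fully reproducible without disturbing user code.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eleaf <- function(stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  stop(msg, call. = FALSE)
}

check_number <- function(x, name, lo = -Inf, hi = Inf, stage = "config") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_eleaf(stage, "`", name, "` must be a single number")
  }
  if (x < lo || x > hi) {
    stop_eleaf(stage, "`", name, "` = ", format(x),
               " outside allowed range [", lo, ", ", hi, "]")
  }
  invisible(x)
}
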