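# Internal helpers shared across modules.

# Run `expr` under a temporarily seeded RNG, restoring the caller's RNG state.
# All user-facing randomness is funneled through this so that a given seed
# yields bitwise-identical output regardless of the surrounding session.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stage-labelled condition constructor: every error path names its stage and
# a machine-readable reason code.
fv_stop <- function(stage, reason, message, call. = FALSE) {
  cond <- structure(
    class = c(paste0("fibervitals_", reason), "fibervitals_error",
              "error", "condition"),
    list(message = sprintf("[%s] %s: %s", stage, reason, message),
         call = if (call.) sys.call(-1) else NULL,
         stage = stage, reason = reason)
  )
  stop(cond)
}

fv_warn <- function(stage, reason, message) {
  warning(sprintf("[%s] %s: %s", stage, reason, message), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
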