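# Structured condition helpers. Every package error carries a specific class
# ("nerveloc_<what>") so callers can condition on failure mode rather than on
# message text.

nl_stop <- function(class, msg, ..., call = sys.call(-1)) {
  stop(errorCondition(
    sprintf(msg, ...),
    class = c(paste0("nerveloc_", class), "nerveloc_error"),
    call = call
  ))
}

nl_warn <- function(class, msg, ...) {
  warning(warningCondition(
    sprintf(msg, ...),
    class = c(paste0("nerveloc_", class), "nerveloc_warning")
  ))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps fits and simulators
# reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
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
  }
  force(expr)
}
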