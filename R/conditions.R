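## Classed conditions so callers can distinguish failure modes programmatically.

metaboError <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "metabOPLSError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

metaboWarning <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "metabOPLSWarning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

## Muffle package warnings inside repeated-refit loops (the caller already
## saw the condition once on the primary fit).
.quietly <- function(expr) {
  withCallingHandlers(expr, metabOPLSWarning = function(w)
    invokeRestart("muffleWarning"))
}

## Evaluate expr under a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    metaboError("SpecError", "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
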