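# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific child seed from a root seed so that stages draw
# from independent, individually reproducible streams (kept < 2^31).
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 7919L * (offs %% 100003L)) %% .Machine$integer.max
}

stop_if_not_prob <- function(x, name, strict_upper = FALSE) {
  hi_ok <- if (strict_upper) all(x < 1) else all(x <= 1)
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || !hi_ok)
    stop(sprintf("`%s` must lie in [0, 1%s]", name,
                 if (strict_upper) ")" else ""), call. = FALSE)
  invisible(x)
}
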