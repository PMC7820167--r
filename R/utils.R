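# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` runs `code` against the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

check_prob <- function(x, name, len_ok = TRUE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be numeric probabilities in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
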