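# Internal helpers shared across modules.

logistic <- function(x) 1 / (1 + exp(-x))

# Run expr with a temporary RNG state so package functions never disturb the
# caller's random stream.
with_local_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# scalar validators ----------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_config("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_config("'%s' must be a single number in [%s, %s]", name, min, max)
  as.numeric(x)
}
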