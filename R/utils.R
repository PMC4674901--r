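# Internal helpers: seed scoping and argument checks.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop("`", name, "` must be > ", min, " (got ", x, ")", call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop("`", name, "` must be >= ", min, " (got ", x, ")", call. = FALSE)
  }
  if (x > max) {
    stop("`", name, "` must be <= ", max, " (got ", x, ")", call. = FALSE)
  }
  if (integerish && x != floor(x)) {
    stop("`", name, "` must be an integer (got ", x, ")", call. = FALSE)
  }
  x
}

# Pad a counts (or cumulative) vector on the right.
pad_right <- function(x, len, fill = 0) {
  if (length(x) >= len) return(x[seq_len(len)])
  c(x, rep(fill, len - length(x)))
}
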