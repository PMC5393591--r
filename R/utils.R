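# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream (mirrors the local-seed idiom of simulate() methods).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# K child seeds derived deterministically from one parent seed, all < 2^31.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

check_matrix <- function(X, name = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(X)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  X
}
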