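`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream tag.
sub_seed <- function(seed, tag) {
  (as.integer(seed) %% 1000003L) * 1009L + (sum(utf8ToInt(tag)) %% 997L)
}
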