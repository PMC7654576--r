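# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never perturb the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index * 7919) %% 2147483647)
}

stop_retispec <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "retispec_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
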