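# Condition classes shared across the package. Validation problems (bad
# parameters, malformed files) and numeric failures (gradient blow-up,
# degenerate firing) are kept distinct so the CLI can map them to exit codes.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("anfiscall_validation_error", "anfiscall_error")))
}

abort_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("anfiscall_numeric_error", "anfiscall_error")))
}

warn_anfiscall <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "anfiscall_warning"))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomness in the package flows
# through this helper so library calls never disturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_validation("seed must be a single finite number, got %s", format(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: keeps derived seeds inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1009L
}

clip01 <- function(x) {
  # pmin/pmax take attributes from their first argument, which would strip
  # matrix dims; restore them.
  y <- pmin(1, pmax(0, x))
  attributes(y) <- attributes(x)
  y
}
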