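# Shared fixtures. Everything is built in code; the only stored fixture is
# the six-base worked example shipped with the package itself.

# Independent brute-force Sugeno inference: explicit loop over rules and
# antecedent MFs, no shared code with infer() beyond mf_eval().
infer_oracle <- function(fis, x) {
  x <- as.numeric(x)
  num <- 0; den <- 0
  for (i in seq_len(nrow(fis$antecedents))) {
    w <- if (fis$tnorm == "product") 1 else Inf
    for (v in seq_along(fis$inputs)) {
      mu <- mf_eval(fis$inputs[[v]]$mfs[[fis$antecedents[i, v]]], x[v])
      w <- if (fis$tnorm == "product") w * mu else min(w, mu)
    }
    num <- num + w * fis$consequents[i]
    den <- den + w
  }
  num / den
}

# Random grid-partitioned FIS: 1-3 inputs, 2-5 MFs, random family/tnorm,
# consequents ~ U(0,1). Caller controls the RNG state.
random_fis <- function(max_inputs = 3L, tnorm = NULL) {
  d <- sample(max_inputs, 1L)
  vars <- lapply(seq_len(d), function(v)
    fuzzy_variable(paste0("x", v), n_mfs = sample(2:5, 1L),
                   family = sample(mf_families(), 1L)))
  if (is.null(tnorm)) tnorm <- sample(c("product", "min"), 1L)
  fis <- grid_partition(vars, tnorm = tnorm)
  fis$consequents <- stats::runif(nrow(fis$antecedents))
  fis
}

# Teacher for function-recovery experiments: default grid premises with
# uniform random consequents; samples drawn uniformly on the unit square.
make_teacher_problem <- function(seed, n = 500L, family = "triangular") {
  teacher <- grid_partition(list(
    fuzzy_variable("x1", n_mfs = 5, family = family),
    fuzzy_variable("x2", n_mfs = 5, family = family)))
  set.seed(seed)
  teacher$consequents <- stats::runif(nrow(teacher$antecedents))
  X <- matrix(stats::runif(2 * n), ncol = 2)
  y <- infer(teacher, X)
  list(teacher = teacher, samples = sample_set(X, y, "teacher"))
}

fresh_student <- function(target_mid = 0.5, family = "triangular") {
  grid_partition(list(
    fuzzy_variable("x1", n_mfs = 5, family = family),
    fuzzy_variable("x2", n_mfs = 5, family = family)),
    consequent = target_mid)
}

# A pipeline trained once per test run on default synthetic files and cached.
# 200 epochs is enough for every qualitative property the unit tests assert;
# the acceptance suite trains the full 500-epoch regime itself.
.model_cache <- new.env(parent = emptyenv())
trained_model <- function(epochs = 200L, seed = 1L) {
  key <- sprintf("m_%d_%d", epochs, seed)
  if (is.null(.model_cache[[key]])) {
    files <- make_training_files(generator_config(seed = seed))
    .model_cache[[key]] <- fit_pipeline(
      files, training_config(epochs = epochs, seed = seed))
  }
  .model_cache[[key]]
}

# Constant-output pipeline: every consequent of every system set to `value`.
constant_model <- function(value) {
  m <- new_pipeline_model()
  for (slot in c("peakness_fis", "height_fis", "spacing_fis", "confidence_fis"))
    m[[slot]]$consequents <- rep(value, length(m[[slot]]$consequents))
  m$fitted <- TRUE
  m
}

expect_mf_ordering <- function(fis) {
  for (v in fis$inputs)
    for (m in v$mfs)
      expect_null(anfiscall:::mf_param_problem(m$family, m$params))
}
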