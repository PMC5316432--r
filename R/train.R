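#' Supervised sample sets
#'
#' A labeled collection of `(x, y)` pairs: an `n x d` input matrix with
#' targets in `[0, 1]`. All values must be finite.
#'
#' @param x numeric matrix (or data frame) of inputs, one row per record.
#' @param y numeric target vector, length `nrow(x)`.
#' @param name identifier carried through logs and splits.
#' @return an object of class `sample_set`.
#' @export
sample_set <- function(x, y, name = "samples") {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) == 0L) abort_validation("sample set '%s' is empty", name)
  if (length(y) != nrow(X))
    abort_validation("sample set '%s': %d rows but %d targets", name, nrow(X), length(y))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    abort_validation("sample set '%s': all values must be finite", name)
  structure(list(x = X, y = y, name = as.character(name)), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set '%s'> %d records, %d input(s)\n",
              x$name, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' @export
length.sample_set <- function(x) nrow(x$x)

subset_samples <- function(s, idx, suffix) {
  sample_set(s$x[idx, , drop = FALSE], s$y[idx], paste0(s$name, suffix))
}

#' Train/test split
#'
#' Default mode is `contiguous` -- the first `n_train` records train, the
#' remainder test, matching the convention of splitting a 500-record file
#' into 350 training and 150 testing samples. `shuffled` permutes records
#' reproducibly from `seed` before splitting.
#'
#' @param samples a [sample_set()].
#' @param n_train number of training records (`0 < n_train < length(samples)`).
#' @param mode `"contiguous"` (default) or `"shuffled"`.
#' @param seed required in shuffled mode.
#' @return list with elements `train` and `test`, both `sample_set`s.
#' @export
split_samples <- function(samples, n_train = 350L,
                          mode = c("contiguous", "shuffled"), seed = NULL) {
  stopifnot(inherits(samples, "sample_set"))
  mode <- match.arg(mode)
  n <- length(samples)
  n_train <- as.integer(n_train)
  if (is.na(n_train) || n_train <= 0L || n_train >= n)
    abort_validation("n_train must satisfy 0 < n_train < %d, got %s", n, format(n_train))
  idx <- seq_len(n)
  if (mode == "shuffled") {
    if (is.null(seed)) abort_validation("shuffled mode requires a seed")
    idx <- with_seed(seed, sample.int(n))
  }
  list(train = subset_samples(samples, idx[seq_len(n_train)], "_train"),
       test  = subset_samples(samples, idx[(n_train + 1L):n], "_test"))
}

#' Training configuration
#'
#' Defaults mirror the training regime of the confidence model: full-batch
#' backpropagation for 500 epochs. The step size follows the classic ANFIS
#' adaptation rule: after 4 consecutive accepted error decreases it grows by
#' 10%; a step that would increase the training error is rejected and the
#' step size shrinks by 10%.
#'
#' @param epochs number of training epochs (default 500).
#' @param learning_rate initial step length along the normalized gradient
#'   (default 0.02).
#' @param lr_adaptation `"step_adaptive"` (default) or `"fixed"`.
#' @param method `"backprop"` (default) or `"hybrid"` (least-squares
#'   consequent solve each epoch, then one gradient step on the premises).
#' @param seed RNG seed recorded for provenance (training itself is
#'   deterministic; the seed feeds data generation upstream).
#' @param consequent_bounds optional `c(lo, hi)`; consequents are projected
#'   into this interval after every update, which in turn bounds all outputs.
#' @return an object of class `training_config`.
#' @export
training_config <- function(epochs = 500L, learning_rate = 0.02,
                            lr_adaptation = c("step_adaptive", "fixed"),
                            method = c("backprop", "hybrid"),
                            seed = 1L, consequent_bounds = NULL) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) abort_validation("epochs must be >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    abort_validation("learning_rate must be positive")
  if (!is.null(consequent_bounds) &&
      (length(consequent_bounds) != 2L || consequent_bounds[1] >= consequent_bounds[2]))
    abort_validation("consequent_bounds must be c(lo, hi) with lo < hi")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 lr_adaptation = match.arg(lr_adaptation),
                 method = match.arg(method), seed = as.integer(seed),
                 batch = "full", consequent_bounds = consequent_bounds),
            class = "training_config")
}

# ---- parameter packing -----------------------------------------------------

premise_params <- function(fis) {
  lapply(fis$inputs, function(v) lapply(v$mfs, `[[`, "params"))
}

set_premise_params <- function(fis, theta) {
  for (v in seq_along(fis$inputs))
    for (k in seq_along(fis$inputs[[v]]$mfs))
      fis$inputs[[v]]$mfs[[k]]$params <- theta[[v]][[k]]
  fis
}

project_premises <- function(fis) {
  for (v in seq_along(fis$inputs)) {
    dom <- fis$inputs[[v]]$domain
    for (k in seq_along(fis$inputs[[v]]$mfs)) {
      m <- fis$inputs[[v]]$mfs[[k]]
      fis$inputs[[v]]$mfs[[k]]$params <- mf_project(m$family, m$params)
    }
  }
  fis
}

flatten_theta <- function(theta) unlist(theta, use.names = FALSE)

unflatten_theta <- function(flat, template) {
  pos <- 0L
  for (v in seq_along(template))
    for (k in seq_along(template[[v]])) {
      n <- length(template[[v]][[k]])
      template[[v]][[k]] <- flat[pos + seq_len(n)]
      pos <- pos + n
    }
  template
}

# ---- forward / backward ----------------------------------------------------

anfis_forward <- function(fis, X, y) {
  W <- firing_strengths(fis, X)
  S <- rowSums(W)
  S[S == 0] <- 1e-12
  o <- as.numeric(W %*% fis$consequents) / S
  r <- o - y
  list(W = W, S = S, o = o, r = r, rmse = sqrt(mean(r^2)))
}

# Full-batch gradient of the mean squared error with respect to every
# premise parameter and every consequent, via the standard ANFIS chain rule
# through the weighted-average defuzzifier. Product t-norm only.
anfis_gradients <- function(fis, X, fw) {
  if (fis$tnorm != "product")
    abort_validation("gradient training requires the product t-norm")
  N <- nrow(X)
  ant <- fis$antecedents
  d <- n_inputs(fis)
  degs <- lapply(seq_len(d), function(v) variable_degrees(fis$inputs[[v]], X[, v]))
  cons <- fis$consequents
  scale <- 2 / N

  g_cons <- scale * as.numeric(crossprod(fw$W / fw$S, fw$r))

  g_theta <- vector("list", d)
  # (c_i - o_j)/S_j enters every premise partial for rule i at sample j
  CO <- outer(fw$o, cons, function(o, cc) cc - o) / fw$S
  for (v in seq_len(d)) {
    Wexcl <- matrix(1, N, nrow(ant))
    for (u in seq_len(d)) if (u != v)
      Wexcl <- Wexcl * degs[[u]][, ant[, u], drop = FALSE]
    M <- Wexcl * CO
    g_theta[[v]] <- vector("list", length(fis$inputs[[v]]$mfs))
    for (k in seq_along(fis$inputs[[v]]$mfs)) {
      idx <- which(ant[, v] == k)
      A <- rowSums(M[, idx, drop = FALSE])
      G <- mf_grad(fis$inputs[[v]]$mfs[[k]], X[, v])
      g_theta[[v]][[k]] <- scale * as.numeric(crossprod(G, fw$r * A))
    }
  }
  list(theta = g_theta, consequents = g_cons)
}

solve_consequents <- function(fis, X, y, ridge = 1e-8) {
  W <- firing_strengths(fis, X)
  S <- rowSums(W)
  S[S == 0] <- 1e-12
  Wb <- W / S
  A <- crossprod(Wb)
  diag(A) <- diag(A) + ridge
  as.numeric(solve(A, crossprod(Wb, y)))
}

apply_cons_bounds <- function(cons, bounds) {
  if (is.null(bounds)) cons else pmin(bounds[2], pmax(bounds[1], cons))
}

#' Train a Sugeno system
#'
#' Full-batch supervised training. `method = "backprop"` takes one step per
#' epoch along the normalized gradient of the mean squared error with
#' respect to all membership-function parameters and consequents;
#' `method = "hybrid"` first solves the consequents exactly by (ridge
#' stabilized) linear least squares with the premises frozen, then takes one
#' gradient step on the premises. After every update the membership
#' parameters are projected back onto their feasible ordering (sort/clamp,
#' sigma floor, plateau collapse for two-sided Gaussians).
#'
#' With `lr_adaptation = "step_adaptive"` a step that would increase the
#' training RMSE is rejected (parameters stay put) and the step size
#' shrinks, so the recorded RMSE trace is non-increasing.
#'
#' @param fis a `sugeno_fis` whose input count matches the sample dimension.
#' @param train_set a [sample_set()].
#' @param cfg a [training_config()].
#' @param test_set optional held-out `sample_set`; if given, the final test
#'   RMSE is recorded in the result.
#' @param verbose print per-epoch RMSE every `verbose` epochs (0 = silent).
#' @return an object of class `anfis_run`: `fis` (trained),
#'   `train_rmse_by_epoch` (length `cfg$epochs`), `test_rmse` (or `NA`),
#'   `initial_rmse`, `config`.
#' @export
anfis_train <- function(fis, train_set, cfg = training_config(),
                        test_set = NULL, verbose = 0L) {
  stopifnot(inherits(fis, "sugeno_fis"), inherits(train_set, "sample_set"),
            inherits(cfg, "training_config"))
  if (ncol(train_set$x) != n_inputs(fis))
    abort_validation("FIS has %d input(s) but samples have %d column(s)",
                     n_inputs(fis), ncol(train_set$x))
  X <- clip_to_domain(fis, train_set$x)
  y <- train_set$y
  eta <- cfg$learning_rate
  adaptive <- cfg$lr_adaptation == "step_adaptive"
  rmse_trace <- numeric(cfg$epochs)
  streak <- 0L

  fw <- anfis_forward(fis, X, y)
  initial_rmse <- fw$rmse

  for (epoch in seq_len(cfg$epochs)) {
    if (cfg$method == "hybrid") {
      fis$consequents <- apply_cons_bounds(solve_consequents(fis, X, y),
                                           cfg$consequent_bounds)
      fw <- anfis_forward(fis, X, y)
    }
    gr <- anfis_gradients(fis, X, fw)
    theta <- premise_params(fis)
    g_flat <- flatten_theta(gr$theta)
    if (cfg$method == "backprop") {
      g_cons <- gr$consequents
      if (!is.null(cfg$consequent_bounds)) {
        # projected gradient: a consequent pinned at a bound with its
        # gradient pointing outside the box contributes nothing to the step
        # (otherwise blocked components dominate the normalized direction
        # and stall training).
        b <- cfg$consequent_bounds
        g_cons[fis$consequents <= b[1] & g_cons > 0] <- 0
        g_cons[fis$consequents >= b[2] & g_cons < 0] <- 0
      }
      g_flat <- c(g_flat, g_cons)
    }
    gnorm <- sqrt(sum(g_flat^2))

    if (!is.finite(fw$rmse) || !is.finite(gnorm))
      abort_numeric("non-finite training loss or gradient at epoch %d", epoch)

    if (gnorm > 1e-15) {
      n_theta <- length(flatten_theta(theta))
      theta_flat <- flatten_theta(theta)
      make_candidate <- function(step_len) {
        step <- -step_len / gnorm
        cand <- set_premise_params(fis, unflatten_theta(
          theta_flat + step * g_flat[seq_len(n_theta)], theta))
        cand <- project_premises(cand)
        if (cfg$method == "backprop")
          cand$consequents <- apply_cons_bounds(
            fis$consequents + step * g_flat[-seq_len(n_theta)],
            cfg$consequent_bounds)
        cand
      }
      if (!adaptive) {
        cand <- make_candidate(eta)
        fw_cand <- anfis_forward(cand, X, y)
        if (!is.finite(fw_cand$rmse))
          abort_numeric("non-finite training loss at epoch %d", epoch)
        fis <- cand
        fw <- fw_cand
      } else {
        # backtracking: a trial step that would raise the training error is
        # rejected and shrinks the rate; the first trial of an epoch that
        # succeeds outright extends the growth streak.
        first_try <- TRUE
        for (trial in seq_len(40L)) {
          cand <- make_candidate(eta)
          fw_cand <- anfis_forward(cand, X, y)
          if (!is.finite(fw_cand$rmse))
            abort_numeric("non-finite training loss at epoch %d", epoch)
          if (fw_cand$rmse <= fw$rmse) {
            fis <- cand
            fw <- fw_cand
            if (first_try) {
              streak <- streak + 1L
              if (streak >= 4L) { eta <- eta * 1.1; streak <- 0L }
            }
            break
          }
          eta <- eta * 0.9
          streak <- 0L
          first_try <- FALSE
        }
      }
    }
    rmse_trace[epoch] <- fw$rmse
    if (verbose > 0L && epoch %% verbose == 0L)
      message(sprintf("epoch %4d  train RMSE %.6f  step %.4g", epoch, fw$rmse, eta))
  }

  test_rmse <- if (!is.null(test_set)) evaluate_fis(fis, test_set) else NA_real_
  structure(list(fis = fis, train_rmse_by_epoch = rmse_trace,
                 test_rmse = test_rmse, initial_rmse = initial_rmse,
                 config = cfg),
            class = "anfis_run")
}

#' @export
print.anfis_run <- function(x, ...) {
  cat(sprintf("<anfis_run> %s, %d epochs: train RMSE %.5f -> %.5f%s\n",
              x$config$method, x$config$epochs, x$initial_rmse,
              x$train_rmse_by_epoch[length(x$train_rmse_by_epoch)],
              if (is.na(x$test_rmse)) "" else sprintf(", test RMSE %.5f", x$test_rmse)))
  invisible(x)
}

#' Held-out error of a Sugeno system
#'
#' Root-mean-square difference between `infer()` outputs and targets.
#'
#' @param fis a `sugeno_fis`.
#' @param test_set a non-empty [sample_set()] with matching input dimension.
#' @return the RMSE, a non-negative scalar.
#' @export
evaluate_fis <- function(fis, test_set) {
  stopifnot(inherits(fis, "sugeno_fis"), inherits(test_set, "sample_set"))
  if (ncol(test_set$x) != n_inputs(fis))
    abort_validation("FIS has %d input(s) but samples have %d column(s)",
                     n_inputs(fis), ncol(test_set$x))
  sqrt(mean((infer(fis, test_set$x) - test_set$y)^2))
}
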