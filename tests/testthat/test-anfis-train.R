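test_that("split_samples honors counts, modes and determinism", {
  set.seed(1)
  s <- sample_set(matrix(stats::runif(1000), ncol = 2), stats::runif(500))
  parts <- split_samples(s, 350)
  expect_equal(length(parts$train), 350L)
  expect_equal(length(parts$test), 150L)
  expect_equal(rbind(parts$train$x, parts$test$x), unname(s$x))

  tiny <- sample_set(matrix(c(0.1, 0.9)), c(0.2, 0.8))
  p2 <- split_samples(tiny, 1)
  expect_equal(length(p2$train), 1L)
  expect_equal(length(p2$test), 1L)

  a <- split_samples(s, 350, mode = "shuffled", seed = 99)
  b <- split_samples(s, 350, mode = "shuffled", seed = 99)
  expect_identical(a$train$x, b$train$x)
  expect_identical(a$test$y, b$test$y)
  # shuffled split is a permutation of the records
  expect_equal(sort(c(a$train$y, a$test$y)), sort(s$y))

  expect_error(split_samples(s, 0), class = "anfiscall_validation_error")
  expect_error(split_samples(s, 500), class = "anfiscall_validation_error")
  expect_error(split_samples(s, 350, mode = "shuffled"),
               class = "anfiscall_validation_error")
})

test_that("sample_set and training_config validate their fields", {
  expect_error(sample_set(matrix(1, 2, 2), c(0.5)), class = "anfiscall_validation_error")
  expect_error(sample_set(matrix(c(1, NA), 1), 0.5), class = "anfiscall_validation_error")
  expect_error(training_config(epochs = 0), class = "anfiscall_validation_error")
  expect_error(training_config(learning_rate = -1), class = "anfiscall_validation_error")
  expect_error(training_config(consequent_bounds = c(1, 0)),
               class = "anfiscall_validation_error")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  fis <- grid_partition(list(
    fuzzy_variable("a", n_mfs = 3, family = "triangular"),
    fuzzy_variable("b", n_mfs = 3, family = "gauss2")))
  fis$consequents <- stats::runif(9)
  X <- matrix(stats::runif(40), ncol = 2)
  y <- stats::runif(20)
  fw <- anfiscall:::anfis_forward(fis, X, y)
  gr <- anfiscall:::anfis_gradients(fis, X, fw)
  loss <- function(f) mean(anfiscall:::anfis_forward(f, X, y)$r^2)
  eps <- 1e-6

  gnum <- vapply(seq_along(fis$consequents), function(i) {
    f1 <- fis; f1$consequents[i] <- f1$consequents[i] + eps
    f2 <- fis; f2$consequents[i] <- f2$consequents[i] - eps
    (loss(f1) - loss(f2)) / (2 * eps)
  }, numeric(1))
  expect_equal(gr$consequents, gnum, tolerance = 1e-6)

  for (v in 1:2) for (k in 1:3) {
    p <- fis$inputs[[v]]$mfs[[k]]$params
    gnum <- vapply(seq_along(p), function(j) {
      f1 <- fis; f1$inputs[[v]]$mfs[[k]]$params[j] <- p[j] + eps
      f2 <- fis; f2$inputs[[v]]$mfs[[k]]$params[j] <- p[j] - eps
      (loss(f1) - loss(f2)) / (2 * eps)
    }, numeric(1))
    expect_equal(gr$theta[[v]][[k]], gnum, tolerance = 1e-6)
  }
})

test_that("training a self-consistent target is a fixed point", {
  set.seed(11)
  fis <- fresh_student()
  fis$consequents <- stats::runif(25)
  X <- matrix(stats::runif(200), ncol = 2)
  s <- sample_set(X, infer(fis, X))
  run <- anfis_train(fis, s, training_config(epochs = 5))
  expect_lt(run$initial_rmse, 1e-12)
  expect_true(all(run$train_rmse_by_epoch < 1e-12))
})

test_that("constant targets drive the output to the constant", {
  set.seed(12)
  X <- matrix(stats::runif(400), ncol = 2)
  s <- sample_set(X, rep(0.6, 200))
  run <- anfis_train(fresh_student(), s, training_config(epochs = 300))
  final <- run$train_rmse_by_epoch[300]
  expect_lt(final, 1e-3)
  expect_true(all(abs(infer(run$fis, X) - 0.6) < 5e-3))
})

test_that("step-adaptive training is monotone and beats its start", {
  set.seed(13)
  prob <- make_teacher_problem(13, n = 200)
  parts <- split_samples(prob$samples, 150)
  run <- anfis_train(fresh_student(mean(range(parts$train$y))), parts$train,
                     training_config(epochs = 120))
  expect_true(all(diff(run$train_rmse_by_epoch) <= 1e-14))
  expect_lte(run$train_rmse_by_epoch[120], run$initial_rmse)
})

test_that("training recovers a teacher FIS on held-out data", {
  prob <- make_teacher_problem(1)
  parts <- split_samples(prob$samples, 350)
  run <- anfis_train(fresh_student(mean(range(parts$train$y))), parts$train,
                     training_config(epochs = 500, seed = 1),
                     test_set = parts$test)
  expect_lte(run$test_rmse, 0.05)
})

test_that("MF ordering invariants survive training in every family", {
  for (fam in mf_families()) {
    prob <- make_teacher_problem(21, n = 120, family = fam)
    parts <- split_samples(prob$samples, 90)
    run <- anfis_train(fresh_student(0.5, family = fam), parts$train,
                       training_config(epochs = 60))
    expect_mf_ordering(run$fis)
  }
})

test_that("hybrid training is at least as good as backprop at equal epochs", {
  prob <- make_teacher_problem(31, n = 300)
  parts <- split_samples(prob$samples, 220)
  student <- fresh_student(mean(range(parts$train$y)))
  rb <- anfis_train(student, parts$train, training_config(epochs = 40, method = "backprop"))
  rh <- anfis_train(student, parts$train, training_config(epochs = 40, method = "hybrid"))
  expect_lte(rh$train_rmse_by_epoch[40], rb$train_rmse_by_epoch[40] + 1e-6)
})

test_that("evaluate_fis matches closed forms and ignores record order", {
  set.seed(14)
  fis <- fresh_student(0.5)
  X <- matrix(stats::runif(100), ncol = 2)
  perfect <- sample_set(X, infer(fis, X))
  expect_equal(evaluate_fis(fis, perfect), 0)

  const <- sample_set(X, rep(0.7, 50))
  expect_equal(evaluate_fis(fis, const), 0.2)  # |0.5 - 0.7|

  mixed <- sample_set(X, stats::runif(50))
  perm <- sample.int(50)
  expect_equal(evaluate_fis(fis, mixed),
               evaluate_fis(fis, sample_set(X[perm, ], mixed$y[perm])))
})

test_that("dimension mismatches are rejected", {
  fis <- fresh_student()
  s3 <- sample_set(matrix(stats::runif(30), ncol = 3), stats::runif(10))
  expect_error(anfis_train(fis, s3, training_config(epochs = 1)),
               class = "anfiscall_validation_error")
  expect_error(evaluate_fis(fis, s3), class = "anfiscall_validation_error")
})
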