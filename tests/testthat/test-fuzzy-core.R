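test_that("mf_eval matches the closed forms at anchor points", {
  tri <- membership_function("triangular", c(0, 0.5, 1))
  expect_equal(mf_eval(tri, 0.5), 1)
  expect_equal(mf_eval(tri, 0.25), 0.5)  # hand evaluation of (x-a)/(b-a)
  expect_equal(mf_eval(tri, c(-1, 0, 1, 2)), c(0, 0, 0, 0))

  trap <- membership_function("trapezoidal", c(0, 0.2, 0.8, 1))
  expect_equal(mf_eval(trap, 1.5), 0)
  expect_equal(mf_eval(trap, c(0.2, 0.5, 0.8)), c(1, 1, 1))
  expect_equal(mf_eval(trap, 0.1), 0.5)
  expect_equal(mf_eval(trap, 0.9), 0.5)

  g2 <- membership_function("gauss2", c(0.1, 0.4, 0.1, 0.6))
  expect_equal(mf_eval(g2, 0.5), 1)          # plateau
  expect_equal(mf_eval(g2, c(0.4, 0.6)), c(1, 1))
  expect_equal(mf_eval(g2, 0.3), exp(-0.01 / (2 * 0.01)))
})

test_that("invalid MF parameters are rejected at construction", {
  expect_error(membership_function("triangular", c(0.5, 0.2, 1)),
               class = "anfiscall_validation_error")
  expect_error(membership_function("triangular", c(0, 0, 0)),
               class = "anfiscall_validation_error")
  expect_error(membership_function("trapezoidal", c(0, 0.5, 0.4, 1)),
               class = "anfiscall_validation_error")
  expect_error(membership_function("gauss2", c(-0.1, 0.4, 0.1, 0.6)),
               class = "anfiscall_validation_error")
  expect_error(membership_function("gauss2", c(0.1, 0.7, 0.1, 0.6)),
               class = "anfiscall_validation_error")
  expect_error(membership_function("triangular", c(0, NA, 1)),
               class = "anfiscall_validation_error")
})

test_that("mf_eval maps the real line into [0,1] for random valid params", {
  set.seed(101)
  xs <- c(stats::runif(200, -2, 3), -1e6, 1e6)
  for (rep in 1:40) {
    p <- sort(stats::runif(4))
    mfs <- list(
      membership_function("triangular", p[1:3]),
      membership_function("trapezoidal", p),
      membership_function("gauss2", c(stats::runif(1, 0.01, 1), p[2],
                                      stats::runif(1, 0.01, 1), p[3])))
    for (m in mfs) {
      mu <- mf_eval(m, xs)
      expect_true(all(mu >= 0 & mu <= 1))
    }
  }
})

test_that("fuzzy_variable builds a uniform partition with full coverage", {
  v <- fuzzy_variable("NP_called", n_mfs = 5, family = "triangular")
  expect_equal(vapply(v$mfs, function(m) m$params[2], numeric(1)),
               c(0, 0.25, 0.5, 0.75, 1))

  v2 <- fuzzy_variable("x", n_mfs = 2, family = "triangular")
  expect_equal(vapply(v2$mfs, function(m) m$params[2], numeric(1)), c(0, 1))

  grid <- seq(0, 1, length.out = 501)
  for (fam in mf_families()) {
    v <- fuzzy_variable("x", n_mfs = 5, family = fam)
    deg <- vapply(v$mfs, mf_eval, numeric(length(grid)), x = grid)
    expect_gt(min(apply(deg, 1, max)), 0)
    centers <- vapply(v$mfs, anfiscall:::mf_center, numeric(1))
    expect_true(all(diff(centers) > 0))
  }

  expect_error(fuzzy_variable("x", n_mfs = 1), class = "anfiscall_validation_error")
  expect_error(fuzzy_variable("x", domain = c(1, 0)), class = "anfiscall_validation_error")
})

test_that("grid_partition enumerates the full factorial of MF indices", {
  cases <- list(list(mfs = c(5, 5), rules = 25L),
                list(mfs = c(5, 5, 5), rules = 125L),
                list(mfs = c(2), rules = 2L),
                list(mfs = c(3, 4), rules = 12L))
  for (cs in cases) {
    vars <- lapply(seq_along(cs$mfs), function(i)
      fuzzy_variable(paste0("x", i), n_mfs = cs$mfs[i], family = "triangular"))
    fis <- grid_partition(vars)
    expect_equal(nrow(fis$antecedents), cs$rules)
    expect_equal(nrow(unique(as.data.frame(fis$antecedents))), cs$rules)
  }
})

test_that("infer handles constant consequents and single active rules", {
  vars <- list(fuzzy_variable("a", n_mfs = 5, family = "triangular"),
               fuzzy_variable("b", n_mfs = 5, family = "gauss2"))
  fis <- grid_partition(vars, consequent = 0.7)
  set.seed(7)
  X <- matrix(stats::runif(40), ncol = 2)
  expect_equal(infer(fis, X), rep(0.7, 20))

  one <- grid_partition(list(fuzzy_variable("a", n_mfs = 5, family = "triangular")))
  one$consequents <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  # at apex k only rule k fires (triangular feet sit at neighboring apexes)
  expect_equal(infer(one, matrix(c(0, 0.25, 0.5, 0.75, 1))), one$consequents)
})

test_that("infer agrees with the brute-force rule-enumeration oracle", {
  set.seed(202)
  for (rep in 1:30) {
    fis <- random_fis()
    x <- stats::runif(length(fis$inputs))
    expect_equal(infer(fis, x), infer_oracle(fis, x), tolerance = 1e-12)
  }
})

test_that("infer output stays within the consequent range", {
  set.seed(303)
  for (rep in 1:20) {
    fis <- random_fis()
    fis$consequents <- stats::runif(length(fis$consequents), -2, 5)
    X <- matrix(stats::runif(30 * length(fis$inputs)), ncol = length(fis$inputs))
    out <- infer(fis, X)
    expect_true(all(out >= min(fis$consequents) - 1e-12))
    expect_true(all(out <= max(fis$consequents) + 1e-12))
  }
})

test_that("infer is continuous in its input", {
  set.seed(404)
  fis <- random_fis(max_inputs = 1L, tnorm = "product")
  grid <- seq(0, 1, length.out = 2001)
  out <- infer(fis, matrix(grid))
  # max jump between adjacent grid points shrinks with the grid step
  expect_lt(max(abs(diff(out))), 0.05)
  fine <- seq(0.3, 0.31, length.out = 2001)
  expect_lt(max(abs(diff(infer(fis, matrix(fine))))), 5e-4)
})

test_that("out-of-domain inputs are clipped with a warning", {
  fis <- grid_partition(list(fuzzy_variable("a", n_mfs = 3, family = "triangular")))
  fis$consequents <- c(0.2, 0.5, 0.8)
  expect_warning(out <- infer(fis, matrix(c(-0.5, 1.5))),
                 class = "anfiscall_warning")
  expect_equal(out, infer(fis, matrix(c(0, 1))))
})

test_that("zero total firing strength is guarded, not fatal", {
  fis <- grid_partition(list(fuzzy_variable("a", n_mfs = 2, family = "triangular")))
  # shrink supports so the middle of the domain is uncovered
  fis$inputs[[1]]$mfs[[1]]$params <- c(0, 0, 0.1)
  fis$inputs[[1]]$mfs[[2]]$params <- c(0.9, 1, 1)
  expect_warning(out <- infer(fis, matrix(0.5)), class = "anfiscall_warning")
  expect_true(is.finite(out))
})

test_that("FIS JSON round trip is bit-faithful and preserves inference", {
  set.seed(505)
  fis <- random_fis(tnorm = "product")
  # make the parameters "ugly" irrational-ish doubles
  fis$consequents <- fis$consequents * pi / 3
  path <- withr::local_tempfile(fileext = ".json")
  write_fis(fis, path)
  back <- read_fis(path)
  expect_identical(back$consequents, fis$consequents)
  for (v in seq_along(fis$inputs))
    for (k in seq_along(fis$inputs[[v]]$mfs))
      expect_identical(back$inputs[[v]]$mfs[[k]]$params,
                       fis$inputs[[v]]$mfs[[k]]$params)
  X <- matrix(stats::runif(25 * length(fis$inputs)), ncol = length(fis$inputs))
  expect_identical(infer(back, X), infer(fis, X))
})
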