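test_that("OLS matches a normal-equations + t-distribution oracle", {
  X <- cbind(a = c(1, 2, 3, 4, 5, 6, 7, 8),
             b = c(2, 1, 4, 3, 6, 5, 8, 7),
             c = c(1, 1, 2, 2, 3, 3, 4, 5))
  y <- c(3, 5, 4, 8, 9, 13, 12, 18)
  m <- ols_fit(X, y)

  Xi <- cbind(1, X)
  xtxi <- solve(t(Xi) %*% Xi)
  beta <- drop(xtxi %*% t(Xi) %*% y)
  resid <- y - drop(Xi %*% beta)
  s2 <- sum(resid^2) / (8 - 4)
  se <- sqrt(diag(xtxi) * s2)
  pv <- 2 * pt(-abs(beta / se), 8 - 4)

  expect_equal(unname(c(m$intercept, m$coefficients)), unname(beta),
               tolerance = 1e-10)
  expect_equal(unname(m$se), unname(se[-1]), tolerance = 1e-10)
  expect_equal(unname(m$p_values), unname(pv[-1]), tolerance = 1e-10)
  expect_equal(m$r_op, cor(drop(Xi %*% beta), y), tolerance = 1e-12)
})

test_that("exact relationships and degenerate designs behave", {
  x <- 1:20
  m <- ols_fit(cbind(x = x), 2 * x)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-12)
  expect_equal(m$r_op, 1, tolerance = 1e-12)

  X <- cbind(a = rnorm(30), b = 0)
  X[, "b"] <- 3 * X[, "a"]
  expect_error(ols_fit(X, rnorm(30)), "b")
  expect_error(ols_fit(cbind(a = rnorm(5), b = rnorm(5), c = rnorm(5),
                             d = rnorm(5)), rnorm(5)), "n > p")
})

test_that("null-feature p-values are not spuriously small", {
  set.seed(23)
  n <- 1000
  reps <- 500
  hits <- 0
  for (i in seq_len(reps)) {
    m <- ols_fit(cbind(x = rnorm(n)), rnorm(n))
    if (m$p_values[["x"]] > 0.001) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.99)
})

test_that("forward selection picks an exact predictor first", {
  set.seed(2)
  y <- rnorm(100)
  X <- cbind(noise = rnorm(100), copy = y)
  m <- forward_select(X, y)
  expect_equal(m$trace$feature[1], "copy")
  expect_equal(m$r_op, 1, tolerance = 1e-10)
  expect_equal(nrow(m$trace), 1)  # perfect fit stops selection
  expect_warning(
    expect_error(forward_select(cbind(k = rep(1, 50)), rnorm(50)),
                 "non-constant"),
    "constant candidate")
})

test_that("selection equals the exhaustive greedy lm() oracle step by step", {
  set.seed(13)
  for (rep in 1:3) {
    n <- 150
    X <- cbind(matrix(rnorm(n * 8), n),
               matrix(rbinom(n * 4, 1, 0.4), n))
    colnames(X) <- sprintf("f%02d", 1:12)
    y <- 0.8 * X[, 2] + 0.5 * X[, 10] - 0.4 * X[, 5] + rnorm(n)
    m <- forward_select(X, y, selection_config(max_steps = 5))
    oracle <- greedy_oracle(X, y, 5)
    expect_equal(m$trace$feature, colnames(X)[oracle$selected])
    expect_equal(m$trace$r_op, oracle$r_op, tolerance = 1e-9)
    # trace invariants
    expect_true(all(diff(m$trace$r_op) >= -1e-12))
    expect_equal(m$trace$increment, diff(c(0, m$trace$r_op)),
                 tolerance = 1e-12)
  }
})

test_that("running selection to exhaustion attains the full-model fit", {
  set.seed(4)
  n <- 60
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, letters[1:5]))
  y <- rnorm(n)
  m <- forward_select(X, y, selection_config(max_steps = 5))
  full <- ols_fit(X, y)
  expect_equal(m$r_op, full$r_op, tolerance = 1e-10)
  expect_setequal(m$features, full$features)
})

test_that("all-zero feature rows predict at the intercept", {
  set.seed(6)
  n <- 200
  X <- matrix(rbinom(n * 5, 1, 0.3), n,
              dimnames = list(NULL, paste0("b", 1:5)))
  X[1, ] <- 0
  y <- drop(0.4 + X %*% c(0.5, -0.2, 0.3, 0.1, -0.4)) + rnorm(n, 0, 0.1)
  m <- forward_select(X, y, selection_config(max_steps = 5))
  expect_equal(unname(predict(m, X)[1]), m$intercept, tolerance = 1e-12)
})

test_that("cross-validation is seeded, balanced and exact on noiseless data", {
  set.seed(8)
  n <- 400
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -2, 0.5)) + 3
  cv <- cross_validate_model(X, y, selection_config(max_steps = 3), seed = 5)
  expect_equal(cv$r_op_train, 1, tolerance = 1e-9)
  expect_equal(cv$r_op_test, 1, tolerance = 1e-9)
  expect_equal(cv$n_train, 200)

  cv2 <- cross_validate_model(X, y, selection_config(max_steps = 3), seed = 5)
  expect_identical(cv$r_op_test, cv2$r_op_test)
  expect_identical(cv$model$trace, cv2$model$trace)
  expect_error(cross_validate_model(X[1:100, ], y[1:100],
                                    selection_config()), "n >= 200")
})

test_that("the predicted mean profile averages per-line fits", {
  set.seed(10)
  n <- 30
  x <- rnorm(n)
  y1 <- 2 * x
  y2 <- -x + 1
  l1 <- list(features = cbind(x = x), y = y1)
  pmp_same <- build_predicted_mean_profile(list(l1, l1, l1),
                                           selection_config(max_steps = 1))
  expect_equal(as.numeric(pmp_same), y1, tolerance = 1e-10)

  l2 <- list(features = cbind(x = x), y = y2)
  pmp <- build_predicted_mean_profile(list(l1, l2),
                                      selection_config(max_steps = 1))
  expect_equal(as.numeric(pmp), (y1 + y2) / 2, tolerance = 1e-10)
  expect_error(build_predicted_mean_profile(
    list(l1, list(features = cbind(x = x[1:10]), y = y2[1:10]))),
    "TSS universe")
})

test_that("attendant selection stops at the p-value ceiling", {
  set.seed(12)
  n <- 2000
  X <- cbind(s1 = rbinom(n, 1, 0.3), s2 = rbinom(n, 1, 0.3),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  y <- 1 + X[, "s1"] - 0.8 * X[, "s2"] + rnorm(n, 0, 0.3)
  base <- forward_select(X, y, selection_config(max_steps = 1))
  expect_equal(base$features, "s1")

  # pure-noise candidates never clear 1e-20
  ext0 <- select_attendant_features(X[, c("s1", "n1", "n2", "n3")], y,
                                    base, selection_config(max_steps = 3))
  expect_equal(nrow(ext0), 0)
  # a strong true effect is accepted
  ext1 <- select_attendant_features(X, y, base,
                                    selection_config(max_steps = 3))
  expect_equal(ext1$feature, "s2")
  expect_lt(ext1$p_value, 1e-20)
  # disabling the rule appends exactly max_steps features
  ext2 <- select_attendant_features(X, y, base,
                                    selection_config(max_steps = 2,
                                                     p_stop = Inf))
  expect_equal(nrow(ext2), 2)
})
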