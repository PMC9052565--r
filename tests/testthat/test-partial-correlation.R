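test_that("partial correlation with empty S equals Pearson r", {
  set.seed(1)
  X <- matrix(rnorm(400), 100, 4)
  expect_equal(partial_correlation(X, 1, 2), stats::cor(X[, 1], X[, 2]))
  # duplicate column
  X2 <- cbind(X[, 1], X[, 1])
  expect_equal(partial_correlation(X2, 1, 2), 1)
})

test_that("conditioning on the middle of a chain removes the X-Z correlation", {
  X <- make_structure("chain", 5000, seed = 5)
  marg <- partial_correlation(X, "X", "Z")
  cond <- partial_correlation(X, "X", "Z", S = "Y")
  expect_gt(abs(marg), 0.4)
  expect_lt(abs(cond), 0.05)
  expect_equal(cond, pcor_residual_oracle(X, 1, 3, 2), tolerance = 1e-8)
})

test_that("partial correlation matches the regression-residual oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- 200
    A <- matrix(rnorm(25), 5, 5)
    X <- matrix(rnorm(n * 5), n, 5) %*% A # correlated, well-conditioned
    expect_equal(partial_correlation(X, 1, 2, S = 3:5),
                 pcor_residual_oracle(X, 1, 2, 3:5), tolerance = 1e-8)
    expect_equal(partial_correlation(X, 2, 4, S = c(1, 5)),
                 pcor_residual_oracle(X, 2, 4, c(1, 5)), tolerance = 1e-8)
  }
})

test_that("degenerate inputs signal incomputable instead of throwing", {
  X <- cbind(a = rnorm(50), b = rnorm(50), c = rep(1, 50))
  expect_true(is.na(partial_correlation(X, 1, 2, S = 3)))
  expect_true(is.na(ci_test(X, 1, 2, S = 3)))
  expect_error(partial_correlation(X, 1, 1), "distinct")
  expect_error(partial_correlation(matrix("x", 10, 2), 1, 2), "numeric")
  expect_error(partial_correlation(X[1:3, ], 1, 2, S = 3), "rows")
})

test_that("ridge fallback keeps near-collinear conditioning defined", {
  set.seed(2)
  x <- rnorm(300)
  X <- cbind(a = x, b = x + rnorm(300, sd = 1e-9), c = rnorm(300),
             d = rnorm(300))
  r <- partial_correlation(X, 3, 4, S = c(1, 2))
  expect_true(is.finite(r))
  expect_lt(abs(r), 0.2)
})

test_that("Fisher-z p-values match the closed form on exact correlations", {
  # exact sample correlation 0.5, orthogonal conditioning column:
  # p = 2 * pnorm(-sqrt(100 - 1 - 3) * atanh(0.5)) = 7.38e-8
  X <- exact_corr_pair(100, 0.5, seed = 3)
  expect_equal(partial_correlation(X, 1, 2, S = 3), 0.5, tolerance = 1e-10)
  # closed form: 2 * pnorm(-sqrt(96) * atanh(0.5))
  expect_equal(ci_test(X, 1, 2, S = 3), 7.363040855e-08, tolerance = 1e-6)
  # exactly uncorrelated columns give p = 1
  X0 <- exact_corr_pair(100, 0, seed = 4)
  expect_equal(ci_test(X0, 1, 2), 1, tolerance = 1e-10)
})

test_that("insufficient sample propagates as incomputable", {
  set.seed(6)
  X <- matrix(rnorm(5 * 2), 5, 2)
  expect_false(is.na(ci_test(X, 1, 2))) # n - 0 - 3 = 2 > 0: computable
  X3 <- matrix(rnorm(3 * 2), 3, 2)      # n - 0 - 3 = 0: insufficient
  expect_true(is.na(ci_test(X3, 1, 2)))
})

test_that("selection at alpha 0.01 nests inside selection at alpha 0.05", {
  for (s in 1:25) {
    set.seed(s)
    X <- matrix(rnorm(60 * 3), 60, 3)
    p <- ci_test(X, 1, 2, S = 3)
    if (!is.na(p) && p < 0.01) expect_lt(p, 0.05)
    expect_true(is.na(p) || (p >= 0 && p <= 1))
  }
})
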