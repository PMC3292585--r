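tight <- function(mult, nonneg = FALSE)
  solver_config(lambda_multiplier = mult, nonnegative = nonneg,
                max_iter = 5000, tol = 1e-12, hard_zero_tol = 0)

test_that("lambda_max is the boundary of the all-zero solution", {
  A <- diag(2)
  expect_equal(lambda_max(A, matrix(c(3, -1), 2, 1)), 3)
  expect_equal(lambda_max(A, matrix(0, 2, 4)), 0)
  X <- matrix(rnorm(8), 2, 4)
  expect_equal(lambda_max(A, 2.5 * X), 2.5 * lambda_max(A, X))
})

test_that("orthonormal mixing reduces the solver to closed-form soft-thresholding", {
  A <- diag(2)
  X <- matrix(c(2, 0.5), 2, 1)
  fit <- ist_solve(A, X, tight(0.5))  # lambda = 0.5 * 2 = 1
  expect_equal(fit$lambda, 1)
  expect_equal(as.vector(fit$S), c(1, 0), tolerance = 1e-8)

  ## non-negative variant: negative coordinate clipped, positive shrunk
  Xn <- matrix(c(-1, 2), 2, 1)
  fitn <- ist_solve(A, Xn, tight(0.25, nonneg = TRUE))  # lambda = 0.5
  expect_equal(as.vector(fitn$S), c(0, 1.5), tolerance = 1e-8)
})

test_that("penalties at or above lambda_max zero the whole source matrix", {
  set.seed(50)
  A <- random_unit_mixing(3)
  X <- matrix(rnorm(10), 2, 5)
  fit <- ist_solve(A, X, solver_config(lambda_multiplier = 1))
  expect_true(all(fit$S == 0))
})

test_that("solver matches independent oracles on random instances", {
  set.seed(51)
  for (rep in 1:30) {
    M <- sample(2:5, 1)
    K <- sample(2:16, 1)
    A <- random_unit_mixing(M)
    X <- matrix(rnorm(2 * K), 2, K)
    mult <- sample(c(1e-2, 1e-1, 0.5), 1)
    fit <- ist_solve(A, X, tight(mult))
    S_or <- vapply(seq_len(K),
                   function(k) cd_lasso_oracle(A, X[, k], fit$lambda),
                   numeric(M))
    expect_lt(abs(fit$objective - l1_objective(A, S_or, X, fit$lambda)), 1e-6)

    fit_nn <- ist_solve(A, abs(X), tight(mult, nonneg = TRUE))
    obj_or <- sum(vapply(seq_len(K), function(k)
      nn_lasso_oracle(A, abs(X)[, k], fit_nn$lambda)$objective, numeric(1)))
    expect_true(all(fit_nn$S >= 0))
    expect_lt(abs(fit_nn$objective - obj_or), 1e-6)
  }
})

test_that("support size is non-increasing in the penalty", {
  set.seed(52)
  for (rep in 1:10) {
    A <- random_unit_mixing(4)
    X <- matrix(rnorm(20), 2, 10)
    nnz <- vapply(c(1e-6, 1e-4, 1e-2), function(mult) {
      cfg <- solver_config(lambda_multiplier = mult, max_iter = 5000,
                           tol = 1e-12)
      sum(ist_solve(A, X, cfg)$S != 0)
    }, numeric(1))
    expect_true(all(diff(nnz) <= 0))  # larger lambda, fewer nonzeros
  }
})

test_that("true sparse supports are recovered in the small-penalty limit", {
  set.seed(53)
  hits <- 0; total <- 0
  for (rep in 1:5) {
    M <- 4
    ang <- sort(runif(M, 5, 85))
    A <- rbind(cos(ang * pi / 180), sin(ang * pi / 180))
    K <- 100
    S_true <- matrix(0, M, K)
    for (k in seq_len(K)) {
      if (runif(1) < 0.5) {
        S_true[sample(M, 1), k] <- runif(1, 0.5, 2)
      } else {
        j <- sample(M - 1, 1)   # adjacent pair: identifiable support
        S_true[c(j, j + 1), k] <- runif(2, 0.5, 2)
      }
    }
    X <- A %*% S_true
    fit <- ist_solve(A, X, solver_config(1e-6, max_iter = 1e6, tol = 1e-15))
    supp_est <- fit$S != 0
    hits <- hits + sum(vapply(seq_len(K), function(k)
      identical(supp_est[, k], S_true[, k] != 0), logical(1)))
    total <- total + K
  }
  expect_gte(hits / total, 0.99)
})

test_that("sparseness measure counts relatively small entries", {
  expect_equal(sparseness_measure(c(0, 0, 5), 0.1), 2 / 3)
  expect_equal(sparseness_measure(c(1, 1, 1), 0.5), 0)
  expect_equal(sparseness_measure(c(2, -1, 0.1), 1), 1)
  expect_equal(sparseness_measure(numeric(4), 0.3), 1)
  expect_error(sparseness_measure(c(1, 2), 1.5), "tau")
})
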