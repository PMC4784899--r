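test_that("softThreshold snaps, preserves sign, is identity at gamma 0", {
  expect_equal(softThreshold(0.5, 1), 0)
  expect_equal(softThreshold(-3, 1), -2)
  v <- c(-2, -0.5, 0, 0.7, 3)
  expect_equal(softThreshold(v, 0), v)
  expect_error(softThreshold(1, -1), "nonnegative")
})

test_that("lambda1Max bounds the sparsity path exactly", {
  # hand-evaluated case: n=2, p=1, x=(1,-1), y=(1,-1) gives bound 1
  X <- matrix(c(1, -1), 2, 1)
  y <- c(1, -1)
  expect_equal(lambda1Max(X, y), 1)
  for (delta in c(1e-3, 1e-1)) {
    above <- gelnetFit(X, y, lambda1 = 1 + delta)
    expect_identical(unname(above@w), 0)
    below <- gelnetFit(X, y, lambda1 = 1 - delta)
    expect_true(below@w != 0)
  }

  # constant response -> zero bound; scaling y scales the bound
  set.seed(2)
  X <- matrix(rnorm(60), 12, 5)
  expect_equal(lambda1Max(X, rep(3, 12)), 0)
  y <- rnorm(12)
  expect_equal(lambda1Max(X, -2.5 * y), 2.5 * lambda1Max(X, y))
  expect_error(lambda1Max(X, y, d = rep(0, 5)), "undefined")

  # the guarantee holds on random instances with random weights
  set.seed(4)
  for (i in 1:10) {
    n <- sample(5:20, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    a <- runif(n, 0.2, 2)
    lmax <- lambda1Max(X, y, a = a)
    m0 <- gelnetFit(X, y, lambda1 = 1.001 * lmax, a = a)
    expect_identical(unname(m0@w), rep(0, p))
    expect_equal(m0@b, sum(a * y) / sum(a))
    m1 <- gelnetFit(X, y, lambda1 = 0.9 * lmax, a = a)
    expect_gte(nnzWeights(m1), 1)
  }
})

test_that("unpenalized fit matches closed-form weighted least squares", {
  set.seed(10)
  for (i in 1:5) {
    n <- 40; p <- 4
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% rnorm(p) + rnorm(n)
    a <- runif(n, 0.5, 2)
    m <- gelnetFit(X, y, lambda1 = 0, lambda2 = 0, a = a,
                   control = fitControl(tol = 1e-12, maxIter = 2000))
    oracle <- wls_oracle(X, y, a)
    expect_equal(unname(m@w), as.numeric(oracle$w), tolerance = 1e-6)
    expect_equal(m@b, as.numeric(oracle$b), tolerance = 1e-6)
  }
})

test_that("elastic-net special case agrees with independent oracles", {
  set.seed(20)
  for (i in 1:20) {
    n <- 20; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% (rnorm(p) * rbinom(p, 1, 0.6)) + rnorm(n)
    lambda1 <- runif(1, 0.01, 0.5)
    lambda2 <- runif(1, 0.01, 2)
    m <- gelnetFit(X, y, lambda1, lambda2,
                   control = fitControl(tol = 1e-13, maxIter = 5000))
    oracle <- sign_pattern_oracle(X, y, lambda1, lambda2)
    expect_equal(unname(m@w), oracle$w, tolerance = 1e-5)
    expect_equal(m@b, oracle$b, tolerance = 1e-5)
    # and against glmnet's solution of the same objective
    g <- glmnet_oracle(X, y, lambda1, lambda2)
    expect_equal(unname(m@w), g$w, tolerance = 1e-4)
  }
})

test_that("network-penalized fits reach the global optimum (general P)", {
  set.seed(30)
  for (i in 1:10) {
    n <- 15; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    a <- runif(n, 0.5, 1.5)
    d <- runif(p, 0.5, 2)
    P <- penalty(nickPenalty(random_network(p, 0.5), runif(1, 0.1, 2)))
    lambda1 <- runif(1, 0.02, 0.3)
    lambda2 <- runif(1, 0.1, 1)
    m <- gelnetFit(X, y, lambda1, lambda2, a = a, d = d, P = P,
                   control = fitControl(tol = 1e-13, maxIter = 5000))
    oracle <- sign_pattern_oracle(X, y, lambda1, lambda2, a = a, d = d,
                                  P = P)
    expect_equal(unname(m@w), oracle$w, tolerance = 1e-5)
    expect_equal(m@b, oracle$b, tolerance = 1e-5)
  }
})

test_that("objective decreases every sweep and KKT holds at convergence", {
  set.seed(40)
  for (i in 1:10) {
    n <- 25; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    P <- penalty(laplacianPenalty(random_network(p, 0.25),
                                  normalized = TRUE))
    tol <- 1e-9
    m <- gelnetFit(X, y, lambda1 = 0.05, lambda2 = 0.5, P = P,
                   control = fitControl(tol = tol, maxIter = 3000))
    tr <- m@objectiveTrace
    expect_true(all(diff(tr) <= 1e-10 * pmax(1, abs(tr[-length(tr)]))))
    res <- kkt_residuals(X, y, m@w, m@b, 0.05, 0.5, P = P)
    expect_lt(max(res), 10 * tol)
  }
})

test_that("zero-coordinate skipping is bit-identical to the naive path", {
  set.seed(50)
  for (i in 1:8) {
    n <- 20; p <- 15
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    P <- if (i %% 2) NULL else
      penalty(nickPenalty(random_network(p, 0.2), 1))
    l1 <- runif(1, 0.05, 0.5) * lambda1Max(X, y)
    fast <- gelnetFit(X, y, l1, 0.3, P = P)
    naive <- gelnetFit(X, y, l1, 0.3, P = P, naive = TRUE)
    expect_identical(fast@w, naive@w)
    expect_identical(fast@b, naive@b)
    expect_identical(fast@objectiveTrace, naive@objectiveTrace)
  }
})

test_that("sparsity is monotone along the lambda1 path", {
  set.seed(60)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30)
  lmax <- lambda1Max(X, y)
  nnz <- vapply(seq(0.02, 1, length.out = 15), function(f) {
    nnzWeights(gelnetFit(X, y, f * lmax, 0.1))
  }, 0L)
  expect_true(all(diff(nnz) <= 0))
})

test_that("objective function matches brute-force summation", {
  set.seed(70)
  n <- 12; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n); a <- runif(n); w <- rnorm(p); b <- 0.3
  d <- runif(p); P <- penalty(nickPenalty(random_network(p, 0.5), 0.7))
  got <- gelnetObjective(X, y, w, b = b, lambda1 = 0.2, lambda2 = 0.4,
                         a = a, d = d, P = P)
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + a[i] * (y[i] - sum(w * X[i, ]) - b)^2
  want <- acc / (2 * n) + 0.2 * sum(d * abs(w)) +
    0.4 / 2 * as.numeric(t(w) %*% P %*% w)
  expect_equal(got, want)

  # w = 0 at the weighted mean, no penalties: half the weighted variance
  b0 <- sum(a * y) / sum(a)
  expect_equal(gelnetObjective(X, y, rep(0, p), b = b0, a = a),
               sum(a * (y - b0)^2) / (2 * n))
})

test_that("predictions are consistent with the training objective", {
  set.seed(80)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  m <- gelnetFit(X, y, 0.05, 0.1,
                 control = fitControl(tol = 1e-12, maxIter = 2000))
  pred <- predict(m, X)
  loss <- mean((y - pred)^2) / 2
  pen_obj <- tail(m@objectiveTrace, 1)
  expect_equal(loss + 0.05 * sum(abs(m@w)) + 0.1 / 2 * sum(m@w^2),
               pen_obj, tolerance = 1e-9)
  # trivial prediction shapes
  m0 <- gelnetFit(X, y, lambda1 = 2 * lambda1Max(X, y))
  expect_equal(predict(m0, X), rep(m0@b, 20))
  expect_error(predict(m, X[, 1:2]), "columns")
})

test_that("degenerate zero columns are frozen with a warning", {
  set.seed(90)
  X <- cbind(rnorm(10), 0)
  y <- rnorm(10)
  expect_warning(m <- gelnetFit(X, y, lambda1 = 0, lambda2 = 0),
                 "held at 0")
  expect_identical(unname(m@w[2]), 0)
  expect_error(gelnetFit(X, c(y[-1], NA), 0, 0), "NA")
})

test_that("model TSV serialization round-trips", {
  set.seed(100)
  X <- matrix(rnorm(40), 10, 4)
  colnames(X) <- paste0("gene", 1:4)
  m <- gelnetFit(X, rnorm(10), 0.05, 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGELnetModel(m, path)
  m2 <- readGELnetModel(path)
  expect_equal(m2@w, m@w, tolerance = 1e-9)
  expect_equal(m2@b, m@b, tolerance = 1e-9)
  expect_identical(m2@lambda1, m@lambda1)
  expect_identical(m2@converged, m@converged)
})
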