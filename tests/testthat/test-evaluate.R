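test_that("reconstruction error is a scale-free squared-cosine distance", {
  expect_equal(reconstructionError(c(1, 1, 0), 3 * c(1, 1, 0)), 0)
  expect_equal(reconstructionError(c(1, 1, 0), -2 * c(1, 1, 0)), 0)
  expect_equal(reconstructionError(c(1, 0), c(0, 1)), 1)
  expect_equal(reconstructionError(c(1, 0), c(1, 1)), 0.5)
  expect_equal(reconstructionError(c(1, 0), c(0, 0)), 1)  # null estimate
  expect_error(reconstructionError(c(0, 0), c(1, 0)), "nonzero")
  set.seed(1)
  w <- rnorm(10); v <- rnorm(10)
  expect_equal(reconstructionError(w, v),
               reconstructionError(2.7 * w, -0.3 * v))
})

test_that("rmse is the root mean squared deviation", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5, 1:5 + 2), 2)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("dispersion measures network clustering of the selection", {
  # star graph: hub g1, leaves g2..g7; leaves share no edges -> exactly 1
  A <- matrix(0, 7, 7)
  A[1, 2:7] <- A[2:7, 1] <- 1
  star <- featureNetwork(A)
  w_leaves <- c(0, rep(1, 6))
  expect_identical(dispersion(w_leaves, star), 1)

  # both ends of a single edge: (2 - 2)/2 = 0
  edge <- featureNetwork(rbind(c(0, 1), c(1, 0)))
  expect_equal(dispersion(c(1, -2), edge), 0)

  # any selection with an internal edge scores below 1
  set.seed(6)
  for (i in 1:10) {
    net <- random_network(12, 0.3)
    w <- rbinom(12, 1, 0.5) * rnorm(12)
    Z <- which(w != 0)
    if (length(Z) < 2) next
    val <- dispersion(w, net)
    expect_lte(val, 1)
    internal <- sum(as.matrix(adjacency(net))[Z, Z]) > 0
    if (internal) expect_lt(val, 1) else expect_equal(val, 1)
  }

  expect_error(dispersion(rep(0, 7), star), "no selected features")
})

test_that("LPOCV enumerates pairs and matches a hand-rolled loop", {
  set.seed(7)
  X <- matrix(rnorm(4 * 2), 4, 2)
  y <- rnorm(4)
  fitter <- function(Xtr, ytr) gelnetFit(Xtr, ytr, 0.01, 0.1,
                                         control = fitControl(tol = 1e-10))
  got <- lpocvRmse(X, y, fitter)
  # naive reimplementation over all 6 pairs
  errs <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    m <- fitter(X[-c(i, j), ], y[-c(i, j)])
    errs <- c(errs, (predict(m, X[c(i, j), , drop = FALSE]) - y[c(i, j)])^2)
  }
  expect_equal(as.numeric(got), sqrt(mean(errs)))

  # zero-variance response with an intercept-only model is perfect
  yc <- rep(2, 8)
  Xc <- matrix(rnorm(16), 8, 2)
  got0 <- lpocvRmse(Xc, yc, function(Xtr, ytr)
    gelnetFit(Xtr, ytr, lambda1 = 10))
  expect_equal(as.numeric(got0), 0)

  # sampled pairs are seed-reproducible
  Xl <- matrix(rnorm(30 * 2), 30, 2); yl <- rnorm(30)
  r1 <- lpocvRmse(Xl, yl, fitter, nPairs = 10, seed = 3)
  r2 <- lpocvRmse(Xl, yl, fitter, nPairs = 10, seed = 3)
  expect_identical(r1, r2)
})

test_that("matched-sparsity search hits its target nonzero count", {
  set.seed(8)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- X %*% (rnorm(30) * rbinom(30, 1, 0.3)) + rnorm(40)
  lmax <- lambda1Max(X, y)

  # target 0 is the supremum of the path
  l0 <- matchSparsityLambda1(X, y, targetNnz = 0, lambda2 = 0.1)
  expect_gt(as.numeric(l0), lmax)

  # self-consistency: recover the sparsity of a known path point
  ref <- gelnetFit(X, y, lmax / 9, 0.1)
  target <- nnzWeights(ref)
  l <- matchSparsityLambda1(X, y, targetNnz = target, lambda2 = 0.1)
  check <- gelnetFit(X, y, as.numeric(l), 0.1)
  expect_equal(nnzWeights(check), target)
  expect_true(attr(l, "exact"))

  # monotone: larger targets need smaller lambda1
  targets <- c(2, 8, 15)
  ls <- vapply(targets, function(t)
    as.numeric(matchSparsityLambda1(X, y, t, lambda2 = 0.1)), 0)
  expect_true(all(diff(ls) <= 0))
})

test_that("identity-penalty GELnet coincides with the elastic net", {
  set.seed(9)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- rnorm(25)
  for (l2 in c(0.1, 1)) {
    a <- gelnetFit(X, y, 0.05, l2, P = NULL)
    b <- gelnetFit(X, y, 0.05, l2, P = identityPenalty(10))
    expect_equal(a@w, b@w, tolerance = 1e-12)
    expect_equal(a@b, b@b, tolerance = 1e-12)
  }
})

test_that("a method compared with itself shows zero improvement", {
  grid <- data.frame(method = rep(c("elastic_net", "gelnet"), each = 2),
                     reconstruction = c(0.4, 0.6, 0.4, 0.6),
                     rmse = c(1, 2, 1, 2),
                     dispersion = c(0.9, 0.8, 0.9, 0.8))
  m <- gelnetx:::.marginalize(grid)
  expect_equal(unname(m$improvement), rep(0, 3))
})

test_that("the full comparison pipeline runs and scores both arms", {
  cfg <- simulationConfig(p = 80, n = 16, seed = 21)
  ds <- simulateDataset(cfg, "GGM+")
  cmp <- runComparison(ds, lambda2Grid = c(100, 1),
                       lambda1Fractions = c(1 / 9, 1 / 3),
                       nPairs = 6L, seed = 2)
  grid <- comparisonGrid(cmp)
  expect_equal(nrow(grid), 8)  # 2 x 2 cells x 2 methods
  expect_setequal(unique(grid$method), c("elastic_net", "gelnet"))
  # matched sparsity: per-cell nonzero counts agree across arms
  en <- grid[grid$method == "elastic_net", ]
  gel <- grid[grid$method == "gelnet", ]
  key <- function(d) paste(d$lambda2, d$lambda1_fraction)
  expect_equal(gel$nnz[order(key(gel))], en$nnz[order(key(en))])
  expect_true(all(c("reconstruction", "rmse", "dispersion") %in%
                    names(improvement(cmp))))
  # positive control: the network penalty lowers dispersion on average
  marg <- comparisonMarginal(cmp)
  expect_lte(marg$dispersion[marg$method == "gelnet"],
             marg$dispersion[marg$method == "elastic_net"])
})

test_that("scramble sweep table has the right shape and f=0 anchor", {
  cfg <- simulationConfig(p = 60, n = 12)
  tbl <- scrambleSweep(cfg, fractions = c(0, 1), nRuns = 2, seed = 5,
                       nPairs = 4L, lambda2Grid = c(10, 1),
                       lambda1Fractions = c(1 / 3))
  expect_equal(nrow(tbl), 2 * 2 * 3)  # fractions x runs x metrics
  expect_setequal(unique(tbl$metric),
                  c("reconstruction", "rmse", "dispersion"))
  # determinism of the whole sweep
  tbl2 <- scrambleSweep(cfg, fractions = c(0, 1), nRuns = 2, seed = 5,
                        nPairs = 4L, lambda2Grid = c(10, 1),
                        lambda1Fractions = c(1 / 3))
  expect_identical(tbl, tbl2)
  # edge helper consumes the table
  edge <- scrambleEdge(tbl)
  expect_true(edge %in% c(-Inf, 0, 1))
})

test_that("relevance rule applies the RMSE-or-dispersion thresholds", {
  expect_true(networkRelevance(c(rmse = 3, dispersion = 1)))
  expect_true(networkRelevance(c(rmse = 1, dispersion = 6)))
  expect_false(networkRelevance(c(rmse = 1, dispersion = 1)))
  expect_false(networkRelevance(c(rmse = 3, dispersion = 1),
                                conservative = TRUE))
  expect_true(networkRelevance(c(rmse = 3, dispersion = 6),
                               conservative = TRUE))
})
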