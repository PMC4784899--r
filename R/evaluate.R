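#' Pathway reconstruction error
#'
#' `1 - cos^2(wTrue, wHat)`: scale-invariant in both arguments, 0 for any
#' nonzero multiple of the true vector, 1 for orthogonal vectors, and 1 by
#' convention when the estimate is identically zero (a degenerate null
#' model must not score as perfect).
#'
#' @param wTrue true weight vector (nonzero).
#' @param wHat estimated weight vector.
#' @export
reconstructionError <- function(wTrue, wHat) {
  if (length(wTrue) != length(wHat)) stop("length mismatch")
  nt <- sum(wTrue^2)
  if (nt == 0) stop("wTrue must be nonzero")
  nh <- sum(wHat^2)
  if (nh == 0) return(1)
  1 - sum(wTrue * wHat)^2 / (nt * nh)
}

#' Root mean squared error
#'
#' @param y,yHat equal-length numeric vectors.
#' @export
rmse <- function(y, yHat) {
  if (length(y) != length(yHat)) stop("length mismatch")
  sqrt(mean((y - yHat)^2))
}

# Sparse degree-scaled adjacency A_ij / sqrt(d_i d_j) reused by dispersion
.scaled_adjacency <- function(net) {
  A <- net@adjacency
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Dh <- Matrix::Diagonal(x = inv)
  Dh %*% A %*% Dh
}

#' Network dispersion of a model's selected features
#'
#' Sums the normalized-Laplacian submatrix over the set `Z` of features
#' with nonzero weight and divides by `|Z|`.  The diagonal contributes 1
#' per selected feature (isolated nodes included, by the identity
#' convention), every within-`Z` edge contributes a negative off-diagonal
#' pair, so dispersion is at most 1, equals 1 exactly when `Z` contains no
#' mutual edges, and decreases as the selection clusters on the network.
#'
#' @param w a fitted weight vector or [GELnetModel-class]; the selected
#'   set is `which(w != 0)` (an all-zero model is an error: "no selected
#'   features").
#' @param net the [FeatureNetwork-class] to evaluate on.
#' @export
dispersion <- function(w, net) {
  if (methods::is(w, "GELnetModel")) w <- w@w
  .check_network(net)
  if (length(w) != numNodes(net))
    stop("weight vector length does not match the network")
  Z <- which(w != 0)
  if (!length(Z)) stop("no selected features")
  S <- .scaled_adjacency(net)
  # normalized-Laplacian submatrix sum: |Z| on the diagonal minus edges
  (length(Z) - sum(S[Z, Z])) / length(Z)
}

.make_pairs <- function(n, nPairs, seed = NULL) {
  if (nPairs == 0) return(matrix(integer(), 0, 2))
  all_pairs <- t(combn(n, 2))
  if (nrow(all_pairs) <= nPairs) return(all_pairs)
  pick <- function() all_pairs[sample.int(nrow(all_pairs), nPairs), ,
                               drop = FALSE]
  if (is.null(seed)) pick() else withr::with_seed(seed, pick())
}

#' Leave-pair-out cross-validated RMSE
#'
#' Holds out one pair of samples at a time, refits on the remaining
#' `n - 2`, predicts the pair, and pools all held-out squared errors into
#' a single RMSE.  All `choose(n, 2)` pairs are enumerated when there are
#' at most `nPairs` of them; otherwise `nPairs` distinct pairs are sampled
#' uniformly (seed-controlled).
#'
#' @param X n x p feature matrix.
#' @param y length-n response.
#' @param fitFun function `(Xtrain, ytrain) -> model` where the model is
#'   accepted by [predict()] (e.g. wraps [gelnetFit()]).
#' @param nPairs cap on the number of held-out pairs (default 200).
#' @param seed optional integer seed for pair sampling.
#' @return pooled RMSE; folds whose fit fails are skipped with a warning
#'   and reported in the `nFailed` attribute.
#' @export
lpocvRmse <- function(X, y, fitFun, nPairs = 200L, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("leave-pair-out needs at least 4 samples")
  pairs <- .make_pairs(n, nPairs, seed)
  errs <- c()
  failed <- 0L
  for (r in seq_len(nrow(pairs))) {
    hold <- pairs[r, ]
    m <- tryCatch(fitFun(X[-hold, , drop = FALSE], y[-hold]),
                  error = function(e) NULL)
    if (is.null(m)) { failed <- failed + 1L; next }
    pred <- predict(m, X[hold, , drop = FALSE])
    errs <- c(errs, (pred - y[hold])^2)
  }
  if (failed > 0)
    warning(sprintf("%d LPOCV fold(s) failed and were skipped", failed))
  structure(sqrt(mean(errs)), nFailed = failed)
}

#' Find the L1 penalty giving a target number of nonzero weights
#'
#' Bisection on `lambda1` in `(0, lambda1Max]`: the nonzero count of the
#' fitted model is non-increasing along the path, so the interval shrinks
#' toward the target.  An exact match is preferred (ties resolved toward
#' the larger, sparser `lambda1`); when the count jumps over the target
#' the closest achievable value is returned and flagged.
#'
#' @param X,y,a,d,P,lambda2 as in [gelnetFit()].
#' @param targetNnz desired number of nonzero weights (0 returns
#'   `lambda1Max * (1 + 1e-6)`).
#' @param control a [fitControl()] list.
#' @param maxSteps bisection budget (default 30).
#' @return the selected `lambda1`, with attributes `nnz` (achieved count)
#'   and `exact` (whether the target was hit).
#' @export
matchSparsityLambda1 <- function(X, y, targetNnz, lambda2 = 0, a = NULL,
                                 d = NULL, P = NULL,
                                 control = fitControl(), maxSteps = 30L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (targetNnz < 0 || targetNnz > p) stop("targetNnz out of range")
  l1max <- lambda1Max(X, y, a = a, d = d)
  if (targetNnz == 0)
    return(structure(l1max * (1 + 1e-6), nnz = 0L, exact = TRUE))

  fit_nnz <- function(l1, wInit = NULL, bInit = NULL) {
    ctl <- control
    ctl$wInit <- wInit; ctl$bInit <- bInit
    m <- gelnetFit(X, y, lambda1 = l1, lambda2 = lambda2, a = a, d = d,
                   P = P, control = ctl)
    list(nnz = nnzWeights(m), w = m@w, b = m@b)
  }

  lo <- 0; hi <- l1max
  best <- list(lambda1 = l1max, nnz = 0L)
  warm <- NULL
  for (step in seq_len(maxSteps)) {
    mid <- (lo + hi) / 2
    f <- fit_nnz(mid, warm$w, warm$b)
    warm <- f
    better <- abs(f$nnz - targetNnz) < abs(best$nnz - targetNnz) ||
      (abs(f$nnz - targetNnz) == abs(best$nnz - targetNnz) &&
         mid > best$lambda1)
    if (better) best <- list(lambda1 = mid, nnz = f$nnz)
    if (f$nnz == targetNnz) break
    if (f$nnz > targetNnz) lo <- mid else hi <- mid
  }
  structure(best$lambda1, nnz = as.integer(best$nnz),
            exact = best$nnz == targetNnz)
}

# One grid arm: full-data fits at given (lambda1, lambda2) cells plus
# per-cell LPOCV pooled squared errors, with warm starts throughout.
.fit_cell <- function(X, y, l1, l2, P, ctl, warm = NULL) {
  if (!is.null(warm)) { ctl$wInit <- warm@w; ctl$bInit <- warm@b }
  gelnetFit(X, y, lambda1 = l1, lambda2 = l2, P = P, control = ctl)
}

.lpocv_errors <- function(X, y, l1, l2, P, ctl, pairs, full) {
  ctl$wInit <- full@w
  ctl$bInit <- full@b
  errs <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    hold <- pairs[r, ]
    m <- gelnetFit(X[-hold, , drop = FALSE], y[-hold], lambda1 = l1,
                   lambda2 = l2, P = P, control = ctl)
    pred <- predict(m, X[hold, , drop = FALSE])
    errs <- c(errs, (pred - y[hold])^2)
  }
  errs
}

# Elastic-net arm over the full grid; returns per-cell fits and errors
.en_arm <- function(X, y, lambda2Grid, lambda1Fractions, pairs, ctl) {
  l1max <- lambda1Max(X, y)
  cells <- list()
  for (l2 in lambda2Grid) {
    warm <- NULL
    for (fr in sort(lambda1Fractions, decreasing = TRUE)) {
      full <- .fit_cell(X, y, fr * l1max, l2, NULL, ctl, warm)
      warm <- full
      errs <- .lpocv_errors(X, y, fr * l1max, l2, NULL, ctl, pairs, full)
      cells[[length(cells) + 1L]] <-
        list(lambda2 = l2, fraction = fr, lambda1 = fr * l1max,
             model = full, nnz = nnzWeights(full), sqerr = errs)
    }
  }
  list(cells = cells, l1max = l1max)
}

# GELnet arm matched in sparsity to an elastic-net arm, penalty matrix P
.gel_arm <- function(X, y, en, P, pairs, ctl) {
  cells <- list()
  for (cell in en$cells) {
    l1 <- matchSparsityLambda1(X, y, targetNnz = cell$nnz,
                               lambda2 = cell$lambda2, P = P, control = ctl)
    full <- .fit_cell(X, y, as.numeric(l1), cell$lambda2, P, ctl)
    errs <- .lpocv_errors(X, y, as.numeric(l1), cell$lambda2, P, ctl,
                          pairs, full)
    cells[[length(cells) + 1L]] <-
      list(lambda2 = cell$lambda2, fraction = cell$fraction,
           lambda1 = as.numeric(l1), model = full,
           nnz = nnzWeights(full), sqerr = errs)
  }
  cells
}

.cell_metrics <- function(cells, method, wTrue, Sadj) {
  do.call(rbind, lapply(cells, function(cell) {
    w <- cell$model@w
    Z <- which(w != 0)
    disp <- if (length(Z)) (length(Z) - sum(Sadj[Z, Z])) / length(Z)
            else NA_real_
    data.frame(method = method, lambda2 = cell$lambda2,
               lambda1_fraction = cell$fraction, lambda1 = cell$lambda1,
               nnz = cell$nnz,
               reconstruction = reconstructionError(wTrue, w),
               rmse = if (length(cell$sqerr)) sqrt(mean(cell$sqerr))
                      else NA_real_,
               dispersion = disp)
  }))
}

.marginalize <- function(grid) {
  agg <- stats::aggregate(
    grid[, c("reconstruction", "rmse", "dispersion")],
    by = list(method = grid$method), FUN = mean, na.rm = TRUE)
  en <- agg[agg$method == "elastic_net",
            c("reconstruction", "rmse", "dispersion")]
  gel <- agg[agg$method == "gelnet",
             c("reconstruction", "rmse", "dispersion")]
  imp <- 100 * (unlist(en) - unlist(gel)) / unlist(en)
  list(marginal = agg, improvement = imp)
}

#' Marginalized GELnet vs elastic-net comparison on one dataset
#'
#' Fits the classical elastic net on a 3 x 5 grid: `lambda1` at the given
#' fractions of `lambda1Max` crossed with the `lambda2` grid.  For every
#' cell, a GELnet with `P` equal to the normalized Laplacian of the
#' dataset's supplied network is fitted with `lambda1` chosen by bisection
#' so its nonzero count matches the elastic net's (fair comparison at
#' equal sparsity).  Each cell is scored by pathway reconstruction error,
#' leave-pair-out RMSE (same held-out pairs for both methods) and
#' dispersion on the supplied network; metrics are averaged over the grid
#' into marginalized estimates, and percent improvements
#' `100 * (EN - GELnet) / EN` summarize the comparison.
#'
#' @param ds a [SyntheticDataset-class] (or any object with slots `X`,
#'   `y`, `wTrue`, `netGiven`).
#' @param lambda2Grid quadratic-penalty grid
#'   (default `c(10000, 1000, 100, 10, 1)`).
#' @param lambda1Fractions fractions of `lambda1Max` for the elastic-net
#'   arm (default `c(1/27, 1/9, 1/3)`).
#' @param nPairs held-out pairs per grid cell; `0` skips the
#'   cross-validation entirely and reports `NA` RMSE (useful when only
#'   reconstruction and dispersion are of interest).
#' @param seed integer seed for pair sampling.
#' @param control a [fitControl()] list.
#' @return a [GELnetComparison-class].
#' @export
runComparison <- function(ds, lambda2Grid = c(10000, 1000, 100, 10, 1),
                          lambda1Fractions = c(1 / 27, 1 / 9, 1 / 3),
                          nPairs = 50L, seed = NULL,
                          control = fitControl()) {
  X <- ds@X; y <- ds@y
  pairs <- .make_pairs(nrow(X), nPairs, seed)
  en <- .en_arm(X, y, lambda2Grid, lambda1Fractions, pairs, control)
  P <- laplacianPenalty(ds@netGiven, normalized = TRUE)
  gel <- .gel_arm(X, y, en, P, pairs, control)
  Sadj <- .scaled_adjacency(ds@netGiven)
  grid <- rbind(.cell_metrics(en$cells, "elastic_net", ds@wTrue, Sadj),
                .cell_metrics(gel, "gelnet", ds@wTrue, Sadj))
  m <- .marginalize(grid)
  methods::new("GELnetComparison", grid = grid, marginal = m$marginal,
               improvement = m$improvement)
}

setMethod("show", "GELnetComparison", function(object) {
  cat("GELnetComparison over", nrow(object@grid) / 2, "grid cells\n")
  print(object@marginal, row.names = FALSE)
  cat("percent improvement (GELnet over elastic net):\n")
  print(round(object@improvement, 2))
})

#' @describeIn runComparison per-cell results accessor
#' @param x a [GELnetComparison-class].
#' @export
comparisonGrid <- function(x) x@grid

#' @describeIn runComparison marginal means accessor
#' @export
comparisonMarginal <- function(x) x@marginal

#' @describeIn runComparison percent-improvement accessor
#' @export
improvement <- function(x) x@improvement

#' Scramble-factor sweep
#'
#' Repeats the GGM benchmark while the network handed to the GELnet is
#' increasingly corrupted: for each run a dataset is simulated, and for
#' each scramble fraction `f` the true network has `ceiling(f * p)` of its
#' node indices symmetrically permuted before being used as the GELnet
#' penalty.  Fraction 0 is the true-network (GGM+) comparison; fraction 1
#' matches the fully scrambled (GGM-) case.  The elastic-net arm does not
#' depend on the fraction and is computed once per run.
#'
#' @param config a [simulationConfig()]; its `seed` is ignored in favor of
#'   `seed`.
#' @param fractions scramble fractions to visit
#'   (default `seq(0, 1, by = 0.1)`).
#' @param nRuns independent simulated datasets.
#' @param seed integer seed; run `r` uses `seed + r` for its dataset and
#'   derived draws.
#' @param nPairs,lambda2Grid,lambda1Fractions,control forwarded to the
#'   comparison machinery (see [runComparison()]).
#' @return long-format data frame with columns `fraction`, `run`,
#'   `metric` (`reconstruction`, `rmse`, `dispersion`), `en`, `gelnet`
#'   (marginal means per arm) and `improvement` (percent).
#' @export
scrambleSweep <- function(config, fractions = seq(0, 1, by = 0.1),
                          nRuns = 10L, seed = 1L, nPairs = 50L,
                          lambda2Grid = c(10000, 1000, 100, 10, 1),
                          lambda1Fractions = c(1 / 27, 1 / 9, 1 / 3),
                          control = fitControl()) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0,1]")
  out <- list()
  for (run in seq_len(nRuns)) {
    run_seed <- as.integer(seed + run)
    cfg <- config
    cfg$seed <- run_seed
    ds <- simulateDataset(cfg, "GGM+")
    X <- ds@X; y <- ds@y
    pairs <- .make_pairs(nrow(X), nPairs, seed = run_seed)
    en <- .en_arm(X, y, lambda2Grid, lambda1Fractions, pairs, control)
    for (f in fractions) {
      net_f <- scrambleNetwork(ds@netTrue, f, seed = run_seed + 7919L)
      P <- laplacianPenalty(net_f, normalized = TRUE)
      gel <- .gel_arm(X, y, en, P, pairs, control)
      Sadj <- .scaled_adjacency(net_f)
      grid <- rbind(
        .cell_metrics(en$cells, "elastic_net", ds@wTrue, Sadj),
        .cell_metrics(gel, "gelnet", ds@wTrue, Sadj))
      m <- .marginalize(grid)
      agg <- m$marginal
      for (metric in c("reconstruction", "rmse", "dispersion")) {
        out[[length(out) + 1L]] <- data.frame(
          fraction = f, run = run, metric = metric,
          en = agg[agg$method == "elastic_net", metric],
          gelnet = agg[agg$method == "gelnet", metric],
          improvement = m$improvement[[metric]])
      }
    }
  }
  do.call(rbind, out)
}

#' Largest scramble fraction at which the GELnet still matches the
#' elastic net
#'
#' Aggregates a [scrambleSweep()] table and returns the largest fraction
#' `f` such that the across-run mean of the GELnet's marginalized metric
#' is no worse than the elastic net's at every fraction up to and
#' including `f` (the corruption level the network prior tolerates before
#' losing its edge).
#'
#' @param sweepTable output of [scrambleSweep()].
#' @param metric metric to compare (default `"rmse"`).
#' @return the largest tolerated fraction (`-Inf` if the GELnet is already
#'   worse at fraction 0).
#' @export
scrambleEdge <- function(sweepTable, metric = "rmse") {
  tbl <- sweepTable[sweepTable$metric == metric, ]
  agg <- stats::aggregate(tbl[, c("en", "gelnet")],
                          by = list(fraction = tbl$fraction), FUN = mean)
  agg <- agg[order(agg$fraction), ]
  ok <- agg$gelnet <= agg$en
  if (!ok[1]) return(-Inf)
  last <- which(!ok)[1]
  if (is.na(last)) max(agg$fraction) else agg$fraction[last - 1]
}

#' Decide whether a network prior is relevant to a prediction task
#'
#' Encodes the benchmark's decision rule: a network is flagged relevant
#' when the marginalized GELnet-over-elastic-net improvement reaches at
#' least 2.5% in RMSE or at least 5% in dispersion.  The conservative mode
#' requires both.
#'
#' @param x a [GELnetComparison-class] or a named improvement vector.
#' @param rmseMin,dispersionMin percent thresholds.
#' @param conservative require both criteria instead of either.
#' @return logical.
#' @export
networkRelevance <- function(x, rmseMin = 2.5, dispersionMin = 5,
                             conservative = FALSE) {
  imp <- if (methods::is(x, "GELnetComparison")) x@improvement else x
  hit_rmse <- isTRUE(imp[["rmse"]] >= rmseMin)
  hit_disp <- isTRUE(imp[["dispersion"]] >= dispersionMin)
  if (conservative) hit_rmse && hit_disp else hit_rmse || hit_disp
}
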