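#' Soft-threshold operator
#'
#' `S(v, gamma) = sign(v) * max(|v| - gamma, 0)`; snaps values within
#' `gamma` of zero to exactly zero.  Vectorized in `v`.
#'
#' @param v numeric vector.
#' @param gamma nonnegative threshold.
#' @export
softThreshold <- function(v, gamma) {
  if (any(gamma < 0)) stop("gamma must be nonnegative")
  sign(v) * pmax(abs(v) - gamma, 0)
}

#' Control parameters for the coordinate-descent solver
#'
#' @param tol convergence threshold on the per-sweep objective change
#'   (absolute by default; relative when `relative = TRUE`).
#' @param maxIter maximum number of full coordinate sweeps.
#' @param wInit,bInit optional warm start.
#' @param relative measure the objective change relative to its magnitude.
#' @return a list of class `gelnetControl`.
#' @export
fitControl <- function(tol = 1e-5, maxIter = 100L, wInit = NULL,
                       bInit = NULL, relative = FALSE) {
  stopifnot(tol > 0, maxIter >= 1)
  structure(list(tol = tol, maxIter = as.integer(maxIter),
                 wInit = wInit, bInit = bInit, relative = relative),
            class = "gelnetControl")
}

.as_penalty_matrix <- function(P, p) {
  if (is.null(P)) return(NULL)                    # identity fast path
  if (methods::is(P, "PenaltyMatrix")) P <- P@P
  P <- as.matrix(P)
  if (nrow(P) != p || ncol(P) != p)
    stop("penalty matrix dimensions do not match the feature count")
  P
}

.check_training <- function(X, y, a) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("X must be numeric with no NA")
  if (anyNA(y) || length(y) != nrow(X))
    stop("y must be NA-free with one value per row of X")
  if (nrow(X) < 2) stop("need at least two samples")
  if (is.null(a)) a <- rep(1, nrow(X))
  if (length(a) != nrow(X) || any(a < 0) || sum(a) <= 0)
    stop("sample weights must be nonnegative with a positive sum")
  list(X = X, y = as.numeric(y), a = as.numeric(a))
}

#' Smallest L1 penalty that forces an all-zero model
#'
#' With the bias at the weighted mean of `y`, any `lambda1` strictly above
#' \deqn{\max_j \frac{|\frac1n \sum_i a_i x_{ij} (y_i - b)|}{d_j}}
#' (maximum over features with `d_j > 0`) keeps every weight at zero
#' throughout coordinate descent.  Used to anchor sparsity grids.
#'
#' @param X n x p feature matrix.
#' @param y length-n response.
#' @param a optional nonnegative sample weights (default 1).
#' @param d optional per-feature L1 weights (default 1).
#' @export
lambda1Max <- function(X, y, a = NULL, d = NULL) {
  td <- .check_training(X, y, a)
  p <- ncol(td$X)
  if (is.null(d)) d <- rep(1, p)
  if (length(d) != p || any(d < 0)) stop("d must be nonnegative, length p")
  if (all(d == 0)) stop("lambda1Max is undefined when all d_j are zero")
  b <- sum(td$a * td$y) / sum(td$a)
  g <- abs(crossprod(td$X, td$a * (td$y - b))) / nrow(td$X)
  max(g[d > 0] / d[d > 0])
}

#' Fit a generalized elastic net by cyclic coordinate descent
#'
#' Minimizes the weighted least-squares objective
#' \deqn{\frac{1}{2n}\sum_i a_i (y_i - w^T x_i - b)^2 +
#'   \lambda_1 \sum_j d_j |w_j| + \frac{\lambda_2}{2} w^T P w}
#' by cycling through the coordinates in ascending index order (each update
#' is a closed-form soft-threshold step) followed by a weighted-average
#' bias update, until the per-sweep objective change drops below
#' `control$tol` or `control$maxIter` sweeps are reached.  Coordinates
#' currently at zero whose soft-threshold argument stays inside
#' `lambda1 * d_k` are skipped without touching any cached quantity; the
#' resulting model is bitwise identical to the unskipped path
#' (`naive = TRUE`).
#'
#' `d = 1, P = NULL` (identity) gives the classical elastic net;
#' `lambda1 = lambda2 = 0` gives ordinary weighted least squares.
#' A feature whose column is identically zero and carries no quadratic
#' penalty (`lambda2 * P_kk = 0`) has an undefined update; it is held at
#' zero with a warning.
#'
#' @param X n x p feature matrix.
#' @param y length-n numeric response.
#' @param lambda1 nonnegative L1 penalty.
#' @param lambda2 nonnegative quadratic penalty.
#' @param a optional nonnegative sample weights (default 1).
#' @param d optional per-feature L1 weights (default 1).
#' @param P feature-pair penalty: a [PenaltyMatrix-class], a plain matrix,
#'   or `NULL` for the identity.
#' @param control a [fitControl()] list.
#' @param naive disable the zero-coordinate skip (for verification).
#' @return a [GELnetModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' y <- X[, 1] + rnorm(20, sd = 0.1)
#' m <- gelnetFit(X, y, lambda1 = 0.05, lambda2 = 0.1)
#' coef(m)
#' @export
gelnetFit <- function(X, y, lambda1 = 0, lambda2 = 0, a = NULL, d = NULL,
                      P = NULL, control = fitControl(), naive = FALSE) {
  td <- .check_training(X, y, a)
  p <- ncol(td$X)
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be nonnegative")
  if (is.null(d)) d <- rep(1, p)
  if (length(d) != p || any(d < 0)) stop("d must be nonnegative, length p")
  Pm <- .as_penalty_matrix(P, p)
  w0 <- if (is.null(control$wInit)) rep(0, p) else as.numeric(control$wInit)
  if (length(w0) != p) stop("wInit has the wrong length")
  b0 <- if (is.null(control$bInit)) {
    sum(td$a * td$y) / sum(td$a)
  } else {
    as.numeric(control$bInit)
  }
  fit <- .cd_gelnet(td$X, td$y, td$a, lambda1, lambda2, d,
                    if (is.null(Pm)) matrix(0, 0, 0) else Pm,
                    is.null(Pm), w0, b0,
                    control$tol, control$maxIter, isTRUE(control$relative),
                    !naive)
  if (fit$zero_denom)
    warning("zero-variance feature(s) with no quadratic penalty held at 0")
  w <- as.numeric(fit$w)
  names(w) <- colnames(td$X)
  methods::new("GELnetModel", w = w, b = fit$b,
               lambda1 = lambda1, lambda2 = lambda2,
               nIter = as.integer(fit$n_iter),
               objectiveTrace = as.numeric(fit$objective_trace),
               converged = fit$converged)
}

#' Evaluate the generalized elastic net objective
#'
#' @param X,y,a training data as in [gelnetFit()].
#' @param model a [GELnetModel-class], or a numeric weight vector (then
#'   `b` must be given and `lambda1`/`lambda2` default to 0).
#' @param b,lambda1,lambda2 used when `model` is a plain vector.
#' @param d,P penalty configuration as in [gelnetFit()].
#' @return the scalar objective value.
#' @export
gelnetObjective <- function(X, y, model, b = NULL, lambda1 = NULL,
                            lambda2 = NULL, a = NULL, d = NULL, P = NULL) {
  td <- .check_training(X, y, a)
  if (methods::is(model, "GELnetModel")) {
    w <- model@w; b <- model@b
    if (is.null(lambda1)) lambda1 <- model@lambda1
    if (is.null(lambda2)) lambda2 <- model@lambda2
  } else {
    w <- as.numeric(model)
    if (is.null(b)) stop("b is required when model is a plain vector")
    if (is.null(lambda1)) lambda1 <- 0
    if (is.null(lambda2)) lambda2 <- 0
  }
  p <- ncol(td$X)
  if (is.null(d)) d <- rep(1, p)
  Pm <- .as_penalty_matrix(P, p)
  r <- td$y - as.numeric(td$X %*% w) - b
  quad <- if (is.null(Pm)) sum(w^2) else as.numeric(w %*% Pm %*% w)
  sum(td$a * r^2) / (2 * nrow(td$X)) +
    lambda1 * sum(d * abs(w)) + lambda2 / 2 * quad
}

#' @describeIn gelnetFit predicted responses `X w + b`
#' @param object a [GELnetModel-class].
#' @param newdata matrix with `length(coef)` columns.
#' @param ... ignored.
#' @export
setMethod("predict", "GELnetModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@w))
    stop("newdata has the wrong number of columns")
  as.numeric(newdata %*% object@w) + object@b
})

#' @describeIn gelnetFit model coefficients as `c(bias, weights)`
#' @export
setMethod("coef", "GELnetModel", function(object, ...) {
  c("(bias)" = object@b, object@w)
})

setMethod("show", "GELnetModel", function(object) {
  cat(sprintf(
    "GELnetModel: %d features (%d nonzero), b = %.4g\n",
    length(object@w), sum(object@w != 0), object@b))
  cat(sprintf("  lambda1 = %.4g, lambda2 = %.4g, %d sweep(s), %s\n",
              object@lambda1, object@lambda2, object@nIter,
              if (object@converged) "converged" else "NOT converged"))
})

#' Number of nonzero weights in a model
#'
#' @param model a [GELnetModel-class] or numeric vector.
#' @export
nnzWeights <- function(model) {
  w <- if (methods::is(model, "GELnetModel")) model@w else model
  sum(w != 0)
}

#' Serialize a fitted model to TSV
#'
#' Writes a `feature_id <tab> weight` table preceded by a comment header
#' carrying the bias, penalties, sweep count and convergence flag.
#'
#' @param model a [GELnetModel-class].
#' @param path output path.
#' @name modelIO
#' @export
writeGELnetModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# b=%.10g lambda1=%.10g lambda2=%.10g n_iter=%d converged=%s",
    model@b, model@lambda1, model@lambda2, model@nIter, model@converged),
    con)
  ids <- names(model@w)
  if (is.null(ids)) ids <- paste0("g", seq_along(model@w))
  df <- data.frame(feature_id = ids, weight = sprintf("%.10g", model@w))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname modelIO
#' @export
readGELnetModel <- function(path) {
  header <- readLines(path, n = 1)
  fields <- regmatches(header, gregexpr("[a-z_0-9]+=[^ ]+", header))[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- read.delim(path, skip = 1, header = TRUE)
  w <- as.numeric(df$weight)
  names(w) <- df$feature_id
  methods::new("GELnetModel", w = w, b = as.numeric(vals[["b"]]),
               lambda1 = as.numeric(vals[["lambda1"]]),
               lambda2 = as.numeric(vals[["lambda2"]]),
               nIter = as.integer(vals[["n_iter"]]),
               objectiveTrace = numeric(),
               converged = as.logical(vals[["converged"]]))
}
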