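#' Control parameters for the logistic reduction
#'
#' @param outerTol threshold on the change in penalized negative
#'   log-likelihood between outer iterations.
#' @param outerMaxIter cap on outer (re-weighting) iterations.
#' @param probClip lower bound on the IRLS weights `p(1-p)`, keeping the
#'   coordinate-update denominators away from zero.
#' @param innerControl a [fitControl()] list for the inner solver.
#' @export
logisticControl <- function(outerTol = 1e-5, outerMaxIter = 25L,
                            probClip = 1e-5, innerControl = fitControl()) {
  stopifnot(outerTol > 0, outerMaxIter >= 1, probClip > 0)
  structure(list(outerTol = outerTol,
                 outerMaxIter = as.integer(outerMaxIter),
                 probClip = probClip, innerControl = innerControl),
            class = "gelnetLogisticControl")
}

.penalized_nll <- function(X, y, w, b, lambda1, lambda2, d, Pm) {
  eta <- as.numeric(X %*% w) + b
  # numerically stable -[y*eta - log(1 + exp(eta))]
  nll <- mean(ifelse(eta > 0,
                     (1 - y) * eta + log1p(exp(-eta)),
                     -y * eta + log1p(exp(eta))))
  quad <- if (is.null(Pm)) sum(w^2) else as.numeric(w %*% Pm %*% w)
  nll + lambda1 * sum(d * abs(w)) + lambda2 / 2 * quad
}

#' Penalized binary logistic regression via the GELnet solver
#'
#' Minimizes the average negative log-likelihood of a logistic model plus
#' the generalized elastic net penalty.  Each outer iteration forms the
#' second-order (IRLS-style) quadratic approximation at the current fit --
#' sample weights `a_i = p_i (1 - p_i)` (clipped from below) and working
#' response `z_i = eta_i + (y_i - p_i) / a_i` -- and solves the resulting
#' weighted least-squares GELnet with a warm start.  Stops when the change
#' in penalized negative log-likelihood falls below `control$outerTol`;
#' three consecutive increases beyond a small slack flag non-convergence.
#'
#' @param X n x p feature matrix.
#' @param y binary response in `{0, 1}` (both classes present).
#' @param lambda1,lambda2,d,P penalty configuration as in [gelnetFit()].
#' @param control a [logisticControl()] list.
#' @return a [GELnetModel-class]; `objectiveTrace` holds the running best
#'   penalized negative log-likelihood across outer iterations (the raw
#'   path can wiggle within the quadratic approximation).
#' @export
gelnetLogistic <- function(X, y, lambda1 = 0, lambda2 = 0, d = NULL,
                           P = NULL, control = logisticControl()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("y must contain both classes")
  n <- nrow(X); p <- ncol(X)
  if (is.null(d)) d <- rep(1, p)
  Pm <- .as_penalty_matrix(P, p)

  w <- rep(0, p)
  b <- qlogis(mean(y))
  obj <- .penalized_nll(X, y, w, b, lambda1, lambda2, d, Pm)
  trace <- obj
  converged <- FALSE
  bad_steps <- 0L
  it <- 0L

  for (it in seq_len(control$outerMaxIter)) {
    eta <- as.numeric(X %*% w) + b
    prob <- plogis(eta)
    a <- pmax(prob * (1 - prob), control$probClip)
    z <- eta + (y - prob) / a
    inner <- control$innerControl
    inner$wInit <- w
    inner$bInit <- b
    fit <- gelnetFit(X, z, lambda1 = lambda1, lambda2 = lambda2, a = a,
                     d = d, P = Pm, control = inner)
    w <- fit@w
    b <- fit@b
    obj_new <- .penalized_nll(X, y, w, b, lambda1, lambda2, d, Pm)
    trace <- c(trace, obj_new)
    if (obj_new > obj + 1e-8) bad_steps <- bad_steps + 1L else bad_steps <- 0L
    if (bad_steps >= 3L) break
    if (abs(obj - obj_new) < control$outerTol) { converged <- TRUE; break }
    obj <- obj_new
  }

  names(w) <- colnames(X)
  # trace is the outer NLL path; it can wiggle within the quadratic
  # approximation, so store the running minimum to honor model validity
  methods::new("GELnetModel", w = w, b = b,
               lambda1 = lambda1, lambda2 = lambda2, nIter = it,
               objectiveTrace = cummin(trace), converged = converged)
}

#' Sparse network-regularized principal component
#'
#' Seeks a penalized maximizer of the captured variance
#' \eqn{v^T (X^T X / n) v} by the linearize-solve-normalize iteration for
#' ratios of quadratic forms: at each step the current loading is mapped
#' to the gradient `g = (X^T X / n) v`, the penalized linear subproblem
#' \deqn{\min_w -g^T w + \lambda_1 \sum_j d_j |w_j| +
#'   \frac{\lambda_2}{2} w^T P w}
#' is solved exactly by cyclic coordinate descent, and the result is
#' rescaled to unit norm.  With vanishing penalties this is power
#' iteration, recovering the leading eigenvector; with an L1 penalty the
#' loading is sparse, and with a network penalty it concentrates on
#' well-connected gene sets.  `lambda2` must be positive (it provides the
#' curvature of the subproblem).
#'
#' The sign is fixed so the largest-magnitude loading is positive.
#'
#' @param X n x p matrix; columns are centered defensively (with a message
#'   when centering was actually needed).
#' @param lambda1,lambda2,d,P penalty configuration as in [gelnetFit()].
#' @param control a [fitControl()] list; `tol` bounds the sup-norm change
#'   in the loading between outer iterations.
#' @return a [GELnetComponent-class].
#' @export
gelnetPCA <- function(X, lambda1 = 1e-8, lambda2 = 1e-8, d = NULL,
                      P = NULL, control = fitControl()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (lambda2 <= 0) stop("lambda2 must be positive for the PCA reduction")
  if (is.null(d)) d <- rep(1, p)
  Pm <- .as_penalty_matrix(P, p)
  mu <- colMeans(X)
  if (max(abs(mu)) > 1e-8) {
    message("gelnetPCA: centering columns of X")
    X <- sweep(X, 2, mu)
  }
  zero_component <- function(conv) {
    v <- rep(0, p); names(v) <- colnames(X)
    methods::new("GELnetComponent", v = v, varExplained = 0,
                 objectiveTrace = numeric(), converged = conv)
  }
  if (all(X == 0)) {
    warning("zero data matrix; returning a zero component")
    return(zero_component(TRUE))
  }

  v <- rep(1 / sqrt(p), p)
  trace <- numeric()
  converged <- FALSE
  for (it in seq_len(control$maxIter)) {
    g <- as.numeric(crossprod(X, X %*% v)) / n
    sol <- .cd_linear_quad(g, lambda1, lambda2, d,
                           if (is.null(Pm)) matrix(0, 0, 0) else Pm,
                           is.null(Pm), v, control$tol * 1e-2, 1000L)
    w <- as.numeric(sol$w)
    nw <- sqrt(sum(w^2))
    if (nw == 0) {
      warning("L1 penalty removed every loading; returning a zero component")
      return(zero_component(TRUE))
    }
    v_new <- w / nw
    trace <- c(trace, as.numeric(crossprod(X %*% v_new)) / n)
    if (max(abs(v_new - v)) < control$tol) {
      v <- v_new; converged <- TRUE; break
    }
    v <- v_new
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  names(v) <- colnames(X)
  methods::new("GELnetComponent", v = v,
               varExplained = as.numeric(crossprod(X %*% v)) / n,
               objectiveTrace = trace, converged = converged)
}

#' @describeIn gelnetPCA loading vector accessor
#' @param component a [GELnetComponent-class].
#' @export
loadings <- function(component) component@v

#' @describeIn gelnetPCA captured variance accessor
#' @export
varExplained <- function(component) component@varExplained

setMethod("show", "GELnetComponent", function(object) {
  cat(sprintf(
    "GELnetComponent: %d loadings (%d nonzero), variance %.4g, %s\n",
    length(object@v), sum(object@v != 0), object@varExplained,
    if (object@converged) "converged" else "NOT converged"))
})

#' Deflate a data matrix by a unit loading vector
#'
#' Removes the component `(X v) v'` so that subsequent components are
#' orthogonal to `v` in data space.
#'
#' @param X n x p matrix.
#' @param v unit-norm loading vector of length p.
#' @return the deflated matrix.
#' @export
deflate <- function(X, v) {
  X <- as.matrix(X)
  v <- as.numeric(v)
  if (length(v) != ncol(X)) stop("v has the wrong length")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-8) stop("v must have unit norm")
  X - (X %*% v) %*% t(v)
}
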