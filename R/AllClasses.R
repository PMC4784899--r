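#' FeatureNetwork: an undirected weighted network over model features
#'
#' Thin S4 wrapper around a symmetric, nonnegative, zero-diagonal sparse
#' adjacency matrix with unique node identifiers.  Feature networks are the
#' input to all penalty-matrix constructors and to the dispersion metric.
#'
#' @slot adjacency symmetric nonnegative sparse \linkS4class{Matrix} with
#'   zero diagonal; dimnames carry the node identifiers.
#'
#' @seealso [featureNetwork()], [laplacianPenalty()], [scrambleNetwork()]
#' @exportClass FeatureNetwork
setClass("FeatureNetwork", representation(adjacency = "Matrix"))

setValidity("FeatureNetwork", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (!Matrix::isSymmetric(A, tol = 1e-12))
    msg <- c(msg, "adjacency must be symmetric")
  if (length(A@x) && min(A@x) < 0)
    msg <- c(msg, "edge weights must be nonnegative")
  if (any(Matrix::diag(A) != 0))
    msg <- c(msg, "adjacency must have a zero diagonal (no self-loops)")
  ids <- rownames(A)
  if (is.null(ids) || anyDuplicated(ids) || !identical(ids, colnames(A)))
    msg <- c(msg, "node ids must be unique and shared by rows and columns")
  if (length(msg)) msg else TRUE
})

#' PenaltyMatrix: a positive semi-definite feature-pair penalty
#'
#' Wraps the dense symmetric matrix \eqn{P} of the generalized elastic net
#' L2 term \eqn{(\lambda_2/2) w^T P w} together with a provenance tag
#' recording how it was built.  Validity enforces symmetry (tolerance
#' 1e-10 relative) and positive semi-definiteness (smallest eigenvalue
#' at least \eqn{-10^{-8}} times the spectral norm); violations are errors,
#' never silently clipped.
#'
#' @slot P symmetric p x p numeric matrix.
#' @slot provenance one of `"laplacian"`, `"normalized_laplacian"`,
#'   `"diffusion"`, `"nick"`, `"pseudo_inverse_kernel"`, `"identity"`,
#'   `"custom"`.
#'
#' @seealso [penaltyMatrix()], [laplacianPenalty()], [diffusionPenalty()],
#'   [nickPenalty()], [kernelPenalty()]
#' @exportClass PenaltyMatrix
setClass("PenaltyMatrix",
         representation(P = "matrix", provenance = "character"))

.penalty_provenances <- c("laplacian", "normalized_laplacian", "diffusion",
                          "nick", "pseudo_inverse_kernel", "identity",
                          "custom")

setValidity("PenaltyMatrix", function(object) {
  P <- object@P
  msg <- character()
  if (nrow(P) != ncol(P)) msg <- c(msg, "P must be square")
  scale <- max(1, max(abs(P)))
  if (max(abs(P - t(P))) > 1e-10 * scale)
    msg <- c(msg, "P must be symmetric (tolerance 1e-10)")
  if (!length(msg)) {
    ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
    nrm <- max(abs(ev))
    if (min(ev) < -1e-8 * max(nrm, 1))
      msg <- c(msg, sprintf(
        "P is not positive semi-definite (min eigenvalue %.3e)", min(ev)))
  }
  if (length(object@provenance) != 1 ||
      !object@provenance %in% .penalty_provenances)
    msg <- c(msg, "unknown provenance tag")
  if (length(msg)) msg else TRUE
})

#' GELnetModel: a fitted generalized elastic net
#'
#' @slot w named numeric vector of feature weights.
#' @slot b scalar bias.
#' @slot lambda1,lambda2 penalties used for the fit.
#' @slot nIter number of coordinate-descent sweeps (or outer iterations for
#'   the logistic reduction).
#' @slot objectiveTrace per-sweep objective values; validity requires the
#'   trace to be non-increasing up to a 1e-10 relative slack.
#' @slot converged whether the tolerance was reached within the iteration cap.
#'
#' @seealso [gelnetFit()], [gelnetLogistic()]
#' @exportClass GELnetModel
setClass("GELnetModel",
         representation(w = "numeric", b = "numeric",
                        lambda1 = "numeric", lambda2 = "numeric",
                        nIter = "integer", objectiveTrace = "numeric",
                        converged = "logical"))

setValidity("GELnetModel", function(object) {
  msg <- character()
  if (length(object@b) != 1) msg <- c(msg, "b must be a scalar")
  tr <- object@objectiveTrace
  if (length(tr) > 1) {
    slack <- 1e-10 * pmax(1, abs(tr[-length(tr)]))
    if (any(diff(tr) > slack))
      msg <- c(msg, "objective trace must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' GELnetComponent: a penalized principal-component loading
#'
#' @slot v named loading vector with unit Euclidean norm (or identically
#'   zero when the L1 penalty kills every coordinate).
#' @slot varExplained the variance \eqn{v^T (X^T X / n) v} captured.
#' @slot objectiveTrace captured variance across outer iterations.
#' @slot converged convergence flag.
#'
#' @seealso [gelnetPCA()]
#' @exportClass GELnetComponent
setClass("GELnetComponent",
         representation(v = "numeric", varExplained = "numeric",
                        objectiveTrace = "numeric", converged = "logical"))

setValidity("GELnetComponent", function(object) {
  nv <- sqrt(sum(object@v^2))
  if (abs(nv - 1) > 1e-8 && nv > 1e-8)
    "loading vector must have unit norm or be identically zero" else TRUE
})

#' SyntheticDataset: one draw of the synthetic benchmark
#'
#' @slot X n x p expression matrix drawn from N(0, S).
#' @slot y length-n response, `X %*% wTrue` plus optional noise.
#' @slot wTrue 0/1 pathway indicator vector (connected on `netTrue`).
#' @slot netTrue network used to generate the data.
#' @slot netGiven network handed to the learner (true or scrambled).
#' @slot scenario one of `"GGM+"`, `"GGM-"`, `"Rand+"`, `"Rand-"`.
#' @slot seed integer seed used for the draw (NA when none was supplied).
#'
#' @seealso [simulateDataset()]
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
         representation(X = "matrix", y = "numeric", wTrue = "numeric",
                        netTrue = "FeatureNetwork",
                        netGiven = "FeatureNetwork",
                        scenario = "character", seed = "integer"))

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "nrow(X) must equal length(y)")
  if (ncol(object@X) != length(object@wTrue))
    msg <- c(msg, "ncol(X) must equal length(wTrue)")
  if (!all(object@wTrue %in% c(0, 1)))
    msg <- c(msg, "wTrue must be a 0/1 vector")
  if (!object@scenario %in% c("GGM+", "GGM-", "Rand+", "Rand-"))
    msg <- c(msg, "unknown scenario tag")
  if (length(msg)) msg else TRUE
})

#' GELnetComparison: marginalized GELnet vs elastic-net comparison
#'
#' @slot grid long-format per-cell results: one row per
#'   (lambda2, lambda1 level, method) with nonzero count, reconstruction
#'   error, leave-pair-out RMSE and dispersion.
#' @slot marginal per-method means of the three metrics over the grid.
#' @slot improvement named percent improvements of the GELnet over the
#'   elastic net, `100 * (EN - GELnet) / EN`, for each metric.
#'
#' @seealso [runComparison()], [networkRelevance()]
#' @exportClass GELnetComparison
setClass("GELnetComparison",
         representation(grid = "data.frame", marginal = "data.frame",
                        improvement = "numeric"))
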