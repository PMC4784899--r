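#' Wrap a matrix as a validated penalty matrix
#'
#' @param P symmetric positive semi-definite numeric matrix.
#' @param provenance provenance tag; defaults to `"custom"`.
#' @return a [PenaltyMatrix-class]; asymmetric or indefinite input is an
#'   error (no silent eigenvalue clipping).
#' @export
penaltyMatrix <- function(P, provenance = "custom") {
  methods::new("PenaltyMatrix", P = as.matrix(P), provenance = provenance)
}

#' @describeIn penaltyMatrix extract the penalty matrix itself
#' @param x a [PenaltyMatrix-class].
#' @export
penalty <- function(x) x@P

#' @describeIn penaltyMatrix provenance tag accessor
#' @export
penaltyProvenance <- function(x) x@provenance

setMethod("show", "PenaltyMatrix", function(object) {
  cat(sprintf("PenaltyMatrix (%s): %d x %d\n", object@provenance,
              nrow(object@P), ncol(object@P)))
})

setMethod("dim", "PenaltyMatrix", function(x) dim(x@P))

.check_network <- function(net) {
  if (!methods::is(net, "FeatureNetwork"))
    stop("expected a FeatureNetwork; see featureNetwork()")
  methods::validObject(net)
  net
}

# Sparse normalized Laplacian with unit diagonal everywhere: off-diagonal
# entries -A_ij / sqrt(d_i d_j); isolated nodes keep a diagonal 1 so that a
# fully disconnected node set scores dispersion exactly 1.
.normalized_laplacian <- function(net) {
  A <- net@adjacency
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Dh <- Matrix::Diagonal(x = inv)
  S <- Dh %*% A %*% Dh         # A_ij / sqrt(d_i d_j), stays sparse
  Matrix::Diagonal(nrow(A), 1) - S
}

#' Graph Laplacian penalty matrices
#'
#' The unnormalized Laplacian is `L = Diag(degrees) - A`; its quadratic form
#' satisfies \eqn{w^T L w = \frac12 \sum_{ij} (w_i - w_j)^2 A_{ij}}, so it
#' penalizes weight differences across network edges.  The normalized
#' variant divides each off-diagonal by \eqn{\sqrt{d_i d_j}} and has unit
#' diagonal; isolated nodes are given diagonal 1 (identity convention), so
#' the Laplacian restricted to any set of mutually non-adjacent nodes is an
#' identity submatrix.
#'
#' @param net a [FeatureNetwork-class].
#' @param normalized use the degree-normalized Laplacian.
#' @return a [PenaltyMatrix-class] (dense).
#' @examples
#' net <- featureNetwork(rbind(c(0, 1), c(1, 0)))
#' penalty(laplacianPenalty(net))   # [[1,-1],[-1,1]]
#' @export
laplacianPenalty <- function(net, normalized = FALSE) {
  .check_network(net)
  L <- if (normalized) {
    .normalized_laplacian(net)
  } else {
    A <- net@adjacency
    Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  }
  L <- as.matrix(L)
  dimnames(L) <- list(nodeIds(net), nodeIds(net))
  penaltyMatrix(L, if (normalized) "normalized_laplacian" else "laplacian")
}

#' Diffusion-kernel penalty matrix
#'
#' Computes the diffusion (heat) kernel `D = expm(-t L)` of the unnormalized
#' graph Laplacian via symmetric eigendecomposition and returns the penalty
#' `P = I - D`.  All eigenvalues of `D` lie in `(0, 1]`, so `P` is positive
#' semi-definite; pairs of nodes that exchange much heat (same subgraph,
#' e.g. the same pathway) receive a low penalty.  Unlike the Laplacian,
#' the kernel looks beyond immediate neighbors.
#'
#' @param net a [FeatureNetwork-class].
#' @param t nonnegative diffusion time (default 0.1); `t = 0` gives the
#'   zero penalty, large `t` on a connected graph approaches
#'   `I - ones/p`.
#' @return a [PenaltyMatrix-class].
#' @export
diffusionPenalty <- function(net, t = 0.1) {
  .check_network(net)
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop("diffusion time t must be a nonnegative scalar")
  A <- as.matrix(net@adjacency)
  L <- diag(rowSums(A)) - A
  e <- eigen(L, symmetric = TRUE)
  D <- e$vectors %*% (exp(-t * e$values) * t(e$vectors))
  P <- diag(nrow(L)) - (D + t(D)) / 2
  dimnames(P) <- list(nodeIds(net), nodeIds(net))
  penaltyMatrix(P, "diffusion")
}

#' Network-induced classification kernel (NICK) penalty
#'
#' `P = I + beta * L`, a convex blend of ridge regression (`beta = 0`) and
#' Laplacian smoothing; strictly positive definite for any graph.
#'
#' @param net a [FeatureNetwork-class].
#' @param beta nonnegative trade-off between ridge and network smoothing.
#' @return a [PenaltyMatrix-class].
#' @export
nickPenalty <- function(net, beta) {
  .check_network(net)
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0)
    stop("beta must be a nonnegative scalar")
  A <- as.matrix(net@adjacency)
  P <- diag(nrow(A)) + beta * (diag(rowSums(A)) - A)
  dimnames(P) <- list(nodeIds(net), nodeIds(net))
  penaltyMatrix(P, "nick")
}

#' Penalty from the pseudo-inverse of a kernel matrix
#'
#' Kernels measure similarity, while the quadratic penalty should measure
#' dissimilarity; the Moore-Penrose pseudo-inverse of a PSD kernel is the
#' natural dissimilarity companion (for a graph Laplacian,
#' `pinv(pinv(L)) = L`).  Computed by symmetric eigendecomposition,
#' inverting eigenvalues above `tol * max(eigenvalue)` and zeroing the rest,
#' so the kernel's null space is preserved.
#'
#' @param kernel symmetric positive semi-definite matrix.
#' @param tol relative eigenvalue cutoff for the numerical rank.
#' @return a [PenaltyMatrix-class].
#' @export
kernelPenalty <- function(kernel, tol = 1e-10) {
  K <- as.matrix(kernel)
  if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K))))
    stop("kernel must be symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("kernel must be positive semi-definite")
  inv <- ifelse(e$values > tol * max(e$values, 0), 1 / e$values, 0)
  P <- e$vectors %*% (inv * t(e$vectors))
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(K)
  penaltyMatrix(P, "pseudo_inverse_kernel")
}

#' Identity penalty (classical elastic net)
#'
#' @param p number of features.
#' @param ids optional feature identifiers.
#' @return a [PenaltyMatrix-class] wrapping `diag(p)`.
#' @export
identityPenalty <- function(p, ids = NULL) {
  P <- diag(p)
  if (!is.null(ids)) dimnames(P) <- list(ids, ids)
  penaltyMatrix(P, "identity")
}

#' Read/write a penalty matrix as TSV with node-id header row and column
#'
#' @param x a [PenaltyMatrix-class].
#' @param path file path.
#' @name penaltyIO
#' @export
writePenaltyMatrix <- function(x, path) {
  M <- x@P
  if (is.null(rownames(M)))
    dimnames(M) <- list(paste0("g", seq_len(nrow(M))),
                        paste0("g", seq_len(ncol(M))))
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname penaltyIO
#' @param provenance provenance tag to attach on read.
#' @export
readPenaltyMatrix <- function(path, provenance = "custom") {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  penaltyMatrix(M, provenance)
}
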