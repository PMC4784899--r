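#' Construct a feature network from an adjacency matrix or igraph object
#'
#' @param adjacency a symmetric nonnegative matrix (base or Matrix) with a
#'   zero diagonal, or an `igraph` graph.  For matrices without dimnames,
#'   `nodeIds` supplies the identifiers (default `g1..gp`).
#' @param nodeIds optional character vector of unique node identifiers.
#'
#' @return a [FeatureNetwork-class] object.
#' @examples
#' net <- featureNetwork(rbind(c(0, 1), c(1, 0)), nodeIds = c("a", "b"))
#' degrees(net)
#' @export
featureNetwork <- function(adjacency, nodeIds = NULL) {
  if (inherits(adjacency, "igraph")) {
    g <- adjacency
    A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    if (!is.null(igraph::V(g)$name)) {
      nodeIds <- igraph::V(g)$name
    }
    adjacency <- A
  }
  A <- methods::as(methods::as(adjacency, "CsparseMatrix"), "generalMatrix")
  p <- nrow(A)
  if (is.null(nodeIds)) {
    nodeIds <- rownames(A)
    if (is.null(nodeIds)) nodeIds <- paste0("g", seq_len(p))
  }
  dimnames(A) <- list(nodeIds, nodeIds)
  methods::new("FeatureNetwork", adjacency = Matrix::drop0(A))
}

#' @describeIn featureNetwork adjacency matrix accessor
#' @param net a [FeatureNetwork-class].
#' @export
adjacency <- function(net) net@adjacency

#' @describeIn featureNetwork node identifier accessor
#' @export
nodeIds <- function(net) rownames(net@adjacency)

#' @describeIn featureNetwork number of nodes
#' @export
numNodes <- function(net) nrow(net@adjacency)

#' @describeIn featureNetwork weighted node degrees (adjacency row sums)
#' @export
degrees <- function(net) {
  d <- Matrix::rowSums(net@adjacency)
  names(d) <- nodeIds(net)
  d
}

#' @describeIn featureNetwork number of (undirected) edges
#' @export
numEdges <- function(net) length(net@adjacency@x) / 2

setMethod("show", "FeatureNetwork", function(object) {
  cat(sprintf("FeatureNetwork: %d nodes, %d edges\n",
              numNodes(object), numEdges(object)))
  ids <- nodeIds(object)
  cat("  nodes:", paste(head(ids, 5), collapse = ", "),
      if (length(ids) > 5) "..." else "", "\n")
})

#' Convert a feature network to an igraph graph
#'
#' @param net a [FeatureNetwork-class].
#' @return an undirected `igraph` graph with node names preserved.
#' @export
asIgraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected",
                                      weighted = TRUE)
}

.edge_df_to_network <- function(from, to, weight, nodeIds = NULL) {
  keep <- from != to
  if (any(!keep)) {
    warning(sprintf("dropped %d self-loop(s)", sum(!keep)))
    from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  }
  if (is.null(nodeIds)) nodeIds <- sort(unique(c(from, to)))
  i <- match(from, nodeIds)
  j <- match(to, nodeIds)
  if (anyNA(i) || anyNA(j)) stop("edge endpoints missing from node set")
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
    lo <- lo[!dup]; hi <- hi[!dup]; weight <- weight[!dup]
  }
  p <- length(nodeIds)
  A <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo),
                            x = c(weight, weight), dims = c(p, p))
  featureNetwork(A, nodeIds = nodeIds)
}

#' Read a network from a tab-separated edge list
#'
#' Expects a header and two (unweighted) or three (weighted) columns.
#' Self-loops are dropped with a warning; duplicate edges are collapsed to
#' their first occurrence.
#'
#' @param path file path.
#' @return a [FeatureNetwork-class].
#' @export
readEdgeList <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs at least two columns")
  w <- if (ncol(df) >= 3) as.numeric(df[[3]]) else rep(1, nrow(df))
  .edge_df_to_network(as.character(df[[1]]), as.character(df[[2]]), w)
}

#' Read a network in SIF format (`node <tab> relation <tab> node`)
#'
#' The relation column is ignored; the graph is treated as undirected and
#' unweighted.
#'
#' @param path file path.
#' @return a [FeatureNetwork-class].
#' @export
readSIF <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("SIF needs three columns: node, relation, node")
  .edge_df_to_network(as.character(df[[1]]), as.character(df[[3]]),
                      rep(1, nrow(df)))
}

#' Write a network as a tab-separated edge list
#'
#' @param net a [FeatureNetwork-class].
#' @param path output path.
#' @export
writeEdgeList <- function(net, path) {
  A <- methods::as(Matrix::triu(net@adjacency), "TsparseMatrix")
  ids <- nodeIds(net)
  df <- data.frame(from = ids[A@i + 1L], to = ids[A@j + 1L], weight = A@x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scramble feature-feature relationships in a network
#'
#' Selects `ceiling(fraction * p)` node indices uniformly without
#' replacement and applies a uniformly random permutation among them to
#' both rows and columns of the adjacency matrix.  Node identifiers stay
#' in place, so the features keep their labels while their neighborhoods
#' are reassigned; the degree multiset of the graph is preserved.  This is
#' the "scramble factor" corruption used to probe how much a network prior
#' can be degraded before it stops helping.
#'
#' @param net a [FeatureNetwork-class].
#' @param fraction fraction of nodes to permute, in `[0, 1]`.
#' @param seed optional integer seed (uses [withr::with_seed()]; the session
#'   RNG is untouched).
#' @return a [FeatureNetwork-class] with permuted relationships.
#' @export
scrambleNetwork <- function(net, fraction, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a scalar in [0, 1]")
  run <- function() {
    p <- numNodes(net)
    k <- ceiling(fraction * p)
    if (k < 2) return(net)
    sel <- sample.int(p, k)
    perm <- seq_len(p)
    perm[sel] <- sel[sample.int(k)]
    A <- net@adjacency[perm, perm, drop = FALSE]
    featureNetwork(A, nodeIds = nodeIds(net))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
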