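#' Configuration for the synthetic benchmark
#'
#' Defaults reproduce the benchmark's study conditions: a 5000-node
#' scale-free network, 50 samples, a "pathway" covering 10% of the nodes,
#' preferential attachment with 2 edges per new node, a 0.1 ridge shift in
#' the Gaussian graphical model precision, and a noiseless response.
#'
#' @param p number of features (network nodes).
#' @param n number of samples.
#' @param pathwayFraction fraction of nodes forming the causal pathway.
#' @param attachmentM edges added per node in preferential attachment.
#' @param ggmRidge ridge shift `delta` in the GGM precision matrix.
#' @param noiseSd standard deviation of optional response noise (0 keeps
#'   the exact linear response `y = X w`).
#' @param seed optional integer seed governing every draw.
#' @return a list of class `simulationConfig`.
#' @export
simulationConfig <- function(p = 5000L, n = 50L, pathwayFraction = 0.1,
                             attachmentM = 2L, ggmRidge = 0.1,
                             noiseSd = 0, seed = NULL) {
  stopifnot(pathwayFraction > 0, pathwayFraction < 1,
            p >= attachmentM + 1, n >= 2, ggmRidge > 0, noiseSd >= 0)
  structure(list(p = as.integer(p), n = as.integer(n),
                 pathwayFraction = pathwayFraction,
                 attachmentM = as.integer(attachmentM),
                 ggmRidge = ggmRidge, noiseSd = noiseSd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulationConfig")
}

#' Generate a scale-free network by preferential attachment
#'
#' Barabasi-Albert growth: each new node attaches `attachmentM` edges to
#' existing nodes with probability proportional to their degree.  The
#' result is connected with a heavy-tailed degree distribution, mimicking
#' the topology of gene interaction networks.
#'
#' @param p number of nodes.
#' @param attachmentM edges per new node.
#' @param seed optional integer seed.
#' @return a [FeatureNetwork-class] with nodes `g1..gp`.
#' @export
scaleFreeNetwork <- function(p, attachmentM = 2L, seed = NULL) {
  if (p < attachmentM + 1) stop("need p >= attachmentM + 1")
  run <- function() {
    g <- igraph::sample_pa(p, m = attachmentM, directed = FALSE)
    featureNetwork(g, nodeIds = paste0("g", seq_len(p)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Select a connected pathway by random walk
#'
#' Runs a simple random walk from a uniformly chosen start node, collecting
#' distinct visited nodes until `ceiling(pathwayFraction * p)` are found.
#' The indicator vector of collected nodes plays the role of the true
#' signaling pathway: its support is a connected subgraph of the network.
#'
#' @param net a connected [FeatureNetwork-class].
#' @param pathwayFraction target fraction of nodes, in (0, 1).
#' @param seed optional integer seed.
#' @param maxSteps step budget before giving up (guards against
#'   disconnected graphs, where the walk can never reach the target).
#' @return named 0/1 numeric vector of length p.
#' @export
samplePathwayWeights <- function(net, pathwayFraction = 0.1, seed = NULL,
                                 maxSteps = NULL) {
  .check_network(net)
  p <- numNodes(net)
  target <- ceiling(pathwayFraction * p)
  if (target < 1 || target > p) stop("pathwayFraction out of range")
  if (is.null(maxSteps)) maxSteps <- max(10000L, 1000L * target)
  A <- net@adjacency
  nbr <- split(A@i + 1L,
               factor(rep(seq_len(p), diff(A@p)), levels = seq_len(p)))
  run <- function() {
    node <- sample.int(p, 1)
    selected <- logical(p)
    selected[node] <- TRUE
    count <- 1L
    steps <- 0L
    while (count < target) {
      steps <- steps + 1L
      if (steps > maxSteps)
        stop("random walk exceeded its step budget; is the graph connected?")
      nb <- nbr[[node]]
      if (!length(nb))
        stop("random walk stalled on an isolated node")
      node <- nb[sample.int(length(nb), 1)]
      if (!selected[node]) {
        selected[node] <- TRUE
        count <- count + 1L
      }
    }
    w <- as.numeric(selected)
    names(w) <- nodeIds(net)
    w
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Covariance of a Gaussian graphical model tied to a network
#'
#' Builds the precision matrix
#' `Omega = (max eigenvalue of A + delta) I - A` -- positive definite by
#' construction, with off-diagonal support exactly equal to the network's
#' edges -- and returns its inverse `S`.  Data drawn from `N(0, S)` has
#' the network as its conditional-independence graph, and adjacent
#' features are *positively* partially correlated, mimicking the
#' co-expression of genes in a shared pathway.  The returned matrix
#' carries a `support_ok` attribute certifying (by re-inversion) that the
#' off-diagonal support of `S^-1` matches the adjacency.
#'
#' @param net a [FeatureNetwork-class].
#' @param delta positive ridge shift.
#' @return p x p covariance matrix with attributes `support_ok` and
#'   `shift` (the diagonal loading used).
#' @export
ggmCovariance <- function(net, delta = 0.1) {
  .check_network(net)
  if (delta <= 0) stop("delta must be positive")
  A <- as.matrix(net@adjacency)
  ev_max <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  shift <- ev_max + delta
  Omega <- diag(shift, nrow(A)) - A
  R <- tryCatch(chol(Omega),
                error = function(e) stop("precision matrix not PD: ",
                                         conditionMessage(e)))
  S <- chol2inv(R)
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(A)
  Omega_back <- chol2inv(chol(S))
  off <- abs(Omega_back - diag(diag(Omega_back)))
  support_ok <- identical(unname(off > 1e-6), unname(A > 0))
  attr(S, "support_ok") <- support_ok
  attr(S, "shift") <- shift
  S
}

#' Network-free random covariance matrix
#'
#' Wishart-style draw `S = G G^T / p + 1e-3 I` with `G` a p x p standard
#' normal matrix: positive definite and statistically independent of any
#' network, modeling the negative-control case where the expression data
#' carries no relationship to the gene network.
#'
#' @param p dimension.
#' @param seed optional integer seed.
#' @return p x p covariance matrix.
#' @export
randomCovariance <- function(p, seed = NULL) {
  run <- function() {
    G <- matrix(rnorm(p * p), p, p)
    tcrossprod(G) / p + diag(1e-3, p)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate one dataset of the four-scenario benchmark
#'
#' A scale-free network is generated, a connected pathway selected by
#' random walk, and `n` expression profiles drawn from `N(0, S)` where `S`
#' is either the GGM covariance coupled to the network (`GGM` scenarios)
#' or a random covariance (`Rand` scenarios).  The response is the exact
#' pathway activity `y = X wTrue` (plus optional noise).  In the `+`
#' scenarios the learner is handed the true network; in the `-` scenarios
#' a fully scrambled one (fraction 1).
#'
#' @param config a [simulationConfig()].
#' @param scenario one of `"GGM+"`, `"GGM-"`, `"Rand+"`, `"Rand-"`.
#' @return a [SyntheticDataset-class].
#' @export
simulateDataset <- function(config, scenario = c("GGM+", "GGM-",
                                                 "Rand+", "Rand-")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "simulationConfig"))
  run <- function() {
    net <- scaleFreeNetwork(config$p, config$attachmentM)
    wTrue <- samplePathwayWeights(net, config$pathwayFraction)
    S <- if (startsWith(scenario, "GGM")) {
      ggmCovariance(net, config$ggmRidge)
    } else {
      randomCovariance(config$p)
    }
    Z <- matrix(rnorm(config$n * config$p), config$n, config$p)
    X <- Z %*% chol(S)
    colnames(X) <- nodeIds(net)
    y <- as.numeric(X %*% wTrue)
    if (config$noiseSd > 0) y <- y + rnorm(config$n, sd = config$noiseSd)
    netGiven <- if (endsWith(scenario, "+")) {
      net
    } else {
      scrambleNetwork(net, 1)
    }
    methods::new("SyntheticDataset", X = X, y = y, wTrue = wTrue,
                 netTrue = net, netGiven = netGiven, scenario = scenario,
                 seed = if (is.null(config$seed)) NA_integer_
                        else config$seed)
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset [%s]: %d samples x %d features, pathway size %d\n",
    object@scenario, nrow(object@X), ncol(object@X), sum(object@wTrue)))
})
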