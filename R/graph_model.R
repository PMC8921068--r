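#' Build the Markov information graph of one state
#'
#' Converts a state's back-projected mean and covariance into a weighted
#' directed graph over regions: node weights are the mean activity and the
#' edge weight from region x to y is the absolute correlation |rho(x,y)|
#' divided by the sum of |rho(x,z)| over all z (diagonal included). Every
#' row of W is therefore a probability vector, so W acts as a random-walk
#' transition matrix modelling information flow between regions.
#'
#' @param mu length-D state mean activity
#' @param sigma D x D PSD state covariance
#' @param stateId integer label attached to the graph
#' @param nodes optional region names
#' @param warnRankDeficient warn when sigma is rank-deficient (default TRUE;
#'   back-projected covariances have rank at most d by construction, so the
#'   multiplex builder disables the warning)
#' @return a \linkS4class{StateGraph}
#' @examples
#' g <- markovInformationGraph(c(1, -1), matrix(c(1, .5, .5, 1), 2))
#' edgeWeights(g)
#' @export
markovInformationGraph <- function(mu, sigma, stateId = 1L, nodes = NULL,
                                   warnRankDeficient = TRUE) {
  sigma <- as.matrix(sigma)
  D <- length(mu)
  stopIfNot(identical(dim(sigma), c(D, D)), "mu and sigma dimensions differ")
  v <- diag(sigma)
  if (any(v <= 0)) {
    bad <- if (!is.null(nodes)) nodes[v <= 0] else which(v <= 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (qr(sigma)$rank < D) {
    if (warnRankDeficient)
      warning("rank-deficient covariance; correlations computed with ",
              "ridge-regularized variances")
    sigma <- sigma + diag(1e-10 * sum(v) / D, D)
    v <- diag(sigma)
  }
  rho <- sigma / sqrt(outer(v, v))
  Wabs <- abs(rho)
  W <- Wabs / rowSums(Wabs)
  if (is.null(nodes)) nodes <- paste0("R", seq_len(D))
  new("StateGraph", stateId = as.integer(stateId), nodes = as.character(nodes),
      a = as.numeric(mu), W = W)
}

#' Fraction of matrix energy in the symmetric part
#'
#' Decomposes W into its symmetric part (W + W^T)/2 and antisymmetric part
#' (W - W^T)/2 and returns the fraction of the squared Frobenius norm
#' (matrix energy) carried by the symmetric part. The two parts are
#' orthogonal, so the value lies in [0, 1], with 1 iff W is exactly
#' symmetric and 0 iff antisymmetric.
#'
#' @param W square numeric matrix (nonzero)
#' @return symmetry fraction in [0, 1]
#' @examples
#' symmetryFraction(matrix(c(0, 1, 0, 0), 2))
#' @export
symmetryFraction <- function(W) {
  W <- as.matrix(W)
  stopIfNot(nrow(W) == ncol(W), "W must be square")
  total <- sum(W^2)
  stopIfNot(total > 0, "symmetry fraction is undefined for the zero matrix")
  sym <- (W + t(W)) / 2
  sum(sym^2) / total
}

#' Assemble the multiplex graph model of a fitted HMM
#'
#' Builds one Markov information graph per state from the back-projected
#' parameters and links the layers by the state transition matrix and its
#' stationary distribution.
#'
#' @param model an \linkS4class{HMGModel}
#' @return a \linkS4class{MultiplexModel}
#' @export
multiplexModel <- function(model) {
  nodes <- rownames(model@A@A)
  if (is.null(nodes)) nodes <- paste0("R", seq_len(nrow(model@A@A)))
  layers <- lapply(seq_len(model@K), function(s)
    markovInformationGraph(model@mu[s, ], model@sigma[[s]], stateId = s,
                           nodes = nodes, warnRankDeficient = FALSE))
  new("MultiplexModel", stateGraphs = layers, P = model@P,
      pi = as.numeric(stationaryDistribution(model@P)),
      sigma = model@sigma)
}

#' Assemble a multiplex model directly from state parameters
#'
#' Convenience constructor from explicit per-state means/covariances and a
#' transition matrix, e.g. for planted synthetic state models.
#'
#' @param mus list of length-K state means (each length D)
#' @param sigmas list of K D x D PSD covariances
#' @param P K x K row-stochastic interlayer transition matrix
#' @param nodes optional region names
#' @return a \linkS4class{MultiplexModel}
#' @export
multiplexFromParams <- function(mus, sigmas, P, nodes = NULL) {
  stopIfNot(length(mus) == length(sigmas) && length(mus) == nrow(P),
            "mus, sigmas and P must agree on the number of states")
  layers <- lapply(seq_along(mus), function(s)
    markovInformationGraph(mus[[s]], sigmas[[s]], stateId = s, nodes = nodes))
  new("MultiplexModel", stateGraphs = layers, P = as.matrix(P),
      pi = as.numeric(stationaryDistribution(P)), sigma = sigmas)
}

#' Export a state graph as GraphML and an edge list
#'
#' Writes the graph with node attribute \code{activity} and edge attribute
#' \code{weight} as GraphML, plus a three-column tab-separated edge list.
#'
#' @param graph a \linkS4class{StateGraph}
#' @param file output path; the edge list gets extension \code{.edges.tsv}
#' @return invisibly, the written paths
#' @export
writeStateGraph <- function(graph, file) {
  g <- igraph::graph_from_adjacency_matrix(graph@W, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  igraph::V(g)$name <- graph@nodes
  igraph::V(g)$activity <- graph@a
  igraph::write_graph(g, file, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  edgeFile <- sub("\\.graphml$", "", file)
  edgeFile <- paste0(edgeFile, ".edges.tsv")
  utils::write.table(el, edgeFile, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(file, edgeFile))
}
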