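#' Directed (Leicht-Newman) modularity of a partition
#'
#' Q = (1/m) sum_ij [ W_ij - gamma * s_i^out s_j^in / m ] delta(c_i, c_j),
#' where s^out and s^in are the row and column strengths and m the total
#' weight. Self-loops are counted once in m and enter both strengths. On a
#' symmetric matrix this reduces to classical undirected modularity.
#'
#' @param W nonnegative weighted adjacency matrix (directed allowed)
#' @param labels integer community label per node
#' @param gamma resolution parameter (default 1)
#' @return modularity value Q
#' @examples
#' W <- matrix(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 1, 0), 4,
#'             byrow = TRUE)
#' directedModularity(W, c(1, 1, 2, 2))
#' @export
directedModularity <- function(W, labels, gamma = 1) {
  W <- as.matrix(W)
  stopIfNot(all(W >= 0), "edge weights must be nonnegative")
  m <- sum(W)
  stopIfNot(m > 0, "total edge weight must be positive")
  labels <- as.integer(labels)
  sOut <- rowSums(W)
  sIn <- colSums(W)
  same <- outer(labels, labels, "==")
  sum((W - gamma * outer(sOut, sIn) / m) * same) / m
}

# one Louvain run on the symmetrized graph under a permuted node order;
# returns integer labels in the original node order
.louvainOnce <- function(Wsym, gamma) {
  n <- nrow(Wsym)
  perm <- sample.int(n)
  g <- igraph::graph_from_adjacency_matrix(Wsym[perm, perm],
                                           mode = "undirected",
                                           weighted = TRUE, diag = TRUE)
  cl <- igraph::cluster_louvain(g, resolution = gamma)
  memb <- integer(n)
  memb[perm] <- igraph::membership(cl)
  as.integer(memb)
}

.relabelContiguous <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' Louvain community detection scored by directed modularity
#'
#' Runs Louvain optimisation \code{nRuns} times with shuffled node orders on
#' the symmetrized graph (W + W^T)/2, scores every candidate partition with
#' the directed modularity of the original W at the same resolution, and
#' returns the best-scoring partition. Deterministic given the seed.
#'
#' @param W nonnegative weighted adjacency matrix
#' @param gamma resolution parameter
#' @param seed integer seed
#' @param nRuns number of shuffled-order runs (default 10)
#' @return a \linkS4class{Partition}
#' @export
louvain <- function(W, gamma = 1, seed = 1L, nRuns = 10L) {
  W <- as.matrix(W)
  stopIfNot(all(W >= 0), "edge weights must be nonnegative")
  n <- nrow(W)
  if (n == 1L)
    return(new("Partition", labels = 1L, gamma = gamma, Q = 0))
  Wsym <- (W + t(W)) / 2
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(nRuns)) {
      labels <- .relabelContiguous(.louvainOnce(Wsym, gamma))
      Q <- directedModularity(W, labels, gamma)
      if (is.null(best) || Q > best$Q) best <- list(labels = labels, Q = Q)
    }
    new("Partition", labels = best$labels, gamma = gamma, Q = best$Q)
  })
}

#' Permutation significance of a community partition
#'
#' Compares the observed directed modularity with the empirical distribution
#' obtained by uniformly permuting the community label vector (community
#' sizes preserved) \code{nPerm} times. The p-value uses the add-one rule
#' p = (1 + #\{Q_perm >= Q_obs\}) / (1 + nPerm). A single-community
#' partition has no structure to test and returns p = 1.
#'
#' @param W weighted adjacency matrix
#' @param partition a \linkS4class{Partition} (its gamma is reused)
#' @param nPerm number of permutations (>= 100; default 10000)
#' @param seed integer seed
#' @return permutation p-value
#' @export
modularitySignificance <- function(W, partition, nPerm = 10000L, seed = 1L) {
  stopIfNot(nPerm >= 100, "need at least 100 permutations")
  labels <- partition@labels
  if (max(labels) == 1L) return(1)
  gamma <- partition@gamma
  W <- as.matrix(W)
  m <- sum(W)
  sOut <- rowSums(W); sIn <- colSums(W)
  qOf <- function(l) {
    same <- outer(l, l, "==")
    sum((W - gamma * outer(sOut, sIn) / m) * same) / m
  }
  qObs <- qOf(labels)
  withSeed(seed, {
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      if (qOf(sample(labels)) >= qObs - 1e-12) exceed <- exceed + 1L
    }
    (1 + exceed) / (1 + nPerm)
  })
}

#' Select the Louvain resolution by Variation of Information
#'
#' For every resolution in \code{gammaGrid}, runs Louvain \code{nRuns} times
#' with shuffled node orders and computes the mean pairwise Variation of
#' Information among the resulting partitions. The resolution with the most
#' reproducible partitions (minimum mean VI; smallest gamma on ties) is
#' returned.
#'
#' @param W weighted adjacency matrix
#' @param gammaGrid candidate resolutions
#' @param nRuns Louvain runs per resolution (default 20)
#' @param seed integer seed
#' @return list with \code{gamma} (selected), \code{meanVI} per grid point
#' @export
selectResolutionVI <- function(W, gammaGrid = seq(0.1, 2.0, by = 0.02),
                               nRuns = 20L, seed = 1L) {
  stopIfNot(length(gammaGrid) > 0, "gamma grid must be non-empty")
  W <- as.matrix(W)
  Wsym <- (W + t(W)) / 2
  meanVI <- numeric(length(gammaGrid))
  for (i in seq_along(gammaGrid)) {
    parts <- withSeed(deriveSeed(seed, i), {
      lapply(seq_len(nRuns), function(r) .louvainOnce(Wsym, gammaGrid[i]))
    })
    vi <- 0; np <- 0
    for (a in seq_len(nRuns - 1)) for (b in seq((a + 1), nRuns)) {
      vi <- vi + variationOfInformation(parts[[a]], parts[[b]])
      np <- np + 1
    }
    meanVI[i] <- if (np > 0) vi / np else 0
  }
  list(gamma = gammaGrid[which.min(meanVI)], meanVI = meanVI,
       gammaGrid = gammaGrid)
}

#' Variation of Information between two partitions
#'
#' VI(X, Y) = H(X) + H(Y) - 2 I(X; Y), computed from the joint label
#' contingency table with natural logarithms. VI is a metric on partitions:
#' zero iff the partitions coincide, symmetric, and bounded by log(n).
#'
#' @param a,b integer label vectors over the same nodes
#' @return nonnegative VI value
#' @export
variationOfInformation <- function(a, b) {
  stopIfNot(length(a) == length(b), "partitions must cover the same nodes")
  n <- length(a)
  joint <- table(a, b) / n
  px <- rowSums(joint); py <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- sum(joint[joint > 0] *
              log(joint[joint > 0] / outer(px, py)[joint > 0]))
  max(0, ent(px) + ent(py) - 2 * mi)
}

#' Within-community centrality z-scores
#'
#' For node i in community U, the within-community strength is the sum of
#' its in- and out-weights to members of U; the z-score standardizes it
#' against the mean and standard deviation of that strength within U. A
#' community with zero strength variance gets z = 0 for all members.
#'
#' @param W weighted adjacency matrix
#' @param partition a \linkS4class{Partition}
#' @return numeric z-score per node
#' @export
communityZscore <- function(W, partition) {
  W <- as.matrix(W)
  labels <- partition@labels
  n <- length(labels)
  kWithin <- numeric(n)
  for (i in seq_len(n)) {
    memb <- labels == labels[i]
    kWithin[i] <- sum(W[i, memb]) + sum(W[memb, i])
  }
  z <- numeric(n)
  for (u in unique(labels)) {
    idx <- labels == u
    s <- stats::sd(kWithin[idx])
    if (sum(idx) > 1 && s > 0)
      z[idx] <- (kWithin[idx] - mean(kWithin[idx])) / s
  }
  z
}

#' Select the hub of each community
#'
#' The hub of community U is the member maximising the within-community
#' centrality z-score; ties go to the lower node index.
#'
#' @param z z-scores from \code{\link{communityZscore}}
#' @param partition a \linkS4class{Partition}
#' @return list with \code{hubs} (named integer vector, one node per
#'   community) and \code{z}
#' @export
selectHubs <- function(z, partition) {
  labels <- partition@labels
  comms <- sort(unique(labels))
  hubs <- vapply(comms, function(u) {
    idx <- which(labels == u)
    idx[which.max(z[idx])] # which.max takes the first maximum: lowest index
  }, integer(1))
  names(hubs) <- paste0("U", comms)
  list(hubs = hubs, z = z)
}

#' Ward clustering of fractional occupancy
#'
#' Hierarchical agglomerative clustering of subjects (rows of kappa) and of
#' states (columns) under the correlation distance 1 - Pearson r, using
#' Ward's linkage. Trees are also returned serialized in Newick format.
#'
#' @param kappa an \linkS4class{OccupancyTable} with N >= 2 and K >= 2
#' @return list with \code{subjects} and \code{states} (hclust objects) and
#'   \code{newick} (named character vector of the two serialized trees)
#' @export
wardClusterOccupancy <- function(kappa) {
  km <- occupancy(kappa)
  stopIfNot(nrow(km) >= 2 && ncol(km) >= 2, "need N >= 2 and K >= 2")
  colnames(km) <- paste0("state", seq_len(ncol(km)))
  checkVar <- function(M, what) {
    v <- apply(M, 1, stats::sd)
    if (any(v == 0))
      stop("zero-variance ", what, ": ",
           paste(rownames(M)[v == 0], collapse = ", "), call. = FALSE)
  }
  checkVar(km, "subject row(s)")
  checkVar(t(km), "state column(s)")
  dSub <- stats::as.dist(1 - stats::cor(t(km)))
  dSta <- stats::as.dist(1 - stats::cor(km))
  hSub <- stats::hclust(dSub, method = "ward.D2")
  hSta <- stats::hclust(dSta, method = "ward.D2")
  list(subjects = hSub, states = hSta,
       newick = c(subjects = ape::write.tree(ape::as.phylo(hSub)),
                  states = ape::write.tree(ape::as.phylo(hSta))))
}
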