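#' @import methods
NULL

.isRowStochastic <- function(P, tol = 1e-10) {
  is.matrix(P) && all(P >= -tol) && all(abs(rowSums(P) - 1) < max(tol, 1e-8))
}

#' GeneratorSpec: parameters of the synthetic multi-subject HMM generator
#'
#' Describes the ground-truth process that generated (or is to generate) a
#' multi-subject dataset: a shared K-state Markov chain with per-state
#' multivariate-normal observation models, sampled independently per subject.
#'
#' @slot nSubjects number of subjects (independent trials)
#' @slot nTimepoints trial length T
#' @slot nRegions number of regions D
#' @slot nStates true number of states K
#' @slot transitionMatrix K x K row-stochastic matrix
#' @slot stateMeans K x D matrix of state mean activity
#' @slot stateCovariances list of K symmetric PSD D x D matrices
#' @slot seed integer seed controlling all randomness of generation
#' @exportClass GeneratorSpec
setClass("GeneratorSpec",
  representation(nSubjects = "integer", nTimepoints = "integer",
                 nRegions = "integer", nStates = "integer",
                 transitionMatrix = "matrix", stateMeans = "matrix",
                 stateCovariances = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    K <- object@nStates; D <- object@nRegions
    if (object@nSubjects < 1L || object@nTimepoints < 1L || D < 1L || K < 1L)
      msg <- c(msg, "counts must be positive")
    P <- object@transitionMatrix
    if (!identical(dim(P), c(K, K)) ||
        any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
      msg <- c(msg, "transitionMatrix must be K x K row-stochastic (rows sum to 1 within 1e-12, entries >= 0)")
    if (!identical(dim(object@stateMeans), c(K, D)))
      msg <- c(msg, "stateMeans must be K x D")
    if (length(object@stateCovariances) != K) {
      msg <- c(msg, "need one covariance per state")
    } else {
      for (k in seq_len(K)) {
        S <- object@stateCovariances[[k]]
        if (!is.matrix(S) || !identical(dim(S), c(D, D)) ||
            max(abs(S - t(S))) > 1e-10) {
          msg <- c(msg, sprintf("covariance %d must be symmetric D x D", k))
        } else if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
          msg <- c(msg, sprintf("covariance %d is not positive semi-definite", k))
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: planted structure of a synthetic dataset
#'
#' @slot statePaths list of per-subject integer state sequences
#' @slot temporalLabels community label per state (0-length when none planted)
#' @slot spatialLabels per-state list of region community labels (may be empty)
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(statePaths = "list", temporalLabels = "integer",
                 spatialLabels = "list"),
  validity = function(object) {
    ok <- all(vapply(object@statePaths,
                     function(p) is.integer(p) && all(p >= 1L), logical(1)))
    if (!ok) "state paths must be positive integer sequences" else TRUE
  })

#' Eigenmatrix: PCA projection used for dimensionality reduction
#'
#' Holds the D x d matrix of the leading principal eigenvectors of the pooled
#' correlation matrix, used to reduce the region series before HMM fitting and
#' to back-project state parameters into region space.
#'
#' @slot A D x d matrix with orthonormal columns
#' @slot explainedVariance fraction of total variance captured by the d axes
#' @slot d retained dimension
#' @exportClass Eigenmatrix
setClass("Eigenmatrix",
  representation(A = "matrix", explainedVariance = "numeric", d = "integer"),
  validity = function(object) {
    A <- object@A; d <- object@d
    if (d < 1L || d > nrow(A)) return("need 1 <= d <= D")
    if (ncol(A) != d) return("A must have d columns")
    if (max(abs(crossprod(A) - diag(d))) > 1e-8)
      return("columns of A must be orthonormal")
    if (object@explainedVariance < 0 || object@explainedVariance > 1 + 1e-12)
      return("explainedVariance must lie in [0, 1]")
    TRUE
  })

#' HMGModel: fitted hidden Markov graph model
#'
#' A K-state Gaussian-observation HMM fitted in the reduced d-dimensional
#' space, together with the eigenmatrix and the back-projected region-space
#' state means and covariances.
#'
#' @slot K number of states
#' @slot P K x K row-stochastic state transition matrix
#' @slot pi0 initial state distribution used by the fit
#' @slot muStar K x d reduced-space state means
#' @slot sigmaStar list of K d x d reduced-space covariances
#' @slot A Eigenmatrix mapping reduced to region space
#' @slot mu K x D back-projected state means
#' @slot sigma list of K D x D back-projected covariances
#' @slot logLik training log-likelihood of the selected restart
#' @slot logLikTrace per-iteration EM log-likelihood trace
#' @exportClass HMGModel
setClass("HMGModel",
  representation(K = "integer", P = "matrix", pi0 = "numeric",
                 muStar = "matrix", sigmaStar = "list", A = "Eigenmatrix",
                 mu = "matrix", sigma = "list", logLik = "numeric",
                 logLikTrace = "numeric"),
  validity = function(object) {
    K <- object@K
    if (!identical(dim(object@P), c(K, K)) || !.isRowStochastic(object@P))
      return("P must be K x K row-stochastic (rows sum to 1 within 1e-10)")
    if (nrow(object@muStar) != K || length(object@sigmaStar) != K ||
        nrow(object@mu) != K || length(object@sigma) != K)
      return("state parameter dimensions do not match K")
    A <- object@A@A
    for (k in seq_len(K)) {
      if (max(abs(object@mu[k, ] - drop(A %*% object@muStar[k, ]))) > 1e-8)
        return("back-projected means inconsistent with muStar and A")
      if (max(abs(object@sigma[[k]] -
                  A %*% object@sigmaStar[[k]] %*% t(A))) > 1e-8)
        return("back-projected covariances inconsistent with sigmaStar and A")
    }
    TRUE
  })

#' OccupancyTable: per-subject fractional occupancy of each state
#'
#' Row n holds the time-averaged posterior probability of each state for
#' subject n; every row is a probability vector.
#'
#' @slot kappa N x K matrix of fractional occupancies
#' @slot subjectIds subject identifiers (row names of kappa)
#' @exportClass OccupancyTable
setClass("OccupancyTable",
  representation(kappa = "matrix", subjectIds = "character"),
  validity = function(object) {
    k <- object@kappa
    if (any(k < -1e-12) || any(k > 1 + 1e-12))
      return("occupancies must lie in [0, 1]")
    if (any(abs(rowSums(k) - 1) > 1e-8))
      return("each occupancy row must sum to 1 within 1e-8")
    if (length(object@subjectIds) != nrow(k))
      return("one subject id per row required")
    TRUE
  })

#' StateGraph: the Markov information graph of one state
#'
#' A weighted directed graph over the D regions: node weights are the state
#' mean activity and edge weights are row-normalised absolute correlations,
#' so every row of W is a probability vector over target regions (self-loops
#' included).
#'
#' @slot stateId which state this layer represents
#' @slot nodes ordered region names
#' @slot a node activity vector (state mean per region)
#' @slot W D x D nonnegative row-stochastic edge-weight matrix
#' @exportClass StateGraph
setClass("StateGraph",
  representation(stateId = "integer", nodes = "character", a = "numeric",
                 W = "matrix"),
  validity = function(object) {
    W <- object@W
    D <- length(object@nodes)
    if (!identical(dim(W), c(D, D)) || length(object@a) != D)
      return("W must be D x D and a of length D")
    if (any(W < 0) || any(W > 1 + 1e-12))
      return("edge weights must lie in [0, 1]")
    if (any(abs(rowSums(W) - 1) > 1e-10))
      return("each row of W must sum to 1 within 1e-10")
    if (any(diag(W) <= 0))
      return("diagonal self-loop weights must be positive")
    TRUE
  })

#' MultiplexModel: state graphs linked by the transition matrix
#'
#' The collection of per-state Markov information graphs (layers) together
#' with the interlayer transition matrix P and its stationary distribution.
#'
#' @slot stateGraphs list of StateGraph layers
#' @slot P interlayer K x K transition matrix
#' @slot pi stationary distribution of P
#' @slot sigma list of per-state D x D covariances (used by the
#'   functional-homogeneity ranking)
#' @exportClass MultiplexModel
setClass("MultiplexModel",
  representation(stateGraphs = "list", P = "matrix", pi = "numeric",
                 sigma = "list"),
  validity = function(object) {
    K <- length(object@stateGraphs)
    if (!identical(dim(object@P), c(K, K)) || length(object@pi) != K ||
        length(object@sigma) != K)
      return("number of layers must match dim(P), length(pi) and length(sigma)")
    if (!.isRowStochastic(object@P)) return("P must be row-stochastic")
    if (abs(sum(object@pi) - 1) > 1e-8 || any(object@pi < -1e-12))
      return("pi must be a probability vector")
    TRUE
  })

#' SelectionCurve: cross-validated model-selection results over k
#'
#' @slot kValues candidate state counts
#' @slot cvEntropy leave-one-subject-out cross-validated entropy H(k)
#' @slot cvLogLik held-out log-likelihood per k
#' @slot selectedK argmax of cvEntropy (smallest k on ties)
#' @exportClass SelectionCurve
setClass("SelectionCurve",
  representation(kValues = "integer", cvEntropy = "numeric",
                 cvLogLik = "numeric", selectedK = "integer"),
  validity = function(object) {
    if (length(object@kValues) != length(object@cvEntropy) ||
        length(object@kValues) != length(object@cvLogLik))
      return("curve vectors must share length")
    if (any(object@cvEntropy < -1e-10))
      return("H(k) must be nonnegative")
    best <- object@kValues[which.max(object@cvEntropy)]
    if (object@selectedK != best)
      return("selectedK must be the argmax of cvEntropy (smallest k on ties)")
    TRUE
  })

#' Partition: a community partition of a weighted graph
#'
#' @slot labels integer community label per node, ids contiguous from 1
#' @slot gamma resolution parameter used
#' @slot Q directed modularity of the partition at gamma
#' @exportClass Partition
setClass("Partition",
  representation(labels = "integer", gamma = "numeric", Q = "numeric"),
  validity = function(object) {
    l <- object@labels
    if (length(l) == 0) return("labels must cover at least one node")
    if (!setequal(unique(l), seq_len(max(l))))
      return("community ids must be contiguous from 1")
    TRUE
  })
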