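#' Construct a GeneratorSpec for the synthetic multi-subject HMM generator
#'
#' The generator emulates N subjects observed for T time points over D
#' regions: all subjects share one K-state Markov chain (transition matrix
#' \code{transitionMatrix}) and per-state multivariate-normal observation
#' models. Each subject is an independent realisation; the initial state is
#' drawn uniformly over states.
#'
#' @param nSubjects number of subjects
#' @param nTimepoints trial length T
#' @param nRegions number of regions D
#' @param transitionMatrix K x K row-stochastic matrix
#' @param stateMeans K x D matrix (row k = mean activity of state k)
#' @param stateCovariances list of K symmetric PSD D x D matrices
#' @param seed integer seed; identical seeds give bit-identical datasets
#' @return a validated \linkS4class{GeneratorSpec}
#' @examples
#' sp <- generatorSpec(2, 50, 3, diag(2) * 0.8 + 0.1,
#'                     rbind(c(1, 0, 0), c(0, 1, 0)),
#'                     list(diag(3), diag(3)), seed = 1)
#' @export
generatorSpec <- function(nSubjects, nTimepoints, nRegions, transitionMatrix,
                          stateMeans, stateCovariances, seed = 1L) {
  new("GeneratorSpec",
      nSubjects = as.integer(nSubjects), nTimepoints = as.integer(nTimepoints),
      nRegions = as.integer(nRegions),
      nStates = as.integer(nrow(transitionMatrix)),
      transitionMatrix = as.matrix(transitionMatrix),
      stateMeans = as.matrix(stateMeans),
      stateCovariances = stateCovariances, seed = as.integer(seed))
}

# sample one Markov path of length T (uniform initial state)
.samplePath <- function(P, T) {
  K <- nrow(P)
  path <- integer(T)
  path[1] <- sample.int(K, 1L)
  for (t in seq_len(T - 1L))
    path[t + 1L] <- sample.int(K, 1L, prob = P[path[t], ])
  path
}

# MVN draws via a precomputed symmetric square root (PSD-safe, handles
# rank-deficient covariances from back-projection)
.mvnRoot <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' Generate a ground-truthed multi-subject HMM dataset
#'
#' Simulates, for every subject independently, a hidden state path under the
#' spec's transition matrix and an observation per time point from the
#' current state's multivariate normal model.
#'
#' @param spec a \linkS4class{GeneratorSpec}
#' @return list with \code{series} (list of T x D matrices, one per subject,
#'   columns named \code{R1..RD}) and \code{truth}
#'   (\linkS4class{GroundTruth} holding the hidden state paths)
#' @examples
#' sp <- generatorSpec(2, 100, 2, matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
#'                     rbind(c(3, 3), c(-3, -3)), list(diag(2), diag(2)), 7)
#' d <- generateHmmDataset(sp)
#' dim(d$series[[1]])
#' @export
generateHmmDataset <- function(spec) {
  validObject(spec)
  roots <- lapply(spec@stateCovariances, .mvnRoot)
  withSeed(spec@seed, {
    paths <- vector("list", spec@nSubjects)
    series <- vector("list", spec@nSubjects)
    for (n in seq_len(spec@nSubjects)) {
      path <- .samplePath(spec@transitionMatrix, spec@nTimepoints)
      Z <- matrix(stats::rnorm(spec@nTimepoints * spec@nRegions),
                  spec@nTimepoints, spec@nRegions)
      X <- spec@stateMeans[path, , drop = FALSE]
      for (k in unique(path)) {
        idx <- path == k
        X[idx, ] <- X[idx, , drop = FALSE] +
          Z[idx, , drop = FALSE] %*% t(roots[[k]])
      }
      colnames(X) <- paste0("R", seq_len(spec@nRegions))
      paths[[n]] <- path
      series[[n]] <- X
    }
    names(series) <- paste0("subject", seq_len(spec@nSubjects))
    list(series = series,
         truth = new("GroundTruth", statePaths = paths,
                     temporalLabels = integer(0), spatialLabels = list()))
  })
}

#' Generate a weighted planted-partition graph
#'
#' Blocks of nodes are connected internally with probability \code{pIn} and
#' across blocks with probability \code{pOut}; realised edges get weights
#' uniform(0.5, 1.5) * \code{weightScale} so weighted and unweighted block
#' structure coincide. Used to validate community detection against known
#' labels (e.g. by the adjusted Rand index).
#'
#' @param blockSizes vector of positive block sizes
#' @param pIn within-block edge probability
#' @param pOut between-block edge probability (must not exceed pIn)
#' @param weightScale positive multiplier for edge weights
#' @param directed if FALSE (default) the weight matrix is symmetric
#' @param seed integer seed
#' @return list with \code{W} (weight matrix, zero diagonal) and
#'   \code{labels} (integer block labels)
#' @export
generatePlantedPartitionGraph <- function(blockSizes, pIn, pOut,
                                          weightScale = 1, directed = FALSE,
                                          seed = 1L) {
  stopIfNot(all(blockSizes >= 1), "every block must be non-empty")
  stopIfNot(pOut >= 0 && pOut <= pIn && pIn <= 1,
            "need 0 <= pOut <= pIn <= 1")
  stopIfNot(weightScale > 0, "weightScale must be positive")
  n <- sum(blockSizes)
  labels <- rep(seq_along(blockSizes), blockSizes)
  withSeed(seed, {
    W <- matrix(0, n, n)
    if (directed) {
      idx <- which(row(W) != col(W))
    } else {
      idx <- which(upper.tri(W))
    }
    ij <- arrayInd(idx, dim(W))
    prob <- ifelse(labels[ij[, 1]] == labels[ij[, 2]], pIn, pOut)
    present <- stats::runif(length(idx)) < prob
    W[idx] <- present * stats::runif(length(idx), 0.5, 1.5) * weightScale
    if (!directed) W <- W + t(W)
    list(W = W, labels = labels)
  })
}

#' Plant a coherent community into a state's observation model
#'
#' Builds a D-region state mean/covariance pair in which the member regions
#' of \code{community} share mean \code{meanLevel} and pairwise correlation
#' exactly \code{withinCorr} (unit variances), so the community's functional
#' homogeneity is analytically predictable from the block alone. All other
#' correlations are weak background noise centred on
#' \code{backgroundCorr}, which keeps the resulting state graph irreducible
#' (every region reachable by a random walk) without touching the planted
#' block. The background part is shrunk automatically if needed to keep the
#' covariance positive semi-definite.
#'
#' @param nRegions number of regions D
#' @param community integer indices of the coherent regions (at least 2)
#' @param meanLevel shared mean activity of the community regions
#' @param withinCorr pairwise correlation within the community, in (0, 1)
#' @param seed integer seed for the background noise
#' @param backgroundCorr baseline correlation outside the planted block
#' @param noise half-width of the uniform jitter around backgroundCorr
#' @return list with \code{mu} (length D), \code{sigma} (D x D PSD) and
#'   \code{community}
#' @export
plantCoherentState <- function(nRegions, community, meanLevel = 1,
                               withinCorr = 0.8, seed = 1L,
                               backgroundCorr = 0.3, noise = 0.05) {
  community <- as.integer(community)
  stopIfNot(length(community) >= 2, "community must contain at least 2 regions")
  stopIfNot(all(community >= 1 & community <= nRegions),
            "community indices out of range")
  stopIfNot(withinCorr > 0 && withinCorr < 1,
            "withinCorr must lie in (0, 1) to keep sigma positive definite")
  mu <- numeric(nRegions)
  mu[community] <- meanLevel
  block <- diag(nRegions)
  block[community, community] <- withinCorr
  diag(block) <- 1
  # symmetric background on every pair not inside the planted block
  bg <- withSeed(seed, {
    B <- matrix(0, nRegions, nRegions)
    up <- which(upper.tri(B))
    B[up] <- backgroundCorr + stats::runif(length(up), -noise, noise)
    B <- B + t(B)
    B[community, community] <- 0
    B
  })
  sigma <- block + bg
  shrink <- 0L
  while (!isPSD(sigma, tol = 1e-10) && shrink < 30L) {
    bg <- bg / 2
    sigma <- block + bg
    shrink <- shrink + 1L
  }
  stopIfNot(isPSD(sigma, tol = 1e-10),
            "planted covariance is not positive semi-definite")
  list(mu = mu, sigma = sigma, community = community)
}

#' Write subject series as delimited text, ground truth as JSON
#'
#' One tab-separated file per subject (T rows x D columns, header = region
#' names) plus \code{ground_truth.json} holding the state paths.
#'
#' @param dataset result of \code{\link{generateHmmDataset}}
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
writeSubjectSeries <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(dataset$series)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(dataset$series[[nm]], f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(statePaths = dataset$truth@statePaths), gt)
  invisible(c(paths, gt))
}

#' Read subject series written by \code{\link{writeSubjectSeries}}
#'
#' @param dir directory containing one \code{.tsv} file per subject
#' @return named list of T x D numeric matrices
#' @export
readSubjectSeries <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  stopIfNot(length(files) > 0, "no .tsv subject files found in %s", dir)
  out <- lapply(files, function(f)
    as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                check.names = FALSE)))
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
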