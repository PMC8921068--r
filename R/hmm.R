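#' @useDynLib hmgm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# k-means based initialisation of state parameters for one restart
.initParams <- function(pooled, k, ridge) {
  d <- ncol(pooled)
  if (k == 1L) {
    mu0 <- matrix(colMeans(pooled), 1, d)
    s <- stats::cov(pooled) * (nrow(pooled) - 1) / nrow(pooled)
  } else {
    km <- suppressWarnings(
      stats::kmeans(pooled, centers = k, nstart = 3, iter.max = 50))
    mu0 <- km$centers
    s <- stats::cov(pooled)
  }
  s <- (s + t(s)) / 2
  diag(s) <- diag(s) + ridge * sum(diag(s)) / d
  sigma0 <- array(s, dim = c(d, d, k))
  # sticky transition prior with a little seeded noise to break symmetry
  P0 <- matrix(0.1 / max(1, k - 1), k, k)
  diag(P0) <- if (k > 1) 0.9 else 1
  P0 <- P0 * matrix(stats::runif(k * k, 0.95, 1.05), k, k)
  P0 <- P0 / rowSums(P0)
  list(P0 = P0, pi0 = rep(1 / k, k), mu0 = mu0, sigma0 = sigma0)
}

.listFromCube <- function(a) lapply(seq_len(dim(a)[3]), function(k) a[, , k])

# assemble an HMGModel from a converged EM fit + eigenmatrix
.buildModel <- function(fit, A, order = NULL) {
  k <- nrow(fit$P)
  ord <- if (is.null(order)) seq_len(k) else order
  P <- fit$P[ord, ord, drop = FALSE]
  P <- P / rowSums(P)
  muStar <- fit$mu[ord, , drop = FALSE]
  sigmaStar <- .listFromCube(fit$sigma)[ord]
  bp <- lapply(seq_len(k), function(s)
    backproject(muStar[s, ], sigmaStar[[s]], A))
  new("HMGModel", K = as.integer(k), P = P,
      pi0 = as.numeric(fit$pi0[ord] / sum(fit$pi0)),
      muStar = muStar, sigmaStar = sigmaStar, A = A,
      mu = do.call(rbind, lapply(bp, `[[`, "mu")),
      sigma = lapply(bp, `[[`, "sigma"),
      logLik = fit$loglik, logLikTrace = as.numeric(fit$loglikTrace))
}

#' Fit a multi-trial Gaussian-observation HMM
#'
#' Baum-Welch expectation-maximisation on the concatenated reduced series,
#' treating subjects as independent trials that share one transition matrix
#' and one set of state observation models (the forward-backward recursion
#' restarts at every trial boundary). Several restarts from k-means
#' initialisations are run and the fit with the highest training
#' log-likelihood is returned. Covariances carry a relative ridge on the
#' diagonal for numerical positive definiteness. States are reported in
#' decreasing order of pooled occupancy so output ordering is stable.
#'
#' @param trials list of T x d reduced series (one per subject)
#' @param k number of hidden states
#' @param seed integer seed (controls initialisations; fit is deterministic
#'   given the seed)
#' @param nRestarts number of EM restarts (default 5)
#' @param A optional \linkS4class{Eigenmatrix} used for back-projection;
#'   defaults to the identity (regions = reduced dimensions)
#' @param maxIter maximum EM iterations per restart
#' @param tol relative log-likelihood convergence tolerance
#' @param ridge relative diagonal ridge for covariances (epsilon * trace/d)
#' @return an \linkS4class{HMGModel}
#' @export
fitHmm <- function(trials, k, seed = 1L, nRestarts = 5L, A = NULL,
                   maxIter = 200L, tol = 1e-7, ridge = 1e-6) {
  trials <- lapply(trials, as.matrix)
  k <- as.integer(k)
  stopIfNot(k >= 1, "k must be at least 1")
  stopIfNot(all(vapply(trials, nrow, 1L) >= k),
            "every trial needs at least k time points")
  d <- ncol(trials[[1]])
  stopIfNot(all(vapply(trials, ncol, 1L) == d),
            "all trials must share the reduced dimension")
  if (is.null(A))
    A <- new("Eigenmatrix", A = diag(d), explainedVariance = 1,
             d = as.integer(d))
  pooled <- do.call(rbind, trials)

  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      init <- .initParams(pooled, k, ridge)
      fit <- .cppBaumWelch(trials, init$P0, init$pi0, init$mu0, init$sigma0,
                           as.integer(maxIter), tol, ridge)
      if (isTRUE(fit$degenerate))
        warning("a state became empty during fitting; parameters were kept ",
                "at their last regularized values")
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
      if (k == 1L) break # closed form, restarts identical
    }
  })
  pooledOcc <- colSums(do.call(rbind, lapply(best$gamma, colMeans)))
  .buildModel(best, A, order = order(pooledOcc, decreasing = TRUE))
}

#' Smoothed posterior state marginals for one trial
#'
#' Runs the scaled forward-backward recursion for the given trial under the
#' fitted model and returns Pr(S_t = s | model, trial) for every t and s.
#'
#' @param model an \linkS4class{HMGModel}
#' @param trial T x d reduced series
#' @return T x K matrix of posterior marginals; rows sum to 1. The held-out
#'   log-likelihood of the trial is attached as attribute \code{"logLik"}.
#' @export
posteriorMarginals <- function(model, trial) {
  trial <- as.matrix(trial)
  stopIfNot(ncol(trial) == ncol(model@muStar),
            "trial dimension %d does not match model dimension %d",
            ncol(trial), ncol(model@muStar))
  res <- .cppPosterior(trial, model@P, model@pi0, model@muStar,
                       array(unlist(model@sigmaStar),
                             dim = c(ncol(model@muStar), ncol(model@muStar),
                                     model@K)))
  g <- res$gamma
  attr(g, "logLik") <- res$loglik
  g
}

#' Fractional occupancy per subject
#'
#' The time-average of the posterior state marginals of each subject: row n
#' gives the fraction of the trial subject n is expected to spend in each
#' state. As the trial length grows this converges to the stationary
#' distribution of the transition matrix.
#'
#' @param marginals list of T x K posterior-marginal matrices, one per subject
#' @param subjectIds optional subject identifiers
#' @return an \linkS4class{OccupancyTable}
#' @export
fractionalOccupancy <- function(marginals, subjectIds = NULL) {
  if (is.matrix(marginals)) marginals <- list(marginals)
  K <- ncol(marginals[[1]])
  stopIfNot(all(vapply(marginals, ncol, 1L) == K),
            "all subjects must share the number of states")
  kappa <- do.call(rbind, lapply(marginals, colMeans))
  kappa <- kappa / rowSums(kappa)
  if (is.null(subjectIds)) subjectIds <- paste0("subject", seq_len(nrow(kappa)))
  new("OccupancyTable", kappa = kappa, subjectIds = as.character(subjectIds))
}

#' Stationary distribution of a row-stochastic transition matrix
#'
#' Solves pi P = pi by the leading left eigenvector. The chain must have a
#' single closed communicating class; otherwise no unique stationary
#' distribution exists and an error listing the closed classes is raised.
#'
#' @param P K x K row-stochastic matrix
#' @return probability vector pi with pi P = pi
#' @examples
#' stationaryDistribution(matrix(c(.9, .1, .2, .8), 2, byrow = TRUE))
#' @export
stationaryDistribution <- function(P) {
  P <- as.matrix(P)
  stopIfNot(.isRowStochastic(P, tol = 1e-8), "P must be row-stochastic")
  K <- nrow(P)
  if (K == 1L) return(1)
  g <- igraph::graph_from_adjacency_matrix((P > 1e-14) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  closed <- vapply(seq_len(comp$no), function(cc) {
    memb <- which(comp$membership == cc)
    sum(P[memb, -memb, drop = FALSE]) < 1e-14
  }, logical(1))
  if (sum(closed) != 1L) {
    classes <- vapply(which(closed), function(cc)
      paste0("{", paste(which(comp$membership == cc), collapse = ","), "}"),
      character(1))
    stop("chain is reducible: no unique stationary distribution; closed ",
         "communicating classes: ", paste(classes, collapse = " "),
         call. = FALSE)
  }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stopIfNot(max(abs(v %*% P - v)) < 1e-8, "eigen solve failed to converge")
  pmax(v, 0) / sum(pmax(v, 0))
}
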