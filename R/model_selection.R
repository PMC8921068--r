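#' Select the number of states by cross-validated occupancy entropy
#'
#' For each candidate k and each subject n, an HMM with k states is fitted
#' on all other subjects' trials; the held-out subject's fractional
#' occupancy kappa(., n) is then computed under that model and its entropy
#' -sum_s kappa log kappa accumulated over subjects (0 log 0 := 0). The
#' selected k maximises this pooled cross-validated entropy H(k); the
#' held-out log-likelihood is recorded per k for comparison. Per-fold fits
#' use fold-derived seeds so the whole curve is reproducible from one seed.
#'
#' @param trials list of at least 3 reduced T x d series
#' @param kRange candidate state counts (each below the shortest trial)
#' @param seed integer master seed
#' @param nRestarts EM restarts per fold fit
#' @param maxIter maximum EM iterations per fold fit
#' @return a \linkS4class{SelectionCurve}
#' @export
cvEntropy <- function(trials, kRange, seed = 1L, nRestarts = 2L,
                      maxIter = 100L) {
  trials <- lapply(trials, as.matrix)
  N <- length(trials)
  stopIfNot(N >= 3, "need at least 3 subjects for leave-one-out selection")
  kRange <- sort(as.integer(kRange))
  stopIfNot(all(kRange < min(vapply(trials, nrow, 1L))),
            "every k must be smaller than the shortest trial")
  H <- numeric(length(kRange))
  LL <- numeric(length(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    for (n in seq_len(N)) {
      foldSeed <- deriveSeed(seed, i * 1000L + n)
      fit <- tryCatch(
        fitHmm(trials[-n], k, seed = foldSeed, nRestarts = nRestarts,
               maxIter = maxIter),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("fold for subject %d at k = %d failed; skipped", n, k))
        next
      }
      g <- posteriorMarginals(fit, trials[[n]])
      kap <- colMeans(g)
      kap <- kap / sum(kap)
      nz <- kap > 0
      H[i] <- H[i] - sum(kap[nz] * log(kap[nz]))
      LL[i] <- LL[i] + attr(g, "logLik")
    }
  }
  sel <- kRange[which.max(H)] # which.max takes the first (smallest k) on ties
  new("SelectionCurve", kValues = kRange, cvEntropy = H, cvLogLik = LL,
      selectedK = as.integer(sel))
}

#' Prune rarely occupied states and renormalise the transition matrix
#'
#' A state "occurs" in a subject when its fractional occupancy exceeds one
#' expected time point (kappa > 1/T). States occurring in fewer than
#' \code{threshold * N} subjects are removed; the surviving transition
#' sub-matrix rows are renormalised to sum to one and state parameters are
#' re-indexed.
#'
#' @param model an \linkS4class{HMGModel}
#' @param kappa the \linkS4class{OccupancyTable} of the fitted subjects
#' @param threshold fraction of subjects a state must occur in, in (0, 1)
#' @param nTimepoints trial length T defining the occurrence cutoff 1/T
#' @return pruned \linkS4class{HMGModel} (unchanged if nothing is pruned)
#' @export
pruneStates <- function(model, kappa, threshold = 0.25, nTimepoints) {
  stopIfNot(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  km <- kappa@kappa
  stopIfNot(ncol(km) == model@K, "occupancy table does not match the model")
  occurs <- km > 1 / nTimepoints
  keep <- which(colSums(occurs) >= threshold * nrow(km))
  if (length(keep) == 0)
    stop("all states fall below the occurrence threshold", call. = FALSE)
  if (length(keep) == model@K) return(model)
  P <- model@P[keep, keep, drop = FALSE]
  P <- P / rowSums(P)
  new("HMGModel", K = length(keep), P = P,
      pi0 = model@pi0[keep] / sum(model@pi0[keep]),
      muStar = model@muStar[keep, , drop = FALSE],
      sigmaStar = model@sigmaStar[keep], A = model@A,
      mu = model@mu[keep, , drop = FALSE], sigma = model@sigma[keep],
      logLik = model@logLik, logLikTrace = model@logLikTrace)
}
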