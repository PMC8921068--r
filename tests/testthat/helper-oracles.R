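# Independent oracles and fixture builders shared across tests.

# all set partitions of n elements as restricted-growth label vectors
allPartitions <- function(n) {
  out <- list()
  rec <- function(labels, maxLab) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (l in seq_len(maxLab + 1L)) rec(c(labels, l), max(maxLab, l))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive-enumeration optimum of directed modularity (small n only)
bruteForceMaxQ <- function(W, gamma = 1) {
  max(vapply(allPartitions(nrow(W)),
             function(l) directedModularity(W, l, gamma), numeric(1)))
}

# brute-force double-sum functional homogeneity
fhDoubleSum <- function(mu, sigma, C) {
  acc <- 0
  for (x in C) for (y in C) acc <- acc + mu[x] * sigma[x, y] * mu[y]
  acc
}

# empirical transition frequencies of an integer path
empiricalTransitions <- function(path, K) {
  T <- length(path)
  tab <- table(factor(path[-T], levels = seq_len(K)),
               factor(path[-1], levels = seq_len(K)))
  tab <- matrix(as.numeric(tab), K, K)
  sweep(tab, 1, pmax(rowSums(tab), 1), "/")
}

# best-permutation agreement between decoded and true state paths
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(allPerms(v[-i]), function(p) c(v[i], p))))
}
matchAccuracy <- function(true, decoded, K) {
  best <- 0
  for (p in allPerms(seq_len(K)))
    best <- max(best, mean(p[decoded] == true))
  best
}

# best-permutation entrywise match of a fitted transition matrix
matchedTransitionError <- function(Ptrue, Pfit, truePath, decodedPath, K) {
  best <- Inf; bestPerm <- NULL
  for (p in allPerms(seq_len(K))) {
    acc <- mean(p[decodedPath] == truePath)
    if (is.null(bestPerm) || acc > best) { best <- acc; bestPerm <- p }
  }
  inv <- order(bestPerm) # fitted state p[k] corresponds to true state k
  max(abs(Ptrue - Pfit[inv, inv]))
}

# sticky well-separated multi-subject dataset with known states
wellSeparatedSpec <- function(N, T, K, d, sep = 5, stay = 0.85, seed = 1L) {
  P <- matrix((1 - stay) / (K - 1), K, K)
  diag(P) <- stay
  mu <- sep * diag(max(K, d))[seq_len(K), seq_len(d), drop = FALSE]
  generatorSpec(N, T, d, P, mu,
                replicate(K, diag(d), simplify = FALSE), seed = seed)
}

decodePath <- function(model, trial) {
  apply(posteriorMarginals(model, trial), 1, which.max)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
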