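# Shared multiplex fixtures.

# state 1 carries a planted coherent community; the remaining states are
# zero-mean with weakly correlated (walkable) backgrounds and low stationary
# mass on the planted state
plantedMultiplex <- function(D = 10, C = 1:4, meanLevel = 1, corr = 0.8,
                             K = 4) {
  st <- plantCoherentState(D, C, meanLevel = meanLevel, withinCorr = corr,
                           seed = 1)
  bg <- lapply(seq_len(K - 1), function(k)
    plantCoherentState(D, 5:8, meanLevel = 0, withinCorr = 0.4,
                       seed = 10 + k))
  mus <- c(list(st$mu), lapply(bg, `[[`, "mu"))
  sigmas <- c(list(st$sigma), lapply(bg, `[[`, "sigma"))
  pi <- c(0.1, rep(0.9 / (K - 1), K - 1))
  P <- matrix(pi, K, K, byrow = TRUE) # i.i.d. chain with stationary pi
  multiplexFromParams(mus, sigmas, P)
}

# continuous-FH fixture: every state has nonzero means and dense covariance
randomMultiplex <- function(D = 8, K = 3, seed = 5) {
  withr::with_seed(seed, {
    mus <- replicate(K, rnorm(D, 0, 0.7), simplify = FALSE)
    sigmas <- replicate(K, {
      G <- matrix(rnorm(D * D), D)
      crossprod(G) / D + 0.3 * diag(D)
    }, simplify = FALSE)
    P <- matrix(1 / K, K, K)
    multiplexFromParams(mus, sigmas, P)
  })
}
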