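test_that("functional homogeneity equals its explicit double sum", {
  expect_equal(functionalHomogeneity(c(0, 0, 1), diag(3), 1:2), 0)
  expect_equal(functionalHomogeneity(c(2, 9), diag(c(3, 1)), 1L), 12)
  expect_equal(functionalHomogeneity(c(1, 1), matrix(c(1, .5, .5, 1), 2),
                                     1:2), 3)
  set.seed(17)
  for (r in 1:50) {
    D <- sample(3:8, 1)
    mu <- rnorm(D)
    M <- matrix(rnorm(D * D), D)
    sigma <- crossprod(M) / D
    C <- sample(D, sample(1:D, 1))
    fh <- functionalHomogeneity(mu, sigma, C)
    expect_equal(fh, fhDoubleSum(mu, sigma, C), tolerance = 1e-10)
    expect_gte(fh, -1e-12) # PSD sigma keeps FH nonnegative
  }
  expect_error(functionalHomogeneity(c(1, 1), diag(2), integer(0)),
               "non-empty")
})

test_that("random-walk null sampling respects the graph structure", {
  D <- 6
  mux1 <- multiplexFromParams(list(rep(1, D)),
                              list(diag(D) * 0.5 + 0.5), matrix(1))
  # single irreducible state, size = D: every sampled community is V
  ns <- sampleNullCommunities(mux1, size = D, startPool = 1:D, L = 50,
                              seed = 2)
  for (C in ns$communities) expect_setequal(C, 1:D)

  # size = 1: no walk steps, community = start, uniform over the pool
  ns1 <- sampleNullCommunities(mux1, size = 1, startPool = c(2L, 5L),
                               L = 4000, seed = 3)
  starts <- vapply(ns1$communities, `[`, integer(1), 1)
  expect_setequal(unique(starts), c(2L, 5L))
  expect_lt(abs(mean(starts == 2L) - 0.5), 0.05)

  # near-disconnected blocks: walks almost never escape the start block
  S <- diag(10)
  S[1:5, 1:5] <- 0.6; S[6:10, 6:10] <- 0.6; diag(S) <- 1
  S[1:5, 6:10] <- S[6:10, 1:5] <- 1e-6
  mux2 <- multiplexFromParams(list(numeric(10)), list(S), matrix(1))
  ns2 <- sampleNullCommunities(mux2, size = 3, startPool = 1:5, L = 2000,
                               seed = 4)
  within <- vapply(ns2$communities, function(C) all(C <= 5), logical(1))
  expect_gte(mean(within), 0.99)

  expect_error(sampleNullCommunities(mux1, size = D + 1, startPool = 1:D),
               "1..D")
})

test_that("T-scores separate planted coherence from the null and self-calibrate", {
  mux <- plantedMultiplex()
  # planted coherent community scores near the top of the null
  sc <- tScore(mux, 1, 1:4, L = 2000, seed = 6)
  expect_gte(sc$t, 0.95)
  expect_equal(sc$sign, 1)
  expect_equal(sc$fh, 13.6, tolerance = 1e-10)

  # single-state whole-graph community: every null FH ties, strict > fails
  D <- 6
  mux1 <- multiplexFromParams(list(rep(0.5, D)),
                              list(diag(D) * 0.5 + 0.5), matrix(1))
  sc1 <- tScore(mux1, 1, 1:D, L = 300, seed = 3)
  expect_identical(sc1$t, 0)

  # communities drawn from the null sampler score ~ 0.5 on average when the
  # null FH distribution is effectively continuous
  rmux <- randomMultiplex()
  drawn <- sampleNullCommunities(rmux, size = 4, startPool = 1:8, L = 60,
                                 seed = 8)
  tVals <- vapply(1:60, function(l)
    tScore(rmux, drawn$states[l], drawn$communities[[l]], L = 400,
           seed = 100 + l)$t, numeric(1))
  expect_lt(abs(mean(tVals) - 0.5), 0.1)
})

test_that("T-scores are deterministic and invariant to region relabeling", {
  mux <- plantedMultiplex()
  a <- tScore(mux, 1, 1:4, L = 500, seed = 11)
  b <- tScore(mux, 1, 1:4, L = 500, seed = 11)
  expect_identical(a, b)

  # Monte-Carlo spread across seeds obeys the binomial bound at L = 1000
  ts <- vapply(1:12, function(s)
    tScore(mux, 1, c(1, 2, 5, 7), L = 1000, seed = s)$t, numeric(1))
  expect_lte(sd(ts), 1 / (2 * sqrt(1000)) * 2)

  # relabeling regions permutes nothing that matters for the score
  perm <- c(4:1, 10:5)
  inv <- order(perm)
  st <- plantCoherentState(10, 1:4)
  muP <- st$mu[perm]; sigmaP <- st$sigma[perm, perm]
  expect_equal(functionalHomogeneity(muP, sigmaP, inv[1:4]),
               functionalHomogeneity(st$mu, st$sigma, 1:4), tolerance = 1e-12)
})

test_that("community ranking orders by T-score with documented tie-breaks", {
  mux <- plantedMultiplex()
  part <- new("Partition",
              labels = c(rep(1L, 4), rep(2L, 3), rep(3L, 3)),
              gamma = 2, Q = 0)
  rk <- rankCommunities(mux, 1, part, L = 600, seed = 5)
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$community[1], 1) # planted community wins
  expect_true(all(rk$t >= 0 & rk$t <= 1))
  expect_identical(rankCommunities(mux, 1, part, L = 600, seed = 5), rk)

  # a single community is rank 1 regardless of its score
  part1 <- new("Partition", labels = rep(1L, 10), gamma = 2, Q = 0)
  rk1 <- rankCommunities(mux, 2, part1, L = 200, seed = 2)
  expect_equal(rk1$rank, 1L)
})
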