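test_that("directed modularity matches hand-enumerated values", {
  # any graph, all nodes in one community, gamma = 1: Q = 0 exactly
  set.seed(3)
  W <- matrix(runif(25), 5); diag(W) <- 0
  expect_equal(directedModularity(W, rep(1, 5)), 0, tolerance = 1e-14)

  # two disconnected directed 2-cycles: Q = 1 - 8/16 = 0.5
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- W2[2, 1] <- W2[3, 4] <- W2[4, 3] <- 1
  expect_equal(directedModularity(W2, c(1, 1, 2, 2)), 0.5)

  # singleton partition on a self-loop-free graph is negative
  expect_lt(directedModularity(W2, 1:4), 0)

  # on a symmetric graph the directed form equals classical modularity
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(runif(36) < 0.4, 6); A <- (A | t(A)) * 1; diag(A) <- 0
    labels <- sample(1:2, 6, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(directedModularity(A, labels),
                 igraph::modularity(g, labels), tolerance = 1e-12)
  }
  expect_error(directedModularity(matrix(0, 2, 2), c(1, 2)), "positive")
})

test_that("Louvain recovers exact and planted structure and matches brute force", {
  # two disconnected cliques are recovered exactly on every run
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  for (s in 1:5) {
    p <- louvain(W, seed = s, nRuns = 1)
    expect_equal(ari(communityLabels(p), rep(1:2, each = 4)), 1)
  }
  # single node: trivial partition
  expect_identical(communityLabels(louvain(matrix(1), seed = 1)), 1L)

  # exhaustive oracle on small random directed graphs
  for (s in 1:4) {
    set.seed(100 + s)
    n <- 6
    Wr <- matrix(runif(n * n) * (runif(n * n) < 0.5), n)
    diag(Wr) <- 0
    if (sum(Wr) == 0) next
    p <- louvain(Wr, seed = s, nRuns = 10)
    expect_gte(modularity(p), 0.95 * bruteForceMaxQ(Wr))
  }
})

test_that("permutation significance separates structure from noise", {
  g <- generatePlantedPartitionGraph(c(10, 10), 0.9, 0.05, seed = 5)
  part <- louvain(g$W, seed = 2, nRuns = 5)
  p <- modularitySignificance(g$W, part, nPerm = 2000, seed = 3)
  expect_lte(p, 1e-3)

  # complete uniform-weight graph: Q identical under every permutation
  Wc <- matrix(1, 6, 6); diag(Wc) <- 0
  partArb <- new("Partition", labels = rep(1:2, each = 3L), gamma = 1,
                 Q = directedModularity(Wc, rep(1:2, each = 3)))
  expect_equal(modularitySignificance(Wc, partArb, nPerm = 500, seed = 1), 1)

  # single community has nothing to test
  p1 <- new("Partition", labels = rep(1L, 6), gamma = 1, Q = 0)
  expect_equal(modularitySignificance(Wc, p1, nPerm = 500, seed = 1), 1)

  # null graphs: p behaves like a null (rarely small)
  hits <- vapply(1:10, function(s) {
    gn <- generatePlantedPartitionGraph(c(10, 10), 0.4, 0.4, seed = 300 + s)
    split <- new("Partition", labels = rep(1:2, each = 10L), gamma = 1,
                 Q = directedModularity(gn$W, rep(1:2, each = 10)))
    modularitySignificance(gn$W, split, nPerm = 500, seed = s) > 0.05
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("VI-based resolution selection prefers reproducible scales", {
  # graph with one obvious partition at every resolution: VI = 0 everywhere,
  # smallest gamma returned
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  sel <- selectResolutionVI(W, gammaGrid = c(0.5, 1, 1.5), nRuns = 6,
                            seed = 2)
  expect_true(all(sel$meanVI < 1e-12))
  expect_equal(sel$gamma, 0.5)

  # VI is a metric: zero on itself, symmetric, bounded by log(n)
  set.seed(8)
  for (r in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(variationOfInformation(a, a), 0)
    expect_equal(variationOfInformation(a, b), variationOfInformation(b, a))
    expect_lte(variationOfInformation(a, b), log(12) + 1e-12)
    expect_gte(variationOfInformation(a, b), 0)
  }

  # two-scale nested graph: interior resolution is the stable one most often
  nested <- function(seed) {
    set.seed(seed)
    W <- matrix(0, 16, 16)
    for (b in 0:3) { # 4 tight blocks of 4
      idx <- b * 4 + 1:4
      W[idx, idx] <- 1
    }
    W[1:8, 1:8][W[1:8, 1:8] == 0] <- 0.25   # blocks 1+2 weakly merged
    W[9:16, 9:16][W[9:16, 9:16] == 0] <- 0.25
    diag(W) <- 0
    W
  }
  interior <- vapply(1:10, function(s) {
    sel <- selectResolutionVI(nested(s), gammaGrid = c(0.1, 0.8, 5),
                              nRuns = 8, seed = s)
    which.min(sel$meanVI) == 2L || all(sel$meanVI < 1e-12)
  }, logical(1))
  expect_gte(sum(interior), 7)
})

test_that("community centrality z-scores standardize within-community strength", {
  # 5-node star community: the centre has the unique maximal z
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- 1; W[2:5, 1] <- 1
  part <- new("Partition", labels = rep(1L, 5), gamma = 1,
              Q = directedModularity(W, rep(1, 5)))
  z <- communityZscore(W, part)
  expect_equal(which.max(z), 1L)
  expect_true(all(z[1] > z[2:5]))
  # standardization identity within the community
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  # regular within-community connectivity: all z = 0, hub = lowest index
  ring <- matrix(0, 4, 4)
  ring[cbind(1:4, c(2, 3, 4, 1))] <- 1
  ring[cbind(c(2, 3, 4, 1), 1:4)] <- 1
  partR <- new("Partition", labels = rep(1L, 4), gamma = 1, Q = 0)
  zR <- communityZscore(ring, partR)
  expect_true(all(zR == 0))
  hubs <- selectHubs(zR, partR)
  expect_equal(unname(hubs$hubs), 1L)

  # hubs maximise z within each community
  part2 <- new("Partition", labels = c(1L, 1L, 1L, 2L, 2L), gamma = 1, Q = 0)
  z2 <- c(0.1, 2, -1, 0.5, 0.4)
  expect_equal(unname(selectHubs(z2, part2)$hubs), c(2L, 4L))
})

test_that("Ward clustering of occupancy respects planted subject blocks", {
  # two identical subjects merge first at height 0
  kap <- rbind(c(.6, .3, .1), c(.6, .3, .1), c(.1, .2, .7), c(.2, .35, .45))
  occ <- new("OccupancyTable", kappa = kap, subjectIds = paste0("s", 1:4))
  trees <- wardClusterOccupancy(occ)
  expect_equal(trees$subjects$merge[1, ], c(-1, -2))
  expect_lt(trees$subjects$height[1], 1e-10)
  # heights are non-decreasing along merges
  expect_true(all(diff(trees$subjects$height) >= -1e-12))
  expect_match(trees$newick[["subjects"]], "^\\(")

  # block occupancy: the 2-cut of the subject tree equals the blocks
  kapB <- rbind(c(.5, .45, .03, .02), c(.45, .5, .02, .03),
                c(.48, .47, .03, .02),
                c(.03, .02, .5, .45), c(.02, .03, .45, .5))
  occB <- new("OccupancyTable", kappa = kapB, subjectIds = paste0("s", 1:5))
  tB <- wardClusterOccupancy(occB)
  cut <- cutree(tB$subjects, 2)
  expect_equal(ari(cut, c(1, 1, 1, 2, 2)), 1)

  # zero-variance column is reported by name
  kapZ <- cbind(c(.5, .55, .45), rep(.25, 3), c(.25, .2, .3))
  occZ <- new("OccupancyTable", kappa = kapZ, subjectIds = paste0("s", 1:3))
  expect_error(wardClusterOccupancy(occZ), "state")
})
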