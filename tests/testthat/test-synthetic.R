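test_that("a single-state chain is degenerate and matches its observation model", {
  mu <- matrix(c(2, -1), 1, 2)
  sp <- generatorSpec(2, 2000, 2, matrix(1), mu, list(diag(2)), seed = 5)
  d <- generateHmmDataset(sp)
  for (p in d$truth@statePaths) expect_true(all(p == 1L))
  se <- 1 / sqrt(2000)
  for (s in d$series)
    expect_true(all(abs(colMeans(s) - mu[1, ]) < 3 * se))
})

test_that("empirical transition frequencies converge to the generating matrix", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  sp <- generatorSpec(1, 1e5, 1, P, matrix(0, 2, 1),
                      list(matrix(1), matrix(1)), seed = 42)
  d <- generateHmmDataset(sp)
  emp <- empiricalTransitions(d$truth@statePaths[[1]], 2)
  expect_lt(max(abs(emp - P)), 0.01)
})

test_that("block-modular dynamics keep most consecutive steps within a block", {
  # two 3-state blocks, within-block probability mass 0.95
  B <- matrix(0.95 / 3, 3, 3)
  P <- rbind(cbind(B, matrix(0.05 / 3, 3, 3)),
             cbind(matrix(0.05 / 3, 3, 3), B))
  sp <- generatorSpec(1, 20000, 1, P, matrix(0, 6, 1),
                      replicate(6, matrix(1), simplify = FALSE), seed = 9)
  path <- generateHmmDataset(sp)$truth@statePaths[[1]]
  block <- (path - 1L) %/% 3L
  expect_gte(mean(block[-length(block)] == block[-1]), 0.80)
})

test_that("generation is bit-identical under the same seed and validates inputs", {
  P <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  sp <- generatorSpec(2, 50, 2, P, matrix(0, 2, 2),
                      list(diag(2), diag(2)), seed = 77)
  expect_identical(generateHmmDataset(sp), generateHmmDataset(sp))
  expect_error(generatorSpec(2, 50, 2, matrix(c(0.6, 0.5, 0.5, 0.5), 2),
                             matrix(0, 2, 2), list(diag(2), diag(2))),
               "row-stochastic")
  badSigma <- matrix(c(1, 2, 2, 1), 2) # eigenvalues 3, -1
  expect_error(generatorSpec(2, 50, 2, P, matrix(0, 2, 2),
                             list(badSigma, diag(2))),
               "positive semi-definite")
})

test_that("planted-partition graphs honour their block structure", {
  g <- generatePlantedPartitionGraph(c(5, 5), pIn = 0.9, pOut = 0,
                                     seed = 3)
  ig <- igraph::graph_from_adjacency_matrix(g$W > 0, mode = "max")
  expect_equal(igraph::components(ig)$no, 2)
  expect_true(all(g$W >= 0))
  expect_error(generatePlantedPartitionGraph(c(0, 5), 0.5, 0.1),
               "non-empty")
  expect_error(generatePlantedPartitionGraph(c(5, 5), 0.2, 0.5),
               "pOut <= pIn")
})

test_that("Louvain finds no structure in unstructured graphs and recovers planted blocks", {
  skip_if_not_installed("mclust")
  # p_in = p_out: ARI against the nominal labels is indistinguishable from 0
  ariNull <- vapply(1:20, function(s) {
    g <- generatePlantedPartitionGraph(c(10, 10), 0.5, 0.5, seed = s)
    ari(communityLabels(louvain(g$W, seed = s, nRuns = 5)), g$labels)
  }, numeric(1))
  expect_lt(abs(mean(ariNull)), 0.2)
  # strong planted blocks are recovered nearly always
  hits <- vapply(1:20, function(s) {
    g <- generatePlantedPartitionGraph(c(10, 10), 0.9, 0.05, seed = 100 + s)
    ari(communityLabels(louvain(g$W, seed = s, nRuns = 5)), g$labels) >= 0.9
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("planted coherent states have the predicted functional homogeneity", {
  # zero mean: FH vanishes
  st0 <- plantCoherentState(10, 1:4, meanLevel = 0)
  expect_equal(functionalHomogeneity(st0$mu, st0$sigma, 1:4), 0)
  # |C| = 4, unit variances, corr 0.8: FH = 4 + 12 * 0.8
  st <- plantCoherentState(10, 1:4, meanLevel = 1, withinCorr = 0.8)
  expect_equal(functionalHomogeneity(st$mu, st$sigma, st$community), 13.6)
  expect_true(all(eigen(st$sigma, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  # planted FH beats a same-size zero-mean background community almost surely
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    bg <- sample(5:10, 4)
    muBg <- st$mu
    muBg[bg] <- rnorm(4, 0, 0.3) # background noise means
    fhPlanted <- functionalHomogeneity(st$mu, st$sigma, st$community)
    fhBg <- functionalHomogeneity(muBg, st$sigma, bg)
    fhPlanted > fhBg
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("subject series round-trip through delimited text", {
  sp <- generatorSpec(2, 30, 3, matrix(1), matrix(1:3, 1), list(diag(3)),
                      seed = 8)
  d <- generateHmmDataset(sp)
  dir <- withr::local_tempdir()
  writeSubjectSeries(d, dir)
  back <- readSubjectSeries(dir)
  expect_equal(names(back), names(d$series))
  expect_equal(back$subject1, d$series$subject1, ignore_attr = TRUE,
               tolerance = 1e-12)
})
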