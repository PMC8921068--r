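test_that("standardization centres and scales every region and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 9))
  s <- standardizeSeries(x)
  expect_true(all(abs(colMeans(s)) < 1e-10))
  expect_true(all(abs(apply(s, 2, sd) - 1) < 1e-10))
  expect_equal(standardizeSeries(s), s, tolerance = 1e-10)
  expect_error(standardizeSeries(cbind(ok = 1:3, flat = rep(2, 3))), "flat")
})

test_that("parallel analysis finds planted factors and rejects pure noise", {
  planted <- function(seed) {
    set.seed(seed)
    n <- 300; D <- 20
    F <- matrix(rnorm(n * 3, sd = 5), n, 3)      # 3 strong orthogonal factors
    L <- matrix(0, 3, D)
    L[1, 1:7] <- 1; L[2, 8:14] <- 1; L[3, 15:20] <- 1
    F %*% L + matrix(rnorm(n * D), n, D)
  }
  hits3 <- vapply(1:20, function(s)
    parallelAnalysis(planted(s), nNull = 60, seed = s)$d == 3L, logical(1))
  expect_gte(sum(hits3), 18)

  noiseHits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    parallelAnalysis(matrix(rnorm(300 * 20), 300, 20), nNull = 60,
                     percentile = 0.95, seed = s)$d <= 2L
  }, logical(1))
  expect_gte(sum(noiseHits), 18)
})

test_that("adding a stronger factor never shrinks the retained dimension", {
  base <- function(seed, extra) {
    set.seed(seed)
    n <- 250; D <- 12
    F <- matrix(rnorm(n * 2, sd = 4), n, 2)
    L <- rbind(c(rep(1, 6), rep(0, 6)), c(rep(0, 6), rep(1, 6)))
    X <- F %*% L + matrix(rnorm(n * D), n, D)
    if (extra) {
      f3 <- rnorm(n, sd = 8)
      X[, c(1, 7, 12)] <- X[, c(1, 7, 12)] + f3
    }
    X
  }
  for (s in 1:5) {
    d0 <- parallelAnalysis(base(s, FALSE), nNull = 60, seed = s)$d
    d1 <- parallelAnalysis(base(s, TRUE), nNull = 60, seed = s)$d
    expect_gte(d1, d0)
  }
})

test_that("reduction projects correctly and round-trips with a square eigenmatrix", {
  set.seed(4)
  X <- standardizeSeries(matrix(rnorm(200 * 5), 200, 5) %*%
                           matrix(rnorm(25), 5, 5))
  idA <- new("Eigenmatrix", A = diag(5), explainedVariance = 1, d = 5L)
  expect_equal(reduceSeries(X, idA), X, ignore_attr = TRUE)
  e1 <- new("Eigenmatrix", A = diag(5)[, 1, drop = FALSE],
            explainedVariance = 0.2, d = 1L)
  expect_equal(drop(reduceSeries(X, e1)), X[, 1], ignore_attr = TRUE)

  Afull <- computeEigenmatrix(X, 5)
  red <- reduceSeries(X, Afull)
  expect_lt(max(abs(red %*% t(Afull@A) - X)), 1e-8)
  # projected variance is non-increasing in component index
  v <- apply(reduceSeries(X, computeEigenmatrix(X, 3)), 2, var)
  expect_true(all(diff(v) <= 1e-10))
  expect_error(reduceSeries(X[, 1:3], Afull), "regions")
})

test_that("back-projection reproduces the hand-computed example and spectra", {
  A <- new("Eigenmatrix", A = matrix(c(1, 0), 2, 1),
           explainedVariance = 1, d = 1L)
  bp <- backproject(3, matrix(2), A)
  expect_equal(bp$mu, c(3, 0))
  expect_equal(bp$sigma, matrix(c(2, 0, 0, 0), 2))

  bp0 <- backproject(0, matrix(0), A)
  expect_true(all(bp0$sigma == 0))

  # eigenvalues of the back-projection equal those of sigma* padded with zeros
  set.seed(11)
  D <- 6; d <- 3
  Q <- qr.Q(qr(matrix(rnorm(D * D), D)))[, 1:d]
  for (j in 1:d) if (Q[which.max(abs(Q[, j])), j] < 0) Q[, j] <- -Q[, j]
  Aq <- new("Eigenmatrix", A = Q, explainedVariance = 0.5, d = 3L)
  for (r in 1:5) {
    M <- matrix(rnorm(9), 3)
    sStar <- crossprod(M)
    bpR <- backproject(rnorm(3), sStar, Aq)
    evFull <- sort(eigen(bpR$sigma, symmetric = TRUE, only.values = TRUE)$values)
    evStar <- sort(c(eigen(sStar, symmetric = TRUE, only.values = TRUE)$values,
                     rep(0, D - d)))
    expect_equal(evFull, evStar, tolerance = 1e-8)
    expect_true(min(evFull) > -1e-10) # always symmetric PSD
    expect_lt(max(abs(bpR$sigma - t(bpR$sigma))), 1e-12)
  }
  expect_error(backproject(c(1, 1), matrix(c(1, 2, 2, 1), 2), Aq), "definite")
})
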