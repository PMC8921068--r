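#' Standardize a region time-series matrix
#'
#' Subtracts the temporal mean of every region (column) and divides by its
#' standard deviation, so each region series has mean 0 and SD 1.
#'
#' @param series raw T x D numeric matrix (columns = regions)
#' @return standardized matrix of the same shape, column names preserved
#' @examples
#' s <- standardizeSeries(cbind(a = 1:3, b = c(2, 4, 9)))
#' colMeans(s)
#' @export
standardizeSeries <- function(series) {
  series <- as.matrix(series)
  stopIfNot(nrow(series) >= 2, "need at least 2 time points")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant region series cannot be standardized: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- scale(series)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Horn's parallel analysis for the number of principal components
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' eigenvalue distribution of correlation matrices of i.i.d. standard-normal
#' data of identical shape. The retained dimension d is the number of leading
#' observed eigenvalues exceeding the chosen percentile (default 95th) of
#' the matched null eigenvalues; the comparison stops at the first failure
#' and at least one component is always retained.
#'
#' @param pooled stacked (N*T) x D matrix of standardized series
#' @param nNull number of null datasets (>= 50)
#' @param percentile null percentile for the retention threshold, in (0, 1);
#'   0.5 gives the classical mean-eigenvalue criterion
#' @param seed integer seed for the null simulation
#' @return list with \code{d}, observed \code{eigenvalues}, and the null
#'   \code{threshold} per component
#' @export
parallelAnalysis <- function(pooled, nNull = 100L, percentile = 0.95,
                             seed = 1L) {
  pooled <- as.matrix(pooled)
  stopIfNot(nNull >= 50, "need at least 50 null datasets")
  n <- nrow(pooled); D <- ncol(pooled)
  if (D > n)
    warning("more regions than pooled observations: eigen spectrum is rank-deficient")
  obs <- eigen(stats::cor(pooled), symmetric = TRUE, only.values = TRUE)$values
  nullEig <- withSeed(seed, {
    vapply(seq_len(nNull), function(i) {
      Z <- matrix(stats::rnorm(n * D), n, D)
      eigen(stats::cor(Z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(D))
  })
  thr <- apply(nullEig, 1, stats::quantile, probs = percentile, names = FALSE)
  keep <- obs > thr
  d <- if (keep[1]) which.min(c(keep, FALSE)) - 1L else 1L
  d <- max(1L, as.integer(d))
  list(d = d, eigenvalues = obs, threshold = thr)
}

#' Compute the eigenmatrix of the leading principal components
#'
#' Eigendecomposition of the pooled correlation matrix; the first d
#' eigenvectors form the D x d projection A. The sign of every eigenvector
#' is fixed so its largest-magnitude entry is positive.
#'
#' @param pooled stacked (N*T) x D standardized matrix
#' @param d retained dimension (e.g. from \code{\link{parallelAnalysis}})
#' @return an \linkS4class{Eigenmatrix}
#' @export
computeEigenmatrix <- function(pooled, d) {
  pooled <- as.matrix(pooled)
  D <- ncol(pooled)
  d <- as.integer(d)
  stopIfNot(d >= 1 && d <= D, "need 1 <= d <= D")
  e <- eigen(stats::cor(pooled), symmetric = TRUE)
  A <- e$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  rownames(A) <- colnames(pooled)
  new("Eigenmatrix", A = A,
      explainedVariance = sum(e$values[seq_len(d)]) / sum(e$values),
      d = d)
}

#' Project a standardized series onto the retained components
#'
#' @param series standardized T x D matrix
#' @param A an \linkS4class{Eigenmatrix}
#' @return T x d reduced series
#' @export
reduceSeries <- function(series, A) {
  series <- as.matrix(series)
  stopIfNot(ncol(series) == nrow(A@A),
            "series has %d regions but eigenmatrix expects %d",
            ncol(series), nrow(A@A))
  series %*% A@A
}

#' Back-project reduced-space state parameters to region space
#'
#' Maps a state's reduced mean and covariance into the D-dimensional region
#' space through the eigenmatrix: Sigma = A Sigma* A^T and mu = A mu*. The
#' result is symmetric PSD with rank at most d.
#'
#' @param muStar length-d reduced mean
#' @param sigmaStar d x d PSD reduced covariance
#' @param A an \linkS4class{Eigenmatrix}
#' @return list with \code{mu} (length D) and \code{sigma} (D x D)
#' @examples
#' A <- new("Eigenmatrix", A = matrix(c(1, 0), 2, 1),
#'          explainedVariance = 1, d = 1L)
#' backproject(3, matrix(2), A)
#' @export
backproject <- function(muStar, sigmaStar, A) {
  sigmaStar <- as.matrix(sigmaStar)
  stopIfNot(isPSD(sigmaStar, tol = 1e-8),
            "reduced covariance must be symmetric positive semi-definite")
  stopIfNot(length(muStar) == A@d && nrow(sigmaStar) == A@d,
            "reduced parameters must have dimension d")
  M <- A@A
  sigma <- M %*% sigmaStar %*% t(M)
  sigma <- (sigma + t(sigma)) / 2
  list(mu = drop(M %*% muStar), sigma = sigma)
}
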