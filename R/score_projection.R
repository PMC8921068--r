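#' One-step-ahead projection of per-state term scores
#'
#' Propagates a states x terms score table one step through the transition
#' matrix: the projected score of term i in state s is the expectation of
#' the term score over the next state, sum_s' P[s, s'] theta[s', i]. The
#' map is convex, so projected scores stay within the range of the input.
#'
#' @param P K x K row-stochastic transition matrix
#' @param theta K x M matrix of term scores in [-1, 1] (columns = terms)
#' @return projected K x M matrix, dimnames preserved
#' @examples
#' P <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
#' oneStepProjectedScore(P, cbind(term = c(1, -1)))
#' @export
oneStepProjectedScore <- function(P, theta) {
  P <- as.matrix(P); theta <- as.matrix(theta)
  stopIfNot(.isRowStochastic(P, tol = 1e-8), "P must be row-stochastic")
  stopIfNot(nrow(theta) == nrow(P),
            "theta must have one row per state of P")
  stopIfNot(all(theta >= -1 - 1e-12 & theta <= 1 + 1e-12),
            "term scores must lie in [-1, 1]")
  out <- P %*% theta
  dimnames(out) <- dimnames(theta)
  out
}

#' Correlation between current and one-step-projected term scores
#'
#' Pearson-correlates, across states, every current-term column with every
#' projected-term column, tests each correlation with a two-sided t-test
#' (df = K - 2) and adjusts all M^2 p-values with the Benjamini-Hochberg
#' false-discovery-rate procedure. Pairs involving a zero-variance column
#' are reported as missing. Significance tiers: ** (p < 0.01), * (p < 0.05),
#' (*) (p < 0.1) on the adjusted p-values.
#'
#' @param theta K x M current score table (K >= 3)
#' @param projected K x M projected score table (e.g. from
#'   \code{\link{oneStepProjectedScore}})
#' @param method FDR adjustment method (default "BH")
#' @return list with \code{correlation} (M x M, rows = projected terms,
#'   columns = current terms), \code{p} (raw), \code{pAdjusted}, and
#'   \code{signif} (character tier matrix)
#' @export
termDynamicsCorrelation <- function(theta, projected, method = "BH") {
  theta <- as.matrix(theta); projected <- as.matrix(projected)
  K <- nrow(theta)
  stopIfNot(K >= 3, "need at least 3 states for a correlation t-test")
  stopIfNot(all(dim(theta) == dim(projected)),
            "theta and projected must have matching shape")
  M <- ncol(theta)
  terms <- colnames(theta)
  if (is.null(terms)) terms <- paste0("term", seq_len(M))
  r <- matrix(NA_real_, M, M,
              dimnames = list(projected = terms, current = terms))
  p <- r
  sdCur <- apply(theta, 2, stats::sd)
  sdPro <- apply(projected, 2, stats::sd)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (sdPro[i] == 0 || sdCur[j] == 0) next # undefined, stays NA
      rv <- stats::cor(projected[, i], theta[, j])
      r[i, j] <- rv
      if (abs(rv) >= 1) {
        p[i, j] <- 0
      } else {
        tv <- rv * sqrt((K - 2) / (1 - rv^2))
        p[i, j] <- 2 * stats::pt(-abs(tv), df = K - 2)
      }
    }
  }
  pAdj <- matrix(stats::p.adjust(as.vector(p), method = method), M, M,
                 dimnames = dimnames(p))
  tier <- ifelse(is.na(pAdj), "",
          ifelse(pAdj < 0.01, "**",
          ifelse(pAdj < 0.05, "*",
          ifelse(pAdj < 0.1, "(*)", ""))))
  list(correlation = r, p = p, pAdjusted = pAdj, signif = tier)
}

#' Read a term-score table from delimited text
#'
#' Expects a header of term names and state-id row labels in the first
#' column; values must lie in [-1, 1].
#'
#' @param file path to a tab-separated table
#' @return K x M numeric matrix with dimnames
#' @export
readTermScores <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  theta <- as.matrix(tab)
  stopIfNot(all(theta >= -1 & theta <= 1), "term scores must lie in [-1, 1]")
  theta
}

#' Write a term-score (or projected-score) table as delimited text
#'
#' @param theta K x M matrix
#' @param file output path
#' @return invisibly, the path
#' @export
writeTermScores <- function(theta, file) {
  utils::write.table(cbind(state = rownames(theta), as.data.frame(theta)),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
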