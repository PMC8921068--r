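#' Functional homogeneity of a community
#'
#' The quadratic form mu_C' Sigma_C mu_C of the state mean restricted to the
#' community through the community sub-covariance (rows and columns outside
#' C removed). High values mean the community's mean activity aligns with
#' the directions of strongest within-community covariance; the value is
#' nonnegative whenever Sigma is PSD.
#'
#' @param mu length-D state mean
#' @param sigma D x D state covariance
#' @param C community as integer region indices (non-empty)
#' @return functional homogeneity value
#' @examples
#' functionalHomogeneity(c(1, 1), matrix(c(1, .5, .5, 1), 2), c(1, 2))
#' @export
functionalHomogeneity <- function(mu, sigma, C) {
  C <- as.integer(C)
  stopIfNot(length(C) >= 1, "community must be non-empty")
  stopIfNot(all(C >= 1 & C <= length(mu)), "community indices out of range")
  m <- mu[C]
  drop(t(m) %*% sigma[C, C, drop = FALSE] %*% m)
}

# one random walk on W collecting `size` distinct nodes starting at x
.walkCommunity <- function(W, x, size, maxSteps) {
  visited <- integer(size)
  visited[1] <- x
  nSeen <- 1L
  cur <- x
  steps <- 0L
  while (nSeen < size) {
    if (steps >= maxSteps) return(NULL)
    cur <- sample.int(ncol(W), 1L, prob = W[cur, ])
    steps <- steps + 1L
    if (!(cur %in% visited[seq_len(nSeen)])) {
      nSeen <- nSeen + 1L
      visited[nSeen] <- cur
    }
  }
  visited
}

#' Sample null (state, community) pairs by random walks on the multiplex
#'
#' Each draw samples a state from the stationary distribution of the
#' interlayer transition matrix, picks a start region uniformly from
#' \code{startPool}, and performs a simple random walk on that state's
#' Markov information graph (following the rows of W) until \code{size}
#' distinct regions have been visited (start included). Walks that fail to
#' gather enough distinct regions within \code{maxSteps} steps are discarded
#' and redrawn.
#'
#' @param model a \linkS4class{MultiplexModel}
#' @param size community size |C| to sample (at most D)
#' @param startPool integer region indices the start is drawn from
#' @param L number of null pairs
#' @param maxSteps walk-length guard per draw (default 100 * size)
#' @param seed integer seed
#' @return list with \code{states} (length L) and \code{communities}
#'   (list of L integer vectors of length \code{size})
#' @export
sampleNullCommunities <- function(model, size, startPool, L = 10000L,
                                  maxSteps = NULL, seed = 1L) {
  size <- as.integer(size)
  D <- length(model@stateGraphs[[1]]@nodes)
  stopIfNot(size >= 1 && size <= D, "size must lie in 1..D")
  stopIfNot(length(startPool) >= 1, "startPool must be non-empty")
  if (is.null(maxSteps)) maxSteps <- 100L * size
  Ws <- lapply(model@stateGraphs, function(g) g@W)
  withSeed(seed, {
    states <- integer(L)
    comms <- vector("list", L)
    for (l in seq_len(L)) {
      comm <- NULL
      restarts <- 0L
      while (is.null(comm)) {
        if (restarts > 100L)
          stop("random walk failed to gather ", size, " distinct regions ",
               "after 100 restarts; the state graph has near-absorbing ",
               "structure", call. = FALSE)
        s <- sample.int(length(Ws), 1L, prob = model@pi)
        x <- if (length(startPool) == 1L) as.integer(startPool)
             else startPool[sample.int(length(startPool), 1L)]
        comm <- .walkCommunity(Ws[[s]], x, size, maxSteps)
        restarts <- restarts + 1L
      }
      states[l] <- s
      comms[[l]] <- comm
    }
    list(states = states, communities = comms)
  })
}

#' Random-walk null T-score of a community
#'
#' Scores the functional cohesion of community C in state s against L null
#' (state, community) pairs drawn by \code{\link{sampleNullCommunities}}
#' with start pool C: T is the fraction of null pairs whose functional
#' homogeneity (computed under the null pair's own state parameters) is
#' strictly exceeded by FH(s, C). Ties count as not exceeded. The sign of
#' the community's summed mean activity is returned alongside; T-scores are
#' not comparable across states.
#'
#' @param model a \linkS4class{MultiplexModel} built by
#'   \code{\link{multiplexModel}} (carries the state covariances)
#' @param s state index of the candidate community
#' @param C integer region indices of the community
#' @param L number of null draws (values below 100 trigger a warning)
#' @param seed integer seed
#' @return list with \code{t} in [0, 1], \code{fh}, and \code{sign}
#' @export
tScore <- function(model, s, C, L = 10000L, seed = 1L) {
  C <- as.integer(C)
  stopIfNot(length(C) >= 1, "community must be non-empty")
  if (L < 100) warning("T-score with fewer than 100 null draws is unstable")
  sigmas <- model@sigma
  fh <- functionalHomogeneity(model@stateGraphs[[s]]@a, sigmas[[s]], C)
  nullSample <- sampleNullCommunities(model, length(C), startPool = C,
                                      L = L, seed = seed)
  fhNull <- vapply(seq_len(L), function(l) {
    sl <- nullSample$states[l]
    functionalHomogeneity(model@stateGraphs[[sl]]@a, sigmas[[sl]],
                          nullSample$communities[[l]])
  }, numeric(1))
  muSum <- sum(model@stateGraphs[[s]]@a[C])
  list(t = mean(fh > fhNull), fh = fh, sign = sign(muSum))
}

#' Rank the spatial communities of one state by T-score
#'
#' Scores every community of the given partition of the state's regions
#' with \code{\link{tScore}} and ranks them by decreasing T, breaking ties
#' by larger functional homogeneity and then lower community id.
#'
#' @param model a \linkS4class{MultiplexModel}
#' @param s state index
#' @param partition a \linkS4class{Partition} over the state's regions
#' @param L null draws per community
#' @param seed integer seed
#' @return data.frame with columns state, community, members, fh, t, sign,
#'   rank (ordered by rank)
#' @export
rankCommunities <- function(model, s, partition, L = 10000L, seed = 1L) {
  labels <- partition@labels
  comms <- sort(unique(labels))
  rows <- lapply(seq_along(comms), function(i) {
    C <- which(labels == comms[i])
    sc <- tScore(model, s, C, L = L, seed = deriveSeed(seed, i))
    data.frame(state = s, community = comms[i],
               members = paste(C, collapse = ","),
               fh = sc$fh, t = sc$t, sign = sc$sign)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$t, -out$fh, out$community)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
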