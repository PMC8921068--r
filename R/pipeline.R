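#' Configuration for the end-to-end pipeline
#'
#' Collects every tunable of the analysis flow (standardize -> reduce ->
#' select K -> fit -> prune -> graphs -> communities -> hubs -> rank ->
#' project). All stage seeds are derived deterministically from
#' \code{masterSeed}, so a rerun with the same config is bit-identical.
#'
#' @param kRange candidate state counts for entropy-based selection; ignored
#'   when \code{fixedK} is given
#' @param fixedK skip selection and fit exactly this many states (optional)
#' @param dSelection "auto" (Horn's parallel analysis) or a fixed integer d
#' @param pruneThreshold fraction of subjects a state must occur in (0.25)
#' @param gammaTemporal "auto" (Variation-of-Information selection over
#'   \code{gammaGrid}) or a numeric resolution for the temporal graph
#' @param gammaGrid resolution grid used when gammaTemporal = "auto"
#' @param gammaSpatial resolution for spatial communities of hub states (2)
#' @param nPerm label permutations for modularity significance (10000)
#' @param L null draws per T-score (10000)
#' @param nRestarts EM restarts for the final fit
#' @param masterSeed integer master seed
#' @return a named list of class \code{hmgmConfig}
#' @export
pipelineConfig <- function(kRange = 2:6, fixedK = NULL, dSelection = "auto",
                           pruneThreshold = 0.25, gammaTemporal = "auto",
                           gammaGrid = seq(0.2, 2.0, by = 0.2),
                           gammaSpatial = 2, nPerm = 10000L, L = 10000L,
                           nRestarts = 5L, masterSeed = 1L) {
  stopIfNot(pruneThreshold > 0 && pruneThreshold < 1,
            "pruneThreshold must lie in (0, 1)")
  stopIfNot(nPerm >= 100 && L >= 100, "nPerm and L must be at least 100")
  structure(list(kRange = as.integer(kRange), fixedK = fixedK,
                 dSelection = dSelection, pruneThreshold = pruneThreshold,
                 gammaTemporal = gammaTemporal, gammaGrid = gammaGrid,
                 gammaSpatial = gammaSpatial, nPerm = as.integer(nPerm),
                 L = as.integer(L), nRestarts = as.integer(nRestarts),
                 masterSeed = as.integer(masterSeed)),
            class = "hmgmConfig")
}

#' Run the full hidden-Markov-graph-model pipeline
#'
#' Standardizes every subject series, selects the reduced dimension by
#' parallel analysis (or uses a fixed d), projects, selects the number of
#' states by cross-validated occupancy entropy (or uses a fixed k), fits
#' the HMM, prunes rarely occupied states, builds the multiplex graph,
#' detects temporal communities of the transition matrix (with permutation
#' significance and hub states), detects and ranks spatial communities in
#' every hub state's graph, and optionally projects a supplied term-score
#' table one step ahead. When \code{outDir} is given, all artifacts are
#' written there as delimited text / GraphML / Newick / JSON together with
#' a manifest recording configuration and seeds.
#'
#' @param series named list of raw T x D subject matrices
#' @param config a \code{\link{pipelineConfig}}
#' @param theta optional K x M term-score table for the projection stage
#'   (rows must match the pruned states)
#' @param outDir optional output directory
#' @return list with components selection, model, occupancy, multiplex,
#'   temporal (partition, p-value, hubs, gamma), spatial (per-hub partition
#'   and ranking), projection (when theta given), and manifest
#' @export
runPipeline <- function(series, config = pipelineConfig(), theta = NULL,
                        outDir = NULL) {
  stopIfNot(length(series) >= 1, "no input series")
  seed <- config$masterSeed
  log <- function(fmt, ...) message(sprintf(paste0("[hmgm] ", fmt), ...))

  log("standardizing %d subjects", length(series))
  std <- lapply(series, standardizeSeries)
  pooled <- do.call(rbind, std)

  if (identical(config$dSelection, "auto")) {
    pa <- parallelAnalysis(pooled, seed = deriveSeed(seed, 1L))
    d <- pa$d
    log("parallel analysis retained d = %d components", d)
  } else {
    d <- as.integer(config$dSelection)
    log("using fixed d = %d", d)
  }
  A <- computeEigenmatrix(pooled, d)
  reduced <- lapply(std, reduceSeries, A = A)

  if (is.null(config$fixedK)) {
    curve <- cvEntropy(reduced, config$kRange, seed = deriveSeed(seed, 2L))
    k <- selectedK(curve)
    log("cross-validated entropy selected k = %d", k)
  } else {
    k <- as.integer(config$fixedK)
    curve <- NULL
    log("using fixed k = %d", k)
  }

  model <- fitHmm(reduced, k, seed = deriveSeed(seed, 3L),
                  nRestarts = config$nRestarts, A = A)
  marg <- lapply(reduced, function(x) posteriorMarginals(model, x))
  occ <- fractionalOccupancy(marg, names(series))
  Tlen <- nrow(std[[1]])
  model <- pruneStates(model, occ, config$pruneThreshold, Tlen)
  if (model@K < k) {
    log("pruned to %d states; recomputing occupancy", model@K)
    marg <- lapply(reduced, function(x) posteriorMarginals(model, x))
    occ <- fractionalOccupancy(marg, names(series))
  }

  mux <- multiplexModel(model)

  temporal <- NULL
  if (model@K >= 2) {
    gammaT <- config$gammaTemporal
    if (identical(gammaT, "auto")) {
      sel <- selectResolutionVI(model@P, config$gammaGrid,
                                seed = deriveSeed(seed, 4L))
      gammaT <- sel$gamma
      log("VI selected temporal resolution gamma = %.2f", gammaT)
    }
    part <- louvain(model@P, gamma = gammaT, seed = deriveSeed(seed, 5L))
    pval <- modularitySignificance(model@P, part, nPerm = config$nPerm,
                                   seed = deriveSeed(seed, 6L))
    z <- communityZscore(model@P, part)
    hubs <- selectHubs(z, part)
    trees <- if (nrow(occ@kappa) >= 2 && model@K >= 2)
      tryCatch(wardClusterOccupancy(occ), error = function(e) NULL)
    temporal <- list(partition = part, p = pval, z = z,
                     hubs = hubs$hubs, gamma = gammaT, trees = trees)
    log("temporal communities: %d (Q = %.4f, p = %.4g)",
        max(communityLabels(part)), modularity(part), pval)
  } else {
    log("single-state model: no temporal communities")
  }

  spatial <- list()
  hubSet <- if (is.null(temporal)) integer(0) else unname(temporal$hubs)
  for (h in hubSet) {
    sg <- mux@stateGraphs[[h]]
    part <- louvain(sg@W, gamma = config$gammaSpatial,
                    seed = deriveSeed(seed, 100L + h))
    ranking <- rankCommunities(mux, h, part, L = config$L,
                               seed = deriveSeed(seed, 200L + h))
    spatial[[as.character(h)]] <- list(partition = part, ranking = ranking)
    log("hub state %d: %d spatial communities ranked", h,
        max(communityLabels(part)))
  }

  projection <- NULL
  if (!is.null(theta)) {
    projected <- oneStepProjectedScore(model@P, theta)
    projection <- list(projected = projected,
                       correlation = termDynamicsCorrelation(theta, projected))
    log("projected %d term scores one step ahead", ncol(as.matrix(theta)))
  }

  manifest <- list(
    package = "hmgm",
    version = as.character(utils::packageVersion("hmgm")),
    config = unclass(config), d = d, k = k, finalK = model@K,
    subjects = names(series), timestampFree = TRUE)

  result <- list(selection = curve, model = model, occupancy = occ,
                 multiplex = mux, temporal = temporal, spatial = spatial,
                 projection = projection, manifest = manifest)
  if (!is.null(outDir)) .writeRunDirectory(result, outDir)
  result
}

# serialize all pipeline artifacts as plain text under outDir
.writeRunDirectory <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wTab <- function(x, f) utils::write.table(x, file.path(outDir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  if (!is.null(result$selection)) {
    s <- result$selection
    wTab(data.frame(k = s@kValues, cv_entropy = s@cvEntropy,
                    cv_loglik = s@cvLogLik), "selection_curve.tsv")
  }
  m <- result$model
  utils::write.table(m@P, file.path(outDir, "transition_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = FALSE)
  wTab(data.frame(state = seq_len(m@K), m@mu), "state_means.tsv")
  wTab(data.frame(subject = result$occupancy@subjectIds,
                  result$occupancy@kappa), "occupancy.tsv")
  writeLines(jsonlite::toJSON(list(pi = result$multiplex@pi),
                              auto_unbox = FALSE, digits = NA),
             file.path(outDir, "stationary.json"))
  for (g in result$multiplex@stateGraphs)
    writeStateGraph(g, file.path(outDir,
                                 sprintf("state_graph_%02d.graphml",
                                         g@stateId)))
  if (!is.null(result$temporal)) {
    tp <- result$temporal
    wTab(data.frame(state = seq_along(communityLabels(tp$partition)),
                    community = communityLabels(tp$partition),
                    z = tp$z), "temporal_partition.tsv")
    if (!is.null(tp$trees))
      writeLines(tp$trees$newick,
                 file.path(outDir, "occupancy_trees.nwk"))
  }
  for (h in names(result$spatial)) {
    sp <- result$spatial[[h]]
    wTab(data.frame(region = seq_along(communityLabels(sp$partition)),
                    community = communityLabels(sp$partition)),
         sprintf("spatial_partition_state%s.tsv", h))
    wTab(sp$ranking, sprintf("ranking_state%s.tsv", h))
  }
  if (!is.null(result$projection)) {
    wTab(as.data.frame(result$projection$projected), "projected_scores.tsv")
    wTab(as.data.frame(result$projection$correlation$correlation),
         "term_correlation.tsv")
  }
  writeLines(jsonlite::toJSON(result$manifest, auto_unbox = TRUE,
                              digits = NA, null = "null"),
             file.path(outDir, "manifest.json"))
  invisible(outDir)
}
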