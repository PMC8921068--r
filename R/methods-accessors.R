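#' @rdname transitionMatrix
#' @aliases transitionMatrix,HMGModel-method
setMethod("transitionMatrix", "HMGModel", function(object) object@P)

#' @rdname transitionMatrix
#' @aliases transitionMatrix,MultiplexModel-method
setMethod("transitionMatrix", "MultiplexModel", function(object) object@P)

#' @rdname nStates
#' @aliases nStates,HMGModel-method
setMethod("nStates", "HMGModel", function(object) object@K)

#' @rdname nStates
#' @aliases nStates,MultiplexModel-method
setMethod("nStates", "MultiplexModel", function(object) length(object@stateGraphs))

#' @rdname stateMeans
#' @aliases stateMeans,HMGModel-method
setMethod("stateMeans", "HMGModel", function(object, space = c("region", "reduced")) {
  space <- match.arg(space)
  if (space == "region") object@mu else object@muStar
})

#' @rdname stateCovariances
#' @aliases stateCovariances,HMGModel-method
setMethod("stateCovariances", "HMGModel", function(object, space = c("region", "reduced")) {
  space <- match.arg(space)
  if (space == "region") object@sigma else object@sigmaStar
})

#' @rdname occupancy
#' @aliases occupancy,OccupancyTable-method
setMethod("occupancy", "OccupancyTable", function(object) {
  k <- object@kappa
  rownames(k) <- object@subjectIds
  k
})

#' @rdname edgeWeights
#' @aliases edgeWeights,StateGraph-method
setMethod("edgeWeights", "StateGraph", function(object) {
  W <- object@W
  dimnames(W) <- list(object@nodes, object@nodes)
  W
})

#' @rdname nodeActivity
#' @aliases nodeActivity,StateGraph-method
setMethod("nodeActivity", "StateGraph", function(object)
  stats::setNames(object@a, object@nodes))

#' @rdname selectedK
#' @aliases selectedK,SelectionCurve-method
setMethod("selectedK", "SelectionCurve", function(object) object@selectedK)

#' @rdname communityLabels
#' @aliases communityLabels,Partition-method
setMethod("communityLabels", "Partition", function(object) object@labels)

#' @rdname modularity
#' @aliases modularity,Partition-method
setMethod("modularity", "Partition", function(object) object@Q)

#' @rdname stateGraphs
#' @aliases stateGraphs,MultiplexModel-method
setMethod("stateGraphs", "MultiplexModel", function(object) object@stateGraphs)

setMethod("show", "HMGModel", function(object) {
  cat("HMGModel with", object@K, "states\n")
  cat("  reduced dimension d =", object@A@d,
      "| regions D =", nrow(object@A@A), "\n")
  cat("  training log-likelihood:", format(object@logLik, digits = 8), "\n")
})

setMethod("show", "OccupancyTable", function(object) {
  cat("OccupancyTable:", nrow(object@kappa), "subjects x",
      ncol(object@kappa), "states\n")
  print(round(utils::head(occupancy(object), 4), 3))
  if (nrow(object@kappa) > 4) cat("  ...\n")
})

setMethod("show", "StateGraph", function(object) {
  cat("StateGraph for state", object@stateId, "with",
      length(object@nodes), "regions\n")
  cat("  symmetry fraction Sym(W) =",
      format(symmetryFraction(object@W), digits = 4), "\n")
})

setMethod("show", "MultiplexModel", function(object) {
  cat("MultiplexModel:", length(object@stateGraphs), "state layers over",
      length(object@stateGraphs[[1]]@nodes), "regions\n")
  cat("  stationary distribution:",
      paste(round(object@pi, 3), collapse = " "), "\n")
})

setMethod("show", "SelectionCurve", function(object) {
  cat("SelectionCurve over k =", paste(object@kValues, collapse = ", "), "\n")
  cat("  selected k =", object@selectedK,
      "(max cross-validated entropy)\n")
})

setMethod("show", "Partition", function(object) {
  cat("Partition:", max(object@labels), "communities over",
      length(object@labels), "nodes (gamma =", object@gamma,
      ", Q =", format(object@Q, digits = 4), ")\n")
})

setMethod("show", "Eigenmatrix", function(object) {
  cat("Eigenmatrix:", nrow(object@A), "regions ->", object@d,
      "components (", round(100 * object@explainedVariance, 1),
      "% variance )\n")
})

setMethod("show", "GeneratorSpec", function(object) {
  cat("GeneratorSpec:", object@nSubjects, "subjects x",
      object@nTimepoints, "timepoints x", object@nRegions,
      "regions,", object@nStates, "states (seed", object@seed, ")\n")
})
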