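#' Transition matrix of a model object
#' @param object a fitted model or multiplex model
#' @return the K x K row-stochastic transition matrix
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' Number of states of a model object
#' @param object a fitted model or multiplex model
#' @return integer state count
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' State mean activity
#' @param object a fitted model
#' @param space "region" (back-projected, default) or "reduced"
#' @return K x D (or K x d) matrix of state means
#' @export
setGeneric("stateMeans", function(object, space = c("region", "reduced"))
  standardGeneric("stateMeans"))

#' State covariance matrices
#' @param object a fitted model
#' @param space "region" (back-projected, default) or "reduced"
#' @return list of K covariance matrices
#' @export
setGeneric("stateCovariances", function(object, space = c("region", "reduced"))
  standardGeneric("stateCovariances"))

#' Fractional-occupancy matrix
#' @param object an OccupancyTable
#' @return N x K matrix with subjects in rows
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' Edge-weight matrix of a state graph
#' @param object a StateGraph
#' @return D x D row-stochastic weight matrix
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))

#' Node activity of a state graph
#' @param object a StateGraph
#' @return named numeric vector of mean regional activity
#' @export
setGeneric("nodeActivity", function(object) standardGeneric("nodeActivity"))

#' Selected number of states of a selection curve
#' @param object a SelectionCurve
#' @return integer k maximising the cross-validated entropy
#' @export
setGeneric("selectedK", function(object) standardGeneric("selectedK"))

#' Community labels of a partition
#' @param object a Partition
#' @return integer vector of community ids, one per node
#' @export
setGeneric("communityLabels", function(object) standardGeneric("communityLabels"))

#' Modularity of a partition
#' @param object a Partition
#' @return directed modularity Q at the partition's resolution
#' @export
setGeneric("modularity", function(object) standardGeneric("modularity"))

#' State graphs (layers) of a multiplex model
#' @param object a MultiplexModel
#' @return list of StateGraph objects
#' @export
setGeneric("stateGraphs", function(object) standardGeneric("stateGraphs"))
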