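#' @include AllClasses.R
NULL

#' Node table of a logical model
#' @param object a [LogicalModel-class]
#' @return data.frame with columns id, label, kind
#' @export
setGeneric("modelNodes", function(object) standardGeneric("modelNodes"))

#' Hyperarc list of a logical model
#' @param object a [LogicalModel-class]
#' @return list of hyperarcs
#' @export
setGeneric("modelArcs", function(object) standardGeneric("modelArcs"))

#' Declared timescale set of a logical model
#' @param object a [LogicalModel-class]
#' @return sorted integer vector
#' @export
setGeneric("timescales", function(object) standardGeneric("timescales"))

#' Node and interaction counts
#' @param object a [LogicalModel-class]
#' @return list with nNodes, nArcs and per-kind node counts
#' @export
setGeneric("modelStats", function(object) standardGeneric("modelStats"))

#' Timescale subnetwork
#'
#' Returns the model restricted to interactions with timescale constant
#' tau' <= tau; all nodes are retained.
#' @param object a [LogicalModel-class]
#' @param tau non-negative integer
#' @return a [LogicalModel-class]
#' @export
setGeneric("subnetwork", function(object, tau) standardGeneric("subnetwork"))

#' Logical steady state under three-valued logic
#' @param object a [LogicalModel-class]
#' @param scenario a [Scenario-class]
#' @param tau timescale: only arcs with tau' <= tau are included
#' @return an [LSSResult-class]
#' @export
setGeneric("computeLSS",
           function(object, scenario, tau) standardGeneric("computeLSS"))

#' Signed digraph expansion of a hypergraph
#'
#' One signed edge per (literal, arc) pair.
#' @param object a [LogicalModel-class]
#' @return data.frame with columns source, target, sign (+1/-1)
#' @export
setGeneric("signedEdges", function(object) standardGeneric("signedEdges"))

#' Species on negative feedback loops
#'
#' A node is a member iff a closed signed walk through it with negative sign
#' product exists, decided by reachability on the sign-doubled graph.
#' @param object a [LogicalModel-class]
#' @param tau timescale restriction
#' @return character vector of node ids
#' @export
setGeneric("negativeLoopMembers",
           function(object, tau) standardGeneric("negativeLoopMembers"))

#' Dependency matrix (all-pairs signed influence classification)
#' @param object a [LogicalModel-class]
#' @param tau timescale restriction
#' @return a [DependencyMatrix-class]
#' @export
setGeneric("dependencyMatrix",
           function(object, tau) standardGeneric("dependencyMatrix"))

#' Ternarize fold-change data
#' @param object an [ExpressionPanel-class]
#' @param foldThreshold fold-change threshold (default 2)
#' @param alpha significance level (default 0.05)
#' @return a [TernaryPattern-class]
#' @export
setGeneric("ternarize",
           function(object, foldThreshold = 2, alpha = 0.05)
             standardGeneric("ternarize"))

#' Genes regulated in a condition
#'
#' Genes with a nonzero ternary call at one or more time points.
#' @param object a [TernaryPattern-class]
#' @param condition condition label (e.g. "LPS", "IL4_13"); NULL = any
#' @return character vector of gene names
#' @export
setGeneric("regulatedGenes",
           function(object, condition = NULL)
             standardGeneric("regulatedGenes"))
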