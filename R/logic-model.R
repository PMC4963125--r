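#' @include AllGenerics.R
NULL

NODE_KINDS <- c("input", "housekeeping", "signaling", "mRNA", "protein",
                "secreted")

## structured validation error carrying the offending identifiers
stopValidation <- function(msg, ..., ids = NULL) {
  cond <- structure(class = c("macpol_validation_error", "error", "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1),
                         ids = ids))
  stop(cond)
}

validateLogicalModel <- function(object) {
  validateModelParts(object@nodes, object@arcs, object@timescales)
}

validateModelParts <- function(nodes, arcs, timescales) {
  if (!all(c("id", "label", "kind") %in% names(nodes)))
    stopValidation("node table must have columns id, label, kind")
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup))
    stopValidation("duplicate node id(s): %s", paste(dup, collapse = ", "),
                   ids = dup)
  bad <- setdiff(nodes$kind, NODE_KINDS)
  if (length(bad))
    stopValidation("unknown node kind(s): %s", paste(bad, collapse = ", "))
  ids <- nodes$id
  targetsOfArcs <- vapply(arcs, `[[`, "", "target")
  for (k in seq_along(arcs)) {
    arc <- arcs[[k]]
    if (!arc$target %in% ids)
      stopValidation("arc %d targets undeclared node '%s'", k, arc$target,
                     ids = arc$target)
    if (nrow(arc$literals) < 1)
      stopValidation("arc %d (target '%s') has no literals", k, arc$target)
    miss <- setdiff(arc$literals$node, ids)
    if (length(miss))
      stopValidation("arc %d (target '%s') references undeclared node(s): %s",
                     k, arc$target, paste(miss, collapse = ", "), ids = miss)
    if (!all(arc$literals$sign %in% c("+", "-")))
      stopValidation("arc %d (target '%s') has literal sign outside {+, -}",
                     k, arc$target)
    if (!arc$tau %in% timescales)
      stopValidation("arc %d (target '%s') has tau = %d outside timescale set",
                     k, arc$target, arc$tau)
  }
  ## inputs have no incoming arcs
  inputIds <- ids[nodes$kind == "input"]
  badIn <- intersect(inputIds, targetsOfArcs)
  if (length(badIn))
    stopValidation("input node(s) with incoming arcs: %s",
                   paste(badIn, collapse = ", "), ids = badIn)
  ## housekeeping nodes are driven only by tau = 0 arcs
  hkIds <- ids[nodes$kind == "housekeeping"]
  for (k in seq_along(arcs)) {
    if (arcs[[k]]$target %in% hkIds && arcs[[k]]$tau != 0L)
      stopValidation("housekeeping node '%s' driven by arc with tau = %d (must be 0)",
                     arcs[[k]]$target, arcs[[k]]$tau, ids = arcs[[k]]$target)
  }
  TRUE
}

setValidity("LogicalModel", function(object) {
  tryCatch({ validateLogicalModel(object); TRUE },
           macpol_validation_error = function(e) conditionMessage(e))
})

#' Construct a logical model from node and arc descriptions
#'
#' @param nodes data.frame with columns id, label, kind
#' @param arcs list of arcs, each \code{list(target=, literals=, tau=)} where
#'   \code{literals} is a data.frame (node, sign) or a list of
#'   \code{c(node, sign)} pairs
#' @param timescales integer vector of admissible timescale constants
#' @return a [LogicalModel-class]
#' @export
LogicalModel <- function(nodes, arcs, timescales) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  arcs <- lapply(arcs, function(a) {
    lit <- a$literals
    if (!is.data.frame(lit))
      lit <- data.frame(node = vapply(lit, `[[`, "", 1L),
                        sign = vapply(lit, `[[`, "", 2L),
                        stringsAsFactors = FALSE)
    list(target = a$target, literals = lit, tau = as.integer(a$tau))
  })
  timescales <- sort(unique(as.integer(timescales)))
  validateModelParts(nodes, arcs, timescales)
  new("LogicalModel", nodes = nodes, arcs = arcs,
      timescales = timescales)
}

#' Read a logical model from its YAML definition file
#'
#' The canonical model-definition dialect is YAML with top-level keys
#' \code{timescales}, \code{nodes} (id, label, kind) and \code{arcs}
#' (target, literals as \code{[node, "+"|"-"]} pairs, tau).
#'
#' @param path path to a YAML model definition
#' @return a validated [LogicalModel-class]
#' @export
readLogicalModel <- function(path) {
  if (!file.exists(path)) stopValidation("model file not found: %s", path)
  y <- yaml::read_yaml(path)
  for (key in c("timescales", "nodes", "arcs"))
    if (is.null(y[[key]]))
      stopValidation("model file lacks top-level key '%s'", key)
  nodes <- do.call(rbind, lapply(y$nodes, function(n)
    data.frame(id = n$id,
               label = if (is.null(n$label)) n$id else n$label,
               kind = n$kind, stringsAsFactors = FALSE)))
  arcs <- lapply(y$arcs, function(a)
    list(target = a$target,
         literals = lapply(a$literals, function(l) c(l[[1]], l[[2]])),
         tau = a$tau))
  LogicalModel(nodes, arcs, y$timescales)
}

#' Write a logical model to the native YAML dialect
#'
#' Round-trips losslessly through [readLogicalModel()].
#' @param model a [LogicalModel-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeLogicalModel <- function(model, path) {
  y <- list(
    timescales = as.integer(model@timescales),
    nodes = lapply(seq_len(nrow(model@nodes)), function(i)
      list(id = model@nodes$id[i], label = model@nodes$label[i],
           kind = model@nodes$kind[i])),
    arcs = lapply(model@arcs, function(a)
      list(target = a$target,
           literals = lapply(seq_len(nrow(a$literals)), function(j)
             list(a$literals$node[j], a$literals$sign[j])),
           tau = a$tau)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname modelNodes
#' @export
setMethod("modelNodes", "LogicalModel", function(object) object@nodes)

#' @rdname modelArcs
#' @export
setMethod("modelArcs", "LogicalModel", function(object) object@arcs)

#' @rdname timescales
#' @export
setMethod("timescales", "LogicalModel", function(object) object@timescales)

#' @rdname modelStats
#' @export
setMethod("modelStats", "LogicalModel", function(object) {
  kinds <- table(factor(object@nodes$kind, levels = NODE_KINDS))
  list(nNodes = nrow(object@nodes), nArcs = length(object@arcs),
       byKind = as.list(kinds))
})

#' @rdname subnetwork
#' @export
setMethod("subnetwork", "LogicalModel", function(object, tau) {
  stopifnot(tau >= 0)
  keep <- vapply(object@arcs, function(a) a$tau <= tau, NA)
  new("LogicalModel", nodes = object@nodes, arcs = object@arcs[keep],
      timescales = object@timescales)
})

#' @rdname signedEdges
#' @export
setMethod("signedEdges", "LogicalModel", function(object) {
  if (!length(object@arcs))
    return(data.frame(source = character(), target = character(),
                      sign = integer()))
  do.call(rbind, lapply(object@arcs, function(a)
    data.frame(source = a$literals$node, target = a$target,
               sign = ifelse(a$literals$sign == "+", 1L, -1L),
               stringsAsFactors = FALSE)))
})

setMethod("show", "LogicalModel", function(object) {
  st <- modelStats(object)
  cat("LogicalModel with", st$nNodes, "nodes and", st$nArcs,
      "interactions\n")
  cat("  timescales:", paste(object@timescales, collapse = ", "), "\n")
  ks <- unlist(st$byKind)
  ks <- ks[ks > 0]
  cat("  nodes by kind:",
      paste(sprintf("%s (%d)", names(ks), ks), collapse = ", "), "\n")
})

#' Define an input/clamp scenario for a model
#'
#' @param model a [LogicalModel-class]
#' @param inputs named 0/1 vector; must cover all declared input nodes
#' @param clamps named 0/1 vector of nodes to clamp (knockout = 0, forced
#'   activation = 1); clamps take precedence over inputs and arcs
#' @return a [Scenario-class]
#' @export
makeScenario <- function(model, inputs = numeric(), clamps = numeric()) {
  declared <- model@nodes$id[model@nodes$kind == "input"]
  miss <- setdiff(declared, names(inputs))
  if (length(miss))
    stopValidation("scenario lacks values for input(s): %s",
                   paste(miss, collapse = ", "), ids = miss)
  unknown <- setdiff(c(names(inputs), names(clamps)), model@nodes$id)
  if (length(unknown))
    stopValidation("scenario references unknown node(s): %s",
                   paste(unknown, collapse = ", "), ids = unknown)
  stopifnot(all(inputs %in% c(0, 1)), all(clamps %in% c(0, 1)))
  new("Scenario", inputs = inputs, clamps = clamps)
}

setMethod("show", "Scenario", function(object) {
  cat("Scenario: inputs {",
      paste(sprintf("%s=%d", names(object@inputs), object@inputs),
            collapse = ", "), "}")
  if (length(object@clamps))
    cat("; clamps {",
        paste(sprintf("%s=%d", names(object@clamps), object@clamps),
              collapse = ", "), "}")
  cat("\n")
})
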