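#' @include logic-model.R
NULL

## Kleene three-valued connectives on integer vectors with NA = UNKNOWN.
kleeneAnd <- function(x) {
  if (any(x == 0L, na.rm = TRUE)) return(0L)
  if (anyNA(x)) return(NA_integer_)
  1L
}

kleeneOr <- function(x) {
  if (any(x == 1L, na.rm = TRUE)) return(1L)
  if (anyNA(x)) return(NA_integer_)
  0L
}

kleeneNot <- function(x) 1L - x  # NA stays NA

#' @rdname computeLSS
#'
#' @details
#' The logical steady state of the tau-subnetwork is the Kleene least fixed
#' point: clamped nodes and inputs are held at their assigned values,
#' housekeeping source nodes (housekeeping kind, no incoming arcs) are held
#' at 1, all other nodes start UNKNOWN and are updated synchronously with
#' arc = Kleene-AND over literals (a "-" literal is negated) and node =
#' Kleene-OR over its included arcs. A non-clamped node with no included arc
#' evaluates to 0: interactions excluded by the timescale are events that
#' have not yet happened, not sources of uncertainty. Iteration stops at the
#' first sweep without change; because the connectives are monotone in the
#' information order the sweep sequence always converges, and a defensive
#' cap of 2 * nNodes sweeps guards against implementation errors. Nodes
#' still UNKNOWN at the fixed point (unresolved cycles) are reported as NA.
#' @export
setMethod("computeLSS", "LogicalModel", function(object, scenario, tau) {
  stopifnot(is(scenario, "Scenario"), tau >= 0)
  nodes <- object@nodes$id
  n <- length(nodes)
  arcs <- Filter(function(a) a$tau <= tau, object@arcs)

  ## fixed assignments: housekeeping sources, then inputs, then clamps
  fixed <- rep(NA_integer_, n)
  names(fixed) <- nodes
  allTargets <- vapply(object@arcs, `[[`, "", "target")
  hkSource <- object@nodes$id[object@nodes$kind == "housekeeping" &
                                !(object@nodes$id %in% allTargets)]
  fixed[hkSource] <- 1L
  fixed[names(scenario@inputs)] <- as.integer(scenario@inputs)
  fixed[names(scenario@clamps)] <- as.integer(scenario@clamps)
  isFixed <- !is.na(fixed)

  ## index arcs per target for the sweep
  byTarget <- split(seq_along(arcs),
                    factor(vapply(arcs, `[[`, "", "target"), levels = nodes))
  litIdx <- lapply(arcs, function(a) match(a$literals$node, nodes))
  litNeg <- lapply(arcs, function(a) a$literals$sign == "-")

  state <- fixed
  state[!isFixed] <- NA_integer_
  cap <- max(2L * n, 2L)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    newState <- state
    for (i in seq_len(n)) {
      if (isFixed[i]) next
      ix <- byTarget[[i]]
      if (!length(ix)) { newState[i] <- 0L; next }
      arcVals <- vapply(ix, function(k) {
        vals <- state[litIdx[[k]]]
        vals[litNeg[[k]]] <- kleeneNot(vals[litNeg[[k]]])
        kleeneAnd(vals)
      }, integer(1))
      newState[i] <- kleeneOr(arcVals)
    }
    if (identical(newState, state)) break
    state <- newState
    if (iterations > cap)
      stop("computeLSS: iteration cap exceeded without a fixed point")
  }
  new("LSSResult", tau = as.integer(tau), states = state,
      resolved = !anyNA(state), iterations = iterations)
})

#' States of a logical steady state
#' @param lss an [LSSResult-class]
#' @return named integer vector (1/0/NA)
#' @export
lssStates <- function(lss) lss@states

setMethod("show", "LSSResult", function(object) {
  cat("LSSResult at tau =", object@tau, "-",
      if (object@resolved) "fully resolved" else
        paste(sum(is.na(object@states)), "node(s) UNKNOWN"),
      sprintf("(%d sweeps)\n", object@iterations))
  on <- names(object@states)[!is.na(object@states) & object@states == 1L]
  cat("  ON:", if (length(on)) paste(on, collapse = ", ") else "(none)",
      "\n")
})

#' Write a logical steady state as a two-column TSV
#'
#' Columns: node, state (0/1, NA for UNKNOWN).
#' @param lss an [LSSResult-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeLss <- function(lss, path) {
  utils::write.table(
    data.frame(node = names(lss@states), state = lss@states),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
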