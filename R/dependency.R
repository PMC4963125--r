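#' @include logic-model.R
NULL

## Sign-doubled graph machinery. For a signed digraph with vertices V, the
## doubled graph has vertices (v, +) and (v, -); an edge u -> v with sign s
## induces (u, +) -> (v, s) and (u, -) -> (v, -s). A walk from i to j with
## sign product s exists iff (i, +) reaches (j, s).

## returns list(reach1 = 2n x 2n logical matrix of length>=1 reachability,
## nodes = node ids); vertex order: all (v,+) then all (v,-)
doubledReachability <- function(model, tau) {
  sub <- subnetwork(model, tau)
  nodes <- model@nodes$id
  n <- length(nodes)
  ed <- signedEdges(sub)
  A <- matrix(FALSE, 2L * n, 2L * n)
  if (nrow(ed)) {
    si <- match(ed$source, nodes)
    ti <- match(ed$target, nodes)
    pos <- ed$sign > 0
    ## (u,+) -> (v,s)
    A[cbind(si, ifelse(pos, ti, ti + n))] <- TRUE
    ## (u,-) -> (v,-s)
    A[cbind(si + n, ifelse(pos, ti + n, ti))] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  R0 <- is.finite(igraph::distances(g, mode = "out"))  # length >= 0
  reach1 <- (A %*% R0) > 0                              # length >= 1
  list(reach1 = reach1, nodes = nodes)
}

#' @rdname negativeLoopMembers
#' @export
setMethod("negativeLoopMembers", "LogicalModel", function(object, tau) {
  if (missing(tau)) tau <- max(object@timescales)
  dr <- doubledReachability(object, tau)
  n <- length(dr$nodes)
  member <- dr$reach1[cbind(seq_len(n), seq_len(n) + n)]
  dr$nodes[member]
})

DEP_CATEGORIES <- c("no_influence", "total_activator", "nontotal_activator",
                    "total_inhibitor", "nontotal_inhibitor", "ambivalent")

#' @rdname dependencyMatrix
#'
#' @details
#' Influence of i on j is classified from the existence of positive- and/or
#' negative-signed connecting walks in the signed digraph of the
#' tau-subnetwork, computed by reachability on the sign-doubled graph (the
#' CellNetAnalyzer-style convention). No walk: \code{no_influence}; both
#' signs: \code{ambivalent}; one sign: activator/inhibitor, downgraded to
#' non-total when at least one species lying on a connecting walk belongs
#' to a negative feedback loop. Rows are sources, columns targets, both in
#' model declaration order.
#' @export
setMethod("dependencyMatrix", "LogicalModel", function(object, tau) {
  if (missing(tau)) tau <- max(object@timescales)
  dr <- doubledReachability(object, tau)
  nodes <- dr$nodes
  n <- length(nodes)
  ip <- seq_len(n); im <- ip + n
  pos <- dr$reach1[ip, ip, drop = FALSE]   # positive walk i -> j
  neg <- dr$reach1[ip, im, drop = FALSE]   # negative walk i -> j
  anyR <- pos | neg                        # unsigned reachability, length>=1

  loop <- nodes %in% negativeLoopMembers(object, tau)
  ## w lies on some connecting walk i -> j iff (w == i or i reaches w) and
  ## (w == j or w reaches j); non-total iff such a w is a neg-loop member
  eye <- diag(TRUE, n)
  fromI <- anyR | eye                      # [i, w]: i reaches w or w == i
  toJ <- anyR | eye                        # [w, j]: w reaches j or w == j
  nontotal <- (fromI[, loop, drop = FALSE] %*% toJ[loop, , drop = FALSE]) > 0

  cat <- matrix("no_influence", n, n, dimnames = list(nodes, nodes))
  cat[pos & neg] <- "ambivalent"
  cat[pos & !neg] <- ifelse(nontotal[pos & !neg],
                            "nontotal_activator", "total_activator")
  cat[!pos & neg] <- ifelse(nontotal[!pos & neg],
                            "nontotal_inhibitor", "total_inhibitor")
  new("DependencyMatrix", categories = cat, tau = as.integer(tau))
})

#' Category codes of a dependency matrix
#' @param dm a [DependencyMatrix-class]
#' @return character matrix (rows = sources, columns = targets)
#' @export
dependencyCategories <- function(dm) dm@categories

setMethod("show", "DependencyMatrix", function(object) {
  tab <- table(factor(object@categories, levels = DEP_CATEGORIES))
  cat("DependencyMatrix (", nrow(object@categories), "x",
      ncol(object@categories), ") at tau =", object@tau, "\n")
  for (nm in names(tab))
    if (tab[[nm]] > 0) cat(sprintf("  %-20s %d\n", nm, tab[[nm]]))
})

#' Write a dependency matrix as CSV of category codes
#' @param dm a [DependencyMatrix-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeDependencyMatrix <- function(dm, path) {
  utils::write.csv(as.data.frame(dm@categories), path, row.names = TRUE)
  invisible(path)
}
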