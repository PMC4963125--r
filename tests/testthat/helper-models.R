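## Small builders and independent oracles used across the suite.

## minimal A -> B model
toyChainModel <- function() {
  LogicalModel(
    nodes = data.frame(id = c("A", "B"), label = c("A", "B"),
                       kind = c("input", "signaling")),
    arcs = list(list(target = "B", literals = list(c("A", "+")), tau = 0)),
    timescales = 0)
}

## random signed single-literal-arc model; optionally acyclic
randomSignedModel <- function(nNodes, nArcs, seed, acyclic = FALSE,
                              negProb = 0.4, taus = c(0, 1, 2)) {
  set.seed(seed)
  ids <- paste0("n", seq_len(nNodes))
  nodes <- data.frame(id = ids, label = ids,
                      kind = c("input", rep("signaling", nNodes - 1)))
  arcs <- list()
  for (k in seq_len(nArcs)) {
    if (acyclic) {
      j <- sample(2:nNodes, 1)
      i <- sample(seq_len(j - 1), 1)
    } else {
      i <- sample(nNodes, 1)
      j <- sample(setdiff(seq_len(nNodes), 1), 1)
    }
    arcs[[k]] <- list(target = ids[j],
                      literals = list(c(ids[i],
                                        if (stats::runif(1) < negProb) "-"
                                        else "+")),
                      tau = sample(taus, 1))
  }
  LogicalModel(nodes, arcs, taus)
}

## oracle: evaluate an acyclic model in topological order (three-valued)
topoEvalOracle <- function(model, scenario, tau) {
  ed <- signedEdges(subnetwork(model, tau))
  ids <- modelNodes(model)$id
  g <- igraph::graph_from_data_frame(
    ed[, c("source", "target")], vertices = ids)
  ord <- names(igraph::topo_sort(g))
  states <- setNames(rep(NA_integer_, length(ids)), ids)
  fixed <- c(scenario@inputs, scenario@clamps)
  arcs <- modelArcs(subnetwork(model, tau))
  targets <- vapply(arcs, `[[`, "", "target")
  for (v in ord) {
    if (v %in% names(fixed)) { states[v] <- as.integer(fixed[[v]]); next }
    ix <- which(targets == v)
    if (!length(ix)) { states[v] <- 0L; next }
    vals <- vapply(ix, function(k) {
      lit <- arcs[[k]]$literals
      lv <- states[lit$node]
      lv[lit$sign == "-"] <- 1L - lv[lit$sign == "-"]
      if (any(lv == 0L, na.rm = TRUE)) 0L
      else if (anyNA(lv)) NA_integer_ else 1L
    }, integer(1))
    states[v] <- if (any(vals == 1L, na.rm = TRUE)) 1L
                 else if (anyNA(vals)) NA_integer_ else 0L
  }
  states
}

## oracle: all simple paths i -> j with their sign products (for DAGs this
## is exhaustive over all walks as well)
simplePathSigns <- function(model, tau, from, to) {
  ed <- signedEdges(subnetwork(model, tau))
  if (!nrow(ed)) return(integer())
  key <- paste(ed$source, ed$target)
  adj <- split(seq_len(nrow(ed)), ed$source)
  signs <- integer()
  recurse <- function(v, visited, prod) {
    for (k in adj[[v]]) {
      w <- ed$target[k]; s <- prod * ed$sign[k]
      if (w == to) signs <<- c(signs, s)
      if (!(w %in% visited) && w != to)
        recurse(w, c(visited, w), s)
    }
  }
  recurse(from, c(from), 1L)
  unique(signs)
}

## oracle: negative-closed-walk membership via boolean matrix closure on
## the sign-doubled adjacency (independent of the igraph-based route)
doubledClosureOracle <- function(model, tau) {
  ed <- signedEdges(subnetwork(model, tau))
  ids <- modelNodes(model)$id
  n <- length(ids)
  A <- matrix(FALSE, 2 * n, 2 * n)
  if (nrow(ed)) {
    si <- match(ed$source, ids); ti <- match(ed$target, ids)
    pos <- ed$sign > 0
    A[cbind(si, ifelse(pos, ti, ti + n))] <- TRUE
    A[cbind(si + n, ifelse(pos, ti + n, ti))] <- TRUE
  }
  R <- A
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  list(reach1 = R, ids = ids)
}

## oracle: all simple cycles through each node with sign products
simpleCycleNegMembers <- function(model, tau) {
  ids <- modelNodes(model)$id
  members <- character()
  for (v in ids) {
    s <- simplePathSigns(model, tau, v, v)
    if (-1L %in% s) members <- c(members, v)
  }
  members
}
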