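#' @include logic-model.R
NULL

#' Export a logical model
#'
#' \code{"native"} writes the canonical YAML dialect (lossless round trip).
#' \code{"bnet"} writes BoolNet's \code{targets, factors} format with
#' hyperarcs as OR-of-AND clauses and inhibitory literals as \code{!};
#' BoolNet has no notion of timescale constants, so they are dropped with a
#' warning. Inputs become self-loops, housekeeping source nodes the
#' constant 1, and undriven nodes the constant 0.
#'
#' @param model a [LogicalModel-class]
#' @param path output file
#' @param format "native" or "bnet"
#' @return invisibly, \code{path}
#' @export
exportModel <- function(model, path, format = c("native", "bnet")) {
  format <- match.arg(format)
  if (format == "native") return(writeLogicalModel(model, path))
  warning("BoolNet export drops timescale constants")
  nodes <- model@nodes
  targets <- vapply(model@arcs, `[[`, "", "target")
  lines <- "targets, factors"
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    arcIdx <- which(targets == id)
    rhs <- if (length(arcIdx)) {
      clauses <- vapply(arcIdx, function(k) {
        lit <- model@arcs[[k]]$literals
        terms <- ifelse(lit$sign == "-", paste0("!", lit$node), lit$node)
        if (length(terms) > 1) paste0("(", paste(terms, collapse = " & "), ")")
        else terms
      }, "")
      paste(clauses, collapse = " | ")
    } else if (nodes$kind[i] == "input") {
      id
    } else if (nodes$kind[i] == "housekeeping") {
      "1"
    } else {
      "0"
    }
    lines <- c(lines, paste0(id, ", ", rhs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import a BoolNet file as a logical model
#'
#' Accepts the OR-of-AND grammar written by [exportModel()]. All arcs get
#' the default timescale constant (0); self-loop rules are interpreted as
#' inputs and constant-1 rules as housekeeping source nodes.
#'
#' @param path a .bnet file
#' @param tauDefault timescale assigned to every arc
#' @return a [LogicalModel-class]
#' @export
readBnet <- function(path, tauDefault = 0) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!grepl("^targets\\s*,\\s*factors$", lines[1], ignore.case = TRUE))
    stopValidation("not a BoolNet file (missing 'targets, factors' header)")
  nodes <- list(); arcs <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stopValidation("malformed BoolNet line: %s", ln)
    target <- trimws(parts[1])
    rhs <- trimws(paste(parts[-1], collapse = ","))
    if (rhs == "1") {
      nodes[[target]] <- "housekeeping"
    } else if (rhs == "0") {
      nodes[[target]] <- "signaling"
    } else if (rhs == target) {
      nodes[[target]] <- "input"
    } else {
      nodes[[target]] <- "signaling"
      for (clause in strsplit(rhs, "|", fixed = TRUE)[[1]]) {
        clause <- gsub("[()]", "", clause)
        terms <- trimws(strsplit(clause, "&", fixed = TRUE)[[1]])
        lit <- data.frame(
          node = sub("^!", "", terms),
          sign = ifelse(startsWith(terms, "!"), "-", "+"),
          stringsAsFactors = FALSE)
        arcs[[length(arcs) + 1L]] <-
          list(target = target, literals = lit, tau = tauDefault)
      }
    }
  }
  mentioned <- unique(unlist(lapply(arcs, function(a) a$literals$node)))
  for (m in setdiff(mentioned, names(nodes))) nodes[[m]] <- "signaling"
  nodeDf <- data.frame(id = names(nodes), label = names(nodes),
                       kind = unlist(nodes), stringsAsFactors = FALSE)
  LogicalModel(nodeDf, arcs, unique(c(tauDefault,
                                      vapply(arcs, `[[`, 0, "tau"))))
}
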