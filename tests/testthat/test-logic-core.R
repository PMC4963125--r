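test_that("model files load, validate and report structured errors", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "timescales: [0]",
    "nodes:",
    "- {id: A, kind: input}",
    "- {id: B, kind: signaling}",
    "arcs:",
    "- {target: B, tau: 0, literals: [[A, \"+\"]]}"), path)
  m <- readLogicalModel(path)
  expect_s4_class(m, "LogicalModel")
  expect_equal(modelStats(m)$nNodes, 2)
  expect_equal(modelStats(m)$nArcs, 1)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "timescales: [0]",
    "nodes:",
    "- {id: A, kind: input}",
    "arcs:",
    "- {target: Zzz, tau: 0, literals: [[A, \"+\"]]}"), bad)
  err <- tryCatch(readLogicalModel(bad), error = function(e) e)
  expect_s3_class(err, "macpol_validation_error")
  expect_match(conditionMessage(err), "Zzz")

  expect_error(
    LogicalModel(data.frame(id = c("A", "A"), kind = c("input", "input")),
                 list(), 0),
    class = "macpol_validation_error")
  expect_error(
    LogicalModel(data.frame(id = c("A", "B"),
                            kind = c("input", "signaling")),
                 list(list(target = "B", literals = list(c("A", "+")),
                           tau = 99)),
                 0),
    class = "macpol_validation_error")
})

test_that("subnetwork keeps nodes and filters arcs by timescale", {
  m <- buildRefinedModel()
  expect_identical(modelStats(subnetwork(m, max(timescales(m))))$nArcs,
                   modelStats(m)$nArcs)
  ## transcription starts at tau = 5: no arcs target mRNA nodes before
  sub2 <- subnetwork(m, 2)
  mrna <- modelNodes(m)$id[modelNodes(m)$kind == "mRNA"]
  targets <- vapply(modelArcs(sub2), `[[`, "", "target")
  expect_length(intersect(targets, mrna), 0)
  ## filter oracle on random models
  for (seed in 1:10) {
    rm <- randomSignedModel(6, 10, seed)
    for (tau in c(0, 1, 2)) {
      expected <- sum(vapply(modelArcs(rm), `[[`, 0L, "tau") <= tau)
      expect_equal(modelStats(subnetwork(rm, tau))$nArcs, expected)
    }
    expect_equal(modelNodes(subnetwork(rm, 0)), modelNodes(rm))
  }
})

test_that("computeLSS is a Kleene fixed point with the documented rules", {
  m <- toyChainModel()
  lss <- computeLSS(m, makeScenario(m, c(A = 1)), 0)
  expect_true(lss@resolved)
  expect_equal(unname(lssStates(lss)["B"]), 1L)

  ## zero included arcs (excluded by tau) -> ZERO, not UNKNOWN
  m2 <- LogicalModel(
    data.frame(id = c("A", "B"), kind = c("input", "signaling")),
    list(list(target = "B", literals = list(c("A", "+")), tau = 5)),
    c(0, 5))
  expect_equal(unname(lssStates(
    computeLSS(m2, makeScenario(m2, c(A = 1)), 0))["B"]), 0L)

  ## an unresolved positive cycle stays UNKNOWN
  m3 <- LogicalModel(
    data.frame(id = c("A", "X", "Y"),
               kind = c("input", "signaling", "signaling")),
    list(list(target = "X", literals = list(c("Y", "+")), tau = 0),
         list(target = "Y", literals = list(c("X", "+")), tau = 0)),
    0)
  lss3 <- computeLSS(m3, makeScenario(m3, c(A = 0)), 0)
  expect_false(lss3@resolved)
  expect_true(all(is.na(lssStates(lss3)[c("X", "Y")])))

  ## clamps override arcs and inputs
  lssC <- computeLSS(m, makeScenario(m, c(A = 1), clamps = c(B = 0)), 0)
  expect_equal(unname(lssStates(lssC)["B"]), 0L)
})

test_that("LSS equals topological evaluation on random acyclic models", {
  for (seed in 1:20) {
    rm <- randomSignedModel(10, 14, seed, acyclic = TRUE)
    scen <- makeScenario(rm, c(n1 = seed %% 2))
    for (tau in c(0, 2)) {
      lss <- computeLSS(rm, scen, tau)
      expect_identical(lssStates(lss), topoEvalOracle(rm, scen, tau))
    }
  }
})

test_that("LSS is independent of node declaration order", {
  for (seed in 1:100) {
    rm <- randomSignedModel(8, 12, seed)
    scen <- makeScenario(rm, c(n1 = 1))
    ref <- lssStates(computeLSS(rm, scen, 2))
    perm <- sample(nrow(modelNodes(rm)))
    rmP <- LogicalModel(modelNodes(rm)[perm, ], modelArcs(rm),
                        timescales(rm))
    got <- lssStates(computeLSS(rmP, scen, 2))
    expect_identical(got[names(ref)], ref)
  }
})

test_that("signed digraph expansion unfolds literals", {
  m <- LogicalModel(
    data.frame(id = c("A", "B", "C"),
               kind = c("input", "input", "signaling")),
    list(list(target = "C",
              literals = list(c("A", "+"), c("B", "-")), tau = 0)),
    0)
  ed <- signedEdges(m)
  expect_equal(nrow(ed), 2)
  expect_equal(ed$sign[ed$source == "A"], 1L)
  expect_equal(ed$sign[ed$source == "B"], -1L)
  ## edge count equals total literal count
  mac <- buildRefinedModel()
  expect_equal(nrow(signedEdges(mac)),
               sum(vapply(modelArcs(mac),
                          function(a) nrow(a$literals), 0L)))
  empty <- LogicalModel(data.frame(id = "A", kind = "input"), list(), 0)
  expect_equal(nrow(signedEdges(empty)), 0)
})

test_that("negative feedback loop membership", {
  negLoop <- LogicalModel(
    data.frame(id = c("A", "B"), kind = c("signaling", "signaling")),
    list(list(target = "B", literals = list(c("A", "+")), tau = 0),
         list(target = "A", literals = list(c("B", "-")), tau = 0)),
    0)
  expect_setequal(negativeLoopMembers(negLoop, 0), c("A", "B"))
  posLoop <- LogicalModel(
    data.frame(id = c("A", "B"), kind = c("signaling", "signaling")),
    list(list(target = "B", literals = list(c("A", "+")), tau = 0),
         list(target = "A", literals = list(c("B", "+")), tau = 0)),
    0)
  expect_length(negativeLoopMembers(posLoop, 0), 0)

  for (seed in 1:30) {
    rm <- randomSignedModel(6, 9, seed)
    got <- negativeLoopMembers(rm, 2)
    ## independent boolean-closure oracle (same walk semantics)
    cl <- doubledClosureOracle(rm, 2)
    n <- length(cl$ids)
    expect_setequal(got,
                    cl$ids[cl$reach1[cbind(seq_len(n), seq_len(n) + n)]])
    ## every member of a simple negative cycle must be flagged
    expect_true(all(simpleCycleNegMembers(rm, 2) %in% got))
  }
})

test_that("dependency matrix classifies signed influence", {
  single <- toyChainModel()
  dm <- dependencyCategories(dependencyMatrix(single, 0))
  expect_equal(dm["A", "B"], "total_activator")
  expect_equal(dm["B", "A"], "no_influence")

  ## exhaustive simple-path oracle on random DAGs (walks = simple paths)
  for (seed in 1:25) {
    rm <- randomSignedModel(7, 10, seed, acyclic = TRUE)
    cats <- dependencyCategories(dependencyMatrix(rm, 2))
    ids <- modelNodes(rm)$id
    for (i in ids) for (j in ids) {
      s <- simplePathSigns(rm, 2, i, j)
      expected <- if (!length(s)) "no_influence"
        else if (all(c(1L, -1L) %in% s)) "ambivalent"
        else if (1L %in% s) "total_activator" else "total_inhibitor"
      ## DAGs have no loops, so categories are total
      expect_equal(cats[i, j], expected,
                   info = sprintf("seed %d, %s -> %s", seed, i, j))
    }
  }

  ## no_influence iff unreachable in the signed digraph
  for (seed in 1:15) {
    rm <- randomSignedModel(6, 9, seed)
    cats <- dependencyCategories(dependencyMatrix(rm, 2))
    ed <- signedEdges(rm)
    g <- igraph::graph_from_data_frame(ed[, 1:2],
                                       vertices = modelNodes(rm)$id)
    dist <- igraph::distances(g, mode = "out")
    ids <- modelNodes(rm)$id
    for (i in ids) for (j in ids) {
      reachable <- if (i == j) {
        any(vapply(igraph::neighbors(g, i, "out")$name,
                   function(w) is.finite(dist[w, j]), NA))
      } else is.finite(dist[i, j])
      expect_equal(cats[i, j] == "no_influence", !reachable,
                   info = sprintf("seed %d, %s -> %s", seed, i, j))
    }
  }
})

test_that("walk-based categories match the closure oracle on cyclic graphs", {
  for (seed in 1:20) {
    rm <- randomSignedModel(8, 14, seed)
    cats <- dependencyCategories(dependencyMatrix(rm, 2))
    cl <- doubledClosureOracle(rm, 2)
    n <- length(cl$ids)
    pos <- cl$reach1[seq_len(n), seq_len(n), drop = FALSE]
    neg <- cl$reach1[seq_len(n), n + seq_len(n), drop = FALSE]
    expect_identical(unname(cats == "no_influence"), !(pos | neg))
    expect_identical(unname(cats == "ambivalent"), pos & neg)
    expect_identical(as.vector(cats %in% c("total_activator",
                                           "nontotal_activator")),
                     as.vector(pos & !neg))
    expect_identical(as.vector(cats %in% c("total_inhibitor",
                                           "nontotal_inhibitor")),
                     as.vector(!pos & neg))
  }
})
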