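mac <- buildRefinedModel()

test_that("the shipped fixture validates and resolves fully everywhere", {
  expect_s4_class(mac, "LogicalModel")
  expect_identical(timescales(mac), c(0L, 1L, 2L, 5L, 7L, 10L, 12L, 15L))
  combos <- expand.grid(LPS = 0:1, IL4 = 0:1, IL13 = 0:1)
  for (i in seq_len(nrow(combos))) {
    scen <- makeScenario(mac, c(LPS = combos$LPS[i], IL4 = combos$IL4[i],
                                IL13 = combos$IL13[i]))
    for (tau in timescales(mac)) {
      expect_true(computeLSS(mac, scen, tau)@resolved,
                  info = sprintf("inputs %d%d%d tau %d", combos$LPS[i],
                                 combos$IL4[i], combos$IL13[i], tau))
    }
  }
})

test_that("inhibitory literals are confined to the last timescale", {
  for (a in modelArcs(mac))
    if (any(a$literals$sign == "-")) expect_equal(a$tau, 15L)
})

test_that("ONE-set grows monotonically with tau below the inhibition tier", {
  for (cond in c("M1", "M2")) {
    scen <- polarizationScenario(mac, cond)
    prev <- character()
    for (tau in c(0, 1, 2, 5, 7, 10, 12)) {
      st <- lssStates(computeLSS(mac, scen, tau))
      on <- names(st)[st == 1L]
      expect_true(all(prev %in% on), info = paste(cond, tau))
      prev <- on
    }
  }
})

test_that("M1 and M2 polarization patterns match the expression program", {
  p1 <- simulatePolarization(mac, "M1")
  p2 <- simulatePolarization(mac, "M2")
  m1Nodes <- unname(MACROPHAGE_ALIASES[M1_GENES])
  ## all 16 LPS-regulated mRNAs ON from the first transcriptional tier,
  ## including IL-10 and Socs3 (early MK2 route)
  expect_true(all(polarizationCalls(p1)[m1Nodes, ] == 1L))
  ## M2: exactly the four Stat6 targets
  on2 <- rownames(polarizationCalls(p2))[polarizationCalls(p2)[, "15"] == 1L]
  expect_setequal(on2, unname(MACROPHAGE_ALIASES[M2_UP_GENES]))
  ## disjoint except the shared chemokines Ccl2 / Ccl7
  on1 <- rownames(polarizationCalls(p1))[polarizationCalls(p1)[, "15"] == 1L]
  expect_setequal(intersect(on1, on2), c("Ccl2_mRNA", "Ccl7_mRNA"))
  ## no stimulus: every mRNA silent at every tau
  p0 <- simulatePolarization(
    mac, "M1", clamps = c(LPS = 0))  # clamp overrides the M1 input
  expect_true(all(polarizationCalls(p0) == 0L))
})

test_that("refinements are reflected in the network content", {
  ids <- modelNodes(mac)$id
  ## IFN-gamma, its receptor, Cxcl5 and Osm were removed
  expect_false(any(c("IFNGR", "IFNg", "Cxcl5_mRNA", "Osm_mRNA") %in% ids))
  ## only IFN-beta and IL-10 occur as secreted species (autocrine loops)
  expect_setequal(ids[modelNodes(mac)$kind == "secreted"],
                  c("IFNb", "IL10"))
  ## no secreted IL-6 exists, so IL-6 cannot be an ancestor of Stat3
  dm <- dependencyCategories(dependencyMatrix(mac, 15))
  expect_false("IL6" %in% ids)
  expect_equal(dm["IL6_mRNA", "Stat3"], "no_influence")
  ## Ccl7 is both an NF-kB and a Stat6 target
  expect_equal(dm["NFkB", "Ccl7_mRNA"], "total_activator")
  expect_equal(dm["Stat6", "Ccl7_mRNA"], "total_activator")
  ## IL-10R signaling is insensitive to Socs3, IFNAR is not: the
  ## inhibitory arc exists only towards IFNAR (through the negative
  ## feedback loop the walk-based pair category is ambivalent)
  expect_equal(dm["Socs3_syn", "IL10R_act"], "no_influence")
  ed <- signedEdges(mac)
  expect_true(any(ed$source == "Socs3_syn" & ed$target == "IFNAR_act" &
                    ed$sign == -1L))
  expect_false(any(ed$source == "Socs3_syn" & ed$target == "IL10R_act"))
  expect_equal(dm["Socs3_syn", "IFNAR_act"], "ambivalent")
  ## secretion arcs at tau 10 (IFN-beta) and 12 (IL-10)
  taus <- vapply(modelArcs(mac), `[[`, 0L, "tau")
  targets <- vapply(modelArcs(mac), `[[`, "", "target")
  expect_equal(taus[targets == "IFNb"], 10L)
  expect_equal(taus[targets == "IL10"], 12L)
})

test_that("Akt knockouts repolarize as observed in vivo", {
  akt1 <- knockoutScenario(mac, "Akt1", "M2")
  expect_equal(unname(akt1$readout["miR155"]), 1L)   # M1-like
  akt2 <- knockoutScenario(mac, "Akt2", "M1")
  expect_equal(unname(akt2$readout["miR155"]), 0L)   # M2-like
  expect_equal(unname(akt2$readout["Arg1_mRNA"]), 1L)
  ## empty knockout set reproduces the plain simulation
  none <- knockoutScenario(mac, character(0), "M1")
  expect_identical(polarizationCalls(none$pattern),
                   polarizationCalls(simulatePolarization(mac, "M1")))
  expect_error(knockoutScenario(mac, "NotANode", "M1"),
               class = "macpol_validation_error")
})

test_that("the TLR4 co-regulatory signal gates miRNA-155 polarization", {
  expect_equal(unname(coregulationToggle(mac, FALSE, "M2")["miR155"]), 1L)
  expect_equal(unname(coregulationToggle(mac, TRUE, "M2")["miR155"]), 0L)
  expect_equal(unname(coregulationToggle(mac, TRUE, "M1")["miR155"]), 1L)
})
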