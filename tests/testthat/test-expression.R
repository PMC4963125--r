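makePanelDf <- function(genes, conditions = "LPS", times = c(0.5, 1),
                        fold = 1, p = 1) {
  d <- expand.grid(gene = genes, condition = conditions, time_h = times,
                   stringsAsFactors = FALSE)
  d$fold_change <- fold
  d$sd <- 0.1
  d$n <- 3
  d$p <- p
  d
}

test_that("panels read from CSV and reject malformed input", {
  path <- tempfile(fileext = ".csv")
  write.csv(makePanelDf(c("Tnf", "Il6", "Ccl2")), path, row.names = FALSE)
  panel <- readPanel(path)
  expect_s4_class(panel, "ExpressionPanel")
  expect_length(unique(panelData(panel)$gene), 3)

  d <- makePanelDf("Tnf")
  expect_error(ExpressionPanel(d[, setdiff(names(d), "sd")]),
               class = "macpol_validation_error")
  expect_error(ExpressionPanel(rbind(d, d)),
               class = "macpol_validation_error")
  d2 <- d; d2$fold_change <- -1
  expect_error(ExpressionPanel(d2), class = "macpol_validation_error")
  ## missing values are flagged, not dropped
  d3 <- makePanelDf(c("Tnf", "Il6"))
  d3$fold_change[2] <- NA
  p3 <- ExpressionPanel(d3)
  expect_equal(nrow(panelData(p3)), nrow(d3))
  expect_equal(attr(panelData(p3), "flagged"), 2L)
})

test_that("ternarize implements the significant two-fold rule", {
  d <- makePanelDf("g")[1, ]
  cases <- list(list(1.0, 1.0, 0L), list(4.0, 0.001, 1L),
                list(0.25, 0.001, -1L), list(4.0, 0.2, 0L),
                list(2.0, 0.05, 1L), list(0.5, 0.05, -1L),
                list(1.9, 0.001, 0L))
  for (cs in cases) {
    d$fold_change <- cs[[1]]; d$p <- cs[[2]]
    tp <- ternarize(ExpressionPanel(d))
    expect_identical(ternaryCalls(tp)$call, cs[[3]],
                     info = sprintf("fold %g p %g", cs[[1]], cs[[2]]))
  }
})

test_that("ternarize properties: scale consistency and sign mirror", {
  set.seed(5)
  for (rep in 1:20) {
    d <- makePanelDf(paste0("g", 1:6), times = c(0.5, 1, 2))
    d$fold_change <- exp(rnorm(nrow(d), 0, 1.5))
    d$p <- runif(nrow(d))
    panel <- ExpressionPanel(d)
    c0 <- ternaryCalls(ternarize(panel, foldThreshold = 2))$call
    ## multiplying folds and threshold by c leaves calls unchanged
    dScaled <- d; dScaled$fold_change <- d$fold_change * 3
    expect_identical(
      ternaryCalls(ternarize(ExpressionPanel(dScaled),
                             foldThreshold = 6))$call[d$fold_change >= 1],
      c0[d$fold_change >= 1])
    ## reciprocal folds mirror the call sign at equal p
    dInv <- d; dInv$fold_change <- 1 / d$fold_change
    expect_identical(ternaryCalls(ternarize(ExpressionPanel(dInv)))$call,
                     -c0)
  }
})

test_that("regulated genes: any nonzero call, monotone in the threshold", {
  d <- makePanelDf(paste0("g", 1:5), times = c(0.5, 1))
  panel0 <- ExpressionPanel(d)
  expect_length(regulatedGenes(ternarize(panel0), "LPS"), 0)

  set.seed(9)
  d$fold_change <- exp(rnorm(nrow(d), 0, 1.2))
  d$p <- 0.01
  panel <- ExpressionPanel(d)
  prev <- Inf
  for (thr in c(1.5, 2, 4, 8)) {
    ng <- length(regulatedGenes(ternarize(panel, foldThreshold = thr),
                                "LPS"))
    expect_lte(ng, prev)
    prev <- ng
  }
})

test_that("co-expression recovers planted correlation structure", {
  set.seed(11)
  x <- rnorm(50)
  raw <- cbind(a = x, b = -x, c = rnorm(50))
  cx <- coexpression(raw)
  expect_equal(unname(diag(cx$cc)), c(1, 1, 1))
  expect_equal(unname(cx$cc["a", "b"]), -1)
  ## planted rho = 0.9
  z <- rnorm(50)
  raw2 <- cbind(g1 = z, g2 = 0.9 * z + sqrt(1 - 0.81) * rnorm(50))
  expect_lt(abs(coexpression(raw2)$cc["g1", "g2"] - 0.9), 0.1)
  ## too few complete pairs -> undefined
  raw3 <- cbind(p = c(1, 2, NA, NA, NA), q = c(NA, 2, 3, 1, NA))
  expect_true(is.na(coexpression(raw3)$cc["p", "q"]))
})

test_that("concordance scores model/data upregulation agreement", {
  mac <- buildRefinedModel()
  pol <- simulatePolarization(mac, "M1")
  scenarios <- generateTernaryScenarios(mac, c(0, 1, 5), seed = 3,
                                        condition = "M1")
  c0 <- concordance(scenarios[[1]], pol, condition = "M1")
  expect_equal(c0$fraction, 1.0)
  c1 <- concordance(scenarios[[2]], pol, condition = "M1")
  expect_equal(sum(c1$table$category %in% c("data_only", "model_only")), 1)
  c5 <- concordance(scenarios[[3]], pol, condition = "M1")
  expect_equal(sum(c5$table$category %in% c("data_only", "model_only")), 5)
  ## unmapped gene names are reported, not fatal
  odd <- scenarios[[1]]
  odd@calls$gene[odd@calls$gene == "Tnf"] <- "NotAGene"
  cOdd <- concordance(odd, pol, condition = "M1")
  expect_true("NotAGene" %in% cOdd$unmapped)
})
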