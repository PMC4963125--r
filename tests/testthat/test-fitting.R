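smallModel <- function() {
  buildOdeModel(c("GeneA", "GeneB"), c(GeneA = "u1", GeneB = "u1"),
                character(0), character(0))
}

smallTruth <- function(seed = 1, cv = 0, n = 3) {
  model <- smallModel()
  kin <- odeStates(model)
  kin$ks_true <- c(80, 30)
  kin$kd_true <- c(1.5, 0.8)
  syntheticTruth(model, kinetics = kin, cv = cv, n = n, seed = seed)
}

test_that("chi2 is the weighted residual sum of squares", {
  model <- smallModel()
  truth <- smallTruth()
  par <- truthParameters(truth)
  sim <- simulateClosedForm(model, par, c(0.5, 1, 2, 6, 10))
  d <- data.frame(gene = sim$gene, condition = sim$condition,
                  time_h = sim$time_h, fold_change = sim$value,
                  sd = 0.5, n = 3, p = 0.01)
  panel <- ExpressionPanel(d)
  ## simulated == data -> 0
  expect_equal(chiSquare(model, par, panel), 0)
  ## one point off by exactly one SD -> 1
  d1 <- d; d1$fold_change[4] <- d1$fold_change[4] + d1$sd[4]
  expect_equal(chiSquare(model, par, ExpressionPanel(d1)), 1)
  ## equals an independently coded residual sum on random parameters
  set.seed(21)
  for (rep in 1:10) {
    p2 <- par
    p2[grep("^k", names(p2))] <- p2[grep("^k", names(p2))] *
      exp(rnorm(4, 0, 0.3))
    simRef <- simulateClosedForm(model, p2, c(0.5, 1, 2, 6, 10))
    ref <- sum(((simRef$value - d$fold_change) / pmax(d$sd, 0.05))^2)
    expect_equal(chiSquare(model, p2, panel), ref)
  }
  ## SEM weighting divides the SD by sqrt(n)
  expect_equal(chiSquare(model, par, ExpressionPanel(d1), weight = "sem"),
               (d1$sd[4] / (d1$sd[4] / sqrt(3)))^2)
  ## unmapped points are an error
  dBad <- d; dBad$gene[1] <- "Nope"
  expect_error(chiSquare(model, par, ExpressionPanel(dBad)),
               class = "macpol_validation_error")
})

test_that("noiseless synthetic data are recovered almost exactly", {
  truth <- smallTruth(seed = 4, cv = 0)
  model <- truth@model
  panel <- generatePanel(truth)$panel
  fit <- fitOdeModel(model, panel, nStarts = 2, seed = 7)
  true <- truthParameters(truth)
  expect_lt(fit@chi2, 1e-4)
  for (pn in c("ks_GeneA_LPS", "ks_GeneB_LPS", "kd_GeneA", "kd_GeneB"))
    expect_lt(abs(fit@par[[pn]] - true[[pn]]) / true[[pn]], 0.01)
  ## window recovery to well below the sampling resolution
  expect_lt(abs(fit@par[["t_p65_off"]] - true[["t_p65_off"]]), 0.1)
})

test_that("fits are reproducible and monotone in the number of starts", {
  truth <- smallTruth(seed = 8, cv = 0.15)
  model <- truth@model
  panel <- generatePanel(truth)$panel
  f1 <- fitOdeModel(model, panel, nStarts = 1, seed = 5)
  f2 <- fitOdeModel(model, panel, nStarts = 1, seed = 5)
  expect_identical(f1@par, f2@par)
  expect_identical(f1@chi2, f2@chi2)
  f3 <- fitOdeModel(model, panel, nStarts = 4, seed = 5)
  ## more starts can only improve the optimum (up to solver round-off)
  expect_lte(f3@chi2, f1@chi2 * (1 + 1e-4))
})

test_that("profile likelihood: optimum anchoring, CIs, classification", {
  truth <- smallTruth(seed = 12, cv = 0.1)
  model <- truth@model
  panel <- generatePanel(truth)$panel
  fit <- fitOdeModel(model, panel, nStarts = 3, seed = 2)
  pc <- profileLikelihood(model, panel, fit, "kd_GeneA")
  ## the profile passes through and never undercuts the optimum
  expect_equal(min(pc@chi2), fit@chi2)
  expect_true(all(pc@chi2 >= fit@chi2 - 1e-6 * max(fit@chi2, 1)))
  expect_equal(pc@threshold, fit@chi2 + 1.0)
  ## a well-sampled degradation rate is identifiable with a finite CI
  expect_equal(pc@classification, "identifiable")
  expect_true(pc@ciLower < truth@kinetics$kd_true[1] &&
                truth@kinetics$kd_true[1] < pc@ciUpper)

  ## a synthesis rate the sampling design never observes is flat:
  ## window entirely after the last sample time
  modelU <- smallModel()
  kin <- odeStates(modelU)
  kin$ks_true <- c(80, 30); kin$kd_true <- c(1.5, 0.8)
  truthU <- syntheticTruth(
    modelU, windows = list(p65 = c(23, 46) / 60, Stat3 = c(0.78, 9.9),
                           Stat6 = c(0.08, 0.78), repressor = c(0.5, 1.3)),
    kinetics = kin, cv = 0.1, seed = 3)
  panelU <- generatePanel(truthU)$panel
  dU <- panelData(panelU)
  dU <- dU[dU$gene != "GeneB" | dU$time_h <= 0, ]  # GeneB never observed
  ## give GeneB a window beyond every remaining sample: profile its ks
  fitU <- fitOdeModel(modelU, ExpressionPanel(
    panelData(panelForModel(ExpressionPanel(dU), modelU))),
    nStarts = 2, seed = 9)
  pcU <- profileLikelihood(modelU, ExpressionPanel(
    panelData(panelForModel(ExpressionPanel(dU), modelU))),
    fitU, "ks_GeneB_LPS")
  expect_match(pcU@classification, "non_identifiable")
})
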