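defaultPars <- function(model = buildOdeModel()) {
  truthParameters(syntheticTruth(model))
}

test_that("model structure: states and parameter bookkeeping", {
  om <- buildOdeModel()
  expect_equal(nrow(odeStates(om)), 23)
  expect_length(odeParameters(om), 47)
  expect_equal(sum(grepl("^t_", odeParameters(om))), 8)
  expect_equal(sum(grepl("^k", odeParameters(om))), 39)
  expect_equal(sum(grepl("^ks_", odeParameters(om))), 23)
  expect_equal(sum(grepl("^kd_", odeParameters(om))), 16)

  ## smallest model: one gene, one condition
  om1 <- buildOdeModel("Tnf", c(Tnf = "u1"), character(0), character(0))
  expect_equal(nrow(odeStates(om1)), 1)
  expect_equal(sum(grepl("^k", odeParameters(om1))), 2)

  ## g genes, d dual: states g + d, rate constants 2g + d
  set.seed(2)
  for (rep in 1:10) {
    g <- sample(3:10, 1)
    genes <- paste0("G", seq_len(g))
    d <- sample(0:g, 1)
    dual <- sample(genes, d)
    dUp <- sample(0:d, 1)
    om2 <- buildOdeModel(genes,
                         setNames(sample(c("u1", "u2", "u3"), g, TRUE),
                                  genes),
                         m2Up = head(dual, dUp),
                         m2Down = tail(dual, d - dUp))
    expect_equal(nrow(odeStates(om2)), g + d)
    expect_equal(sum(grepl("^k", odeParameters(om2))), 2 * g + d)
  }

  ## invalid assignments are rejected
  expect_error(buildOdeModel("Tnf", c(Tnf = "u5"), character(0),
                             character(0)),
               class = "macpol_validation_error")
  expect_error(buildOdeModel("Tnf", c(Tnf = "u1"), "Ccl2", character(0)),
               class = "macpol_validation_error")
  expect_error(buildOdeModel(c("Tnf", "Ccl2"),
                             c(Tnf = "u1", Ccl2 = "u2"), "Ccl2", "Ccl2"),
               class = "macpol_validation_error")
})

test_that("closed form: steady states, limits and edge cases", {
  om <- buildOdeModel("Tnf", c(Tnf = "u1"), character(0), character(0))
  par <- defaultPars(om)
  ## synthesis off: flat at the scaled control level 1
  par0 <- par; par0["ks_Tnf_LPS"] <- 1e-9
  tr <- simulateClosedForm(om, par0, seq(0, 10, by = 0.5))
  expect_equal(tr$value, rep(1, nrow(tr)), tolerance = 1e-6)
  ## long window: X approaches 1 + ks/kd
  parL <- par
  parL[c("t_p65_on", "t_p65_off")] <- c(0.01, 1000)
  trL <- simulateClosedForm(om, parL, c(0, 500))
  expect_equal(trL$value[trL$time_h == 500],
               1 + parL[["ks_Tnf_LPS"]] / parL[["kd_Tnf"]],
               tolerance = 1e-6)
  ## value at t = 0 is 1 (steady state before stimulation)
  expect_equal(tr$value[tr$time_h == 0], 1)
  ## empty time vector -> empty trajectory
  expect_equal(nrow(simulateClosedForm(om, par, numeric(0))), 0)
  expect_equal(nrow(simulateNumeric(om, par, numeric(0))), 0)
  expect_error(checkParams(om, par[-1]),
               class = "macpol_validation_error")
})

test_that("closed form matches numeric integration on random draws", {
  om <- buildOdeModel(c("A", "B"), c(A = "u1", B = "u2"), "A", "B")
  set.seed(31)
  times <- c(0.5, 1, 2, 6, 10)
  for (rep in 1:40) {
    par <- defaultPars(om)
    par[grep("^ks_", names(par))] <- exp(runif(4, log(0.5), log(200)))
    par[grep("^kd_", names(par))] <- exp(runif(2, log(0.05), log(5)))
    ons <- runif(4, 0.05, 3)
    par[grep("_on$", names(par))] <- ons
    par[grep("_off$", names(par))] <- ons + exp(runif(4, log(0.1), log(8)))
    ## keep the repressed state positive
    par["ks_B_IL4_13"] <- 0.9 * par[["kd_B"]]
    cf <- simulateClosedForm(om, par, times)
    nm <- simulateNumeric(om, par, times)
    expect_lt(max(abs(cf$value - nm$value) / pmax(abs(cf$value), 1e-6)),
              1e-8)
  }
})

test_that("trajectory shape properties", {
  om <- buildOdeModel(c("A", "B"), c(A = "u1", B = "u1"), "A", "B")
  par <- defaultPars(om)
  par["ks_B_IL4_13"] <- 0.9 * par[["kd_B"]]
  tt <- seq(0, 48, by = 0.05)
  tr <- simulateClosedForm(om, par, tt)
  ## positivity for induced states; bounded-repression state stays > 0
  expect_true(all(tr$value > 0))
  ## return to the scaled steady state long after all windows close
  expect_equal(tr$value[tr$time_h == 48], rep(1, 4), tolerance = 1e-3)
  ## time-shift equivariance
  delta <- 0.75
  parS <- par
  winPars <- grep("^t_", names(par), value = TRUE)
  parS[winPars] <- par[winPars] + delta
  trS <- simulateClosedForm(om, parS, tt + delta)
  expect_equal(trS$value, tr$value, tolerance = 1e-9)
})
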