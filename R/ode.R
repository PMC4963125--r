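#' @include AllClasses.R logic-model.R macrophage.R
NULL

TFA_REGULATORS <- c("p65", "Stat3", "Stat6", "repressor")

TFA_PAR_NAMES <- as.vector(t(outer(paste0("t_", TFA_REGULATORS),
                                   c("on", "off"), paste, sep = "_")))

#' Transcription-factor activity windows
#'
#' Each regulator is active on a single window (t_on, t_off), 0 < t_on <
#' t_off, in hours. The five model inputs derive from the windows as
#' indicator functions: u1 = p65, u2 = p65 union Stat3, u3 = Stat3,
#' u4 = Stat6, u5 = repressor.
#'
#' @param p65,Stat3,Stat6,repressor numeric c(on, off) in hours
#' @return named list of validated windows
#' @export
tfaWindows <- function(p65, Stat3, Stat6, repressor) {
  w <- list(p65 = p65, Stat3 = Stat3, Stat6 = Stat6, repressor = repressor)
  for (nm in names(w)) {
    stopifnot(length(w[[nm]]) == 2)
    if (!(w[[nm]][1] > 0 && w[[nm]][1] < w[[nm]][2]))
      stopValidation("window for %s must satisfy 0 < t_on < t_off", nm)
  }
  w
}

## windows from a full parameter vector (t_<reg>_on / t_<reg>_off entries)
windowsFromPar <- function(params) {
  list(p65 = c(params[["t_p65_on"]], params[["t_p65_off"]]),
       Stat3 = c(params[["t_Stat3_on"]], params[["t_Stat3_off"]]),
       Stat6 = c(params[["t_Stat6_on"]], params[["t_Stat6_off"]]),
       repressor = c(params[["t_repressor_on"]],
                     params[["t_repressor_off"]]))
}

## active intervals (matrix with columns on, off) of an input u1..u5
inputIntervals <- function(input, windows) {
  iv <- switch(input,
               u1 = rbind(windows$p65),
               u2 = rbind(windows$p65, windows$Stat3),
               u3 = rbind(windows$Stat3),
               u4 = rbind(windows$Stat6),
               u5 = rbind(windows$repressor),
               stop("unknown input id: ", input))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  ## merge overlaps (u2 union)
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[k, 2])
    else merged <- rbind(merged, iv[k, ])
  }
  unname(merged)
}

## merged active intervals together with the window parameter owning each
## surviving edge (edges swallowed by a union merge carry no sensitivity);
## returns a list with fields a, b, onPar, offPar and nrow() support via
## length(a). Only u2 (p65 union Stat3) can need a merge.
inputIntervalsLabeled <- function(input, windows) {
  one <- function(reg)
    list(a = windows[[reg]][1], b = windows[[reg]][2],
         onPar = paste0("t_", reg, "_on"),
         offPar = paste0("t_", reg, "_off"))
  if (input != "u2")
    return(one(switch(input, u1 = "p65", u3 = "Stat3", u4 = "Stat6",
                      u5 = "repressor",
                      stop("unknown input id: ", input))))
  w1 <- one("p65"); w2 <- one("Stat3")
  if (w1$a > w2$a) { tmp <- w1; w1 <- w2; w2 <- tmp }
  if (w2$a <= w1$b) {        # overlapping: union is one interval
    if (w2$b > w1$b) list(a = w1$a, b = w2$b, onPar = w1$onPar,
                          offPar = w2$offPar)
    else w1
  } else {
    list(a = c(w1$a, w2$a), b = c(w1$b, w2$b),
         onPar = c(w1$onPar, w2$onPar),
         offPar = c(w1$offPar, w2$offPar))
  }
}

## indicator u(t) for vector t
inputValue <- function(input, t, windows) {
  iv <- inputIntervals(input, windows)
  u <- numeric(length(t))
  for (k in seq_len(nrow(iv)))
    u[t >= iv[k, 1] & t < iv[k, 2]] <- 1
  u
}

DEFAULT_LPS_INPUTS <- c(
  Tnf = "u1", Il1b = "u1", Il6 = "u1", Cxcl1 = "u1", Cxcl2 = "u1",
  Cxcl3 = "u1", Ifnb1 = "u1",
  Il10 = "u2", Socs3 = "u2", Ccl2 = "u2", Ccl5 = "u2", Ccl7 = "u2",
  Il1rn = "u2",
  Socs1 = "u3", Ccl3 = "u3", Ccl4 = "u3")

DEFAULT_M2_UP <- c("Ccl2", "Ccl7", "Il1rn", "Socs1")
DEFAULT_M2_DOWN <- c("Ccl3", "Cxcl3", "Ccl4")

#' Build the ODE model of mRNA expression
#'
#' One scaled state per regulated gene-condition pair with dynamics
#' dX/dt = kd + s * ks * u(t) - kd * X, X(0) = 1 (fold of untreated
#' control). Every LPS-regulated gene contributes an LPS state; genes also
#' regulated under IL-4/13 (dual genes) contribute a second state with its
#' own synthesis rate (u4, s = +1, Stat6-driven upregulation, or u5,
#' s = -1, repression) but the same degradation constant, so with g genes
#' of which d are dual the model has g + d states and 2g + d rate
#' constants; with the default 16 genes / 7 dual genes that is 23 states
#' and 23 + 16 + 8 = 47 free parameters (the 8 being the TF window times).
#'
#' @param m1Genes LPS-regulated genes
#' @param lpsInputs named character, gene -> "u1"/"u2"/"u3"
#' @param m2Up dual genes upregulated via Stat6 (input u4)
#' @param m2Down dual genes repressed under IL-4/13 (input u5)
#' @return an [ODEExpressionModel-class]
#' @export
buildOdeModel <- function(m1Genes = M1_GENES,
                          lpsInputs = DEFAULT_LPS_INPUTS,
                          m2Up = DEFAULT_M2_UP,
                          m2Down = DEFAULT_M2_DOWN) {
  if (length(bad <- setdiff(m1Genes, names(lpsInputs))))
    stopValidation("no LPS input assignment for gene(s): %s",
                   paste(bad, collapse = ", "), ids = bad)
  if (!all(lpsInputs[m1Genes] %in% c("u1", "u2", "u3")))
    stopValidation("LPS-condition genes must use inputs u1-u3 (u4/u5 are IL-4/13 inputs)")
  if (length(bad <- setdiff(c(m2Up, m2Down), m1Genes)))
    stopValidation("dual gene(s) not among the LPS-regulated genes: %s",
                   paste(bad, collapse = ", "), ids = bad)
  if (length(bad <- intersect(m2Up, m2Down)))
    stopValidation("gene(s) assigned both u4 and u5: %s",
                   paste(bad, collapse = ", "), ids = bad)
  blocks <- list(
    data.frame(gene = m1Genes, condition = "LPS",
               input = unname(lpsInputs[m1Genes]), sign = 1,
               stringsAsFactors = FALSE))
  if (length(m2Up))
    blocks <- c(blocks, list(
      data.frame(gene = m2Up, condition = "IL4_13", input = "u4",
                 sign = 1, stringsAsFactors = FALSE)))
  if (length(m2Down))
    blocks <- c(blocks, list(
      data.frame(gene = m2Down, condition = "IL4_13", input = "u5",
                 sign = -1, stringsAsFactors = FALSE)))
  states <- do.call(rbind, blocks)
  states$state <- paste(states$gene, states$condition, sep = ".")
  states$ks <- paste("ks", states$gene, states$condition, sep = "_")
  states$kd <- paste("kd", states$gene, sep = "_")
  parNames <- c(states$ks, unique(states$kd), TFA_PAR_NAMES)
  new("ODEExpressionModel",
      states = states[, c("state", "gene", "condition", "input", "sign",
                          "ks", "kd")],
      genes = unique(states$gene), parNames = parNames)
}

#' State table of an ODE expression model
#' @param model an [ODEExpressionModel-class]
#' @return data.frame of states
#' @export
odeStates <- function(model) model@states

#' Free parameter names of an ODE expression model
#' @param model an [ODEExpressionModel-class]
#' @return character vector
#' @export
odeParameters <- function(model) model@parNames

setMethod("show", "ODEExpressionModel", function(object) {
  cat("ODEExpressionModel:", nrow(object@states), "states (",
      length(object@genes), "genes ),", length(object@parNames),
      "free parameters\n")
  cat("  inputs:",
      paste(sprintf("%s (%d)", names(table(object@states$input)),
                    table(object@states$input)), collapse = ", "), "\n")
})

checkParams <- function(model, params) {
  miss <- setdiff(model@parNames, names(params))
  if (length(miss))
    stopValidation("missing parameter(s): %s", paste(miss, collapse = ", "),
                   ids = miss)
  kd <- params[unique(model@states$kd)]
  if (any(kd <= 0)) stopValidation("degradation constants must be > 0")
  windowsFromPar(params)  # validates window availability
  invisible(TRUE)
}

## Exact solution for one state on its piecewise-constant input. With
## X(0) = 1 the solution is the convolution
##   X(t) = 1 + s ks int_0^t exp(-kd (t - tau)) u(tau) dtau,
## which over the disjoint active intervals [a, b] of u evaluates to
##   X(t) = 1 + (s ks / kd) sum ( exp(-kd max(t-b, 0))
##                              - exp(-kd max(t-a, 0)) ).
closedFormState <- function(ks, kd, s, intervals, times) {
  out <- rep(1, length(times))
  for (k in seq_len(nrow(intervals))) {
    eb <- exp(-kd * pmax(times - intervals[k, 2], 0))
    ea <- exp(-kd * pmax(times - intervals[k, 1], 0))
    out <- out + s * ks / kd * (eb - ea)
  }
  out
}

## value plus analytic derivatives w.r.t. ks, kd and each interval edge;
## dA and dB are nTimes x nIntervals matrices
closedFormStateGrad <- function(ks, kd, s, intervals, times) {
  nI <- nrow(intervals)
  value <- rep(1, length(times))
  dkd <- numeric(length(times))
  dA <- matrix(0, length(times), nI)
  dB <- matrix(0, length(times), nI)
  for (k in seq_len(nI)) {
    a <- intervals[k, 1]; b <- intervals[k, 2]
    beta <- pmax(times - b, 0); alpha <- pmax(times - a, 0)
    eb <- exp(-kd * beta); ea <- exp(-kd * alpha)
    value <- value + s * ks / kd * (eb - ea)
    dkd <- dkd + s * ks * (-(eb - ea) / kd^2 +
                             (-beta * eb + alpha * ea) / kd)
    dA[, k] <- -s * ks * ea * (times > a)
    dB[, k] <- s * ks * eb * (times > b)
  }
  list(value = value, dks = (value - 1) / ks, dkd = dkd, dA = dA, dB = dB)
}

#' Simulate the ODE expression model analytically
#'
#' On every interval where the step input u is constant the solution is the
#' exponential relaxation X(t) = Xss + (X(t0) - Xss) exp(-kd (t - t0)) with
#' Xss = 1 + s ks u / kd; breakpoints at the window edges are inserted
#' automatically, making the trajectory exact to machine precision.
#'
#' @param model an [ODEExpressionModel-class]
#' @param params full named parameter vector (rate constants and window
#'   times)
#' @param times sorted non-negative times (h)
#' @return tidy data.frame (state, gene, condition, time_h, value)
#' @export
simulateClosedForm <- function(model, params, times) {
  checkParams(model, params)
  stopifnot(all(times >= 0), !is.unsorted(times))
  if (!length(times))
    return(data.frame(state = character(), gene = character(),
                      condition = character(), time_h = numeric(),
                      value = numeric()))
  windows <- windowsFromPar(params)
  st <- model@states
  do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    iv <- inputIntervals(st$input[i], windows)
    data.frame(state = st$state[i], gene = st$gene[i],
               condition = st$condition[i], time_h = times,
               value = closedFormState(params[[st$ks[i]]],
                                       params[[st$kd[i]]],
                                       st$sign[i], iv, times),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate the ODE expression model numerically
#'
#' Stiff-capable integration (deSolve::lsoda) with the integration split at
#' every discontinuity of the step inputs.
#'
#' @inheritParams simulateClosedForm
#' @param rtol,atol integration tolerances
#' @return tidy data.frame (state, gene, condition, time_h, value)
#' @export
simulateNumeric <- function(model, params, times, rtol = 1e-10,
                            atol = 1e-12) {
  checkParams(model, params)
  stopifnot(all(times >= 0), !is.unsorted(times))
  if (!length(times))
    return(data.frame(state = character(), gene = character(),
                      condition = character(), time_h = numeric(),
                      value = numeric()))
  windows <- windowsFromPar(params)
  st <- model@states
  do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    iv <- inputIntervals(st$input[i], windows)
    ks <- params[[st$ks[i]]]; kd <- params[[st$kd[i]]]; s <- st$sign[i]
    edges <- sort(unique(c(iv)))
    edges <- edges[edges > 0 & edges < max(times)]
    breaks <- unique(c(0, edges, max(times)))
    x <- 1
    vals <- numeric(length(times))
    vals[times == 0] <- 1
    for (seg in seq_len(length(breaks) - 1L)) {
      t0 <- breaks[seg]; t1 <- breaks[seg + 1L]
      mid <- (t0 + t1) / 2
      u <- any(mid >= iv[, 1] & mid < iv[, 2])
      inSeg <- times > t0 & times <= t1
      tOut <- unique(c(t0, times[inSeg], t1))
      sol <- deSolve::lsoda(
        y = c(X = x), times = tOut,
        func = function(t, y, p) list(kd + s * ks * as.numeric(u) - kd * y),
        parms = NULL, rtol = rtol, atol = atol)
      if (any(inSeg))
        vals[inSeg] <- sol[match(times[inSeg], sol[, "time"]), "X"]
      x <- unname(sol[nrow(sol), "X"])  # deSolve keeps the state name
    }
    data.frame(state = st$state[i], gene = st$gene[i],
               condition = st$condition[i], time_h = times, value = vals,
               stringsAsFactors = FALSE)
  }))
}
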