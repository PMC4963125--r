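#' @include ode.R expression.R
NULL

## Parameter bookkeeping. Optimization runs in a transformed space:
## log(ks), log(kd) for rate constants; window times as (t_on, log duration)
## so that t_on < t_off holds by construction. Window times profiled or
## otherwise fixed are handled on the natural scale.

DEFAULT_BOUNDS <- list(ks = c(1e-3, 1e3), kd = c(1e-3, 10),
                       t_on = c(0.01, 12), dur = c(0.01, 24))

parInfo <- function(model) {
  nm <- model@parNames
  type <- ifelse(grepl("^ks_", nm), "ks",
          ifelse(grepl("^kd_", nm), "kd",
          ifelse(grepl("_on$", nm), "on", "off")))
  reg <- ifelse(type %in% c("on", "off"),
                sub("^t_(.*)_(on|off)$", "\\1", nm), NA)
  data.frame(name = nm, type = type, regulator = reg,
             stringsAsFactors = FALSE)
}

## fast weighted chi2 closure with analytic gradient; precomputes the
## panel -> state mapping and vectorizes over the states sharing an input
## function. Returns function(params, gradient = FALSE); with gradient =
## TRUE the result carries attr "gradient", a named vector over the
## model's natural parameters.
makeChi2 <- function(model, panel, sigmaFloor = 0.05,
                     weight = c("sd", "sem")) {
  weight <- match.arg(weight)
  d <- panelData(panel)
  d <- d[stats::complete.cases(d), ]
  d$stateKey <- paste(d$gene, d$condition, sep = ".")
  st <- model@states
  bad <- setdiff(unique(d$stateKey), st$state)
  if (length(bad))
    stopValidation("panel point(s) map to no model state: %s",
                   paste(bad, collapse = ", "), ids = bad)
  sigma <- if (weight == "sem") d$sd / sqrt(d$n) else d$sd
  sigma <- pmax(sigma, sigmaFloor)
  parNames <- model@parNames
  ## one dense block per input id: times x states matrices of data,
  ## weights and a mask for missing cells
  blocks <- lapply(split(seq_len(nrow(st)),
                         factor(st$input, unique(st$input))),
                   function(ix) {
    rows <- which(d$stateKey %in% st$state[ix])
    tt <- sort(unique(d$time_h[rows]))
    m <- length(ix)
    Y <- matrix(0, length(tt), m)
    S <- matrix(1, length(tt), m)
    M <- matrix(0, length(tt), m)
    col <- match(d$stateKey[rows], st$state[ix])
    row <- match(d$time_h[rows], tt)
    Y[cbind(row, col)] <- d$fold_change[rows]
    S[cbind(row, col)] <- sigma[rows]
    M[cbind(row, col)] <- 1
    list(input = st$input[ix[1]], tt = tt, Y = Y, S = S, M = M,
         ksName = st$ks[ix], kdName = st$kd[ix], s = st$sign[ix])
  })
  function(params, gradient = FALSE) {
    windows <- windowsFromPar(params)
    chi2 <- 0
    grad <- if (gradient) stats::setNames(numeric(length(parNames)),
                                          parNames)
    for (bl in blocks) {
      iv <- inputIntervalsLabeled(bl$input, windows)
      ks <- unname(params[bl$ksName]); kd <- unname(params[bl$kdName])
      sk <- bl$s * ks / kd
      tt <- bl$tt
      nI <- length(iv$a)
      EA <- EB <- vector("list", nI)
      G <- 0
      for (r in seq_len(nI)) {
        alpha <- pmax(tt - iv$a[r], 0); beta <- pmax(tt - iv$b[r], 0)
        EA[[r]] <- exp(-outer(alpha, kd)); EB[[r]] <- exp(-outer(beta, kd))
        G <- G + (EB[[r]] - EA[[r]])
      }
      X <- 1 + sweep(G, 2, sk, "*")
      R <- (X - bl$Y) / bl$S * bl$M
      chi2 <- chi2 + sum(R * R)
      if (gradient) {
        W2 <- 2 * R / bl$S
        ## d chi2 / d ks
        grad[bl$ksName] <- grad[bl$ksName] +
          colSums(W2 * sweep(G, 2, bl$s / kd, "*"))
        ## d chi2 / d kd (shared kd names accumulate)
        dkd <- 0
        for (r in seq_len(nI)) {
          alpha <- pmax(tt - iv$a[r], 0); beta <- pmax(tt - iv$b[r], 0)
          dkd <- dkd + (-sweep(EB[[r]] - EA[[r]], 2, 1 / kd, "*") -
                          beta * EB[[r]] + alpha * EA[[r]])
        }
        kdContrib <- colSums(W2 * sweep(dkd, 2, bl$s * ks / kd, "*"))
        for (j in seq_along(bl$kdName))
          grad[bl$kdName[j]] <- grad[bl$kdName[j]] + kdContrib[j]
        ## d chi2 / d window edges
        for (r in seq_len(nI)) {
          onMask <- tt > iv$a[r]; offMask <- tt > iv$b[r]
          grad[iv$onPar[r]] <- grad[iv$onPar[r]] +
            sum(colSums((W2 * EA[[r]]) * onMask) * (-bl$s * ks))
          grad[iv$offPar[r]] <- grad[iv$offPar[r]] +
            sum(colSums((W2 * EB[[r]]) * offMask) * (bl$s * ks))
        }
      }
    }
    if (gradient) attr(chi2, "gradient") <- grad
    chi2
  }
}

#' Weighted chi-square of the ODE model against a panel
#'
#' Sum over all complete panel points of ((sim - mean) / max(SD,
#' sigmaFloor))^2, where sim is the closed-form model value for the
#' matching gene-condition state at the sampling time. With \code{weight =
#' "sem"} the standard error of the mean replaces the SD.
#'
#' @param model an [ODEExpressionModel-class]
#' @param params full named parameter vector
#' @param panel an [ExpressionPanel-class]
#' @param sigmaFloor lower bound on the weighting sigma (fold units;
#'   default 0.05, i.e. 5 percent of the control level)
#' @param weight "sd" (default) or "sem"
#' @return the chi-square value
#' @export
chiSquare <- function(model, params, panel, sigmaFloor = 0.05,
                      weight = c("sd", "sem")) {
  checkParams(model, params)
  makeChi2(model, panel, sigmaFloor, match.arg(weight))(params)
}

## natural <-> transformed packing with an optional set of fixed naturals
packTheta <- function(info, params, fixed = character()) {
  theta <- c(); lower <- c(); upper <- c()
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]; type <- info$type[i]
    if (nm %in% fixed) next
    if (type %in% c("ks", "kd")) {
      theta[paste0("L_", nm)] <- log(params[[nm]])
      lower[paste0("L_", nm)] <- log(DEFAULT_BOUNDS[[type]][1])
      upper[paste0("L_", nm)] <- log(DEFAULT_BOUNDS[[type]][2])
    } else if (type == "on") {
      offName <- paste0("t_", info$regulator[i], "_off")
      theta[nm] <- params[[nm]]
      lower[nm] <- DEFAULT_BOUNDS$t_on[1]
      upper[nm] <- if (offName %in% fixed)
        params[[offName]] - 1e-3 else DEFAULT_BOUNDS$t_on[2]
    } else {  # off -> log duration unless its t_on is fixed too
      onName <- paste0("t_", info$regulator[i], "_on")
      dnm <- paste0("D_", info$regulator[i])
      theta[dnm] <- log(max(params[[nm]] - params[[onName]], 1e-4))
      lower[dnm] <- log(DEFAULT_BOUNDS$dur[1])
      upper[dnm] <- log(DEFAULT_BOUNDS$dur[2])
    }
  }
  list(theta = theta, lower = lower, upper = upper)
}

## one bounded local minimization in transformed space (analytic
## gradient). The natural <-> transformed mapping is compiled once into
## integer index vectors so the per-iteration cost is a handful of
## vectorized operations; the gradient evaluation is memoized because
## L-BFGS-B requests fn and gr at the same point.
localFit <- function(chi2fn, info, start, fixed = numeric(),
                     maxit = 400) {
  start[names(fixed)] <- fixed
  pk <- packTheta(info, start, names(fixed))
  pk$theta <- pmin(pmax(pk$theta, pk$lower), pk$upper)
  thetaNames <- names(pk$theta)
  nTheta <- length(pk$theta)

  ## compile the transform plan
  template <- stats::setNames(numeric(nrow(info)), info$name)
  template[names(fixed)] <- fixed
  isFixed <- info$name %in% names(fixed)
  ## NB: paste0("x", character(0)) yields "x", so every derived index is
  ## built conditionally on its row set being non-empty
  safeMatch <- function(prefix, x, suffix = "", table) {
    if (!length(x)) integer(0) else match(paste0(prefix, x, suffix), table)
  }
  rateRows <- which(info$type %in% c("ks", "kd") & !isFixed)
  ratePos <- safeMatch("L_", info$name[rateRows], "", thetaNames)
  onRows <- which(info$type == "on" & !isFixed)
  onPos <- if (length(onRows)) match(info$name[onRows], thetaNames)
           else integer(0)
  onOffIdx <- safeMatch("t_", info$regulator[onRows], "_off", info$name)
  onOffFree <- !isFixed[onOffIdx]
  offRows <- which(info$type == "off" & !isFixed)
  offPos <- safeMatch("D_", info$regulator[offRows], "", thetaNames)
  offOnIdx <- safeMatch("t_", info$regulator[offRows], "_on", info$name)

  unpack <- function(th) {
    params <- template
    params[rateRows] <- exp(th[ratePos])
    params[onRows] <- th[onPos]
    params[offRows] <- params[offOnIdx] + exp(th[offPos])
    params
  }
  lastTheta <- NULL; lastVal <- NULL; lastGrad <- NULL
  eval2 <- function(th) {
    if (!is.null(lastTheta) && identical(th, lastTheta)) return()
    params <- unpack(th)
    v <- chi2fn(params, gradient = TRUE)
    gn <- attr(v, "gradient")
    g <- numeric(nTheta)
    g[ratePos] <- gn[rateRows] * params[rateRows]
    g[onPos] <- gn[onRows] + ifelse(onOffFree, gn[onOffIdx], 0)
    g[offPos] <- gn[offRows] * (params[offRows] - params[offOnIdx])
    lastTheta <<- th; lastVal <<- as.numeric(v); lastGrad <<- g
  }
  obj <- function(th) { eval2(th); lastVal }
  gr <- function(th) { eval2(th); lastGrad }
  res <- stats::optim(pk$theta, obj, gr, method = "L-BFGS-B",
                      lower = pk$lower, upper = pk$upper,
                      control = list(maxit = maxit, factr = 1e7))
  list(par = unpack(res$par), value = res$value,
       convergence = res$convergence)
}

randomStart <- function(info, seedWindows = NULL) {
  params <- numeric(nrow(info)); names(params) <- info$name
  for (i in seq_len(nrow(info))) {
    type <- info$type[i]
    params[i] <- switch(type,
      ks = exp(stats::runif(1, log(0.05), log(200))),
      kd = exp(stats::runif(1, log(0.02), log(5))),
      on = stats::runif(1, 0.05, 4),
      off = 0)
  }
  for (r in unique(stats::na.omit(info$regulator))) {
    on <- params[[paste0("t_", r, "_on")]]
    params[paste0("t_", r, "_off")] <-
      on + exp(stats::runif(1, log(0.2), log(10)))
  }
  params
}

## submodel restricted to a subset of states (keeps all window parameters)
subModel <- function(model, stateIdx) {
  st <- model@states[stateIdx, , drop = FALSE]
  new("ODEExpressionModel", states = st, genes = unique(st$gene),
      parNames = c(st$ks, unique(st$kd), TFA_PAR_NAMES))
}

## staged initialization: the chi2 decomposes over regulator blocks
## (u1 -> p65; u2, u3 -> Stat3 given p65; u4 -> Stat6; u5 -> repressor),
## coupled only through shared kd's. Window basins are separated by the
## sampling grid (moving an edge across a sample time is a gradient
## barrier), so each block's window is located by a deterministic scan
## over candidate windows with rates-only fits, then refined with the
## window free. Shared kd's stay free per block; the joint polish
## reconciles them along the ks/kd ridge. Returns a full natural-scale
## start vector.
stagedStart <- function(model, panel, sigmaFloor, weight, maxit = 300,
                        init = NULL) {
  info <- parInfo(model)
  st <- model@states
  start <- if (is.null(init)) randomStart(info) else init
  d <- panelData(panel)
  maxDev <- tapply(abs(d$fold_change - 1),
                   paste(d$gene, d$condition, sep = "."), max)
  onGrid <- c(0.05, 0.2, 0.4, 0.6, 1, 1.5, 2.5)
  durGrid <- c(0.2, 0.5, 1, 2, 4, 8, 12)
  ## on the first pass Stat3 is unknown, so p65 is located on the u1 block
  ## alone; when refining from a previous fit the u2 block (p65 union
  ## Stat3, with Stat3 pinned) also informs the p65 window
  stages <- if (is.null(init))
    list(p65 = "u1", Stat3 = c("u2", "u3"), Stat6 = "u4", repressor = "u5")
  else
    list(p65 = c("u1", "u2"), Stat3 = c("u2", "u3"), Stat6 = "u4",
         repressor = "u5")
  for (reg in names(stages)) {
    idx <- which(st$input %in% stages[[reg]])
    if (!length(idx)) next
    sm <- subModel(model, idx)
    sp <- panelForModel(panel, sm)
    if (!nrow(panelData(sp))) next
    subInfo <- parInfo(sm)
    subChi2 <- makeChi2(sm, sp, sigmaFloor, weight)
    ownWin <- paste0("t_", reg, c("_on", "_off"))
    otherWin <- setdiff(grep("^t_", sm@parNames, value = TRUE), ownWin)
    ## rate start for this block: moment-matched on the first pass, the
    ## current estimate when refining from an earlier fit
    blockStart <- start
    if (is.null(init)) {
      for (i in idx) {
        mv <- maxDev[st$state[i]]
        if (is.na(mv)) mv <- 0.5
        blockStart[st$kd[i]] <- 1
        blockStart[st$ks[i]] <- if (st$sign[i] < 0) 0.5 else
          min(max(mv, 0.5), DEFAULT_BOUNDS$ks[2])
      }
    }
    best <- NULL
    for (a in onGrid) for (dur in durGrid) {
      cand <- blockStart
      cand[ownWin] <- c(a, min(a + dur, DEFAULT_BOUNDS$t_on[2] +
                                 DEFAULT_BOUNDS$dur[2]))
      fx <- stats::setNames(cand[c(otherWin, ownWin)],
                            c(otherWin, ownWin))
      res <- tryCatch(localFit(subChi2, subInfo, cand, fixed = fx,
                               maxit = 40),
                      error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    if (!is.null(best)) {
      ## refine with the window free
      fx <- stats::setNames(best$par[otherWin], otherWin)
      res <- tryCatch(localFit(subChi2, subInfo, best$par, fixed = fx,
                               maxit = maxit),
                      error = function(e) NULL)
      if (!is.null(res) && res$value < best$value) best <- res
      free <- setdiff(names(best$par), otherWin)
      start[free] <- best$par[free]
    }
  }
  start
}

## coordinate basin-hopping over window edges: restart the joint fit with
## one window edge moved to a candidate anchored at the sampling grid
## (basins of the window likelihood are delimited by the sample times),
## keep any restart that improves the optimum
refineWindows <- function(chi2fn, info, best, times, usedRegs, st,
                          maxDev, maxit = 120, rounds = 2,
                          fixed = numeric(), twoPhase = TRUE) {
  times <- sort(unique(times))
  mids <- (utils::head(times, -1) + utils::tail(times, -1)) / 2
  cand <- sort(unique(c(0.05, 0.15, 0.3, times, mids,
                        1.2 * max(times), 2 * max(times))))
  winPars <- setdiff(info$name[info$type %in% c("on", "off") &
                                 info$regulator %in% usedRegs],
                     names(fixed))
  for (round in seq_len(rounds)) {
    improved <- FALSE
    for (pn in winPars) {
      reg <- info$regulator[info$name == pn]
      isOn <- info$type[info$name == pn] == "on"
      onName <- paste0("t_", reg, "_on")
      offName <- paste0("t_", reg, "_off")
      other <- best$par[[if (isOn) offName else onName]]
      for (v in cand) {
        if (abs(v - best$par[[pn]]) < 0.15 * max(v, best$par[[pn]])) next
        q <- best$par
        if (isOn && v >= other) {
          ## translate the whole window, keeping its duration
          dur <- best$par[[offName]] - best$par[[onName]]
          q[onName] <- v
          q[offName] <- v + dur
          if (offName %in% names(fixed)) next
        } else if (!isOn && v <= other) {
          dur <- best$par[[offName]] - best$par[[onName]]
          q[offName] <- v
          q[onName] <- max(v - dur, DEFAULT_BOUNDS$t_on[1])
          if (onName %in% names(fixed)) next
        } else {
          q[pn] <- v
        }
        ## rates tuned to the old window would pull the probe straight
        ## back into its basin: amplitude-match the synthesis rates of
        ## the states this regulator drives to the new duration
        inputsOfReg <- switch(reg, p65 = c("u1", "u2"),
                              Stat3 = c("u2", "u3"), Stat6 = "u4",
                              repressor = "u5")
        durOld <- best$par[[offName]] - best$par[[onName]]
        durNew <- q[[offName]] - q[[onName]]
        for (i in which(st$input %in% inputsOfReg)) {
          kd <- q[[st$kd[i]]]
          scale <- (1 - exp(-kd * durOld)) / (1 - exp(-kd * durNew))
          q[st$ks[i]] <- min(max(q[[st$ks[i]]] * scale,
                                 DEFAULT_BOUNDS$ks[1]),
                             DEFAULT_BOUNDS$ks[2])
        }
        ## synthesis rates collapsed onto the bound carry no window
        ## signal; reseed them so the probe is informative
        for (i in which(q[st$ks] <= 2 * DEFAULT_BOUNDS$ks[1] &
                          maxDev[st$state] > 0.5)) {
          q[st$ks[i]] <- if (st$sign[i] < 0) 0.9 * q[[st$kd[i]]] else
            min(maxDev[[st$state[i]]] * max(q[[st$kd[i]]], 0.2),
                DEFAULT_BOUNDS$ks[2])
        }
        ## two-phase probe: settle the rates with the probed window
        ## pinned, then release it -- otherwise the rates of the old
        ## basin can drag the window straight back
        if (twoPhase) {
          pinNames <- setdiff(c(onName, offName), names(fixed))
          pin <- c(fixed, stats::setNames(q[pinNames], pinNames))
          pre <- tryCatch(localFit(chi2fn, info, q, fixed = pin,
                                   maxit = 60),
                          error = function(e) NULL)
          if (!is.null(pre)) q <- pre$par
        }
        res <- tryCatch(localFit(chi2fn, info, q, fixed = fixed,
                                 maxit = maxit),
                        error = function(e) NULL)
        if (!is.null(res) && res$value < best$value - 1e-8) {
          best <- res
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best
}

#' Calibrate the ODE expression model by multi-start least squares
#'
#' Draws \code{nStarts} start points (rates log-uniform, window times
#' uniform on-time with log-uniform duration), runs a bounded local
#' weighted least-squares minimization from each (L-BFGS-B in a transformed
#' space where t_on < t_off holds by construction) and returns the best
#' local optimum. Reproducible for a fixed seed.
#'
#' @inheritParams chiSquare
#' @param nStarts number of random starts (>= 1)
#' @param seed integer seed for the start draws
#' @param startAt optional named parameter vector used as an additional
#'   first start (e.g. a previous fit)
#' @param staged use the block-staged initialization (locating each
#'   regulator's window on its own gene block first) as one extra start
#' @param refine run the post-fit refinement (stagewise re-scan and
#'   coordinate basin-hopping over window edges)
#' @param maxit iteration cap per local optimization
#' @return a [FitResult-class]
#' @export
fitOdeModel <- function(model, panel, nStarts = 50, seed = 1,
                        sigmaFloor = 0.05, weight = c("sd", "sem"),
                        startAt = NULL, staged = TRUE, refine = staged,
                        maxit = 400) {
  stopifnot(nStarts >= 1)
  weight <- match.arg(weight)
  info <- parInfo(model)
  chi2fn <- makeChi2(model, panel, sigmaFloor, weight)
  set.seed(seed)
  stagedInit <- if (staged)
    tryCatch(stagedStart(model, panel, sigmaFloor, weight),
             error = function(e) NULL)
  ## restart the stream so the first nStarts draws do not depend on how
  ## much randomness the staged initialization consumed: increasing
  ## nStarts then only extends the candidate set
  set.seed(seed)
  starts <- lapply(seq_len(nStarts), function(k) randomStart(info))
  if (!is.null(stagedInit)) starts <- c(list(stagedInit), starts)
  if (!is.null(startAt)) starts <- c(list(startAt[info$name]), starts)
  fits <- vector("list", length(starts))
  diag <- data.frame(start = seq_along(starts), chi2 = NA_real_,
                     convergence = NA_integer_, error = NA_character_)
  for (k in seq_along(starts)) {
    fits[[k]] <- tryCatch(localFit(chi2fn, info, starts[[k]], maxit = maxit),
                          error = function(e) e)
    if (inherits(fits[[k]], "error")) {
      diag$error[k] <- conditionMessage(fits[[k]])
    } else {
      diag$chi2[k] <- fits[[k]]$value
      diag$convergence[k] <- fits[[k]]$convergence
    }
  }
  ok <- which(!is.na(diag$chi2))
  if (!length(ok)) {
    stop("all optimization starts failed:\n",
         paste(utils::head(stats::na.omit(diag$error), 5), collapse = "\n"))
  }
  st <- model@states
  best <- fits[[ok[which.min(diag$chi2[ok])]]]
  ## long final polish of the winning start
  pol <- tryCatch(localFit(chi2fn, info, best$par, maxit = 5000),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) best <- pol
  ## escape synthesis rates collapsed onto the lower bound while the data
  ## show clear regulation (a window/rate bound trap): re-seed them at a
  ## moment-matched magnitude and repolish
  d <- panelData(panel)
  maxDev <- tapply(abs(d$fold_change - 1),
                   paste(d$gene, d$condition, sep = "."), max)
  escapeStuck <- function(best) {
    stuck <- which(best$par[st$ks] <= 2 * DEFAULT_BOUNDS$ks[1] &
                     maxDev[st$state] > 0.5)
    if (!length(stuck)) return(best)
    q <- best$par
    for (i in stuck) {
      kdVal <- q[[st$kd[i]]]
      q[st$ks[i]] <- if (st$sign[i] < 0) 0.9 * kdVal
                     else min(maxDev[[st$state[i]]] * kdVal,
                              DEFAULT_BOUNDS$ks[2])
    }
    res <- tryCatch(localFit(chi2fn, info, q, maxit = 5000),
                    error = function(e) NULL)
    if (!is.null(res) && res$value < best$value) res else best
  }
  best <- escapeStuck(best)
  ## refinement: a second stagewise pass seeded from the polished optimum
  ## (multi-block models only -- it reconciles shared kd's across blocks)
  ## and coordinate basin-hopping on individual window edges
  if (refine) {
    if (length(unique(st$input)) > 1) {
      q <- tryCatch(stagedStart(model, panel, sigmaFloor, weight,
                                init = best$par),
                    error = function(e) NULL)
      if (!is.null(q)) {
        res <- tryCatch(localFit(chi2fn, info, q, maxit = 5000),
                        error = function(e) NULL)
        if (!is.null(res) && res$value < best$value) best <- res
      }
    }
    regsByInput <- list(u1 = "p65", u2 = c("p65", "Stat3"), u3 = "Stat3",
                        u4 = "Stat6", u5 = "repressor")
    usedRegs <- unique(unlist(regsByInput[unique(st$input)]))
    best <- refineWindows(chi2fn, info, best,
                          unique(panelData(panel)$time_h), usedRegs,
                          st, maxDev)
    best <- escapeStuck(best)
    pol2 <- tryCatch(localFit(chi2fn, info, best$par, maxit = 5000),
                     error = function(e) NULL)
    if (!is.null(pol2) && pol2$value < best$value) best <- pol2
  }
  new("FitResult", par = best$par, chi2 = best$value,
      nStarts = as.integer(length(starts)), seed = as.integer(seed),
      starts = diag, model = model)
}

#' Best-fit parameters
#' @param fit a [FitResult-class]
#' @return named numeric vector
#' @export
fittedParameters <- function(fit) fit@par

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: chi2 = %.4g after %d start(s) (seed %d)\n",
              object@chi2, object@nStarts, object@seed))
  w <- windowsFromPar(object@par)
  for (r in names(w))
    cat(sprintf("  %-10s active %.3f - %.3f h\n", r, w[[r]][1], w[[r]][2]))
})

#' Profile likelihood of one parameter
#'
#' The parameter is stepped down and up from its optimum (multiplicative
#' steps); at every grid value all other parameters are re-optimized by
#' weighted least squares, warm-started from the neighbouring grid point.
#' The pointwise confidence interval is where the profile crosses
#' best-chi2 + \code{deltaChi2} (default 1.0, the 1-sigma / 68 percent
#' rule); a side on which the profile never crosses before the parameter
#' bound is an open bound and marks practical non-identifiability on that
#' side.
#'
#' @inheritParams chiSquare
#' @param fit a converged [FitResult-class]
#' @param parameter name of the parameter to profile
#' @param fixed named values of parameters held fixed throughout (e.g.
#'   activity windows treated as known in a conditional analysis)
#' @param nGrid grid points per side
#' @param stepFactor multiplicative step between grid points
#' @param deltaChi2 chi2 increase defining the confidence level
#' @param maxit iteration cap per re-optimization
#' @return a [ProfileCurve-class]
#' @export
profileLikelihood <- function(model, panel, fit, parameter, nGrid = 8,
                              stepFactor = 10^0.25, deltaChi2 = 1.0,
                              sigmaFloor = 0.05, weight = c("sd", "sem"),
                              fixed = numeric(), maxit = 200) {
  weight <- match.arg(weight)
  info <- parInfo(model)
  if (!parameter %in% info$name)
    stopValidation("unknown parameter: %s", parameter, ids = parameter)
  chi2fn <- makeChi2(model, panel, sigmaFloor, weight)
  type <- info$type[info$name == parameter]
  bound <- switch(type, ks = DEFAULT_BOUNDS$ks, kd = DEFAULT_BOUNDS$kd,
                  c(1e-3, DEFAULT_BOUNDS$t_on[2] + DEFAULT_BOUNDS$dur[2]))
  opt <- fit@par[[parameter]]
  st <- model@states
  d <- panelData(panel)
  maxDev <- tapply(abs(d$fold_change - 1),
                   paste(d$gene, d$condition, sep = "."), max)
  regsByInput <- list(u1 = "p65", u2 = c("p65", "Stat3"), u3 = "Stat3",
                      u4 = "Stat6", u5 = "repressor")
  ## basin-hopping inside the profile only needs the windows coupled to
  ## the profiled parameter (its gene's inputs, or the window's own
  ## regulator and union partner)
  usedRegs <- if (type %in% c("ks", "kd")) {
    gene <- sub("_(LPS|IL4_13)$", "", sub("^k[sd]_", "", parameter))
    unique(unlist(regsByInput[st$input[st$gene == gene]]))
  } else {
    reg <- info$regulator[info$name == parameter]
    if (reg %in% c("p65", "Stat3")) c("p65", "Stat3") else reg
  }
  threshold <- fit@chi2 + deltaChi2

  oneSide <- function(direction) {
    vals <- c(); chis <- c()
    cur <- fit@par
    v <- opt
    prevBelow <- TRUE
    for (k in seq_len(nGrid)) {
      v <- if (direction > 0) v * stepFactor else v / stepFactor
      if (v < bound[1] || v > bound[2]) break
      ## keep windows feasible when moving a time parameter
      if (type == "on" && v >= cur[[sub("_on$", "_off", parameter)]])
        break
      if (type == "off" && v <= cur[[sub("_off$", "_on", parameter)]])
        break
      fx <- c(fixed, stats::setNames(v, parameter))
      res <- tryCatch(localFit(chi2fn, info, cur, fixed = fx,
                               maxit = maxit),
                      error = function(e) NULL)
      ## where the curve first exceeds the threshold, guard against a
      ## degrading warm path (restart from the unconstrained optimum)
      ## and against window-basin trapping (coordinate basin-hopping);
      ## both would overstate the profile exactly where the confidence
      ## bound is read off
      if (prevBelow && (is.null(res) || res$value > threshold)) {
        res0 <- tryCatch(localFit(chi2fn, info, fit@par, fixed = fx,
                                  maxit = maxit),
                         error = function(e) NULL)
        if (is.null(res) || (!is.null(res0) && res0$value < res$value))
          res <- res0
        if (!is.null(res) && res$value > threshold) {
          hop <- tryCatch(
            refineWindows(chi2fn, info, res, unique(d$time_h), usedRegs,
                          st, maxDev, maxit = 80, rounds = 1,
                          fixed = fx, twoPhase = FALSE),
            error = function(e) NULL)
          if (!is.null(hop) && hop$value < res$value) res <- hop
        }
      }
      if (is.null(res)) next  # flagged point; curve continues
      vals <- c(vals, v); chis <- c(chis, res$value)
      cur <- res$par
      prevBelow <- res$value <= threshold
    }
    list(vals = vals, chis = chis)
  }

  lo <- oneSide(-1); hi <- oneSide(+1)
  grid <- c(rev(lo$vals), opt, hi$vals)
  chi2 <- c(rev(lo$chis), fit@chi2, hi$chis)
  ## the profile can only be >= the unconstrained optimum; clip tiny
  ## numerical undershoots from re-optimization
  chi2 <- pmax(chi2, fit@chi2)

  crossing <- function(vals, chis) {
    ## first threshold crossing walking away from the optimum; the
    ## profile is locally quadratic, so interpolate linearly in
    ## sqrt(delta-chi2) (exact for a parabola -- plain linear
    ## interpolation of chi2 on a coarse grid would badly understate
    ## the interval)
    above <- which(chis > threshold)
    if (!length(above)) return(NA_real_)
    k <- above[1]
    if (k == 1) return(vals[1])
    v0 <- vals[k - 1]; v1 <- vals[k]
    s0 <- sqrt(max(chis[k - 1] - fit@chi2, 0))
    s1 <- sqrt(chis[k] - fit@chi2)
    sT <- sqrt(deltaChi2)
    v0 + (sT - s0) / (s1 - s0) * (v1 - v0)
  }
  ciLower <- crossing(c(opt, lo$vals), c(fit@chi2, pmax(lo$chis, fit@chi2)))
  ciUpper <- crossing(c(opt, hi$vals), c(fit@chi2, pmax(hi$chis, fit@chi2)))
  classification <-
    if (is.na(ciLower) && is.na(ciUpper)) "practically_non_identifiable_both"
    else if (is.na(ciLower)) "practically_non_identifiable_lower"
    else if (is.na(ciUpper)) "practically_non_identifiable_upper"
    else "identifiable"
  new("ProfileCurve", parameter = parameter, grid = grid, chi2 = chi2,
      chi2Optimum = fit@chi2, threshold = threshold,
      ciLower = ciLower, ciUpper = ciUpper,
      classification = classification)
}

setMethod("show", "ProfileCurve", function(object) {
  cat(sprintf("ProfileCurve for %s: %s\n", object@parameter,
              object@classification))
  cat(sprintf("  68%% CI: [%s, %s]\n",
              ifelse(is.na(object@ciLower), "open",
                     format(object@ciLower, digits = 4)),
              ifelse(is.na(object@ciUpper), "open",
                     format(object@ciUpper, digits = 4))))
})

#' Predicted transcription-factor activity windows
#'
#' Window times from a fit, in display units matching common reporting:
#' minutes when below one hour, hours otherwise. When profile curves for
#' window parameters are supplied, their confidence bounds are attached.
#'
#' @param fit a [FitResult-class]
#' @param profiles optional named list of [ProfileCurve-class] objects
#'   (names = parameter names)
#' @return data.frame (regulator, t_on_h, t_off_h, display, ci columns)
#' @export
predictTfa <- function(fit, profiles = NULL) {
  w <- windowsFromPar(fit@par)
  fmt <- function(t) ifelse(t < 1, sprintf("%.0f min", t * 60),
                            sprintf("%.2g h", t))
  out <- data.frame(regulator = names(w),
                    t_on_h = vapply(w, `[`, 0, 1),
                    t_off_h = vapply(w, `[`, 0, 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$display <- sprintf("%s - %s", fmt(out$t_on_h), fmt(out$t_off_h))
  for (side in c("on", "off")) {
    lo <- hi <- rep(NA_real_, nrow(out))
    for (i in seq_len(nrow(out))) {
      pn <- sprintf("t_%s_%s", out$regulator[i], side)
      if (!is.null(profiles[[pn]])) {
        lo[i] <- profiles[[pn]]@ciLower
        hi[i] <- profiles[[pn]]@ciUpper
      }
    }
    out[[paste0("t_", side, "_ci_lower")]] <- lo
    out[[paste0("t_", side, "_ci_upper")]] <- hi
  }
  out
}
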