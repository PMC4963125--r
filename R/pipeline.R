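#' @include macrophage.R expression.R synthetic.R io-export.R
NULL

#' Run the full characterization pipeline
#'
#' Binds the stages in their analysis order: encode/load the Boolean model,
#' compute M1/M2 logical steady states and the dependency matrix, obtain an
#' expression panel (read from file, or generate synthetically when none is
#' given), ternarize and score concordance against the Boolean predictions,
#' and optionally calibrate the ODE expression model. All intermediate
#' artifacts are persisted into \code{outDir} together with a provenance
#' record (configuration, seeds, package version), so a rerun with the same
#' configuration reproduces the bundle.
#'
#' @param config list with elements \code{outDir} (required), and
#'   optionally \code{model} (path to a model YAML; default the shipped
#'   refined macrophage model), \code{panel} (path to a panel CSV/XLSX;
#'   default: synthetic panel from the default truth), \code{seed}
#'   (default 1), \code{foldThreshold} (2), \code{alpha} (0.05), and
#'   \code{fit} (list; \code{enabled} = FALSE, \code{nStarts} = 10)
#' @return invisibly, a list with the stage results
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outDir))
    stopValidation("config lacks required field 'outDir'")
  if (!is.null(config$panel) && !file.exists(config$panel))
    stopValidation("panel file not found: %s", config$panel)
  if (!is.null(config$model) && !file.exists(config$model))
    stopValidation("model file not found: %s", config$model)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  foldThreshold <- if (is.null(config$foldThreshold)) 2
                   else config$foldThreshold
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  fitCfg <- utils::modifyList(list(enabled = FALSE, nStarts = 10),
                              if (is.null(config$fit)) list()
                              else config$fit)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$outDir, "")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  model <- stage("model", {
    if (is.null(config$model)) buildRefinedModel()
    else readLogicalModel(config$model)
  })

  patterns <- stage("lss", {
    pats <- list(M1 = simulatePolarization(model, "M1"),
                 M2 = simulatePolarization(model, "M2"))
    for (cond in names(pats)) {
      scen <- polarizationScenario(model, cond)
      writeLss(computeLSS(model, scen, max(model@timescales)),
               paste0(out, "lss_", cond, ".tsv"))
      utils::write.csv(polarizationCalls(pats[[cond]]),
                       paste0(out, "polarization_", cond, ".csv"))
    }
    pats
  })

  dm <- stage("depmatrix", {
    m <- dependencyMatrix(model, max(model@timescales))
    writeDependencyMatrix(m, paste0(out, "dependency_matrix.csv"))
    m
  })

  panel <- stage("panel", {
    if (!is.null(config$panel)) readPanel(config$panel)
    else generatePanel(syntheticTruth(seed = seed))$panel
  })

  ternary <- stage("ternarize", {
    tp <- ternarize(panel, foldThreshold, alpha)
    utils::write.csv(ternaryCalls(tp), paste0(out, "ternary_pattern.csv"),
                     row.names = FALSE)
    tp
  })

  conc <- stage("concordance", {
    cc <- list(M1 = concordance(ternary, patterns$M1, condition = "LPS"),
               M2 = concordance(ternary, patterns$M2, condition = "IL4_13"))
    for (cond in names(cc))
      utils::write.csv(cc[[cond]]$table,
                       paste0(out, "concordance_", cond, ".csv"),
                       row.names = FALSE)
    cc
  })

  fit <- NULL
  if (isTRUE(fitCfg$enabled)) {
    fit <- stage("ode-fit", {
      odeModel <- buildOdeModel()
      f <- fitOdeModel(odeModel, panelForModel(panel, odeModel),
                       nStarts = fitCfg$nStarts, seed = seed)
      jsonlite::write_json(
        list(chi2 = f@chi2, parameters = as.list(f@par),
             tfa = predictTfa(f)),
        paste0(out, "ode_fit.json"), auto_unbox = TRUE, digits = NA)
      f
    })
  }

  stage("provenance", {
    jsonlite::write_json(
      list(package = "macpol",
           version = as.character(utils::packageVersion("macpol")),
           seed = seed,
           config = config[setdiff(names(config), "outDir")],
           configHash = sum(utf8ToInt(paste(
             deparse(config[order(names(config))]), collapse = "")))),
      paste0(out, "provenance.json"), auto_unbox = TRUE, digits = NA)
  })

  invisible(list(model = model, patterns = patterns, dependency = dm,
                 panel = panel, ternary = ternary, concordance = conc,
                 fit = fit))
}
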