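#' @include AllGenerics.R logic-model.R
NULL

PANEL_COLUMNS <- c("gene", "condition", "time_h", "fold_change", "sd", "n",
                   "p")

#' Construct an expression panel from a data.frame
#'
#' @param data data.frame with columns gene, condition, time_h, fold_change,
#'   sd, n, p
#' @return an [ExpressionPanel-class]
#' @export
ExpressionPanel <- function(data) {
  miss <- setdiff(PANEL_COLUMNS, names(data))
  if (length(miss))
    stopValidation("panel lacks column(s): %s", paste(miss, collapse = ", "),
                   ids = miss)
  data <- as.data.frame(data)[PANEL_COLUMNS]
  for (col in c("time_h", "fold_change", "sd", "n", "p")) {
    if (!is.numeric(data[[col]])) {
      conv <- suppressWarnings(as.numeric(data[[col]]))
      if (anyNA(conv) && !all(is.na(data[[col]]) == is.na(conv)))
        stopValidation("non-numeric value(s) in column '%s'", col)
      data[[col]] <- conv
    }
  }
  key <- paste(data$gene, data$condition, data$time_h)
  if (anyDuplicated(key))
    stopValidation("duplicate (gene, condition, time) row(s): %s",
                   paste(unique(key[duplicated(key)]), collapse = "; "))
  complete <- stats::complete.cases(data)
  obj <- new("ExpressionPanel", data = data)
  attr(obj@data, "flagged") <- which(!complete)
  ok <- complete
  with_vals <- data[ok, ]
  if (any(with_vals$fold_change <= 0))
    stopValidation("fold_change must be > 0")
  if (any(with_vals$sd < 0) || any(with_vals$n < 1) ||
      any(with_vals$p < 0 | with_vals$p > 1))
    stopValidation("invalid sd/n/p value(s) in panel")
  obj
}

#' Read an expression panel from CSV or XLSX
#'
#' Expects the long layout of the deposited transcript-expression tables:
#' one row per (gene, condition, time point) with the mean fold change
#' versus untreated control, its standard deviation, the number of samples
#' and the p-value for regulation. Rows with missing values are flagged in
#' the \code{"flagged"} attribute of the panel data, not dropped.
#'
#' @param path CSV (comma-separated, header) or XLSX file
#' @return an [ExpressionPanel-class]
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stopValidation("panel file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stopValidation("reading XLSX panels requires the readxl package")
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  ExpressionPanel(df)
}

#' Panel data accessor
#' @param panel an [ExpressionPanel-class]
#' @return the underlying data.frame
#' @export
panelData <- function(panel) panel@data

setMethod("show", "ExpressionPanel", function(object) {
  d <- object@data
  cat("ExpressionPanel:", length(unique(d$gene)), "genes x",
      length(unique(d$condition)), "conditions x",
      length(unique(d$time_h)), "time points\n")
})

#' @rdname ternarize
#'
#' @details
#' A gene-condition-time cell is called +1 when its mean fold change is at
#' least \code{foldThreshold} with p <= \code{alpha}, -1 when the fold
#' change is at most 1/\code{foldThreshold} with p <= \code{alpha}, and 0
#' otherwise (balanced ternary transformation of the panel). Cells with
#' missing values are called NA.
#' @export
setMethod("ternarize", "ExpressionPanel",
          function(object, foldThreshold = 2, alpha = 0.05) {
  stopifnot(foldThreshold > 0, alpha >= 0, alpha <= 1)
  d <- object@data
  call <- ifelse(d$fold_change >= foldThreshold & d$p <= alpha, 1L,
          ifelse(d$fold_change <= 1 / foldThreshold & d$p <= alpha, -1L, 0L))
  new("TernaryPattern",
      calls = data.frame(gene = d$gene, condition = d$condition,
                         time_h = d$time_h, call = call,
                         stringsAsFactors = FALSE))
})

#' Ternary calls accessor
#' @param pattern a [TernaryPattern-class]
#' @return data.frame (gene, condition, time_h, call)
#' @export
ternaryCalls <- function(pattern) pattern@calls

setMethod("show", "TernaryPattern", function(object) {
  tab <- table(factor(object@calls$call, levels = c(-1, 0, 1)))
  cat("TernaryPattern:", nrow(object@calls), "calls (",
      tab[["-1"]], "down /", tab[["0"]], "unchanged /", tab[["1"]],
      "up )\n")
})

#' @rdname regulatedGenes
#' @export
setMethod("regulatedGenes", "TernaryPattern",
          function(object, condition = NULL) {
  d <- object@calls
  if (!is.null(condition)) d <- d[d$condition == condition, ]
  sort(unique(d$gene[!is.na(d$call) & d$call != 0L]))
})

#' Pairwise gene co-expression from per-sample centered CT values
#'
#' Pearson correlation over pairwise-complete samples; two genes are
#' co-expressed when their coefficient is close to 1. Pairs with fewer than
#' \code{minPairs} complete observations are reported as NA.
#'
#' @param raw numeric matrix, rows = samples, columns = genes, of per-sample
#'   CT values minus the gene's mean expression
#' @param minPairs minimum complete pairs (default 3)
#' @return list with \code{cc} (correlation matrix) and \code{nPairs}
#'   (complete-pair counts)
#' @export
coexpression <- function(raw, minPairs = 3) {
  raw <- as.matrix(raw)
  stopifnot(!is.null(colnames(raw)))
  cc <- suppressWarnings(stats::cor(raw, use = "pairwise.complete.obs"))
  ok <- !is.na(raw)
  nPairs <- crossprod(ok)
  cc[nPairs < minPairs] <- NA_real_
  diag(cc)[diag(nPairs) >= 1] <- 1
  list(cc = cc, nPairs = nPairs)
}

#' Default mapping from sampling times (h) to Boolean timescales
#' @export
DEFAULT_TIME_TAU_MAP <- c("0.5" = 5, "1" = 7, "2" = 10, "6" = 12, "10" = 15)

#' Concordance between ternarized data and Boolean simulation
#'
#' Compares upregulation calls: per (gene, time) cell the data call (+1 or
#' not) is matched against the model's mRNA steady state at the mapped
#' timescale. Downregulation (-1) is not represented by the Boolean
#' simulation and is excluded from the comparison (treated as not-up).
#' Gene names are reconciled through an alias map; unmapped genes are
#' listed in the result, not fatal.
#'
#' @param pattern a [TernaryPattern-class] (one condition is selected)
#' @param polarization a [PolarizationPattern-class]
#' @param condition condition label to select from \code{pattern}
#' @param timeTauMap named numeric, sampling time (h, as name) -> tau
#' @param aliases named character, panel gene -> model mRNA node id
#' @return list with \code{table} (per gene/time categories: match,
#'   model_only, data_only, neither), \code{fraction} (matches over all
#'   up-calls in either source) and \code{unmapped}
#' @export
concordance <- function(pattern, polarization, condition,
                        timeTauMap = DEFAULT_TIME_TAU_MAP,
                        aliases = MACROPHAGE_ALIASES) {
  d <- pattern@calls
  if (!missing(condition)) d <- d[d$condition == condition, ]
  d <- d[as.character(d$time_h) %in% names(timeTauMap), ]
  genes <- unique(d$gene)
  mapped <- aliases[genes]
  unmapped <- genes[is.na(mapped) | !(mapped %in% rownames(polarization@calls))]
  keep <- !(d$gene %in% unmapped)
  d <- d[keep, ]
  tauCol <- as.character(timeTauMap[as.character(d$time_h)])
  modelUp <- polarization@calls[cbind(aliases[d$gene], tauCol)] == 1L
  dataUp <- !is.na(d$call) & d$call == 1L
  category <- ifelse(modelUp & dataUp, "match",
              ifelse(modelUp & !dataUp, "model_only",
              ifelse(!modelUp & dataUp, "data_only", "neither")))
  tab <- data.frame(gene = d$gene, time_h = d$time_h, tau = as.integer(tauCol),
                    data_call = d$call, model_state = as.integer(modelUp),
                    category = category, stringsAsFactors = FALSE)
  denom <- sum(category %in% c("match", "model_only", "data_only"))
  list(table = tab,
       fraction = if (denom == 0) 1.0 else sum(category == "match") / denom,
       unmapped = unmapped)
}
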