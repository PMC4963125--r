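#' @import methods
NULL

## Central S4 classes. Ternary node states are represented throughout as
## integer vectors with values 1L (active), 0L (inactive) and NA_integer_
## (UNKNOWN, i.e. not uniquely determined by propagation from the inputs).

#' Logical interaction hypergraph with timescale constants
#'
#' A signed Boolean network in hypergraph form: each interaction (hyperarc)
#' is an AND over possibly negated source literals acting on one target;
#' several hyperarcs on the same target combine by OR. Every hyperarc carries
#' a timescale constant tau drawn from the model's declared timescale set,
#' ordering events chronologically (housekeeping, receptor signaling,
#' transcription, translation, secretion, feedback inhibition).
#'
#' @slot nodes data.frame with columns \code{id}, \code{label}, \code{kind};
#'   \code{kind} is one of \code{input}, \code{housekeeping},
#'   \code{signaling}, \code{mRNA}, \code{protein}, \code{secreted}.
#' @slot arcs list of hyperarcs; each is a list with elements \code{target}
#'   (node id), \code{literals} (data.frame with columns \code{node},
#'   \code{sign} in \code{"+"}/\code{"-"}) and \code{tau} (integer).
#' @slot timescales sorted integer vector of admissible tau values.
#'
#' @seealso [readLogicalModel()], [computeLSS()], [dependencyMatrix()]
#' @export
setClass("LogicalModel",
         representation(nodes = "data.frame",
                        arcs = "list",
                        timescales = "integer"))

#' Input/clamp scenario for logical steady-state analysis
#'
#' @slot inputs named numeric vector of 0/1 values covering every declared
#'   input node of the model.
#' @slot clamps named numeric vector of 0/1 values; clamped nodes override
#'   any arc evaluation (knockout = 0, forced activation = 1).
#' @export
setClass("Scenario",
         representation(inputs = "numeric", clamps = "numeric"))

#' Logical steady state of a timescale subnetwork
#'
#' @slot tau timescale at which the LSS was computed (arcs with tau' <= tau).
#' @slot states named integer vector, one entry per node: 1, 0 or NA
#'   (UNKNOWN).
#' @slot resolved TRUE iff no node is UNKNOWN.
#' @slot iterations number of synchronous sweeps until the fixed point.
#' @export
setClass("LSSResult",
         representation(tau = "integer", states = "integer",
                        resolved = "logical", iterations = "integer"))

#' All-pairs signed-path influence classification
#'
#' Each element (i, j) classifies the influence of species i on species j by
#' the signs of connecting paths in the signed digraph of the tau-subnetwork:
#' \code{no_influence}, \code{total_activator}, \code{nontotal_activator},
#' \code{total_inhibitor}, \code{nontotal_inhibitor} or \code{ambivalent}.
#' "Non-total" means at least one species on a connecting path lies on a
#' negative feedback loop.
#'
#' @slot categories character matrix, rows = source, columns = target, in
#'   model declaration order.
#' @slot tau timescale at which the matrix was computed.
#' @export
setClass("DependencyMatrix",
         representation(categories = "matrix", tau = "integer"))

#' Polarization pattern of the mRNA layer across timescales
#'
#' @slot condition "M1" or "M2" (or a free-text scenario label).
#' @slot calls integer matrix, rows = mRNA-kind nodes, columns = timescales
#'   (as character), entries 1/0/NA.
#' @export
setClass("PolarizationPattern",
         representation(condition = "character", calls = "matrix"))

#' Normalized expression panel (fold-change vs untreated control)
#'
#' Long-format container for per-gene, per-condition, per-time summaries of
#' qPCR fold changes: mean fold change, standard deviation, replicate count
#' and p-value for regulation versus untreated controls.
#'
#' @slot data data.frame with columns \code{gene}, \code{condition},
#'   \code{time_h}, \code{fold_change}, \code{sd}, \code{n}, \code{p}.
#' @export
setClass("ExpressionPanel", representation(data = "data.frame"))

#' Balanced ternary regulation calls
#'
#' @slot calls data.frame with columns \code{gene}, \code{condition},
#'   \code{time_h}, \code{call} (-1, 0, +1).
#' @export
setClass("TernaryPattern", representation(calls = "data.frame"))

#' Linear ODE model of mRNA expression with step-function TF activity
#'
#' One state per regulated gene-condition pair, with scaled dynamics
#' dX/dt = kd + s * ks * u(t) - kd * X, X(0) = 1, where u in {0, 1} is the
#' indicator of a transcription-factor activity window (u1 = p65,
#' u2 = p65 or Stat3, u3 = Stat3, u4 = Stat6, u5 = repressor; s = -1 for u5).
#' Genes regulated under both conditions share one degradation constant.
#'
#' @slot states data.frame with columns \code{state}, \code{gene},
#'   \code{condition}, \code{input}, \code{sign}, \code{ks}, \code{kd}
#'   (the latter two are parameter names).
#' @slot genes character vector of distinct gene names.
#' @slot parNames character vector of all free parameter names (ks's, kd's
#'   and the eight TF window time points).
#' @export
setClass("ODEExpressionModel",
         representation(states = "data.frame", genes = "character",
                        parNames = "character"))

#' Result of multi-start weighted least-squares calibration
#'
#' @slot par named numeric vector of best-fit parameters (natural scale).
#' @slot chi2 weighted residual sum of squares at the optimum.
#' @slot nStarts number of local optimizations performed.
#' @slot seed RNG seed used for start-point draws.
#' @slot starts data.frame of per-start diagnostics (chi2, convergence code).
#' @slot model the [ODEExpressionModel-class] that was fitted.
#' @export
setClass("FitResult",
         representation(par = "numeric", chi2 = "numeric",
                        nStarts = "integer", seed = "integer",
                        starts = "data.frame", model = "ODEExpressionModel"))

#' Profile-likelihood curve for one parameter
#'
#' @slot parameter parameter name.
#' @slot grid parameter values scanned (natural scale, includes the optimum).
#' @slot chi2 re-optimized chi2 at each grid value.
#' @slot chi2Optimum unconstrained optimum chi2.
#' @slot threshold chi2Optimum + delta-chi2 defining the pointwise CI.
#' @slot ciLower,ciUpper confidence bounds; NA means the profile never
#'   crossed the threshold on that side (open bound).
#' @slot classification one of \code{identifiable},
#'   \code{practically_non_identifiable_lower}, \code{..._upper},
#'   \code{..._both}.
#' @export
setClass("ProfileCurve",
         representation(parameter = "character", grid = "numeric",
                        chi2 = "numeric", chi2Optimum = "numeric",
                        threshold = "numeric", ciLower = "numeric",
                        ciUpper = "numeric", classification = "character"))

#' Ground truth for the synthetic panel generator
#'
#' @slot windows named list of c(on, off) activity windows in hours for
#'   p65, Stat3, Stat6 and the IL-4/13 repressor.
#' @slot kinetics data.frame of true per-state kinetic parameters.
#' @slot design list with elements \code{times}, \code{conditions}, \code{n}
#'   (replicates) and \code{cv} (lognormal coefficient of variation).
#' @slot seed integer seed making the generated panel reproducible.
#' @slot model the [ODEExpressionModel-class] the truth refers to.
#' @export
setClass("SyntheticTruth",
         representation(windows = "list", kinetics = "data.frame",
                        design = "list", seed = "integer",
                        model = "ODEExpressionModel"))
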