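#' @import methods
#' @importFrom stats rnorm dnorm pt sd cor aov TukeyHSD p.adjust convolve
#'   setNames qt
#' @importFrom utils write.table read.table packageVersion
#' @useDynLib painDCM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' DCMSpec: one hypothesized network structure
#'
#' A directed-graph hypothesis over a set of brain regions: which
#' interregional connections exist (self-connections are implicit and always
#' present), which regions receive the driving stimulus input, and which
#' family of propagation hypotheses the model belongs to.
#'
#' @slot regions ordered character vector of region labels
#'   (canonically \code{c("S1","AMY","h")}).
#' @slot edges two-column character matrix (\code{src}, \code{dst}) of
#'   directed interregional connections; never contains self-loops.
#' @slot inputTargets regions receiving the driving input.
#' @slot familyId integer family membership (1-3 for the canonical space).
#' @slot modelId integer model identifier (1-16 for the canonical space).
#'
#' @seealso [enumeratePaperModels()], [specToAdjacency()]
#' @export
setClass("DCMSpec",
  representation(
    regions = "character",
    edges = "matrix",
    inputTargets = "character",
    familyId = "integer",
    modelId = "integer"
  )
)

setValidity("DCMSpec", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2 && nrow(e) > 0)
    msg <- c(msg, "edges must be a 2-column (src, dst) matrix")
  if (nrow(e) > 0) {
    if (!all(e %in% object@regions))
      msg <- c(msg, "edge endpoint not a member of regions")
    if (any(e[, 1] == e[, 2]))
      msg <- c(msg, "self-connections are implicit and must not be listed")
    key <- paste(e[, 1], e[, 2], sep = "->")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate edges")
  }
  if (!all(object@inputTargets %in% object@regions))
    msg <- c(msg, "inputTargets must be a subset of regions")
  if (anyDuplicated(object@regions))
    msg <- c(msg, "duplicated region labels")
  if (length(msg)) msg else TRUE
})

#' Construct a DCMSpec
#'
#' @param regions character vector of region labels.
#' @param edges two-column character matrix or a list of
#'   \code{c(src, dst)} pairs; may be empty.
#' @param inputTargets regions receiving the driving input.
#' @param familyId,modelId integer identifiers (default \code{NA}).
#' @return a [DCMSpec-class] object.
#' @export
DCMSpec <- function(regions, edges = NULL, inputTargets = regions[1],
                    familyId = NA_integer_, modelId = NA_integer_) {
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2)
  } else if (is.list(edges)) {
    edges <- do.call(rbind, edges)
  }
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("src", "dst")))
  new("DCMSpec", regions = regions, edges = edges,
      inputTargets = inputTargets,
      familyId = as.integer(familyId), modelId = as.integer(modelId))
}

#' StimulusDesign: block-design stimulus timing
#'
#' Square-wave (boxcar) stimulus timing for one scanning run: stimulus
#' onsets and durations in seconds, the repetition time, and the number of
#' scans acquired.
#'
#' @slot onsets numeric, onset times (s), strictly increasing.
#' @slot durations numeric, one duration (s) per onset; blocks do not
#'   overlap.
#' @slot TR repetition time (s).
#' @slot nScans number of scans.
#' @export
setClass("StimulusDesign",
  representation(onsets = "numeric", durations = "numeric",
                 TR = "numeric", nScans = "integer")
)

setValidity("StimulusDesign", function(object) {
  msg <- character()
  o <- object@onsets; d <- object@durations
  if (length(o) != length(d))
    msg <- c(msg, "onsets and durations must have equal length")
  if (length(o)) {
    if (any(o < 0)) msg <- c(msg, "onsets must be nonnegative")
    if (is.unsorted(o, strictly = TRUE))
      msg <- c(msg, "onsets must be strictly increasing")
    if (length(o) > 1 && any(o[-length(o)] + d[-length(d)] > o[-1] + 1e-9))
      msg <- c(msg, "stimulus blocks overlap")
  }
  if (object@TR <= 0) msg <- c(msg, "TR must be positive")
  if (object@nScans < 1) msg <- c(msg, "nScans must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusDesign
#'
#' @param onsets,durations numeric vectors (seconds).
#' @param TR repetition time (seconds).
#' @param nScans number of scans in the run.
#' @return a [StimulusDesign-class] object.
#' @export
StimulusDesign <- function(onsets, durations, TR, nScans) {
  new("StimulusDesign", onsets = as.numeric(onsets),
      durations = as.numeric(durations), TR = TR,
      nScans = as.integer(nScans))
}

#' NeuralParams: bilinear neural coupling parameters
#'
#' The A/B/C parameterization of bilinear neural dynamics
#' \eqn{dz/dt = (A + \sum_j u_j B^{(j)}) z + C u}: \code{A} holds intrinsic
#' effective connectivity in Hz (entry \eqn{(i,j)} is the influence of
#' region j on region i; the diagonal is self-inhibition and must be
#' negative), \code{B} input-dependent modulation (one matrix per input,
#' all-zero by default), and \code{C} driving-input weights.
#'
#' @slot A n x n numeric matrix (Hz).
#' @slot B list of n x n numeric matrices, one per input.
#' @slot C n x m numeric matrix of driving-input weights.
#' @export
setClass("NeuralParams",
  representation(A = "matrix", B = "list", C = "matrix")
)

setValidity("NeuralParams", function(object) {
  msg <- character()
  n <- nrow(object@A)
  if (ncol(object@A) != n) msg <- c(msg, "A must be square")
  if (any(diag(object@A) >= 0))
    msg <- c(msg, "diagonal of A (self-inhibition) must be strictly negative")
  if (nrow(object@C) != n) msg <- c(msg, "C must have one row per region")
  m <- ncol(object@C)
  if (length(object@B) != m)
    msg <- c(msg, "B must hold one matrix per input (column of C)")
  for (Bj in object@B) {
    if (!is.matrix(Bj) || any(dim(Bj) != n))
      msg <- c(msg, "each B matrix must be n x n")
  }
  if (length(msg)) msg else TRUE
})

#' Construct NeuralParams
#'
#' @param A square coupling matrix (Hz), negative diagonal.
#' @param C driving-input weight matrix (n x m), or a vector for a single
#'   input.
#' @param B optional list of modulatory matrices (default: all zero).
#' @return a [NeuralParams-class] object.
#' @export
NeuralParams <- function(A, C, B = NULL) {
  A <- as.matrix(A)
  if (!is.matrix(C)) C <- matrix(C, ncol = 1)
  if (is.null(B))
    B <- replicate(ncol(C), matrix(0, nrow(A), ncol(A)), simplify = FALSE)
  if (is.matrix(B)) B <- list(B)
  # slots assigned individually: an argument named "C" would partially
  # match new()'s Class formal
  obj <- new("NeuralParams")
  obj@A <- A; obj@B <- B; obj@C <- C
  validObject(obj)
  obj
}

#' HemoParams: balloon-Windkessel hemodynamic constants
#'
#' Region-level hemodynamic parameters mapping neural activity to the BOLD
#' signal: vasodilatory signal decay \code{kappa} (1/s), flow
#' autoregulation \code{gamma} (1/s), mean transit time \code{tau} (s),
#' Grubb vessel-stiffness exponent \code{alpha}, resting oxygen extraction
#' fraction \code{E0} and resting venous blood-volume fraction \code{V0}.
#'
#' @slot kappa,gamma,tau,alpha,E0,V0 numeric scalars.
#' @export
setClass("HemoParams",
  representation(kappa = "numeric", gamma = "numeric", tau = "numeric",
                 alpha = "numeric", E0 = "numeric", V0 = "numeric")
)

setValidity("HemoParams", function(object) {
  v <- c(object@kappa, object@gamma, object@tau, object@alpha,
         object@E0, object@V0)
  msg <- character()
  if (any(v <= 0)) msg <- c(msg, "all hemodynamic parameters must be positive")
  if (object@alpha >= 1) msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@E0 >= 1) msg <- c(msg, "E0 must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Default hemodynamic parameters
#'
#' Conventional balloon-Windkessel constants: kappa = 0.64/s, gamma =
#' 0.32/s, tau = 2 s, alpha = 0.32, E0 = 0.4, V0 = 0.04. All overridable.
#'
#' @param kappa,gamma,tau,alpha,E0,V0 numeric scalars.
#' @return a [HemoParams-class] object.
#' @export
HemoParams <- function(kappa = 0.64, gamma = 0.32, tau = 2.0,
                       alpha = 0.32, E0 = 0.4, V0 = 0.04) {
  new("HemoParams", kappa = kappa, gamma = gamma, tau = tau,
      alpha = alpha, E0 = E0, V0 = V0)
}

#' ROITimeSeries: per-subject multi-region BOLD series
#'
#' A scans x regions matrix of BOLD signal (percent signal change) sampled
#' at the repetition time, together with the stimulus design that produced
#' it.
#'
#' @slot series numeric matrix, scans x regions, column names are region
#'   labels.
#' @slot TR repetition time (s).
#' @slot design the [StimulusDesign-class] of the run.
#' @export
setClass("ROITimeSeries",
  representation(series = "matrix", TR = "numeric", design = "StimulusDesign")
)

setValidity("ROITimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@series)) msg <- c(msg, "series must be numeric")
  if (is.null(colnames(object@series)))
    msg <- c(msg, "series columns must be named by region")
  if (abs(object@TR - object@design@TR) > 1e-9)
    msg <- c(msg, "TR of series and design disagree")
  if (length(msg)) msg else TRUE
})

#' Construct an ROITimeSeries
#'
#' @param series scans x regions numeric matrix with region column names.
#' @param design the [StimulusDesign-class] used.
#' @return an [ROITimeSeries-class] object.
#' @export
ROITimeSeries <- function(series, design) {
  new("ROITimeSeries", series = series, TR = design@TR, design = design)
}

#' PriorSpec: Gaussian shrinkage priors for inversion
#'
#' Priors over the stacked free-parameter vector (A off-diagonals present
#' in the model, log self-connection scales, driving-input weights) and
#' over the log noise precision lambda.
#'
#' @slot mean named numeric vector of prior means.
#' @slot cov prior covariance matrix (diagonal by construction).
#' @slot lambdaMean,lambdaVar hyperprior over log noise precision.
#' @export
setClass("PriorSpec",
  representation(mean = "numeric", cov = "matrix",
                 lambdaMean = "numeric", lambdaVar = "numeric")
)

setValidity("PriorSpec", function(object) {
  msg <- character()
  p <- length(object@mean)
  if (any(dim(object@cov) != p))
    msg <- c(msg, "cov dimension must match mean length")
  if (!isSymmetric(unname(object@cov), tol = 1e-10))
    msg <- c(msg, "cov must be symmetric")
  ev <- eigen(object@cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) msg <- c(msg, "cov must be positive definite")
  if (object@lambdaVar <= 0) msg <- c(msg, "lambdaVar must be positive")
  if (length(msg)) msg else TRUE
})

#' PosteriorEstimate: Gaussian posterior from variational inversion
#'
#' @slot mu named posterior mean vector.
#' @slot Sigma posterior covariance matrix.
#' @slot lambda posterior log noise precision.
#' @slot F free energy (nats), the evidence lower bound used for model
#'   comparison.
#' @slot nIter outer iterations used.
#' @slot converged logical convergence flag.
#' @slot modelId identifier of the inverted model.
#' @slot Fhistory free energy at each accepted outer iteration.
#' @export
setClass("PosteriorEstimate",
  representation(mu = "numeric", Sigma = "matrix", lambda = "numeric",
                 F = "numeric", nIter = "integer", converged = "logical",
                 modelId = "integer", Fhistory = "numeric")
)

setValidity("PosteriorEstimate", function(object) {
  msg <- character()
  p <- length(object@mu)
  if (any(dim(object@Sigma) != p))
    msg <- c(msg, "Sigma dimension must match mu length")
  if (!isSymmetric(unname(object@Sigma), tol = 1e-6))
    msg <- c(msg, "Sigma must be symmetric")
  if (object@converged && !is.finite(object@F))
    msg <- c(msg, "F must be finite when converged")
  if (length(msg)) msg else TRUE
})

#' EvidenceTable: subjects x models free energies
#'
#' @slot F numeric matrix of free energies, one row per subject, one
#'   column per model.
#' @slot modelIds integer model identifiers (columns).
#' @slot familyIds integer family membership, one per model.
#' @export
setClass("EvidenceTable",
  representation(F = "matrix", modelIds = "integer", familyIds = "integer")
)

setValidity("EvidenceTable", function(object) {
  msg <- character()
  if (!all(is.finite(object@F))) msg <- c(msg, "free energies must be finite")
  if (length(object@modelIds) != ncol(object@F))
    msg <- c(msg, "one modelId per column required")
  if (length(object@familyIds) != ncol(object@F))
    msg <- c(msg, "one familyId per column required")
  if (length(msg)) msg else TRUE
})

#' Construct an EvidenceTable
#'
#' @param F subjects x models matrix of free energies (nats).
#' @param modelIds integer vector of model ids, one per column.
#' @param familyIds integer vector assigning each model to a family.
#' @return an [EvidenceTable-class] object.
#' @export
EvidenceTable <- function(F, modelIds, familyIds) {
  F <- as.matrix(F)
  new("EvidenceTable", F = F, modelIds = as.integer(modelIds),
      familyIds = as.integer(familyIds))
}

#' BMSResult: outcome of fixed-effects Bayesian model selection
#'
#' @slot pooledLogEvidence named per-model pooled (summed) free energies.
#' @slot modelPosterior single-stage posterior probabilities over all
#'   models.
#' @slot familyPosterior posterior probabilities over families.
#' @slot withinFamilyPosterior posteriors over models of the winning
#'   family, renormalized.
#' @slot winningFamily,winningModel integer identifiers.
#' @slot bayesFactor Bayes factor of the winning model against the
#'   runner-up within the winning family.
#' @export
setClass("BMSResult",
  representation(pooledLogEvidence = "numeric", modelPosterior = "numeric",
                 familyPosterior = "numeric",
                 withinFamilyPosterior = "numeric",
                 winningFamily = "integer", winningModel = "integer",
                 bayesFactor = "numeric")
)

setValidity("BMSResult", function(object) {
  msg <- character()
  if (abs(sum(object@modelPosterior) - 1) > 1e-9)
    msg <- c(msg, "model posteriors must sum to 1")
  if (abs(sum(object@familyPosterior) - 1) > 1e-9)
    msg <- c(msg, "family posteriors must sum to 1")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "DCMSpec", function(object) {
  cat("DCMSpec model", object@modelId, "(family", object@familyId, ")\n")
  cat(" regions:", paste(object@regions, collapse = ", "), "\n")
  if (nrow(object@edges))
    cat(" edges:  ",
        paste(object@edges[, 1], object@edges[, 2], sep = "->",
              collapse = ", "), "\n")
  else cat(" edges:   (none)\n")
  cat(" input -> ", paste(object@inputTargets, collapse = ", "), "\n")
})

setMethod("show", "ROITimeSeries", function(object) {
  cat("ROITimeSeries:", nrow(object@series), "scans x",
      ncol(object@series), "regions (",
      paste(colnames(object@series), collapse = ", "),
      "), TR =", object@TR, "s\n")
})

setMethod("show", "PosteriorEstimate", function(object) {
  cat("PosteriorEstimate (model", object@modelId, "): F =",
      format(object@F, digits = 6), "nats,",
      object@nIter, "iterations,",
      if (object@converged) "converged" else "NOT converged", "\n")
  print(round(object@mu, 4))
})

setMethod("show", "BMSResult", function(object) {
  cat("FFX Bayesian model selection\n")
  cat(" family posterior:",
      paste(sprintf("F%d=%.3f", seq_along(object@familyPosterior),
                    object@familyPosterior), collapse = " "), "\n")
  cat(" winning family:", object@winningFamily,
      " winning model:", object@winningModel,
      " BF vs runner-up:", format(object@bayesFactor, digits = 4), "\n")
})

# ---- accessors --------------------------------------------------------------

#' @rdname DCMSpec-class
#' @param object,x a package object.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname DCMSpec-class
#' @export
setMethod("regions", "DCMSpec", function(x) x@regions)
#' @rdname ROITimeSeries-class
#' @export
setMethod("regions", "ROITimeSeries", function(x) colnames(x@series))

#' @rdname DCMSpec-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname DCMSpec-class
#' @export
setMethod("edges", "DCMSpec", function(x) x@edges)

#' @rdname DCMSpec-class
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname DCMSpec-class
#' @export
setMethod("familyId", "DCMSpec", function(x) x@familyId)

#' @rdname DCMSpec-class
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname DCMSpec-class
#' @export
setMethod("modelId", "DCMSpec", function(x) x@modelId)
#' @rdname PosteriorEstimate-class
#' @export
setMethod("modelId", "PosteriorEstimate", function(x) x@modelId)

#' @rdname ROITimeSeries-class
#' @export
setGeneric("boldSeries", function(x) standardGeneric("boldSeries"))
#' @rdname ROITimeSeries-class
#' @export
setMethod("boldSeries", "ROITimeSeries", function(x) x@series)

#' @rdname ROITimeSeries-class
#' @export
setGeneric("stimDesign", function(x) standardGeneric("stimDesign"))
#' @rdname ROITimeSeries-class
#' @export
setMethod("stimDesign", "ROITimeSeries", function(x) x@design)

#' @rdname PosteriorEstimate-class
#' @export
setGeneric("posteriorMean", function(x) standardGeneric("posteriorMean"))
#' @rdname PosteriorEstimate-class
#' @export
setMethod("posteriorMean", "PosteriorEstimate", function(x) x@mu)

#' @rdname PosteriorEstimate-class
#' @export
setGeneric("freeEnergyOf", function(x) standardGeneric("freeEnergyOf"))
#' @rdname PosteriorEstimate-class
#' @export
setMethod("freeEnergyOf", "PosteriorEstimate", function(x) x@F)
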