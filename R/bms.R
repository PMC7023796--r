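#' Pool subject evidences under fixed effects
#'
#' Fixed-effects group log evidence: the sum of per-subject free energies
#' for each model (subjects are assumed to share one generating model, so
#' their log evidences add).
#'
#' @param table an [EvidenceTable-class].
#' @return named numeric vector of pooled log evidences (names = model
#'   ids).
#' @export
ffxPool <- function(table) {
  stopifnot(is(table, "EvidenceTable"))
  setNames(colSums(table@F), table@modelIds)
}

#' Posterior model probabilities from log evidences
#'
#' Softmax of pooled log evidence plus log prior, computed with
#' max-subtraction so no overflow occurs for |F| up to at least 1e4.
#'
#' @param pooled numeric vector of (pooled) log evidences.
#' @param prior prior model probabilities (default uniform); must sum
#'   to 1.
#' @return probabilities summing to 1.
#' @export
modelPosterior <- function(pooled,
                           prior = rep(1 / length(pooled), length(pooled))) {
  if (abs(sum(prior) - 1) > 1e-9) stop("prior must sum to 1")
  lp <- pooled + log(prior)
  lp <- lp - max(lp)
  w <- exp(lp)
  p <- w / sum(w)
  names(p) <- names(pooled)
  p
}

#' Family-level inference
#'
#' Posterior probability of each model family under a size-corrected
#' prior: the family prior (uniform by default) is split equally among a
#' family's member models, so unequal family sizes (e.g. the 4/4/8
#' partition of the canonical space) do not bias the comparison. The
#' family posterior is the sum of its members' model posteriors.
#'
#' @param table an [EvidenceTable-class].
#' @param familyPrior prior over families (default uniform).
#' @return list: \code{familyPosterior} (named by family id),
#'   \code{winningFamily}, and the underlying \code{modelPosterior}.
#' @export
familyInference <- function(table, familyPrior = NULL) {
  stopifnot(is(table, "EvidenceTable"))
  fams <- sort(unique(table@familyIds))
  if (is.null(familyPrior)) familyPrior <- rep(1 / length(fams), length(fams))
  if (length(familyPrior) != length(fams))
    stop("one prior entry per family required")
  sizes <- vapply(fams, function(f) sum(table@familyIds == f), 1L)
  if (any(sizes == 0)) stop("empty family")
  modelPrior <- familyPrior[match(table@familyIds, fams)] /
    sizes[match(table@familyIds, fams)]
  post <- modelPosterior(ffxPool(table), modelPrior)
  famPost <- vapply(fams, function(f) sum(post[table@familyIds == f]), 1)
  names(famPost) <- fams
  win <- fams[which.max(famPost)]
  list(familyPosterior = famPost, winningFamily = as.integer(win),
       modelPosterior = post)
}

#' Bayes factor between two log evidences
#'
#' \eqn{BF_{ij} = \exp(F_i - F_j)}; the log10 Bayes factor is reported
#' alongside.
#'
#' @param Fi,Fj log evidences (nats).
#' @return list with \code{bf} and \code{log10bf}.
#' @export
bayesFactor <- function(Fi, Fj) {
  list(bf = exp(Fi - Fj), log10bf = (Fi - Fj) / log(10))
}

#' Two-stage fixed-effects Bayesian model selection
#'
#' Stage 1 determines the winning family by [familyInference()]; stage 2
#' renormalizes the model posteriors within that family and picks the
#' highest-posterior member. Ties are broken toward the lowest model id
#' with a warning. The reported Bayes factor compares the winner with the
#' runner-up inside the winning family.
#'
#' @param table an [EvidenceTable-class].
#' @param familyPrior prior over families (default uniform,
#'   size-corrected).
#' @return a [BMSResult-class].
#' @export
selectModels <- function(table, familyPrior = NULL) {
  fam <- familyInference(table, familyPrior)
  pooled <- ffxPool(table)
  post <- fam$modelPosterior
  inFam <- table@familyIds == fam$winningFamily
  within <- post[inFam] / sum(post[inFam])
  mx <- max(within)
  tied <- which(abs(within - mx) < 1e-12)
  if (length(tied) > 1)
    warning("tie in model posteriors; breaking toward the lowest model id")
  winIdx <- tied[1]
  winId <- table@modelIds[inFam][winIdx]
  famPooled <- pooled[inFam]
  ord <- order(famPooled, decreasing = TRUE)
  bf <- if (length(famPooled) > 1)
    bayesFactor(famPooled[ord[1]], famPooled[ord[2]])$bf
  else Inf
  new("BMSResult", pooledLogEvidence = pooled, modelPosterior = post,
      familyPosterior = fam$familyPosterior,
      withinFamilyPosterior = within,
      winningFamily = fam$winningFamily,
      winningModel = as.integer(winId), bayesFactor = bf)
}

#' Assemble an EvidenceTable from fits
#'
#' @param fits list (subjects) of lists (models) of
#'   [PosteriorEstimate-class], or a subjects x models matrix of free
#'   energies.
#' @param specs model space (list of [DCMSpec-class]) supplying model and
#'   family ids, in column order.
#' @return an [EvidenceTable-class].
#' @export
evidenceFromFits <- function(fits, specs) {
  if (is.matrix(fits)) {
    F <- fits
  } else {
    F <- do.call(rbind, lapply(fits, function(row)
      vapply(row, function(f) f@F, numeric(1))))
  }
  EvidenceTable(F, vapply(specs, modelId, 1L), vapply(specs, familyId, 1L))
}

#' Write a BMS result as JSON plus a plain-text report
#'
#' @param result a [BMSResult-class].
#' @param path JSON path; a \code{.txt} report is written alongside.
#' @return \code{path} invisibly.
#' @export
writeBMSResult <- function(result, path) {
  doc <- list(pooled_log_evidence = as.list(result@pooledLogEvidence),
              model_posterior = as.list(result@modelPosterior),
              family_posterior = as.list(result@familyPosterior),
              within_family_posterior = as.list(result@withinFamilyPosterior),
              winning_family = result@winningFamily,
              winning_model = result@winningModel,
              bayes_factor = result@bayesFactor)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  rpt <- sub("\\.json$", ".txt", path)
  con <- file(rpt, "w")
  on.exit(close(con))
  writeLines(c(
    "Fixed-effects Bayesian model selection",
    "",
    "Family posteriors:",
    sprintf("  family %s: %.6f", names(result@familyPosterior),
            result@familyPosterior),
    "",
    sprintf("Winning family: %d", result@winningFamily),
    "",
    "Within-family model posteriors:",
    sprintf("  model %s: %.6f", names(result@withinFamilyPosterior),
            result@withinFamilyPosterior),
    "",
    sprintf("Winning model: %d (Bayes factor vs runner-up: %.4g)",
            result@winningModel, result@bayesFactor)), con)
  invisible(path)
}
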