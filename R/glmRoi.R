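#' Canonical hemodynamic response function
#'
#' Double-gamma HRF: a gamma-density response peaking near
#' \code{peakDelay} seconds minus a later gamma undershoot scaled by
#' \code{undershootRatio}. The default shape (peak 6 s, undershoot 16 s,
#' ratio 1/6, 32 s support) is the conventional human canonical form;
#' rodent hemodynamics are faster, so \code{peakDelay} is a parameter
#' (e.g. 2.8 s for a rat preset).
#'
#' @param dt sampling interval of the kernel (s).
#' @param peakDelay time-to-peak parameter (s).
#' @param undershootDelay undershoot delay parameter (s).
#' @param undershootRatio relative undershoot amplitude.
#' @param length kernel support (s), default 32.
#' @return numeric vector sampling the kernel at \code{0, dt, 2dt, ...},
#'   normalized to unit sum.
#' @export
canonicalHrf <- function(dt, peakDelay = 6, undershootDelay = 16,
                         undershootRatio = 1 / 6, length = 32) {
  t <- seq(0, length, by = dt)
  h <- stats::dgamma(t, shape = peakDelay, rate = 1) -
    undershootRatio * stats::dgamma(t, shape = undershootDelay, rate = 1)
  h / sum(h)
}

#' Build a first-level GLM design matrix
#'
#' Constructs the stimulus regressor by sampling the boxcar at a
#' micro-time resolution, convolving with the canonical HRF and
#' downsampling to scan times (matching the sampling convention of
#' [integrateDCM()]: scan k is at time k*TR). Optional nuisance columns
#' (e.g. head-motion estimates) are appended; the constant term is last.
#'
#' @param design a [StimulusDesign-class]; must contain at least one
#'   event.
#' @param nuisance optional numeric matrix of nuisance regressors
#'   (scans x q).
#' @param microDt micro-time resolution (s), default \code{TR/16}.
#' @param hrf HRF kernel sampled at \code{microDt}; default
#'   [canonicalHrf()].
#' @return list with \code{X} (scans x regressors matrix), \code{names},
#'   and \code{TR}; first column is the stimulus regressor, last the
#'   constant.
#' @export
buildDesign <- function(design, nuisance = NULL, microDt = design@TR / 16,
                        hrf = canonicalHrf(microDt)) {
  stopifnot(is(design, "StimulusDesign"))
  if (length(design@onsets) == 0)
    stop("design has no stimulus events; constant-only designs are rejected")
  runEnd <- design@nScans * design@TR
  tmicro <- seq(0, runEnd, by = microDt)
  u <- rep(0, length(tmicro))
  for (i in seq_along(design@onsets)) {
    on <- design@onsets[i]
    off <- on + design@durations[i]
    u[tmicro >= on & tmicro < off] <- 1
    if (design@durations[i] == 0) {                      # impulse event
      u[which.min(abs(tmicro - on))] <- 1
    }
  }
  conv <- convolve(u, rev(hrf), type = "open")[seq_along(tmicro)]
  scanT <- seq_len(design@nScans) * design@TR
  idx <- round(scanT / microDt) + 1
  stim <- conv[pmin(idx, length(conv))]
  X <- cbind(stimulus = stim)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != design@nScans)
      stop("nuisance regressors must have one row per scan")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X <- cbind(X, constant = 1)
  if (any(colSums(abs(X)) == 0)) stop("design contains an all-zero column")
  list(X = X, names = colnames(X), TR = design@TR)
}

#' Ordinary least-squares fit of one ROI series
#'
#' Fits \code{y = X beta + e} by OLS and returns the t-statistic for the
#' stimulus regressor (first column) with \code{n - rank(X)} degrees of
#' freedom, as used for the ROI activation check.
#'
#' @param y numeric vector, one scan per entry.
#' @param X design matrix or the list from [buildDesign()].
#' @return list: \code{beta} (named), \code{tStat}, \code{pValue}
#'   (two-tailed), \code{df}, \code{residuals}, \code{sigma2}.
#' @export
glmFit <- function(y, X) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y and X have different scan counts")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("estimation error: design is rank deficient")
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- length(y) - qrX$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se1 <- sqrt(sigma2 * XtXinv[1, 1])
  tStat <- beta[1] / se1
  list(beta = beta, tStat = unname(tStat),
       pValue = 2 * pt(-abs(tStat), df), df = df,
       residuals = drop(res), sigma2 = sigma2)
}

#' First eigenvariate of a voxel-by-time matrix
#'
#' Region summary series used in place of the voxel average: the first
#' left singular vector of the scans x voxels matrix, scaled by its
#' singular value over sqrt(number of voxels), with the sign chosen so
#' the summary correlates nonnegatively with the across-voxel mean
#' series.
#'
#' @param voxelMatrix numeric matrix, scans x voxels, no missing values.
#' @return numeric vector of length scans.
#' @export
firstEigenvariate <- function(voxelMatrix) {
  voxelMatrix <- as.matrix(voxelMatrix)
  if (nrow(voxelMatrix) == 0 || ncol(voxelMatrix) == 0)
    stop("empty voxel matrix")
  if (anyNA(voxelMatrix)) stop("voxel matrix contains missing values")
  sv <- svd(voxelMatrix, nu = 1, nv = 0)
  e <- sv$u[, 1] * sv$d[1] / sqrt(ncol(voxelMatrix))
  m <- rowMeans(voxelMatrix)
  if (sum(e * m) < 0) e <- -e
  e
}
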