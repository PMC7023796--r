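#' Default shrinkage priors for a model structure
#'
#' Free parameters, in a fixed documented order: one coupling per directed
#' edge of the spec ("A:src->dst", prior N(0, 1/16)); one log
#' self-connection scale per region ("self:R", with
#' \eqn{a_{ii} = -0.5\,e^{\theta}}, prior N(0, 1/64), guaranteeing
#' negative self-connections); one driving-input weight per input target
#' ("C:R", prior N(0, 1)). The log noise precision lambda has hyperprior
#' N(4, 1). Hemodynamic parameters are fixed at their defaults during
#' inversion. The prior covariance is diagonal by construction.
#'
#' @param spec a [DCMSpec-class].
#' @param edgeVar,selfVar,inputVar,lambdaMean,lambdaVar prior variances /
#'   hyperprior moments, all overridable.
#' @return a [PriorSpec-class].
#' @export
defaultPriors <- function(spec, edgeVar = 1 / 16, selfVar = 1 / 64,
                          inputVar = 1, lambdaMean = 4, lambdaVar = 1) {
  stopifnot(is(spec, "DCMSpec"))
  e <- spec@edges
  nm <- character(0); v <- numeric(0)
  if (nrow(e)) {
    nm <- paste0("A:", e[, 1], "->", e[, 2])
    v <- rep(edgeVar, nrow(e))
  }
  nm <- c(nm, paste0("self:", spec@regions))
  v <- c(v, rep(selfVar, length(spec@regions)))
  nm <- c(nm, paste0("C:", spec@inputTargets))
  v <- c(v, rep(inputVar, length(spec@inputTargets)))
  mu <- setNames(rep(0, length(nm)), nm)
  new("PriorSpec", mean = mu, cov = diag(v, length(v)),
      lambdaMean = lambdaMean, lambdaVar = lambdaVar)
}

#' Map a free-parameter vector to NeuralParams
#'
#' Inverse of the parameterization documented in [defaultPriors()].
#'
#' @param theta named numeric vector in prior order.
#' @param spec a [DCMSpec-class].
#' @return a [NeuralParams-class].
#' @export
thetaToParams <- function(theta, spec) {
  r <- spec@regions
  n <- length(r)
  A <- matrix(0, n, n, dimnames = list(r, r))
  diag(A) <- -0.5 * exp(theta[paste0("self:", r)])
  e <- spec@edges
  if (nrow(e)) {
    for (k in seq_len(nrow(e)))
      A[e[k, 2], e[k, 1]] <- theta[paste0("A:", e[k, 1], "->", e[k, 2])]
  }
  Cm <- matrix(0, n, 1, dimnames = list(r, "stim"))
  Cm[spec@inputTargets, 1] <- theta[paste0("C:", spec@inputTargets)]
  NeuralParams(A = A, C = Cm)
}

# prediction vector for theta; NULL when the proposed system is unstable
.dcmPredict <- function(theta, spec, hemo, design, dt) {
  p <- thetaToParams(theta, spec)
  if (max(Re(eigen(p@A, only.values = TRUE)$values)) > -1e-6) return(NULL)
  out <- tryCatch(integrateDCM(p, hemo, design, dt = dt),
                  error = function(e) NULL)
  if (is.null(out)) return(NULL)
  as.numeric(out@series)
}

# central finite-difference Jacobian of the prediction
.dcmJacobian <- function(theta, spec, hemo, design, dt, g0,
                         step = 1e-4) {
  p <- length(theta)
  J <- matrix(0, length(g0), p)
  for (i in seq_len(p)) {
    h <- step * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- theta[i] + h
    tm <- theta; tm[i] <- theta[i] - h
    gp <- .dcmPredict(tp, spec, hemo, design, dt)
    gm <- .dcmPredict(tm, spec, hemo, design, dt)
    if (!is.null(gp) && !is.null(gm)) {
      J[, i] <- (gp - gm) / (2 * h)
    } else if (!is.null(gp)) {
      J[, i] <- (gp - g0) / h
    } else if (!is.null(gm)) {
      J[, i] <- (g0 - gm) / h
    }                       # both sides unstable: leave column at zero
  }
  J
}

#' Variational free energy of a Gaussian posterior
#'
#' Laplace-form evidence lower bound for a Gaussian observation model
#' linearized at the posterior mean: expected log-likelihood under the
#' posterior minus KL(posterior || prior),
#' \deqn{F = \frac{N}{2}(\lambda - \log 2\pi)
#'   - \frac{e^{\lambda}}{2}\left(e^\top e + tr(\Sigma J^\top J)\right)
#'   - KL\left(N(\mu,\Sigma)\,\|\,N(m_0,\Sigma_0)\right)}
#' with residuals \eqn{e = y - g(\mu)}. For a model that is exactly
#' linear in its parameters this equals the analytic log evidence at the
#' exact posterior. Noise-hyperprior terms are not included here;
#' [variationalLaplace()] adds them to its reported F.
#'
#' @param y observed data vector.
#' @param pred model prediction at \code{mu}.
#' @param J Jacobian of the prediction at \code{mu} (N x p).
#' @param mu,Sigma posterior mean and covariance.
#' @param lambda log noise precision.
#' @param priors a [PriorSpec-class].
#' @return free energy in nats.
#' @export
freeEnergy <- function(y, pred, J, mu, Sigma, lambda, priors) {
  e <- y - pred
  N <- length(y)
  p <- length(mu)
  Pi0 <- chol2inv(chol(priors@cov))
  d <- mu - priors@mean
  acc <- N / 2 * (lambda - log(2 * pi)) -
    exp(lambda) / 2 * (sum(e^2) + sum(diag(Sigma %*% crossprod(J))))
  ld0 <- determinant(priors@cov, logarithm = TRUE)$modulus
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  kl <- 0.5 * (sum(diag(Pi0 %*% Sigma)) + drop(t(d) %*% Pi0 %*% d) -
                 p + ld0 - ld)
  as.numeric(acc - kl)
}

# lambda-prior + entropy contribution of the variational noise posterior
.lambdaTerms <- function(lambda, S, priors) {
  vl <- 1 / (exp(lambda) * S / 2 + 1 / priors@lambdaVar)
  -((lambda - priors@lambdaMean)^2 + vl) / (2 * priors@lambdaVar) -
    0.5 * log(2 * pi * priors@lambdaVar) + 0.5 * log(2 * pi * exp(1) * vl)
}

# 1-D Newton update of the log noise precision given residual mass S
.updateLambda <- function(lambda, N, S, priors) {
  eta <- priors@lambdaMean; s2 <- priors@lambdaVar
  for (i in 1:50) {
    g <- N / 2 - exp(lambda) * S / 2 - (lambda - eta) / s2
    H <- -exp(lambda) * S / 2 - 1 / s2
    stepl <- g / H
    lambda <- lambda - stepl
    lambda <- min(max(lambda, -10), 15)
    if (abs(stepl) < 1e-10) break
  }
  lambda
}

#' Invert a DCM by variational Laplace
#'
#' Gauss-Newton ascent on the variational free energy with
#' Levenberg-style damping: at each outer iteration the prediction and
#' its finite-difference Jacobian are evaluated at the current posterior
#' mean, the log noise precision is updated by a closed-form 1-D Newton
#' step, and a damped Gauss-Newton step on the parameters is accepted
#' only if it increases F (otherwise damping is increased and the step
#' retried; proposals whose neural system is unstable are rejected the
#' same way, not treated as errors). Iteration stops when the F increase
#' falls below \code{tol} or after \code{maxIter} iterations; the best-F
#' iterate is returned. Deterministic given inputs and options.
#'
#' @param y an [ROITimeSeries-class] (or scans x regions matrix sharing
#'   the design's dimensions).
#' @param spec the [DCMSpec-class] to invert.
#' @param design a [StimulusDesign-class]; must match \code{y}.
#' @param priors a [PriorSpec-class], default [defaultPriors()].
#' @param hemo fixed hemodynamic constants.
#' @param tol convergence threshold on the F increase (nats), default
#'   1e-2.
#' @param maxIter maximum outer iterations, default 64.
#' @param dt integrator step (s), default TR/8.
#' @param fdStep relative finite-difference step, default 1e-4.
#' @param init optional starting point for the posterior-mean search
#'   (default: the prior mean).
#' @return a [PosteriorEstimate-class]; slot \code{Fhistory} holds the
#'   accepted-iteration free energies (non-decreasing).
#' @export
variationalLaplace <- function(y, spec, design, priors = defaultPriors(spec),
                               hemo = HemoParams(), tol = 1e-2,
                               maxIter = 64, dt = design@TR / 8,
                               fdStep = 1e-4, init = priors@mean) {
  if (is(y, "ROITimeSeries")) {
    if (abs(y@TR - design@TR) > 1e-9 || nrow(y@series) != design@nScans)
      stop("data and design disagree on TR or number of scans")
    yv <- as.numeric(y@series)
  } else {
    yv <- as.numeric(y)
  }
  N <- length(yv)
  mu <- setNames(as.numeric(init), names(priors@mean))
  Pi0 <- chol2inv(chol(priors@cov))
  lambda <- priors@lambdaMean
  Sigma <- priors@cov
  damping <- 1e-4

  g <- .dcmPredict(mu, spec, hemo, design, dt)
  if (is.null(g))
    stop("prior-mean model is unstable; cannot start inversion")

  Fhist <- numeric(0)
  Flast <- -Inf
  best <- NULL
  converged <- FALSE
  iter <- 0L

  while (iter < maxIter) {
    iter <- iter + 1L
    J <- .dcmJacobian(mu, spec, hemo, design, dt, g, step = fdStep)
    JtJ <- crossprod(J)
    e <- yv - g

    # E-step: damped Gauss-Newton on the parameters at the current lambda
    P <- exp(lambda) * JtJ + Pi0
    SigmaNew <- chol2inv(chol(P))
    grad <- exp(lambda) * crossprod(J, e) - Pi0 %*% (mu - priors@mean)
    Scur <- sum(e^2) + sum(diag(SigmaNew %*% JtJ))
    accepted <- FALSE
    for (inner in 1:12) {
      Pd <- P + damping * diag(diag(P), nrow(P))
      step <- drop(solve(Pd, grad))
      muProp <- mu + step
      gProp <- .dcmPredict(muProp, spec, hemo, design, dt)
      if (!is.null(gProp)) {
        Fcand <- freeEnergy(yv, gProp, J, muProp, SigmaNew, lambda, priors) +
          .lambdaTerms(lambda, Scur, priors)
        if (is.finite(Fcand) && Fcand >= Flast) {
          mu <- muProp; g <- gProp; Sigma <- SigmaNew
          damping <- max(damping / 4, 1e-6)
          accepted <- TRUE
          break
        }
      }
      damping <- damping * 8
    }
    if (!accepted) { converged <- TRUE; break }

    # M-step: noise log-precision from the residuals of the accepted step,
    # with the (tight) posterior covariance in the trace term
    eNew <- yv - g
    S <- sum(eNew^2) + sum(diag(Sigma %*% JtJ))
    lambdaNew <- .updateLambda(lambda, N, S, priors)
    Fnew <- freeEnergy(yv, g, J, mu, Sigma, lambdaNew, priors) +
      .lambdaTerms(lambdaNew, S, priors)
    if (is.finite(Fnew) && Fnew >= Flast) {
      lambda <- lambdaNew
    } else {
      # keep the previous noise estimate if the update would lower F
      Fnew <- freeEnergy(yv, g, J, mu, Sigma, lambda, priors) +
        .lambdaTerms(lambda, S, priors)
    }
    dF <- Fnew - Flast
    if (is.finite(Fnew) && Fnew >= Flast) {
      Flast <- Fnew
      Fhist <- c(Fhist, Fnew)
      best <- list(mu = mu, Sigma = Sigma, lambda = lambda, F = Fnew)
    }
    if (length(Fhist) >= 2 && is.finite(dF) && dF < tol) {
      converged <- TRUE
      break
    }
  }

  if (is.null(best))
    stop("inversion failure: no finite free energy found")
  new("PosteriorEstimate", mu = setNames(best$mu, names(priors@mean)),
      Sigma = (best$Sigma + t(best$Sigma)) / 2, lambda = best$lambda,
      F = best$F, nIter = iter, converged = converged,
      modelId = spec@modelId, Fhistory = Fhist)
}

#' Write / read a single-fit JSON result
#'
#' @param fit a [PosteriorEstimate-class].
#' @param path JSON path.
#' @return \code{writeFit} returns \code{path} invisibly; \code{readFit}
#'   the [PosteriorEstimate-class].
#' @export
writeFit <- function(fit, path) {
  doc <- list(model_id = fit@modelId, F = fit@F,
              mu = as.list(fit@mu), Sigma = as.numeric(fit@Sigma),
              lambda = fit@lambda, n_iter = fit@nIter,
              converged = fit@converged, F_history = fit@Fhistory)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFit
#' @export
readFit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- unlist(doc$mu)
  p <- length(mu)
  new("PosteriorEstimate", mu = mu,
      Sigma = matrix(doc$Sigma, p, p), lambda = doc$lambda,
      F = doc$F, nIter = as.integer(doc$n_iter),
      converged = doc$converged,
      modelId = as.integer(doc$model_id),
      Fhistory = as.numeric(doc$F_history))
}
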