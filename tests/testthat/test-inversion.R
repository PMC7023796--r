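# analytic log evidence of the linear-Gaussian model
#   y = X theta + e,  e ~ N(0, exp(-lambda) I),  theta ~ N(m0, S0)
# used as the independent oracle for the free-energy computation
linGaussEvidence <- function(y, X, m0, S0, lambda) {
  n <- length(y)
  Sy <- exp(-lambda) * diag(n) + X %*% S0 %*% t(X)
  r <- y - drop(X %*% m0)
  -0.5 * (n * log(2 * pi) +
            as.numeric(determinant(Sy, logarithm = TRUE)$modulus) +
            drop(t(r) %*% solve(Sy, r)))
}

linGaussPosterior <- function(y, X, m0, S0, lambda) {
  P <- exp(lambda) * crossprod(X) + solve(S0)
  Sigma <- solve(P)
  mu <- drop(Sigma %*% (exp(lambda) * crossprod(X, y) + solve(S0, m0)))
  list(mu = mu, Sigma = Sigma)
}

toyPriors <- function(m0, S0) {
  new("PriorSpec", mean = m0, cov = S0, lambdaMean = 4, lambdaVar = 1)
}

test_that("free energy equals the conjugate log evidence on a linear model", {
  set.seed(5)
  n <- 40; p <- 3
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  m0 <- setNames(c(0.5, 0, -0.2), paste0("b", 1:p))
  S0 <- diag(c(1, 0.5, 2))
  lambda <- log(1 / 0.3^2)
  theta <- c(1, 0.4, -1)
  y <- drop(X %*% theta) + rnorm(n, 0, 0.3)
  post <- linGaussPosterior(y, X, m0, S0, lambda)
  F <- freeEnergy(y, drop(X %*% post$mu), X, post$mu, post$Sigma, lambda,
                  toyPriors(m0, S0))
  expect_equal(F, linGaussEvidence(y, X, m0, S0, lambda), tolerance = 1e-3)
})

test_that("complexity vanishes when posterior equals prior", {
  set.seed(6)
  n <- 20
  X <- matrix(rnorm(n), n, 1)
  m0 <- c(b = 0); S0 <- diag(1, 1)
  lambda <- 0
  y <- rep(0, n)
  # posterior held at the prior: F reduces to the accuracy term
  Facc <- freeEnergy(y, drop(X %*% m0), X, m0, S0, lambda,
                     toyPriors(m0, S0))
  acc <- n / 2 * (lambda - log(2 * pi)) -
    exp(lambda) / 2 * (sum(y^2) + sum(diag(S0 %*% crossprod(X))))
  expect_equal(Facc, acc, tolerance = 1e-12)
})

test_that("tightening the prior lowers F when posterior differs from it", {
  set.seed(7)
  n <- 30
  X <- matrix(rnorm(n), n, 1)
  lambda <- 2
  y <- drop(X * 1.5) + rnorm(n, 0, exp(-lambda / 2))
  m0 <- c(b = 0)
  Fat <- function(v) {
    S0 <- diag(v, 1)
    post <- linGaussPosterior(y, X, m0, S0, lambda)
    freeEnergy(y, drop(X %*% post$mu), X, post$mu, post$Sigma, lambda,
               toyPriors(m0, S0))
  }
  expect_lt(Fat(0.01), Fat(1))
})

test_that("default priors enumerate the free parameters in stable order", {
  pr <- defaultPriors(model16)
  expect_length(pr@mean, 10)            # 6 edges + 3 selfs + 1 input
  expect_equal(sum(startsWith(names(pr@mean), "A:")), 6)
  prEmpty <- defaultPriors(DCMSpec(c("S1", "AMY", "h")))
  expect_length(prEmpty@mean, 4)        # 3 selfs + 1 input
  expect_true(all(pr@cov[upper.tri(pr@cov)] == 0))   # diagonal prior
  # mapping back to matrices: self-connections always negative
  th <- pr@mean; th[] <- rnorm(length(th))
  names(th) <- names(pr@mean)
  A <- thetaToParams(th, model16)@A
  expect_true(all(diag(A) < 0))
  expect_equal(A["AMY", "S1"], unname(th["A:S1->AMY"]))
})

test_that("zero-noise data from the prior mean returns the prior mean", {
  cfg <- quickCfg()
  d <- makeBlockDesign(cfg)
  pr <- defaultPriors(model16)
  truth <- thetaToParams(pr@mean, model16)
  y <- integrateDCM(truth, HemoParams(), d)
  fit <- quickFit(y, model16, d)
  expect_lt(max(abs(posteriorMean(fit) - pr@mean)), 1e-3)
})

test_that("inversion recovers couplings and is bit-reproducible", {
  cfg <- quickCfg(seed = 3, nPerGroup = 1)
  d <- makeBlockDesign(cfg)
  sim <- simulateSubject(model16, "model", "post", cfg, 1, withTruth = TRUE)
  fit1 <- quickFit(sim$series, model16, d)
  fit2 <- quickFit(sim$series, model16, d)
  expect_identical(posteriorMean(fit1), posteriorMean(fit2))
  expect_identical(freeEnergyOf(fit1), freeEnergyOf(fit2))
  tru <- sim$trueParams@A
  est <- thetaToParams(posteriorMean(fit1), model16)@A
  off <- row(tru) != col(tru)
  expect_gt(cor(tru[off], est[off]), 0.8)
  # free energy non-decreasing over accepted iterations
  expect_true(all(diff(fit1@Fhistory) >= 0))
  # information is never lost: posterior variances below prior variances
  pr <- defaultPriors(model16)
  expect_true(all(diag(fit1@Sigma) <= diag(pr@cov) + 1e-10))
})

test_that("richer generating structure earns higher evidence", {
  cfg <- quickCfg(seed = 9, nPerGroup = 1)
  d <- makeBlockDesign(cfg)
  y <- simulateSubject(model16, "EA", "post", cfg, 1)
  fFull <- freeEnergyOf(quickFit(y, model16, d))
  noEdge <- DCMSpec(c("S1", "AMY", "h"))
  fEmpty <- freeEnergyOf(quickFit(y, noEdge, d))
  expect_gt(fFull, fEmpty)
})

test_that("fits round-trip through JSON", {
  cfg <- quickCfg(seed = 4, nPerGroup = 1)
  d <- makeBlockDesign(cfg)
  fit <- quickFit(simulateSubject(model16, "model", "pre", cfg, 1),
                  model16, d)
  path <- withr::local_tempfile(fileext = ".json")
  writeFit(fit, path)
  back <- readFit(path)
  expect_equal(posteriorMean(back), posteriorMean(fit))
  expect_equal(freeEnergyOf(back), freeEnergyOf(fit))
  expect_equal(back@Sigma, fit@Sigma)
  expect_equal(modelId(back), modelId(fit))
})
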