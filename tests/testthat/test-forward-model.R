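test_that("neural derivative implements the bilinear equation", {
  p <- NeuralParams(A = -diag(3), C = c(0.3, 0, 0))
  expect_equal(neuralDerivative(c(0, 0, 0), 0, p), c(0, 0, 0))
  expect_equal(neuralDerivative(c(0, 0, 0), 1, p), c(0.3, 0, 0))
  expect_equal(neuralDerivative(c(1, 2, 3), 0, p), c(-1, -2, -3))
  # modulation: u scales B into the effective coupling
  B <- matrix(0, 3, 3); B[2, 1] <- 0.5
  pb <- NeuralParams(A = -diag(3), C = c(0, 0, 0), B = B)
  expect_equal(neuralDerivative(c(1, 0, 0), 1, pb), c(-1, 0.5, 0))
  expect_error(neuralDerivative(c(1, 2), 0, p), "wrong length")
})

test_that("hemodynamic derivative has the resting fixed point", {
  h <- HemoParams()
  expect_equal(unname(hemoDerivative(c(0, 1, 1, 1), 0, h)), rep(0, 4))
  # z enters only the vasodilatory signal
  expect_equal(unname(hemoDerivative(c(0, 1, 1, 1), 1, h)), c(1, 0, 0, 0))
  # direct substitution at s = 1
  d <- hemoDerivative(c(1, 1, 1, 1), 0, HemoParams(kappa = 0.64))
  expect_equal(unname(d[1]), -0.64)
  expect_equal(unname(d[2]), 1)
  expect_error(hemoDerivative(c(0, -1, 1, 1), 0, h), "domain")
})

test_that("BOLD observation matches the static nonlinearity", {
  h <- HemoParams(E0 = 0.4, V0 = 0.04)
  expect_equal(boldObservation(1, 1, h), 0)
  expect_equal(boldObservation(1, 0.9, h),
               0.04 * (7 * 0.4 * 0.1 + 2 * 0.1))
  # decreasing q at fixed v increases the signal
  q <- seq(1, 0.8, by = -0.05)
  expect_true(all(diff(boldObservation(1, q, h)) > 0))
})

test_that("integration respects fixed points and propagation structure", {
  cfg <- studyCfg()
  d <- makeBlockDesign(cfg)
  h <- HemoParams()
  # no input: rest is a fixed point
  p0 <- NeuralParams(A = groundTruthParams("model", "pre", cfg)@A,
                     C = c(0, 0, 0))
  expect_true(all(boldSeries(integrateDCM(p0, h, d)) == 0))
  # no off-diagonal coupling: input to S1 cannot reach AMY or h
  A <- diag(c(-0.5, -0.5, -0.5))
  dimnames(A) <- list(c("S1", "AMY", "h"), c("S1", "AMY", "h"))
  p1 <- NeuralParams(A = A, C = c(0.5, 0, 0))
  y <- boldSeries(integrateDCM(p1, h, d))
  expect_gt(max(abs(y[, "S1"])), 0.1)
  expect_true(all(y[, c("AMY", "h")] == 0))
})

test_that("integrator output is deterministic and step-converged", {
  cfg <- studyCfg()
  d <- makeBlockDesign(cfg)
  p <- groundTruthParams("EA", "post", cfg)
  y1 <- boldSeries(integrateDCM(p, HemoParams(), d, dt = d@TR / 8))
  y2 <- boldSeries(integrateDCM(p, HemoParams(), d, dt = d@TR / 8))
  expect_identical(y1, y2)                       # bit-identical
  yHalf <- boldSeries(integrateDCM(p, HemoParams(), d, dt = d@TR / 16))
  expect_lt(max(abs(y1 - yHalf)), 1e-3 * max(abs(y1)))
})

test_that("neural response is linear in C; BOLD is at small signals", {
  cfg <- studyCfg()
  d <- makeBlockDesign(cfg)
  A <- groundTruthParams("model", "pre", cfg)@A
  # neural subsystem integrated directly with neuralDerivative: the peak
  # doubles exactly when C doubles
  zPeak <- function(w) {
    p <- NeuralParams(A = A, C = c(w, 0, 0))
    z <- c(0, 0, 0); dt <- 0.1; peak <- 0
    ends <- d@onsets + d@durations
    for (t in seq(0, 300 - dt, by = dt)) {
      u <- as.numeric(any(t + dt / 2 >= d@onsets & t + dt / 2 < ends))
      k1 <- neuralDerivative(z, u, p)
      k2 <- neuralDerivative(z + dt / 2 * k1, u, p)
      k3 <- neuralDerivative(z + dt / 2 * k2, u, p)
      k4 <- neuralDerivative(z + dt * k3, u, p)
      z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      peak <- max(peak, abs(z))
    }
    peak
  }
  expect_equal(zPeak(0.2) / zPeak(0.1), 2, tolerance = 1e-6)
  # hemodynamic cascade: approaches linearity as the input shrinks
  bPeak <- function(w) max(abs(boldSeries(
    integrateDCM(NeuralParams(A = A, C = c(w, 0, 0)), HemoParams(), d))))
  expect_equal(bPeak(0.005) / bPeak(0.0025), 2, tolerance = 0.05)
  expect_lt(abs(bPeak(0.005) / bPeak(0.0025) - 2),
            abs(bPeak(0.1) / bPeak(0.05) - 2))
})

test_that("shifting onsets by one TR shifts the sampled response", {
  cfg <- studyCfg()
  d <- makeBlockDesign(cfg)
  p <- groundTruthParams("model", "pre", cfg)
  dShift <- StimulusDesign(d@onsets + d@TR, d@durations, d@TR, d@nScans)
  y <- boldSeries(integrateDCM(p, HemoParams(), d))
  yS <- boldSeries(integrateDCM(p, HemoParams(), dShift))
  n <- nrow(y)
  expect_lt(max(abs(yS[2:n, ] - y[1:(n - 1), ])), 1e-6)
})

test_that("all 16 models integrate to finite output at true parameters", {
  cfg <- studyCfg()
  d <- makeBlockDesign(cfg)
  truth <- groundTruthParams("model", "post", cfg)
  for (s in paperSpace) {
    adj <- specToAdjacency(s)
    A <- truth@A * adj
    diag(A) <- diag(truth@A)
    y <- boldSeries(integrateDCM(NeuralParams(A = A, C = truth@C),
                                 HemoParams(), d))
    expect_true(all(is.finite(y)))
  }
})

test_that("a divergent system raises an instability error", {
  A <- matrix(c(-0.01, 1, 1, -0.01), 2, 2)
  d <- StimulusDesign(10, 15, 2, 50)
  expect_error(
    integrateDCM(NeuralParams(A = A, C = c(0.5, 0)), HemoParams(), d),
    "eigenvalue")
})

test_that("ROI series round-trip through TSV + YAML sidecar", {
  cfg <- studyCfg()
  d <- makeBlockDesign(cfg)
  ts <- integrateDCM(groundTruthParams("model", "pre", cfg), HemoParams(), d)
  path <- file.path(withr::local_tempdir(), "run.tsv")
  writeROITimeSeries(ts, path)
  back <- readROITimeSeries(path)
  expect_equal(boldSeries(back), boldSeries(ts), tolerance = 1e-12)
  expect_equal(stimDesign(back)@onsets, d@onsets)
  expect_equal(back@TR, ts@TR)
})
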