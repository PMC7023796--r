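# shared fixtures: model space, compact configs and fast inversion settings

paperSpace <- enumeratePaperModels()
model16 <- paperSpace[[16]]

# full-size study configuration (the defaults) with a given seed
studyCfg <- function(seed = 1, ...) cohortConfig(seed = seed, ...)

# compact run for fast tests: 5 blocks in 150 s, 75 scans
quickCfg <- function(seed = 1, nPerGroup = 2, runLength = 150,
                     nBlocks = 5, ...) {
  cohortConfig(seed = seed, runLength = runLength, nBlocks = nBlocks,
               nPerGroup = nPerGroup, ...)
}

# inversion at the package defaults (integrator step TR/8)
quickFit <- function(y, spec, design, ...) {
  variationalLaplace(y, spec, design, ...)
}

# fabricate a PosteriorEstimate with given posterior-mean couplings
fakeFit <- function(mu, modelId = 16L) {
  p <- length(mu)
  new("PosteriorEstimate", mu = mu, Sigma = diag(1e-4, p), lambda = 4,
      F = -100, nIter = 1L, converged = TRUE, modelId = modelId,
      Fhistory = -100)
}

# long-format coupling table with configurable group/time effects
makeCouplingTable <- function(nPerGroup = 8, effect = 0, noise = 0.05,
                              seed = 1) {
  set.seed(seed)
  labels <- c("S1->AMY", "AMY->S1", "S1->h", "h->S1", "AMY->h", "h->AMY")
  rows <- list()
  for (g in c("model", "EA")) for (tp in c("pre", "post", "treated"))
    for (i in seq_len(nPerGroup)) {
      val <- 0.2 + rnorm(6, 0, noise)
      if (tp != "pre") {
        val[labels %in% c("h->S1", "AMY->S1")] <-
          val[labels %in% c("h->S1", "AMY->S1")] + effect
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = paste0(g, i), group = g, timepoint = tp,
        connection = labels, coupling = val)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
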