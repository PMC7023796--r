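#' CohortConfig: settings for the synthetic study cohort
#'
#' Describes the emulated study: two groups (untreated pain model vs
#' electroacupuncture, "EA") of \code{nPerGroup} subjects each, scanned at
#' three time points (pre-modeling, post-modeling, after treatment) with a
#' block-design run of \code{nBlocks} stimulus blocks inside a
#' \code{runLength}-second acquisition.
#'
#' Ground-truth couplings (Hz) are stand-ins chosen inside the stability
#' region of the neural system, not values from any empirical fit:
#' baseline off-diagonals \code{forwardCoupling} (S1 to AMY and S1 to h),
#' \code{lateralCoupling} (AMY/h interconnections) and
#' \code{backCoupling} (h to S1, AMY to S1); self-connections
#' \code{selfCoupling}. The pain manipulation adds \code{painEffect} to
#' both limbic-to-S1 couplings from pre to post in both groups; treatment
#' adds \code{eaEffect} (negative) at the treated time point in the EA
#' group only.
#'
#' @slot nPerGroup subjects per group.
#' @slot groups,timepoints factor labels.
#' @slot nBlocks stimulus blocks per run.
#' @slot noiseSd BOLD observation noise SD (percent signal).
#' @slot noiseAR lag-1 autocorrelation of the observation noise (0 =
#'   white, the default).
#' @slot subjectDispersion SD (Hz) of per-subject coupling jitter.
#' @slot seed base integer seed; every subject stream derives from it.
#' @slot TR repetition time (s).
#' @slot runLength run duration (s).
#' @slot blockDuration stimulus-on duration per block (s).
#' @slot selfCoupling,forwardCoupling,lateralCoupling,backCoupling
#'   ground-truth couplings (Hz).
#' @slot painEffect,eaEffect condition effects (Hz) on the h->S1 and
#'   AMY->S1 couplings.
#' @slot inputWeight driving-input weight to S1 (C entry).
#' @export
setClass("CohortConfig",
  representation(
    nPerGroup = "integer", groups = "character", timepoints = "character",
    nBlocks = "integer", noiseSd = "numeric", noiseAR = "numeric",
    subjectDispersion = "numeric",
    seed = "integer", TR = "numeric", runLength = "numeric",
    blockDuration = "numeric", selfCoupling = "numeric",
    forwardCoupling = "numeric", lateralCoupling = "numeric",
    backCoupling = "numeric", painEffect = "numeric", eaEffect = "numeric",
    inputWeight = "numeric"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 1) msg <- c(msg, "nPerGroup must be positive")
  if (object@nBlocks < 1) msg <- c(msg, "nBlocks must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (abs(object@noiseAR) >= 1)
    msg <- c(msg, "noiseAR must lie in (-1, 1)")
  if (object@subjectDispersion < 0)
    msg <- c(msg, "subjectDispersion must be nonnegative")
  if (object@TR <= 0 || object@runLength <= 0 || object@blockDuration <= 0)
    msg <- c(msg, "TR, runLength, blockDuration must be positive")
  if (object@selfCoupling >= 0)
    msg <- c(msg, "selfCoupling must be negative")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' Defaults emulate the study conditions: 2 groups x 8 subjects x 3 time
#' points, 10 stimulus blocks within a 5-minute run, TR 2 s.
#'
#' @param nPerGroup subjects per group (default 8).
#' @param groups,timepoints condition labels.
#' @param nBlocks stimulus blocks per run (default 10).
#' @param noiseSd BOLD noise SD, percent signal (default 0.3).
#' @param noiseAR lag-1 noise autocorrelation (default 0, white noise).
#' @param subjectDispersion per-subject coupling jitter SD, Hz
#'   (default 0.05).
#' @param seed base seed (default 1).
#' @param TR repetition time, s (default 2).
#' @param runLength run duration, s (default 300).
#' @param blockDuration stimulus-on time per block, s (default 15).
#' @param selfCoupling,forwardCoupling,lateralCoupling,backCoupling
#'   ground-truth couplings, Hz.
#' @param painEffect,eaEffect condition effects, Hz.
#' @param inputWeight driving-input weight (default 0.5).
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(nPerGroup = 8, groups = c("model", "EA"),
                         timepoints = c("pre", "post", "treated"),
                         nBlocks = 10, noiseSd = 0.3, noiseAR = 0,
                         subjectDispersion = 0.05, seed = 1,
                         TR = 2.0, runLength = 300, blockDuration = 15,
                         selfCoupling = -0.5, forwardCoupling = 0.20,
                         lateralCoupling = 0.10, backCoupling = 0.10,
                         painEffect = 0.30, eaEffect = -0.25,
                         inputWeight = 0.5) {
  new("CohortConfig", nPerGroup = as.integer(nPerGroup), groups = groups,
      timepoints = timepoints, nBlocks = as.integer(nBlocks),
      noiseSd = noiseSd, noiseAR = noiseAR,
      subjectDispersion = subjectDispersion,
      seed = as.integer(seed), TR = TR, runLength = runLength,
      blockDuration = blockDuration, selfCoupling = selfCoupling,
      forwardCoupling = forwardCoupling, lateralCoupling = lateralCoupling,
      backCoupling = backCoupling, painEffect = painEffect,
      eaEffect = eaEffect, inputWeight = inputWeight)
}

#' Block design of the synthetic run
#'
#' \code{nBlocks} equal stimulus-on blocks, each preceded by an equal
#' off-period, tiled over the run: cycle length \code{runLength/nBlocks},
#' stimulus on during the last \code{blockDuration} seconds of each cycle.
#'
#' @param cfg a [CohortConfig-class].
#' @return a [StimulusDesign-class] with
#'   \code{nScans = floor(runLength/TR)}.
#' @export
makeBlockDesign <- function(cfg) {
  stopifnot(is(cfg, "CohortConfig"))
  cycle <- cfg@runLength / cfg@nBlocks
  if (cfg@blockDuration > cycle)
    stop(sprintf(
      "configuration error: %d blocks of %.3g s (+off periods) do not fit in a %.3g s run",
      cfg@nBlocks, cfg@blockDuration, cfg@runLength))
  onsets <- (seq_len(cfg@nBlocks)) * cycle - cfg@blockDuration
  StimulusDesign(onsets = onsets,
                 durations = rep(cfg@blockDuration, cfg@nBlocks),
                 TR = cfg@TR, nScans = floor(cfg@runLength / cfg@TR))
}

#' Ground-truth coupling parameters for one cell of the design
#'
#' Full-model (model 16) A/C matrices for a group x timepoint condition.
#' The limbic-to-S1 couplings (h->S1 and AMY->S1) carry the condition
#' effects: they increase by \code{painEffect} from pre to post in both
#' groups, and additionally change by \code{eaEffect} at the treated time
#' point in the EA group. All other couplings are constant across
#' conditions, and both groups are identical at baseline.
#'
#' @param group one of \code{cfg@groups} (second label is the treated
#'   group).
#' @param timepoint one of \code{cfg@timepoints} (ordered pre, post,
#'   treated).
#' @param cfg a [CohortConfig-class].
#' @return a [NeuralParams-class] whose A matrix is strictly stable.
#' @export
groundTruthParams <- function(group, timepoint, cfg) {
  stopifnot(is(cfg, "CohortConfig"))
  if (!group %in% cfg@groups || !timepoint %in% cfg@timepoints)
    stop("configuration error: condition outside the factorial design")
  r <- c("S1", "AMY", "h")
  A <- matrix(0, 3, 3, dimnames = list(r, r))
  diag(A) <- cfg@selfCoupling
  A["AMY", "S1"] <- cfg@forwardCoupling
  A["h", "S1"] <- cfg@forwardCoupling
  A["h", "AMY"] <- cfg@lateralCoupling
  A["AMY", "h"] <- cfg@lateralCoupling
  back <- cfg@backCoupling
  ti <- match(timepoint, cfg@timepoints)
  if (ti >= 2) back <- back + cfg@painEffect
  if (ti >= 3 && group == cfg@groups[2]) back <- back + cfg@eaEffect
  A["S1", "AMY"] <- back
  A["S1", "h"] <- back
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    stop("ground-truth A is not stable; adjust coupling configuration")
  Cm <- matrix(c(cfg@inputWeight, 0, 0), 3, 1, dimnames = list(r, "stim"))
  NeuralParams(A = A, C = Cm)
}

# deterministic per-subject stream seed, kept below 2^31-1
.subjectSeed <- function(cfg, group, timepoint, subjectIndex) {
  gi <- match(group, cfg@groups)
  ti <- match(timepoint, cfg@timepoints)
  as.integer((as.numeric(cfg@seed) * 100003 + gi * 10007 +
                ti * 1009 + subjectIndex * 101) %% 2147483629)
}

# jitter the couplings present in `spec` and redraw until strictly stable
.jitterParams <- function(truth, spec, sd) {
  adj <- specToAdjacency(spec)
  A0 <- truth@A * adj
  diag(A0) <- diag(truth@A)
  if (sd == 0) return(NeuralParams(A = A0, C = truth@C))
  off <- which(adj == 1 & row(adj) != col(adj))
  for (try in 1:200) {
    A <- A0
    A[off] <- A[off] + rnorm(length(off), 0, sd)
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -0.02)
      return(NeuralParams(A = A, C = truth@C))
  }
  stop("could not draw a stable jittered coupling matrix")
}

#' Simulate one subject's ROI time series
#'
#' Per-subject ground truth is the condition's coupling matrix (masked to
#' the edges of \code{spec}) plus Gaussian jitter on the present
#' off-diagonal couplings (SD \code{subjectDispersion}), redrawn until the
#' system is strictly stable. The noiseless BOLD from [integrateDCM()]
#' then receives i.i.d. Gaussian observation noise of SD \code{noiseSd}
#' percent signal. The random stream is seeded deterministically from
#' (seed, group, timepoint, subjectIndex), so every series is exactly
#' reproducible.
#'
#' @param spec generating model structure (a [DCMSpec-class]).
#' @param group,timepoint condition labels.
#' @param cfg a [CohortConfig-class].
#' @param subjectIndex 1-based subject number within the group.
#' @param hemo hemodynamic constants, default [HemoParams()].
#' @param withTruth if \code{TRUE} return a list with the series, the
#'   subject's true [NeuralParams-class] and the stream seed.
#' @return an [ROITimeSeries-class], or a list when
#'   \code{withTruth = TRUE}.
#' @export
simulateSubject <- function(spec, group, timepoint, cfg, subjectIndex,
                            hemo = HemoParams(), withTruth = FALSE) {
  truth <- groundTruthParams(group, timepoint, cfg)
  streamSeed <- .subjectSeed(cfg, group, timepoint, subjectIndex)
  set.seed(streamSeed)
  subj <- .jitterParams(truth, spec, cfg@subjectDispersion)
  design <- makeBlockDesign(cfg)
  ts <- integrateDCM(subj, hemo, design)
  if (cfg@noiseSd > 0) {
    eps <- matrix(rnorm(length(ts@series)), nrow(ts@series),
                  ncol(ts@series))
    if (cfg@noiseAR != 0) {                 # stationary AR(1), unit variance
      eps <- apply(eps, 2, function(x)
        as.numeric(stats::filter(x, cfg@noiseAR, "recursive"))) *
        sqrt(1 - cfg@noiseAR^2)
    }
    ts <- ROITimeSeries(ts@series + cfg@noiseSd * eps, design)
  }
  if (!withTruth) return(ts)
  list(series = ts, trueParams = subj, seed = streamSeed)
}

#' Simulate the full synthetic cohort
#'
#' All groups x subjects x time points (2 x 8 x 3 = 48 runs under the
#' defaults), each generated by [simulateSubject()] from the same
#' generating model structure, together with a ground-truth manifest
#' recording every subject's true couplings for recovery scoring.
#'
#' @param cfg a [CohortConfig-class].
#' @param spec generating structure; default the fully bidirectional
#'   closed-loop model 16.
#' @param hemo hemodynamic constants.
#' @return a list with elements \code{series} (named list of
#'   [ROITimeSeries-class], names \code{group.timepoint.sNN}),
#'   \code{manifest} (data.frame: group, timepoint, subject, stream seed,
#'   one column per directed coupling, input weight) and \code{config}.
#' @export
simulateCohort <- function(cfg, spec = enumeratePaperModels()[[16]],
                           hemo = HemoParams()) {
  stopifnot(is(cfg, "CohortConfig"))
  series <- list()
  rows <- list()
  r <- spec@regions
  couplingCols <- c(outer(r, r, function(d, s) paste0(s, "->", d)))
  couplingCols <- couplingCols[rep(r, each = 3) != rep(r, 3)]
  for (g in cfg@groups) for (tp in cfg@timepoints)
    for (i in seq_len(cfg@nPerGroup)) {
      sim <- simulateSubject(spec, g, tp, cfg, i, hemo, withTruth = TRUE)
      key <- sprintf("%s.%s.s%02d", g, tp, i)
      series[[key]] <- sim$series
      A <- sim$trueParams@A
      vals <- vapply(couplingCols, function(cc) {
        sd <- strsplit(cc, "->", fixed = TRUE)[[1]]
        A[sd[2], sd[1]]
      }, numeric(1))
      rows[[key]] <- data.frame(group = g, timepoint = tp, subject = i,
                                seed = sim$seed, t(vals),
                                inputWeight = sim$trueParams@C[1, 1],
                                check.names = FALSE)
    }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(series = series, manifest = manifest, config = cfg)
}

#' Write / read a ground-truth manifest (lossless JSON)
#'
#' @param manifest data.frame as produced by [simulateCohort()].
#' @param path JSON file path.
#' @return \code{writeManifest} returns \code{path} invisibly;
#'   \code{readManifest} the data.frame.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(doc, check.names = FALSE)
}
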