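#' Bilinear neural derivative
#'
#' Evaluates \eqn{dz/dt = (A + \sum_j u_j B^{(j)}) z + C u} for the neural
#' state \code{z} under input \code{u}.
#'
#' @param z neural state vector (one entry per region).
#' @param u input vector (one entry per driving input).
#' @param params a [NeuralParams-class].
#' @return numeric vector \eqn{dz/dt}.
#' @export
neuralDerivative <- function(z, u, params) {
  stopifnot(is(params, "NeuralParams"))
  A <- params@A
  if (length(z) != nrow(A)) stop("z has wrong length for A")
  if (length(u) != ncol(params@C)) stop("u has wrong length for C")
  Aeff <- A
  for (j in seq_along(u)) {
    if (u[j] != 0) Aeff <- Aeff + u[j] * params@B[[j]]
  }
  drop(Aeff %*% z + params@C %*% u)
}

#' Balloon-Windkessel hemodynamic derivative
#'
#' One region's hemodynamic state is (s, f, v, q): vasodilatory signal,
#' blood inflow, venous volume and deoxyhemoglobin content (the latter two
#' normalized to rest). Given neural activity \code{z}:
#' \deqn{ds/dt = z - \kappa s - \gamma (f - 1)}
#' \deqn{df/dt = s}
#' \deqn{\tau\, dv/dt = f - v^{1/\alpha}}
#' \deqn{\tau\, dq/dt = f\,[1-(1-E_0)^{1/f}]/E_0 - v^{1/\alpha} q / v}
#' The rest point (0, 1, 1, 1) with z = 0 is a fixed point.
#'
#' @param state numeric vector \code{c(s, f, v, q)}.
#' @param z scalar neural activity.
#' @param hemo a [HemoParams-class].
#' @return numeric vector \code{c(ds, df, dv, dq)}.
#' @export
hemoDerivative <- function(state, z, hemo) {
  stopifnot(is(hemo, "HemoParams"), length(state) == 4)
  s <- state[1]; f <- state[2]; v <- state[3]; q <- state[4]
  if (f <= 0 || v <= 0 || q <= 0)
    stop("hemodynamic state out of domain (f, v, q must be positive)")
  fout <- v^(1 / hemo@alpha)
  E <- 1 - (1 - hemo@E0)^(1 / f)
  c(ds = z - hemo@kappa * s - hemo@gamma * (f - 1),
    df = s,
    dv = (f - fout) / hemo@tau,
    dq = (f * E / hemo@E0 - fout * q / v) / hemo@tau)
}

#' BOLD observation equation
#'
#' Classic static BOLD nonlinearity
#' \eqn{y = V_0 [k_1(1-q) + k_2(1-q/v) + k_3(1-v)]} with
#' \eqn{k_1 = 7E_0}, \eqn{k_2 = 2}, \eqn{k_3 = 2E_0 - 0.2}. Returns the
#' fractional signal change (multiply by 100 for percent); zero at rest
#' (v = q = 1).
#'
#' @param v,q venous volume and deoxyhemoglobin content (rest-normalized).
#' @param hemo a [HemoParams-class].
#' @return fractional BOLD signal change.
#' @export
boldObservation <- function(v, q, hemo = HemoParams()) {
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be positive")
  k1 <- 7 * hemo@E0; k2 <- 2; k3 <- 2 * hemo@E0 - 0.2
  hemo@V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Integrate a DCM forward model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the bilinear neural
#' equations coupled to per-region balloon-Windkessel hemodynamics,
#' starting from rest, with the BOLD output sampled at scan times
#' \eqn{k \cdot TR}, \eqn{k = 1..nScans}. Venous volume and
#' deoxyhemoglobin are integrated in log-space so positivity cannot be
#' lost. Deterministic: identical inputs give bit-identical output.
#'
#' @param params a [NeuralParams-class]; the driving input must be a
#'   single column of \code{C} (the block-design stimulus).
#' @param hemo a [HemoParams-class] shared across regions.
#' @param design a [StimulusDesign-class].
#' @param dt integration step (s); must divide TR and satisfy
#'   \code{dt <= TR/4}. Default \code{TR/8}.
#' @param regionNames optional column labels for the output.
#' @return an [ROITimeSeries-class] of noiseless BOLD in percent signal
#'   change.
#' @export
integrateDCM <- function(params, hemo, design, dt = design@TR / 8,
                         regionNames = NULL) {
  stopifnot(is(params, "NeuralParams"), is(hemo, "HemoParams"),
            is(design, "StimulusDesign"))
  if (ncol(params@C) != 1)
    stop("integrateDCM supports a single driving input (one column of C)")
  if (dt > design@TR / 4 + 1e-12)
    stop("dt must satisfy dt <= TR/4")
  A <- params@A
  ev <- eigen(A, only.values = TRUE)$values
  Bm <- params@B[[1]]
  out <- tryCatch(
    .dcm_integrate_cpp(A, as.numeric(params@C[, 1]),
                       if (any(Bm != 0)) Bm else NULL,
                       design@onsets, design@durations,
                       design@TR, design@nScans, dt,
                       c(hemo@kappa, hemo@gamma, hemo@tau,
                         hemo@alpha, hemo@E0, hemo@V0)),
    error = function(e) {
      if (grepl("diverged", conditionMessage(e))) {
        worst <- ev[which.max(Re(ev))]
        stop(sprintf(
          "unstable DCM: state diverged; largest Re eigenvalue of A = %.4f (eigenvalue %s)",
          max(Re(ev)), format(worst, digits = 4)), call. = FALSE)
      }
      stop(e)
    })
  if (is.null(regionNames)) {
    regionNames <- rownames(A)
    if (is.null(regionNames))
      regionNames <- paste0("R", seq_len(nrow(A)))
  }
  colnames(out) <- regionNames
  ROITimeSeries(out, design)
}

#' Write / read an ROI time series as TSV + YAML sidecar
#'
#' The TSV holds a \code{time_s} column plus one column per region; the
#' sidecar (same path with extension \code{.yaml}) records TR, onsets and
#' durations so the series round-trips.
#'
#' @param x an [ROITimeSeries-class].
#' @param path TSV path; sidecar path is derived from it.
#' @return \code{writeROITimeSeries} returns \code{path} invisibly;
#'   \code{readROITimeSeries} returns the [ROITimeSeries-class].
#' @export
writeROITimeSeries <- function(x, path) {
  stopifnot(is(x, "ROITimeSeries"))
  df <- data.frame(time_s = seq_len(nrow(x@series)) * x@TR, x@series,
                   check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.[^.]*$", ".yaml", path)
  yaml::write_yaml(list(TR = x@TR, n_scans = x@design@nScans,
                        onsets = as.list(x@design@onsets),
                        durations = as.list(x@design@durations)), side)
  invisible(path)
}

#' @rdname writeROITimeSeries
#' @export
readROITimeSeries <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  side <- yaml::read_yaml(sub("\\.[^.]*$", ".yaml", path))
  design <- StimulusDesign(unlist(side$onsets), unlist(side$durations),
                           side$TR, side$n_scans)
  m <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  ROITimeSeries(m, design)
}
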