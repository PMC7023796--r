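#' Build the long-format coupling table from winning-model fits
#'
#' One row per subject x condition x directed connection, holding the
#' posterior-mean coupling (Hz) extracted from each subject's fit of the
#' winning model. The six canonical connection labels are
#' \code{h->S1, AMY->S1, S1->h, S1->AMY, h->AMY, AMY->h}.
#'
#' @param fits list of records, each
#'   \code{list(group=, timepoint=, subject=, fit=PosteriorEstimate)};
#'   records with a missing/NULL fit are dropped with a warning.
#' @param spec the winning model's [DCMSpec-class] (names the
#'   connections).
#' @return data.frame: subject, group, timepoint, connection, coupling.
#' @export
buildCouplingTable <- function(fits, spec) {
  stopifnot(is(spec, "DCMSpec"))
  e <- spec@edges
  labels <- paste0(e[, 1], "->", e[, 2])
  rows <- list()
  nMissing <- 0L
  for (rec in fits) {
    if (is.null(rec$fit)) { nMissing <- nMissing + 1L; next }
    mu <- rec$fit@mu
    vals <- mu[paste0("A:", labels)]
    rows[[length(rows) + 1L]] <- data.frame(
      subject = rec$subject, group = rec$group, timepoint = rec$timepoint,
      connection = labels, coupling = unname(vals))
  }
  if (nMissing > 0)
    warning(sprintf("%d fit(s) missing; corresponding rows absent", nMissing))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  counts <- table(out$group, out$timepoint)
  if (length(unique(counts)) > 1)
    warning("unbalanced design: unequal cell counts")
  out
}

#' Two-way ANOVA with Tukey post-hoc for one connection
#'
#' Fits \code{coupling ~ group * timepoint} for the selected connection
#' and reports the ANOVA table plus Tukey HSD adjusted p-values for the
#' pairwise contrasts of the group x timepoint cells, flagged at adjusted
#' p < 0.05. The contrasts of interest are the within-group comparisons
#' across time points and the between-group comparisons at each time
#' point. An optional Benjamini-Hochberg mode adjusts the unadjusted
#' pairwise p-values by FDR instead.
#'
#' @param table coupling table from [buildCouplingTable()].
#' @param connection one of the six connection labels.
#' @param method \code{"tukey"} (default) or \code{"BH"}.
#' @param alpha significance level for the flag (default 0.05).
#' @return list: \code{anova} (data.frame with F and p per term),
#'   \code{contrasts} (data.frame: contrast, estimate, pAdj, significant),
#'   \code{method}.
#' @export
compareConnection <- function(table, connection, method = c("tukey", "BH"),
                              alpha = 0.05) {
  method <- match.arg(method)
  d <- table[table$connection == connection, , drop = FALSE]
  if (nrow(d) == 0) stop("unknown connection: ", connection)
  d$group <- factor(d$group)
  d$timepoint <- factor(d$timepoint, levels = unique(table$timepoint))
  if (nlevels(d$group) < 2 || nlevels(d$timepoint) < 2)
    stop("need at least 2 levels per factor")
  if (stats::sd(d$coupling) < 1e-12)
    stop("degenerate variance: all coupling values identical")
  fit <- aov(coupling ~ group * timepoint, data = d)
  an <- summary(fit)[[1]]
  anova <- data.frame(term = trimws(rownames(an)),
                      df = an$Df, sumSq = an$`Sum Sq`,
                      F = an$`F value`, p = an$`Pr(>F)`)

  cellMeans <- tapply(d$coupling, interaction(d$group, d$timepoint, sep = ":"),
                      mean)
  tk <- TukeyHSD(fit, "group:timepoint")$`group:timepoint`
  keep <- .relevantContrasts(rownames(tk))
  tk <- tk[keep, , drop = FALSE]
  if (method == "tukey") {
    pAdj <- tk[, "p adj"]
  } else {
    # unadjusted pairwise p from the pooled-variance t statistic, BH-corrected
    pRaw <- .pairwiseRawP(d, rownames(tk), fit)
    pAdj <- p.adjust(pRaw, "BH")
  }
  contrasts <- data.frame(contrast = rownames(tk),
                          estimate = tk[, "diff"],
                          pAdj = unname(pAdj),
                          significant = unname(pAdj < alpha))
  rownames(contrasts) <- NULL
  list(anova = anova, contrasts = contrasts, method = method,
       cellMeans = cellMeans)
}

# keep within-group across-timepoint and between-group within-timepoint pairs
.relevantContrasts <- function(labels) {
  vapply(labels, function(lb) {
    ab <- strsplit(lb, "-", fixed = TRUE)[[1]]
    a <- strsplit(ab[1], ":", fixed = TRUE)[[1]]
    b <- strsplit(ab[2], ":", fixed = TRUE)[[1]]
    a[1] == b[1] || a[2] == b[2]
  }, logical(1))
}

# unadjusted two-sample t p-values on the residual variance of the fit
.pairwiseRawP <- function(d, labels, fit) {
  mse <- sum(fit$residuals^2) / fit$df.residual
  cell <- interaction(d$group, d$timepoint, sep = ":")
  vapply(labels, function(lb) {
    ab <- strsplit(lb, "-", fixed = TRUE)[[1]]
    xa <- d$coupling[cell == ab[1]]
    xb <- d$coupling[cell == ab[2]]
    se <- sqrt(mse * (1 / length(xa) + 1 / length(xb)))
    tt <- (mean(xa) - mean(xb)) / se
    2 * pt(-abs(tt), fit$df.residual)
  }, numeric(1))
}

#' Compare all connections of the winning model
#'
#' Runs [compareConnection()] for every connection label in the table and
#' assembles a tidy statistics table.
#'
#' @param table coupling table from [buildCouplingTable()].
#' @param method,alpha passed to [compareConnection()].
#' @return data.frame: connection, contrast, estimate, F (interaction
#'   term), pAdj, significant.
#' @export
compareAllConnections <- function(table, method = "tukey", alpha = 0.05) {
  out <- lapply(unique(table$connection), function(cc) {
    r <- compareConnection(table, cc, method = method, alpha = alpha)
    Fint <- r$anova$F[r$anova$term == "group:timepoint"]
    data.frame(connection = cc, contrast = r$contrasts$contrast,
               estimate = r$contrasts$estimate,
               interactionF = Fint,
               pAdj = r$contrasts$pAdj,
               significant = r$contrasts$significant)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write coupling statistics and the coupling table as TSV
#'
#' @param stats data.frame from [compareAllConnections()].
#' @param table data.frame from [buildCouplingTable()].
#' @param dir output directory.
#' @return \code{dir} invisibly.
#' @export
writeCouplingStats <- function(stats, table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(stats, file.path(dir, "coupling_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(table, file.path(dir, "coupling_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
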