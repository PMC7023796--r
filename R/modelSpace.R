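#' Enumerate the canonical 16-model space of the 3-region pain network
#'
#' Builds the full candidate space of directed-connectivity hypotheses over
#' S1 (primary somatosensory cortex), AMY (amygdala) and h (hypothalamus),
#' with the driving stimulus input entering at S1. The space is organized
#' in three families of propagation hypotheses:
#' \describe{
#'   \item{family 1 (models 1-4)}{serial pathway S1 -> AMY -> h; each of
#'     the two links is forward-only or bidirectional (4 variants).}
#'   \item{family 2 (models 5-8)}{serial pathway S1 -> h -> AMY; each of
#'     the two links is forward-only or bidirectional (4 variants).}
#'   \item{family 3 (models 9-16)}{closed loop: all three region pairs are
#'     connected; each pair independently forward-only (in the loop
#'     direction S1 -> AMY -> h -> S1) or bidirectional (8 variants).}
#' }
#' Model 16 is the fully bidirectional closed-loop model with all six
#' directed edges. Enumeration is deterministic and order-stable.
#'
#' @param regions region labels, in order; default \code{c("S1","AMY","h")}.
#' @return a list of 16 [DCMSpec-class] objects, ordered by model id.
#' @examples
#' space <- enumeratePaperModels()
#' length(space)                    # 16
#' table(vapply(space, familyId, 1L))
#' @export
enumeratePaperModels <- function(regions = c("S1", "AMY", "h")) {
  stopifnot(length(regions) == 3)
  S1 <- regions[1]; AMY <- regions[2]; h <- regions[3]

  # a "link" is a region pair with a forward direction; variant 0 keeps the
  # forward edge only, variant 1 adds the reverse edge
  linkEdges <- function(pair, bidir) {
    e <- list(pair)
    if (bidir) e <- c(e, list(rev(pair)))
    e
  }
  specs <- list(); id <- 0L

  serialFamily <- function(famId, firstPair, secondPair) {
    out <- list()
    for (b2 in 0:1) for (b1 in 0:1) {
      # variant order: (fwd,fwd), (bidir,fwd), (fwd,bidir), (bidir,bidir)
      ed <- c(linkEdges(firstPair, b1 == 1), linkEdges(secondPair, b2 == 1))
      out[[length(out) + 1L]] <- ed
    }
    out
  }
  fam1 <- serialFamily(1L, c(S1, AMY), c(AMY, h))
  fam2 <- serialFamily(2L, c(S1, h), c(h, AMY))
  fam3 <- list()
  loopPairs <- list(c(S1, AMY), c(AMY, h), c(h, S1))
  for (k in 0:7) {
    bidir <- as.logical(bitwAnd(k, 2^(0:2)))
    ed <- unlist(lapply(seq_along(loopPairs), function(i)
      linkEdges(loopPairs[[i]], bidir[i])), recursive = FALSE)
    fam3[[k + 1L]] <- ed
  }
  allEdges <- c(fam1, fam2, fam3)
  famOf <- rep(1:3, times = c(4L, 4L, 8L))
  for (i in seq_along(allEdges)) {
    specs[[i]] <- DCMSpec(regions = regions, edges = allEdges[[i]],
                          inputTargets = S1,
                          familyId = famOf[i], modelId = i)
  }
  specs
}

#' Adjacency matrix of a model specification
#'
#' Binary structure matrix over the model's regions: entry (i, j) is 1 if
#' the directed connection from region j to region i is present, or if
#' i = j (self-connections are always on).
#'
#' @param spec a [DCMSpec-class].
#' @return square 0/1 matrix with region dimnames.
#' @examples
#' m16 <- enumeratePaperModels()[[16]]
#' specToAdjacency(m16)   # all ones
#' @export
specToAdjacency <- function(spec) {
  stopifnot(is(spec, "DCMSpec"))
  validObject(spec)
  r <- spec@regions
  n <- length(r)
  adj <- diag(1, n)
  dimnames(adj) <- list(r, r)
  e <- spec@edges
  if (nrow(e)) {
    if (!all(e %in% r)) stop("edge references unknown region")
    for (k in seq_len(nrow(e))) adj[e[k, 2], e[k, 1]] <- 1
  }
  adj
}

#' Canonical serialization key of a model's wiring
#'
#' Sorted "src->dst" edge labels; used to check the space for duplicates.
#' @param spec a [DCMSpec-class].
#' @return single character key.
#' @export
specKey <- function(spec) {
  e <- spec@edges
  if (!nrow(e)) return("")
  paste(sort(paste(e[, 1], e[, 2], sep = "->")), collapse = ";")
}

#' Write / read a model space as JSON
#'
#' One object per model with fields \code{model_id}, \code{family_id},
#' \code{regions}, \code{input_targets} and \code{edges} as
#' \code{[src, dst]} pairs.
#'
#' @param specs list of [DCMSpec-class] objects.
#' @param path file path for the JSON document.
#' @return \code{writeModels} returns \code{path} invisibly;
#'   \code{readModels} returns the list of specs.
#' @export
writeModels <- function(specs, path) {
  doc <- lapply(specs, function(s) {
    ed <- s@edges
    list(model_id = s@modelId, family_id = s@familyId,
         regions = s@regions, input_targets = s@inputTargets,
         edges = if (nrow(ed)) lapply(seq_len(nrow(ed)),
                                      function(i) unname(ed[i, ]))
                 else list())
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModels
#' @export
readModels <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, function(m) {
    ed <- if (length(m$edges))
      do.call(rbind, lapply(m$edges, function(e) unlist(e)))
    else NULL
    DCMSpec(regions = unlist(m$regions), edges = ed,
            inputTargets = unlist(m$input_targets),
            familyId = m$family_id, modelId = m$model_id)
  })
}
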