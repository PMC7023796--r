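# evidence table over the canonical space with given per-model group deltas
tableFor <- function(F, familyIds = NULL, modelIds = NULL) {
  F <- as.matrix(F)
  if (is.null(modelIds)) modelIds <- seq_len(ncol(F))
  if (is.null(familyIds)) familyIds <- rep(1:3, c(4, 4, 8))[seq_len(ncol(F))]
  EvidenceTable(F, modelIds, familyIds)
}

test_that("fixed-effects pooling is additive and permutation-invariant", {
  set.seed(1)
  F <- matrix(rnorm(4 * 16, -500, 20), 4, 16)
  tab <- tableFor(F)
  expect_equal(unname(ffxPool(tab)), colSums(F))
  # one subject: identity
  expect_equal(unname(ffxPool(tableFor(F[1, , drop = FALSE]))), F[1, ])
  # two identical subjects double every pooled difference
  tab2 <- tableFor(rbind(F[1, ], F[1, ]))
  d1 <- ffxPool(tableFor(F[1, , drop = FALSE]))
  expect_equal(diff(ffxPool(tab2)), 2 * diff(d1))
  # permuting subject rows changes nothing
  expect_equal(ffxPool(tableFor(F[c(3, 1, 4, 2), ])), ffxPool(tab))
})

test_that("model posteriors are a shift-invariant stable softmax", {
  p <- modelPosterior(c(a = 10, b = 0))
  expect_equal(unname(p[1]), 0.9999546, tolerance = 1e-7)
  expect_equal(unname(p[2]), 4.54e-5, tolerance = 1e-3)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # equal evidence, uniform prior: uniform posterior
  expect_equal(unname(modelPosterior(rep(3, 5))), rep(0.2, 5))
  # adding a constant changes nothing
  expect_equal(modelPosterior(c(a = 10, b = 0) + 123.4), p)
  # no overflow for |F| up to 1e4
  big <- modelPosterior(c(9e3, -9e3, 8.9e3))
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1)
  expect_error(modelPosterior(c(1, 2), prior = c(0.7, 0.6)), "sum to 1")
})

test_that("family inference corrects for unequal family sizes", {
  # equal evidence everywhere: families tie at 1/3 despite the 4/4/8 split
  tab <- tableFor(matrix(-100, 2, 16))
  fam <- familyInference(tab)
  expect_equal(unname(fam$familyPosterior), rep(1 / 3, 3),
               tolerance = 1e-12)
  expect_equal(sum(fam$familyPosterior), 1)
  # one dominant model pulls its family above 0.999
  F <- matrix(-100, 1, 16)
  F[1, 16] <- -50
  fam2 <- familyInference(tableFor(F))
  expect_equal(fam2$winningFamily, 3L)
  expect_gt(fam2$familyPosterior["3"], 0.999)
  expect_error(familyInference(tab, familyPrior = c(0.5, 0.5)),
               "one prior entry per family")
})

test_that("Bayes factors follow the evidence-ratio definition", {
  expect_equal(bayesFactor(-10, -10)$bf, 1)
  expect_equal(bayesFactor(log(60), 0)$bf, 60)
  bf <- bayesFactor(-3, -9)
  expect_equal(bf$bf * bayesFactor(-9, -3)$bf, 1)
  expect_equal(bf$log10bf, 6 / log(10))
})

test_that("two-stage selection picks family then model consistently", {
  set.seed(2)
  F <- matrix(rnorm(3 * 16, -800, 5), 3, 16)
  F[, 16] <- F[, 16] + 40
  res <- selectModels(tableFor(F))
  expect_equal(res@winningFamily, 3L)
  expect_equal(res@winningModel, 16L)
  expect_equal(sum(res@withinFamilyPosterior), 1, tolerance = 1e-12)
  expect_equal(sum(res@modelPosterior), 1, tolerance = 1e-12)
  expect_gt(res@bayesFactor, 1)
  # a single-model table wins with probability 1
  one <- EvidenceTable(matrix(-5, 2, 1), 1L, 1L)
  res1 <- selectModels(one)
  expect_equal(unname(res1@modelPosterior), 1)
  expect_equal(res1@winningModel, 1L)
})

test_that("selection is invariant to model ordering and agrees with the
           single-stage argmax when one model dominates", {
  set.seed(3)
  for (i in 1:20) {
    F <- matrix(rnorm(2 * 16, -600, 8), 2, 16)
    tab <- tableFor(F)
    res <- selectModels(tab)
    # permuted column order gives the same winner and probabilities
    perm <- sample(16)
    tabP <- EvidenceTable(F[, perm], (1:16)[perm],
                          rep(1:3, c(4, 4, 8))[perm])
    resP <- selectModels(tabP)
    expect_equal(resP@winningModel, res@winningModel)
    expect_equal(resP@familyPosterior, res@familyPosterior,
                 tolerance = 1e-12)
    expect_equal(sort(resP@modelPosterior), sort(res@modelPosterior),
                 tolerance = 1e-12)
    # agreement with the single-stage argmax (same size-corrected prior)
    # whenever one model's posterior exceeds 0.5
    post <- res@modelPosterior
    if (max(post) > 0.5)
      expect_equal(res@winningModel,
                   as.integer(names(post)[which.max(post)]))
  }
})

test_that("BMS results serialize with a readable report", {
  F <- matrix(rnorm(2 * 16, -300, 10), 2, 16)
  res <- selectModels(tableFor(F))
  path <- file.path(withr::local_tempdir(), "bms.json")
  writeBMSResult(res, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$winning_model, res@winningModel)
  expect_true(file.exists(sub("json$", "txt", path)))
})
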