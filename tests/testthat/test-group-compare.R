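test_that("coupling table extraction mirrors the fit posteriors", {
  labels <- paste0("A:", c("S1->AMY", "AMY->h", "h->S1",
                           "AMY->S1", "h->AMY", "S1->h"))
  recs <- list()
  for (g in c("model", "EA")) for (tp in c("pre", "post", "treated"))
    for (i in 1:8) {
      mu <- setNames(c(rnorm(6, 0.2, 0.05), rep(0, 3), 0.5),
                     c(labels, "self:S1", "self:AMY", "self:h", "C:S1"))
      recs[[length(recs) + 1L]] <- list(group = g, timepoint = tp,
                                        subject = i, fit = fakeFit(mu))
    }
  tab <- buildCouplingTable(recs, model16)
  expect_equal(nrow(tab), 2 * 8 * 3 * 6)
  expect_equal(sort(unique(tab$connection)),
               sort(c("S1->AMY", "AMY->S1", "S1->h", "h->S1",
                      "AMY->h", "h->AMY")))
  # extraction identity: values are the mu entries of the fits
  first <- tab[tab$subject == 1 & tab$group == "model" &
                 tab$timepoint == "pre", ]
  mu1 <- recs[[1]]$fit@mu
  for (k in seq_len(nrow(first)))
    expect_equal(first$coupling[k],
                 unname(mu1[paste0("A:", first$connection[k])]))
  # a missing fit drops rows with a warning, never silently zeroes
  # (the now-unbalanced design warns as well)
  recs[[1]]$fit <- NULL
  w <- capture_warnings(tab2 <- buildCouplingTable(recs, model16))
  expect_true(any(grepl("missing", w)))
  expect_true(any(grepl("unbalanced", w)))
  expect_equal(nrow(tab2), nrow(tab) - 6)
})

test_that("a configured group-time effect is detected by the ANOVA", {
  tab <- makeCouplingTable(nPerGroup = 8, effect = 0.3, seed = 2)
  res <- compareConnection(tab, "h->S1")
  expect_true(all(c("group", "timepoint", "group:timepoint") %in%
                    res$anova$term))
  prePost <- grepl("pre", res$contrasts$contrast) &
    grepl("post", res$contrasts$contrast) &
    !grepl("treated", res$contrasts$contrast)
  withinGroup <- vapply(strsplit(res$contrasts$contrast, "[-:]"),
                        function(x) x[1] == x[3], logical(1))
  expect_true(any(res$contrasts$significant[prePost & withinGroup]))
})

test_that("ANOVA sum of squares decomposes exactly", {
  tab <- makeCouplingTable(nPerGroup = 6, effect = 0.2, seed = 3)
  res <- compareConnection(tab, "AMY->S1")
  d <- tab[tab$connection == "AMY->S1", ]
  ssTot <- sum((d$coupling - mean(d$coupling))^2)
  expect_equal(sum(res$anova$sumSq), ssTot, tolerance = 1e-8 * ssTot)
})

test_that("Tukey adjustment never falls below the raw pairwise p", {
  tab <- makeCouplingTable(nPerGroup = 8, effect = 0.15, seed = 4)
  tk <- compareConnection(tab, "h->S1", method = "tukey")
  bh <- compareConnection(tab, "h->S1", method = "BH")
  raw <- painDCM:::.pairwiseRawP(
    transform(tab[tab$connection == "h->S1", ],
              group = factor(group),
              timepoint = factor(timepoint, levels = c("pre", "post",
                                                       "treated"))),
    tk$contrasts$contrast,
    aov(coupling ~ group * timepoint,
        data = tab[tab$connection == "h->S1", ]))
  expect_true(all(tk$contrasts$pAdj >= raw - 1e-12))
  expect_true(all(bh$contrasts$pAdj >= raw - 1e-12))
})

test_that("null data give interaction F near 1 and degenerate input errors", {
  set.seed(5)
  Fs <- replicate(40, {
    tab <- makeCouplingTable(nPerGroup = 6, effect = 0,
                             seed = sample.int(1e6, 1))
    res <- compareConnection(tab, "S1->h")
    res$anova$F[res$anova$term == "group:timepoint"]
  })
  expect_equal(mean(Fs), 1, tolerance = 0.35)
  tabC <- makeCouplingTable(nPerGroup = 4, noise = 0)
  expect_error(compareConnection(tabC, "h->S1"), "degenerate")
})

test_that("relabeling timepoints permutes contrasts, not their p-values", {
  tab <- makeCouplingTable(nPerGroup = 8, effect = 0.25, seed = 6)
  res1 <- compareConnection(tab, "h->S1")
  tab2 <- tab
  map <- c(pre = "T1", post = "T2", treated = "T3")
  tab2$timepoint <- unname(map[tab2$timepoint])
  res2 <- compareConnection(tab2, "h->S1")
  relabel <- function(x) {
    for (k in seq_along(map)) x <- gsub(names(map)[k], map[k], x)
    x
  }
  key1 <- setNames(res1$contrasts$pAdj, relabel(res1$contrasts$contrast))
  key2 <- setNames(res2$contrasts$pAdj, res2$contrasts$contrast)
  common <- intersect(names(key1), names(key2))
  expect_gt(length(common), 0)
  expect_equal(key1[common], key2[common], tolerance = 1e-12)
})

test_that("all six connections are compared and written to TSV", {
  tab <- makeCouplingTable(nPerGroup = 6, effect = 0.2, seed = 7)
  stats <- compareAllConnections(tab)
  expect_equal(length(unique(stats$connection)), 6)
  dir <- withr::local_tempdir()
  writeCouplingStats(stats, tab, dir)
  expect_true(file.exists(file.path(dir, "coupling_stats.tsv")))
  back <- read.table(file.path(dir, "coupling_stats.tsv"), sep = "\t",
                     header = TRUE)
  expect_equal(nrow(back), nrow(stats))
})
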