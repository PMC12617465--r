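## small, well-separated simulation study reused across the blocks below
.sepSetup <- function(nSims = 400, seed = 71) {
  mut <- mutationModel(L = 2000, mu = 2e-6)
  tabs <- buildReferenceTable(
    list(small = twoPopTemplate(100, name = "small"),
         large = twoPopTemplate(10000, name = "large")),
    mut = mut, nSimsPerModel = nSims, seed = seed)
  list(table = tabs, mut = mut)
}

test_that("reference tables are balanced, labelled and reproducible", {
  s <- .sepSetup(nSims = 30)
  tab <- s$table
  expect_equal(nrow(tab@stats), 60L)
  expect_equal(as.integer(table(tab@model)), c(30L, 30L))
  expect_false(anyNA(tab@stats))

  again <- buildReferenceTable(
    list(small = twoPopTemplate(100, name = "small"),
         large = twoPopTemplate(10000, name = "large")),
    mut = s$mut, nSimsPerModel = 30, seed = 71)
  expect_identical(tab@stats, again@stats)
})

test_that("LDA axes separate distinguishable models and project linearly", {
  s <- .sepSetup(nSims = 100)
  tab <- addLdaAxes(s$table)
  expect_true("LDA1" %in% colnames(tab@stats))
  expect_length(grep("^LDA", colnames(tab@stats)), 1L)  # k - 1 axes for 2 models
  expect_error(addLdaAxes(tab), "already")

  ax <- tab@stats[, "LDA1"]
  sep <- abs(mean(ax[tab@model == "small"]) - mean(ax[tab@model == "large"])) /
    sd(ax)
  expect_gt(sep, 1)   # clear separation for Ne 100 vs 10,000

  ## permuted class labels carry no separation
  set.seed(72)
  nulls <- replicate(20, {
    shuf <- s$table
    shuf@model <- sample(shuf@model)
    a <- addLdaAxes(shuf)
    x <- a@stats[, "LDA1"]
    abs(mean(x[shuf@model == "small"]) - mean(x[shuf@model == "large"])) / sd(x)
  })
  expect_lt(mean(nulls), 0.5)

  ## the stored projection is the linear map it claims to be
  raw <- s$table@stats[3, s$table@statNames]
  v <- augmentObserved(tab, raw)
  proj <- tab@lda
  manual <- as.numeric(((raw[proj$keep] - proj$center) / proj$scale) %*% proj$loadings)
  expect_equal(unname(v["LDA1"]), manual, tolerance = 1e-9)

  ## agreement with an independent LDA implementation on the same data
  xmat <- s$table@stats[, s$table@statNames]
  xmat <- xmat[, apply(xmat, 2, sd) > 0]
  ml <- suppressWarnings(MASS::lda(xmat, grouping = s$table@model))
  mlAx <- as.numeric(predict(ml, xmat)$x[, 1])
  expect_gt(abs(cor(mlAx, ax)), 0.99)
})

test_that("well-separated models give a near-zero OOB error and reliable recovery", {
  s <- .sepSetup(nSims = 1000)
  tab <- addLdaAxes(s$table)
  clf <- trainClassifier(tab, nTrees = 500, seed = 73)
  expect_lt(clf@oobError, 0.05)

  ## OOB error recomputed independently from the stored OOB votes
  expect_equal(clf@oobError, mean(clf@oobPred != tab@model), tolerance = 1e-12)

  ## fresh datasets from each model are recovered almost always
  hits <- 0
  tSmall <- twoPopTemplate(100, name = "small")
  tLarge <- twoPopTemplate(10000, name = "large")
  pops <- list(pop1 = sprintf("pop1_%03d", 1:10), pop2 = sprintf("pop2_%03d", 1:10))
  for (i in 1:50) {
    dsS <- simulateDataset(tSmall, s$mut, seed = 7300 + i)
    dsL <- simulateDataset(tLarge, s$mut, seed = 7600 + i)
    rS <- selectModel(clf, summaryStatistics(dsS@alignment, pops))
    rL <- selectModel(clf, summaryStatistics(dsL@alignment, pops))
    hits <- hits + (rS@selected == "small") + (rL@selected == "large")
    expect_equal(sum(rS@votes), 500)
    expect_equal(rS@nTrees, 500)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("model-choice diagnostics are internally consistent", {
  s <- .sepSetup(nSims = 150)
  clf <- trainClassifier(addLdaAxes(s$table), nTrees = 500, seed = 74)
  ds <- simulateDataset(twoPopTemplate(100, name = "small"), s$mut, seed = 75)
  r <- selectModel(clf, summaryStatistics(
    ds@alignment, list(pop1 = sprintf("pop1_%03d", 1:10),
                       pop2 = sprintf("pop2_%03d", 1:10))))
  expect_equal(sum(r@votes), 500)
  expect_true(r@posterior >= 0 && r@posterior <= 1)
  expect_equal(rowSums(r@confusion), c(large = 150, small = 150))
  expect_equal(unname(r@ce),
               unname(1 - diag(r@confusion) / rowSums(r@confusion)))
  expect_length(r@ldaProjection, 1L)
})

test_that("hierarchical stages carry winners forward and report full diagnostics", {
  mut <- mutationModel(L = 1000, mu = 2e-6)
  tpls <- list(small = twoPopTemplate(100, name = "small"),
               large = twoPopTemplate(10000, name = "large"),
               mid = twoPopTemplate(1000, name = "mid"))
  ds <- simulateDataset(tpls$small, mut, seed = 76)
  obs <- summaryStatistics(ds@alignment,
                           list(pop1 = sprintf("pop1_%03d", 1:10),
                                pop2 = sprintf("pop2_%03d", 1:10)))
  res <- hierarchicalComparison(
    tpls, obs,
    stages = list(c("small", "large"), c("mid", "large"),
                  c("winner:1", "winner:2")),
    nSimsPerModel = 120, mut = mut, seed = 77, nTrees = 300)
  expect_length(res, 3L)
  expect_equal(res$stage1@selected, "small")
  expect_setequal(rownames(res$stage3@confusion),
                  unique(c(res$stage1@selected, res$stage2@selected)))
  expect_equal(nrow(res$stage2@confusion), 2L)
  expect_error(hierarchicalComparison(tpls, obs, stages = list(),
                                      nSimsPerModel = 5, seed = 1),
               "empty")
  expect_error(hierarchicalComparison(tpls, obs,
                                      stages = list(c("winner:1", "large")),
                                      nSimsPerModel = 5, seed = 1),
               "winner")
})
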