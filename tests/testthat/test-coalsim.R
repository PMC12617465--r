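test_that("two lineages in one deme coalesce at rate 1/Ne on average", {
  m <- demographicModel("D", c(D = 500))
  tips <- data.frame(id = c("a", "b"), deme = "D", time = 0)
  set.seed(31)
  t2 <- vapply(1:20000, function(i) tmrca(simulateGenealogy(m, tips)),
               numeric(1))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 500), 3 * se)
})

test_that("disconnected demes raise a non-coalescence error", {
  m <- demographicModel(c("D1", "D2"), c(D1 = 100, D2 = 100))
  tips <- data.frame(id = c("a", "b"), deme = c("D1", "D2"), time = 0)
  expect_error(simulateGenealogy(m, tips, seed = 1), "non-coalescence")
})

test_that("serial sampling constrains the TMRCA and ancient tip depths", {
  m <- demographicModel("D", c(D = 50))   # tiny Ne: coalescence well before tau
  for (s in 1:50) {
    tips <- data.frame(id = c("old", "new1", "new2"), deme = "D",
                       time = c(40, 0, 0))
    gen <- simulateGenealogy(m, tips, seed = s)
    expect_gte(tmrca(gen), 40)
    ## the ancient tip's branch starts at its sampling time: its root-to-tip
    ## path is exactly rootTime - tau
    depths <- ape::node.depth.edgelength(gen@tree)
    rootTime <- tmrca(gen)
    i <- match("old", gen@tree$tip.label)
    expect_equal(rootTime - depths[i], 40, tolerance = 1e-9)
    j <- match("new1", gen@tree$tip.label)
    expect_equal(rootTime - depths[j], 0, tolerance = 1e-9)
  }
})

test_that("high symmetric migration removes differentiation between demes", {
  tpl <- customTemplate("island",
    data.frame(group = c("p1", "p2"), deme = c("D1", "D2"), n = 10,
               age_mean = 0, age_sd = 0),
    list(ne_D1 = 1000, ne_D2 = 1000), migration = 0.1)
  mut <- mutationModel(L = 2000, mu = 5e-6)
  set.seed(32)
  fst <- vapply(1:40, function(i) {
    ds <- simulateDataset(tpl, mut, seed = 3200 + i)
    a <- ds@alignment
    pairwiseFst(subsetSamples(a, sampleIds(a)[1:10]),
                subsetSamples(a, sampleIds(a)[11:20]))
  }, numeric(1))
  expect_lt(mean(fst), 0.02)
})

test_that("mutation overlay obeys the Poisson clock and determinism", {
  m <- demographicModel("D", c(D = 100))
  tips <- data.frame(id = letters[1:5], deme = "D", time = 0)
  gen <- simulateGenealogy(m, tips, seed = 33)

  ## mu = 0: all sequences identical
  a0 <- mutateGenealogy(gen, mutationModel(L = 100, mu = 0), seed = 1)
  expect_equal(length(haplotypeCounts(collapseHaplotypes(a0))), 1L)

  ## fixed seed: bit-identical alignments
  mut <- mutationModel(L = 500, mu = 1e-4)
  a1 <- mutateGenealogy(gen, mut, seed = 9)
  a2 <- mutateGenealogy(gen, mut, seed = 9)
  expect_identical(alignmentMatrix(a1), alignmentMatrix(a2))

  ## star tree with branch length t: expected pairwise differences ~ 2 t mu L
  n <- 6; tgen <- 30
  star <- structure(list(
    edge = cbind(rep(n + 1L, n), seq_len(n)),
    edge.length = rep(tgen, n),
    tip.label = paste0("t", seq_len(n)), Nnode = 1L), class = "phylo")
  sgen <- new("Genealogy", tree = star,
              tipTimes = setNames(rep(0, n), star$tip.label),
              nodeTimes = c(rep(0, n), tgen),
              tipDemes = setNames(rep("D", n), star$tip.label))
  mu <- 1e-4; L <- 1000
  set.seed(34)
  pis <- vapply(1:800, function(i)
    meanPairwiseDifferences(mutateGenealogy(sgen, mutationModel(L = L, mu = mu))),
    numeric(1))
  expected <- 2 * tgen * mu * L
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * se)
})

test_that("parameter draws respect their distributions", {
  pr <- priorSpec(a = list(dist = "fixed", value = 1000),
                  b = list(dist = "uniform", min = 10, max = 10),
                  c = list(dist = "loguniform", min = 1e2, max = 1e4))
  one <- drawParameters(pr, seed = 1)
  expect_equal(unname(one["a"]), 1000)
  expect_equal(unname(one["b"]), 10)

  set.seed(35)
  draws <- vapply(1:50000, function(i) drawParameters(pr)["c"], numeric(1))
  expect_true(median(draws) > 900 && median(draws) < 1100)  # analytic median 1e3
  expect_true(all(draws >= 1e2 & draws <= 1e4))

  expect_error(drawParameters(priorSpec(x = list(dist = "banana"))), "invalid|unknown")
  expect_error(priorSpec(x = list(dist = "loguniform", min = -1, max = 10)),
               "invalid")
})

test_that("replacement events keep local lineages apart until deep time", {
  ## model C: the Mesolithic deme never feeds the post-Neolithic Sicilian
  ## deme; any (Mesolithic, later-Sicilian) pair must coalesce beyond the
  ## deep-ancestry merge at 2000 generations
  fixed <- lapply(c(ne_SIC = 2000, ne_PHO = 1000, ne_GRE = 1000, ne_ISL = 1000,
                    ne_ANC = 5000, ne_LOC = 500),
                  function(v) list(dist = "fixed", value = v))
  tpl <- modelLibrary("C", config = list(priors = fixed))
  tpl@scheme <- scaleScheme(tpl@scheme, 10)
  for (s in 1:5) {
    ds <- simulateDataset(tpl, mutationModel(L = 200), seed = 400 + s,
                          retainGenealogy = TRUE)
    gen <- ds@genealogy
    tr <- gen@tree
    mes <- grep("^MesolithicUzzo", tr$tip.label)
    mod <- grep("^Modern", tr$tip.label)
    anc <- ape::mrca(tr)
    for (i in mes) for (j in mod)
      expect_gte(gen@nodeTimes[anc[i, j]], 2000)
    ## continuity groups coalesce freely: some pair younger than the merge
    neo <- grep("^NeolithicUzzo", tr$tip.label)
    times <- c(outer(neo, mod, function(i, j) gen@nodeTimes[anc[cbind(i, j)]]))
    expect_true(min(times) < 2000)
  }
})

test_that("identical seeds reproduce entire simulated datasets bit for bit", {
  tpl <- modelLibrary("G")
  tpl@scheme <- scaleScheme(tpl@scheme, 20)
  d1 <- simulateDataset(tpl, mutationModel(L = 300), seed = 77)
  d2 <- simulateDataset(tpl, mutationModel(L = 300), seed = 77)
  expect_identical(alignmentMatrix(d1@alignment), alignmentMatrix(d2@alignment))
  expect_identical(d1@params, d2@params)
  expect_identical(d1@metadata, d2@metadata)
})
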