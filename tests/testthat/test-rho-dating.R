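test_that("rho is the mean root-to-tip mutation count", {
  star <- generateToy("star_rho")           # counts 2, 3, 4
  expect_equal(rhoStatistic(star), 3)
  expect_equal(sigmaStatistic(star), 1)     # star: sigma^2 = rho / n

  zero <- mutationTree(ape::read.tree(text = "(a:0,b:0,c:0);"),
                       c(a = 0, b = 0, c = 0))
  expect_equal(rhoStatistic(zero), 0)

  ## caterpillar with known path sums: (((a:1,b:2):3,c:4):5,d:6)
  cat4 <- mutationTree(ape::read.tree(text = "(((a:1,b:2):3,c:4):5,d:6);"),
                       c(a = 0, b = 0, c = 0, d = 0))
  expect_equal(rhoStatistic(cat4), mean(c(1 + 3 + 5, 2 + 3 + 5, 4 + 5, 6)))
})

test_that("rho and sigma equal brute-force path and branch computations", {
  set.seed(51)
  for (i in 1:1000) {
    mt <- randomMutationTree(sample(3:10, 1))
    expect_equal(rhoStatistic(mt), bruteRho(mt@tree), tolerance = 1e-9)
    expect_equal(sigmaStatistic(mt), bruteSigma(mt@tree), tolerance = 1e-9)
  }
})

test_that("single-tip clades give sigma = sqrt(m)", {
  one <- mutationTree(structure(list(edge = matrix(c(2L, 1L), 1),
                                     edge.length = 9,
                                     tip.label = "a", Nnode = 1L),
                                class = "phylo"), c(a = 0))
  expect_equal(rhoStatistic(one), 9)
  expect_equal(sigmaStatistic(one), 3)
})

test_that("recalibration adds expected mutations to ancient terminal branches", {
  clock <- clockModel(1 / 3624)
  tr <- ape::read.tree(text = "(a:2,b:2);")

  ## a is ancient (one clock unit old), b modern: rho goes 2 -> 2.5... two-tip
  ## forced example: ages {7248, 0} add exactly two mutations to a
  mt <- mutationTree(tr, c(a = 7248, b = 0))
  rec <- recalibrateTree(mt, clock)
  expect_equal(rhoStatistic(mt), 2)
  expect_equal(rhoStatistic(rec), 3)

  ## age equal to one clock unit adds exactly one mutation
  mt1 <- mutationTree(ape::read.tree(text = "(a:5,b:1);"), c(a = 3624, b = 0))
  r1 <- recalibrateTree(mt1, clock)
  i <- match(match("a", r1@tree$tip.label), r1@tree$edge[, 2])
  expect_equal(r1@tree$edge.length[i], 6)

  ## all-modern trees are unchanged
  mod <- mutationTree(tr, c(a = 0, b = 0))
  expect_equal(recalibrateTree(mod, clock)@tree$edge.length, tr$edge.length)

  ## missing ages are named in the error
  expect_error(recalibrateTree(mutationTree(tr), clock), "a")

  ## linearity: recalibrating at rate r with ages c*a == rate c*r with ages a
  set.seed(52)
  mt2 <- randomMutationTree(6)
  ages <- setNames(runif(6, 0, 9000), mt2@tree$tip.label)
  mt2@tipAges <- ages[mt2@tree$tip.label]
  r <- 1 / 5000; cc <- 2.5
  scaled <- mt2; scaled@tipAges <- mt2@tipAges * cc
  expect_equal(recalibrateTree(scaled, clockModel(r))@tree$edge.length,
               recalibrateTree(mt2, clockModel(cc * r))@tree$edge.length,
               tolerance = 1e-12)
})

test_that("clock conversion is linear with a floored confidence interval", {
  clock <- clockModel(1 / 3624)
  y <- rhoToYears(1, 0, clock)
  expect_equal(y$age, 3624)
  y0 <- rhoToYears(0, 0.5, clock)
  expect_equal(y0$age, 0)
  expect_equal(y0$ci[1], 0)
  expect_equal(y0$ci[2], 1.959964 * 0.5 * 3624, tolerance = 1e-6)
})

test_that("dating a clade reports classic and recalibrated estimates coherently", {
  clock <- clockModel(1 / 3624)
  tr <- ape::read.tree(text = "(a:2,b:3,c:4);")

  modern <- dateClade(mutationTree(tr, c(a = 0, b = 0, c = 0)), clock)
  expect_equal(modern@rho, modern@rhoRecal)       # identity for modern clades
  expect_equal(modern@age, modern@ageRecal)

  mixed <- dateClade(mutationTree(tr, c(a = 5000, b = 0, c = 0)), clock)
  expect_gt(mixed@rhoRecal, mixed@rho)            # strictly older with an ancient tip
  expect_gt(mixed@ageRecal, mixed@age)
  expect_true(mixed@ageCI[1] <= mixed@age && mixed@age <= mixed@ageCI[2])
})

test_that("star trees built from a root haplotype count differences under the mask", {
  L <- 30
  root <- paste(rep("A", L), collapse = "")
  v <- function(at, to) { s <- rep("A", L); s[at] <- to; paste(s, collapse = "") }
  aln <- MitoAlignment(c(root = root, t1 = v(1:2, "G"), t2 = v(4:6, "C")))
  mt <- mutationTreeFromAlignment(aln, rootId = "root",
                                  tipAges = c(t1 = 0, t2 = 0))
  expect_equal(sort(mt@tree$edge.length), c(2, 3))
  expect_equal(rhoStatistic(mt), 2.5)
})

test_that("recalibrated rho removes the serial-sampling bias of classic rho", {
  ## star clades of age T: tips accumulate Poisson((T - a) * rate) mutations
  ## when sampled a years before present.  Classic rho then estimates T - a;
  ## recalibration restores T.
  rate <- 1 / 3624
  Tt <- 12000; a <- 4000; n <- 12
  reps <- 2000
  set.seed(53)
  est <- matrix(0, reps, 3,
                dimnames = list(NULL, c("modern", "classic", "recal")))
  for (r in seq_len(reps)) {
    mkStar <- function(counts, ages) {
      tr <- structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                           edge.length = as.numeric(counts),
                           tip.label = paste0("t", seq_len(n)), Nnode = 1L),
                      class = "phylo")
      mutationTree(tr, setNames(ages, tr$tip.label))
    }
    modernTree <- mkStar(rpois(n, Tt * rate), rep(0, n))
    ancientTree <- mkStar(rpois(n, (Tt - a) * rate), rep(a, n))
    est[r, "modern"] <- rhoToYears(rhoStatistic(modernTree), 0, clockModel(rate))$age
    d <- dateClade(ancientTree, clockModel(rate))
    est[r, "classic"] <- d@age
    est[r, "recal"] <- d@ageRecal
  }
  se <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, "modern"]) - Tt), 3 * se["modern"])       # unbiased, all modern
  expect_lt(abs(mean(est[, "classic"]) - (Tt - a)), 3 * se["classic"])  # bias ~ -a
  expect_lt(abs(mean(est[, "recal"]) - Tt), 3 * se["recal"])         # bias removed
  ## the recalibrated estimator is closer to the truth than the classic one
  expect_lt(abs(mean(est[, "recal"]) - Tt), abs(mean(est[, "classic"]) - Tt))
})
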