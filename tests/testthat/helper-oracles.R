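## Independent brute-force oracles. These deliberately share no code with the
## package internals: plain double loops and literal formulas.

randomAlignment <- function(n, L, pN = 0, ids = sprintf("s%02d", seq_len(n))) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L,
              dimnames = list(ids, NULL))
  if (pN > 0) m[sample(length(m), rbinom(1, length(m), pN))] <- "N"
  MitoAlignment(m)
}

## pairwise Hamming count, both-non-missing columns only
brutePairDiff <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  nuc <- c("A", "C", "G", "T")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- m[i, ] %in% nuc & m[j, ] %in% nuc
    d[i, j] <- sum(m[i, ok] != m[j, ok])
  }
  d
}

bruteMeanPi <- function(m) {
  d <- brutePairDiff(m)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + d[i, j]
  tot / (n * (n - 1) / 2)
}

bruteSegSites <- function(m) {
  nuc <- c("A", "C", "G", "T")
  s <- 0L
  for (col in seq_len(ncol(m))) {
    x <- m[, col]
    x <- x[x %in% nuc]
    if (length(unique(x)) >= 2L) s <- s + 1L
  }
  s
}

bruteTajimaD <- function(m) {
  n <- nrow(m)
  S <- bruteSegSites(m)
  if (S == 0L) return(NA_real_)
  pi <- bruteMeanPi(m)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

bruteFst <- function(m1, m2) {
  hw <- (bruteMeanPi(m1) + bruteMeanPi(m2)) / 2
  d <- brutePairDiff(rbind(m1, m2))
  hb <- mean(d[seq_len(nrow(m1)), nrow(m1) + seq_len(nrow(m2))])
  1 - hw / hb
}

brutePiBetween <- function(m1, m2) {
  d <- brutePairDiff(rbind(m1, m2))
  mean(d[seq_len(nrow(m1)), nrow(m1) + seq_len(nrow(m2))])
}

## probability two draws without replacement carry different haplotypes
bruteHd <- function(counts) {
  n <- sum(counts)
  same <- sum(counts * (counts - 1))
  1 - same / (n * (n - 1))
}

## rho by explicit parent walks, sigma by explicit descendant counting
bruteRho <- function(tr) {
  n <- length(tr$tip.label)
  edgeTo <- match(seq_len(n + tr$Nnode), tr$edge[, 2])
  depth <- function(node) {
    tot <- 0
    while (!is.na(edgeTo[node])) {
      e <- edgeTo[node]
      tot <- tot + tr$edge.length[e]
      node <- tr$edge[e, 1]
    }
    tot
  }
  mean(vapply(seq_len(n), depth, numeric(1)))
}

bruteSigma <- function(tr) {
  n <- length(tr$tip.label)
  descend <- function(node) {
    if (node <= n) return(1L)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    sum(vapply(kids, descend, integer(1)))
  }
  tot <- 0
  for (e in seq_len(nrow(tr$edge)))
    tot <- tot + (descend(tr$edge[e, 2]) / n)^2 * tr$edge.length[e]
  sqrt(tot)
}

randomMutationTree <- function(n, lambda = 3) {
  tr <- ape::rtree(n)
  tr$edge.length <- as.numeric(rpois(nrow(tr$edge), lambda))
  mutationTree(tr, setNames(rep(0, n), tr$tip.label))
}

## shared small templates for simulation studies
constantSizeTemplate <- function(ne, n = 20, name = "const") {
  customTemplate(name,
    data.frame(group = "pop", deme = "D", n = n, age_mean = 0, age_sd = 0),
    list(ne_D = ne))
}

twoPopTemplate <- function(ne, n1 = 10, n2 = 10, name = "two") {
  customTemplate(name,
    data.frame(group = c("pop1", "pop2"), deme = "D", n = c(n1, n2),
               age_mean = 0, age_sd = 0),
    list(ne_D = ne))
}
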