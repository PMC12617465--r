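#' Construct a concrete DemographicModel
#'
#' @param demes character vector of deme names.
#' @param ne named numeric vector of haploid effective sizes at time 0.
#' @param events data.frame(time, kind, from, to, size); see
#'   \linkS4class{DemographicModel}. Defaults to no events.
#' @param migrations list of epochs \code{list(start, end, M)}.
#' @param generationTime years per generation (default 25).
#' @return a \linkS4class{DemographicModel}
#' @export
demographicModel <- function(demes, ne, events = NULL, migrations = list(),
                             generationTime = 25) {
  if (is.null(events))
    events <- data.frame(time = numeric(0), kind = character(0),
                         from = character(0), to = character(0),
                         size = numeric(0), stringsAsFactors = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  new("DemographicModel", demes = demes, ne = ne, events = events,
      migrations = migrations, generationTime = generationTime)
}

#' Construct a SamplingScheme
#'
#' @param groups data.frame with columns group, deme, n, age_mean, age_sd
#'   (years B.P.; age_sd = 0 means a fixed age).
#' @return a \linkS4class{SamplingScheme}
#' @export
samplingScheme <- function(groups) new("SamplingScheme", groups = groups)

setMethod("show", "SamplingScheme", function(object) {
  g <- object@groups
  cat(sprintf("SamplingScheme: %d groups, %d sequences\n", nrow(g), sum(g$n)))
})

#' Construct a MutationModel
#'
#' @param L number of sites (default 16569, the complete mitogenome).
#' @param mu per-site per-generation mutation rate. The default corresponds to
#'   the whole-molecule clock of one mutation per 3,624 years at a 25-year
#'   generation time spread over 16,569 sites.
#' @param tsTv transition/transversion weight (default 1).
#' @return a \linkS4class{MutationModel}
#' @export
mutationModel <- function(L = 16569L, mu = 25 / (3624 * 16569), tsTv = 1) {
  new("MutationModel", L = as.integer(L), mu = mu, tsTv = tsTv)
}

#' Construct a PriorSpec and draw from it
#'
#' @param ... named prior definitions, each \code{list(dist = "fixed"|
#'   "uniform"|"loguniform"|"normal", ...)}.
#' @return \code{priorSpec}: a \linkS4class{PriorSpec};
#'   \code{drawParameters}: a named numeric vector with one draw per
#'   parameter.
#' @examples
#' pr <- priorSpec(ne = list(dist = "loguniform", min = 1e2, max = 1e5))
#' drawParameters(pr, seed = 1)
#' @export
priorSpec <- function(...) new("PriorSpec", params = list(...))

#' @rdname priorSpec
#' @param priors a \linkS4class{PriorSpec}
#' @param seed optional integer seed.
#' @export
drawParameters <- function(priors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(priors@params, function(d) {
    switch(d$dist,
      fixed = d$value,
      uniform = runif(1, d$min, d$max),
      loguniform = exp(runif(1, log(d$min), log(d$max))),
      normal = rnorm(1, d$mean, d$sd),
      stop("unknown prior distribution: ", d$dist))
  }, numeric(1))
}

## migration matrix in force at backward time t (zero matrix outside epochs)
.migrationAt <- function(model, t) {
  D <- length(model@demes)
  M <- matrix(0, D, D, dimnames = list(model@demes, model@demes))
  for (ep in model@migrations)
    if (t >= ep$start && t < ep$end) { M <- ep$M; dimnames(M) <- dimnames(M); break }
  diag(M) <- 0
  M
}

#' Simulate a serially sampled structured-coalescent genealogy
#'
#' Continuous-time structured coalescent backward in time: within deme i with
#' k lineages and haploid size Ne_i, pairs coalesce at rate k(k-1)/(2 Ne_i);
#' single lineages migrate from deme i to j at rate M[i,j]; "move" events
#' teleport all lineages of a deme at once (backward merges and
#' replacement/discontinuity events); tips enter at their sampling times.
#'
#' @param model a \linkS4class{DemographicModel}
#' @param tips data.frame with columns id, deme, time (generations before
#'   present), one row per sampled sequence; total n >= 2.
#' @param seed optional integer seed.
#' @param maxGen simulation time cap in generations; exceeding it (or running
#'   out of both rates and events with more than one lineage left) raises a
#'   non-coalescence error.
#' @return a \linkS4class{Genealogy}
#' @export
simulateGenealogy <- function(model, tips, seed = NULL, maxGen = 1e8) {
  if (!is.null(seed)) set.seed(seed)
  demes <- model@demes
  D <- length(demes)
  N <- nrow(tips)
  if (N < 2) stop("at least two tips are required")
  tipDeme <- match(tips$deme, demes)
  if (anyNA(tipDeme)) stop("tip sampled in a deme not present in the model")

  ## fixed-time schedule: tip entries, demographic events, migration epoch
  ## boundaries (to refresh the active matrix)
  sched <- rbind(
    data.frame(time = tips$time, type = "tip", idx = seq_len(N)),
    if (nrow(model@events))
      data.frame(time = model@events$time, type = "event", idx = seq_len(nrow(model@events))),
    if (length(model@migrations))
      data.frame(time = unlist(lapply(model@migrations, function(e) c(e$start, e$end))),
                 type = "mig", idx = 0L)
  )
  sched <- sched[is.finite(sched$time), , drop = FALSE]
  sched <- sched[order(sched$time), , drop = FALSE]

  Ne <- model@ne[demes]
  curM <- .migrationAt(model, 0)
  ## after a "move" event empties deme i into j, any lineage that would later
  ## enter i (a tip older than the deme's founding, or a migrant) is placed in
  ## j instead: backward in time the deme no longer exists
  redirect <- seq_len(D)
  follow <- function(d) { while (redirect[d] != d) d <- redirect[d]; d }
  activeNode <- integer(0)     # phylo-temp node id per active lineage
  activeDeme <- integer(0)
  nodeTime <- numeric(2L * N - 1L)
  nodeTime[seq_len(N)] <- tips$time
  merges <- matrix(0L, N - 1L, 3L)  # childA, childB, (temp parent id = row)
  mergeTime <- numeric(N - 1L)
  nMerged <- 0L

  t <- 0
  si <- 1L
  nSched <- nrow(sched)
  entered <- 0L

  repeat {
    k <- tabulate(activeDeme, D)
    coalRate <- k * (k - 1) / (2 * Ne)
    migOut <- rowSums(curM)
    migRate <- k * migOut
    R <- sum(coalRate) + sum(migRate)
    tNext <- if (si <= nSched) sched$time[si] else Inf

    if (length(activeNode) == 1L && entered == N) break

    if (R <= 0 && is.infinite(tNext))
      stop("non-coalescence: lineages cannot coalesce under this model (disconnected demes?)")

    dt <- if (R > 0) rexp(1, R) else Inf
    if (t + dt >= tNext) {
      ## jump to the fixed event(s)
      t <- tNext
      if (t > maxGen) stop("simulation time cap exceeded before coalescence")
      while (si <= nSched && sched$time[si] <= t) {
        row <- sched[si, ]
        if (row$type == "tip") {
          activeNode <- c(activeNode, row$idx)
          activeDeme <- c(activeDeme, follow(tipDeme[row$idx]))
          entered <- entered + 1L
        } else if (row$type == "event") {
          ev <- model@events[row$idx, ]
          if (ev$kind == "move") {
            from <- follow(match(ev$from, demes))
            to <- follow(match(ev$to, demes))
            if (from != to) {
              activeDeme[activeDeme == from] <- to
              redirect[from] <- to
            }
          } else {
            Ne[match(ev$from, demes)] <- ev$size
          }
        }
        si <- si + 1L
      }
      curM <- .migrationAt(model, t)
      next
    }

    t <- t + dt
    if (t > maxGen) stop("simulation time cap exceeded before coalescence")

    u <- runif(1) * R
    cum <- 0
    picked <- FALSE
    for (d in seq_len(D)) {
      cum <- cum + coalRate[d]
      if (u < cum) {
        ## coalescence in deme d
        cand <- which(activeDeme == d)
        pair <- cand[sample.int(length(cand), 2L)]
        nMerged <- nMerged + 1L
        parentTemp <- N + nMerged
        merges[nMerged, ] <- c(activeNode[pair[1]], activeNode[pair[2]], parentTemp)
        mergeTime[nMerged] <- t
        nodeTime[parentTemp] <- t
        activeNode <- c(activeNode[-pair], parentTemp)
        activeDeme <- c(activeDeme[-pair], d)
        picked <- TRUE
        break
      }
    }
    if (!picked) {
      for (d in seq_len(D)) {
        cum <- cum + migRate[d]
        if (u < cum) {
          cand <- which(activeDeme == d)
          lin <- cand[sample.int(length(cand), 1L)]
          dest <- sample.int(D, 1L, prob = curM[d, ])
          activeDeme[lin] <- follow(dest)
          break
        }
      }
    }
  }

  if (nMerged != N - 1L) stop("internal error: genealogy incomplete")

  ## renumber internal nodes so the root is N + 1 (ape convention)
  tempIds <- N + seq_len(N - 1L)
  finalIds <- setNames(N + (N - 1L):1L, tempIds)  # last merge (root) -> N + 1
  edge <- matrix(0L, 2L * (N - 1L), 2L)
  elen <- numeric(2L * (N - 1L))
  for (i in seq_len(N - 1L)) {
    p <- finalIds[[as.character(N + i)]]
    for (j in 1:2) {
      ch <- merges[i, j]
      chF <- if (ch <= N) ch else finalIds[[as.character(ch)]]
      r <- 2L * (i - 1L) + j
      edge[r, ] <- c(p, chF)
      elen[r] <- mergeTime[i] - nodeTime[ch]
    }
  }
  nodeTimeFinal <- numeric(2L * N - 1L)
  nodeTimeFinal[seq_len(N)] <- nodeTime[seq_len(N)]
  nodeTimeFinal[finalIds] <- nodeTime[as.integer(names(finalIds))]

  labels <- as.character(tips$id)
  tr <- structure(list(edge = edge, edge.length = elen, tip.label = labels,
                       Nnode = N - 1L), class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  new("Genealogy", tree = tr,
      tipTimes = setNames(tips$time, labels),
      nodeTimes = nodeTimeFinal,
      tipDemes = setNames(as.character(tips$deme), labels))
}

setMethod("show", "Genealogy", function(object) {
  cat(sprintf("Genealogy: %d tips, TMRCA %.1f generations\n",
              length(object@tipTimes), max(object@nodeTimes)))
})

#' Time to the most recent common ancestor of a genealogy
#'
#' @param gen a \linkS4class{Genealogy}
#' @return TMRCA in generations before present.
#' @export
tmrca <- function(gen) max(gen@nodeTimes)

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Overlay finite-sites mutations on a genealogy
#'
#' Mutations are Poisson(branch length x mu x L) per branch, placed uniformly
#' over sites (repeat hits allowed). The replacement base is drawn among the
#' three alternatives with the transition weighted by \code{tsTv}. The root
#' sequence is uniform random unless supplied.
#'
#' @param gen a \linkS4class{Genealogy}
#' @param mut a \linkS4class{MutationModel}
#' @param seed optional integer seed.
#' @param rootSeq optional character vector of length L over A,C,G,T.
#' @return a \linkS4class{MitoAlignment} with L columns.
#' @export
mutateGenealogy <- function(gen, mut, seed = NULL, rootSeq = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- gen@tree
  L <- mut@L
  bases <- c("A", "C", "G", "T")
  if (is.null(rootSeq)) rootSeq <- sample(bases, L, replace = TRUE)
  N <- length(tr$tip.label)
  nEdge <- nrow(tr$edge)
  nMut <- rpois(nEdge, tr$edge.length * mut@mu * L)
  m <- matrix(rootSeq, nrow = N, ncol = L, byrow = TRUE,
              dimnames = list(tr$tip.label, NULL))
  total <- sum(nMut)
  if (total > 0L) {
    sites <- sample.int(L, total, replace = TRUE)
    su <- sort(unique(sites))
    siteIdx <- match(sites, su)
    ## per-node genotypes at mutated sites only; cladewise order guarantees
    ## parents are resolved before children
    G <- matrix(NA_integer_, N + tr$Nnode, length(su))
    root <- N + 1L
    G[root, ] <- match(rootSeq[su], bases)
    wts <- c(1, 1, 1)
    mutPtr <- c(0L, cumsum(nMut))
    for (e in seq_len(nEdge)) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      g <- G[parent, ]
      if (nMut[e] > 0L) {
        for (j in (mutPtr[e] + 1L):mutPtr[e + 1L]) {
          s <- siteIdx[j]
          cur <- bases[g[s]]
          alt <- setdiff(bases, cur)
          w <- ifelse(alt == .TRANSITION[[cur]], mut@tsTv, 1)
          g[s] <- match(sample(alt, 1L, prob = w), bases)
        }
      }
      G[child, ] <- g
    }
    m[, su] <- matrix(bases[t(G[seq_len(N), , drop = FALSE])],
                      nrow = N, byrow = TRUE)
  }
  MitoAlignment(m)
}
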