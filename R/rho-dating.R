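#' Construct a MutationTree
#'
#' @param tree an \pkg{ape} \code{phylo} whose branch lengths are mutation
#'   counts.
#' @param tipAges numeric vector of tip ages in years B.P., named by tip
#'   label (or in tip order); NA allowed until recalibration is requested.
#' @return a \linkS4class{MutationTree}
#' @export
mutationTree <- function(tree, tipAges = NULL) {
  n <- length(tree$tip.label)
  if (is.null(tipAges)) tipAges <- setNames(rep(NA_real_, n), tree$tip.label)
  if (is.null(names(tipAges))) names(tipAges) <- tree$tip.label
  new("MutationTree", tree = tree, tipAges = tipAges[tree$tip.label])
}

#' Read a mutation-annotated tree from newick
#'
#' Branch lengths in the newick string are interpreted as mutation counts.
#'
#' @param text newick string, or \code{file} a path.
#' @param tipAges as in \code{\link{mutationTree}}.
#' @param file optional path instead of \code{text}.
#' @return a \linkS4class{MutationTree}
#' @export
readMutationTree <- function(text = NULL, tipAges = NULL, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  mutationTree(tr, tipAges)
}

#' Build a star MutationTree from a root haplotype and tip sequences
#'
#' Each tip's mutation count is its Hamming distance to the root haplotype on
#' the unmasked, pairwise-complete columns. Used when no resolved tree is
#' available (the classic rho setting).
#'
#' @param aln a \linkS4class{MitoAlignment} containing the tips (and the root
#'   if \code{rootId} is used).
#' @param rootId sample id of the root haplotype within \code{aln}, or
#'   \code{rootSeq} a character vector/string of the root haplotype.
#' @param policy optional \linkS4class{MaskPolicy} applied first.
#' @param tipAges named ages in years B.P.
#' @param rootSeq optional explicit root sequence.
#' @return a \linkS4class{MutationTree} (star topology).
#' @export
mutationTreeFromAlignment <- function(aln, rootId = NULL, policy = NULL,
                                      tipAges = NULL, rootSeq = NULL) {
  if (!is.null(policy)) aln <- applyMask(aln, policy)
  m <- aln@seqs
  if (!is.null(rootId)) {
    if (!rootId %in% rownames(m)) stop("rootId not found in alignment")
    root <- m[rootId, ]
    m <- m[setdiff(rownames(m), rootId), , drop = FALSE]
  } else {
    if (is.null(rootSeq)) stop("either rootId or rootSeq is required")
    if (length(rootSeq) == 1L) rootSeq <- strsplit(toupper(rootSeq), "")[[1]]
    if (length(rootSeq) != ncol(m)) stop("root sequence length mismatch")
    root <- rootSeq
  }
  counts <- apply(m, 1L, function(x) {
    ok <- x %in% c("A", "C", "G", "T") & root %in% c("A", "C", "G", "T")
    sum(x[ok] != root[ok])
  })
  n <- nrow(m)
  tr <- structure(list(
    edge = cbind(rep(n + 1L, n), seq_len(n)),
    edge.length = as.numeric(counts),
    tip.label = rownames(m), Nnode = 1L), class = "phylo")
  mutationTree(tr, tipAges)
}

## per-tip root-to-tip mutation-count sums
.tipPathSums <- function(tr) {
  depths <- ape::node.depth.edgelength(tr)
  setNames(depths[seq_along(tr$tip.label)], tr$tip.label)
}

## number of descendant tips under each edge (indexed by edge row)
.edgeDescendants <- function(tr) {
  N <- length(tr$tip.label)
  cnt <- numeric(N + tr$Nnode)
  cnt[seq_len(N)] <- 1
  tr <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(tr$edge)))
    cnt[tr$edge[e, 1]] <- cnt[tr$edge[e, 1]] + cnt[tr$edge[e, 2]]
  list(tree = tr, nb = cnt[tr$edge[, 2]])
}

#' The rho statistic
#'
#' Mean over tips of the summed mutation counts on the root-to-tip path: the
#' average molecular divergence of the clade from its root haplotype.
#'
#' @param x a \linkS4class{MutationTree}
#' @return rho >= 0.
#' @export
rhoStatistic <- function(x) {
  mean(.tipPathSums(x@tree))
}

#' The genealogy-based standard error of rho
#'
#' Saillard-type estimator: sigma^2 = sum over branches of (n_b / n)^2 l_b,
#' with n_b the number of tips descending from the branch and l_b its
#' mutation count. Reduces to sqrt(rho / n) on star trees.
#'
#' @param x a \linkS4class{MutationTree}
#' @return sigma >= 0.
#' @export
sigmaStatistic <- function(x) {
  n <- length(x@tree$tip.label)
  ed <- .edgeDescendants(x@tree)
  sqrt(sum((ed$nb / n)^2 * ed$tree$edge.length))
}

#' Construct a ClockModel
#'
#' @param rate mutations per year on the counted sequence. The default,
#'   1/3624, is the whole-mitogenome substitution clock (one mutation per
#'   3,624 years).
#' @return a \linkS4class{ClockModel}
#' @export
clockModel <- function(rate = 1 / 3624) new("ClockModel", rate = rate)

#' Recalibrate a mutation tree for ancient tips
#'
#' Adds to each tip's terminal branch the mutations the sample would have
#' accumulated between its age and the present: age_bp x clock rate (a
#' real-valued expected count by default; \code{stochastic = TRUE} draws a
#' Poisson count instead, used in recovery experiments). Modern tips
#' (age 0) are unchanged. Rho and sigma computed on the recalibrated tree are
#' directly comparable with those of all-modern clades.
#'
#' @param x a \linkS4class{MutationTree} with all tip ages present.
#' @param clock a \linkS4class{ClockModel}.
#' @param stochastic draw Poisson counts instead of expected values?
#' @return a recalibrated \linkS4class{MutationTree}
#' @export
recalibrateTree <- function(x, clock = clockModel(), stochastic = FALSE) {
  ages <- x@tipAges
  if (anyNA(ages))
    stop("missing tip age for: ",
         paste(head(names(ages)[is.na(ages)], 5), collapse = ", "))
  tr <- x@tree
  extra <- ages * clock@rate
  if (stochastic) extra <- rpois(length(extra), extra)
  tipEdge <- match(seq_along(tr$tip.label), tr$edge[, 2])
  tr$edge.length[tipEdge] <- tr$edge.length[tipEdge] + extra[tr$tip.label]
  mutationTree(tr, ages)
}

#' Convert rho and sigma into an age in years
#'
#' Linear clock conversion: age = rho / rate, with 95\% CI
#' (rho +- 1.96 sigma) / rate floored at 0.
#'
#' @param rho,sigma the rho statistic and its standard error.
#' @param clock a \linkS4class{ClockModel}.
#' @return list(age, ci) in years.
#' @export
rhoToYears <- function(rho, sigma, clock = clockModel()) {
  age <- rho / clock@rate
  ci <- pmax(0, (rho + c(-1, 1) * 1.959964 * sigma) / clock@rate)
  list(age = age, ci = ci)
}

#' Date a clade with classic and recalibrated rho
#'
#' Computes rho and sigma on the tree as given (classic) and on the
#' recalibrated tree in which ancient tips receive the mutations they never
#' had time to accumulate. The recalibrated age is never younger than the
#' classic one, strictly older whenever any tip is ancient.
#'
#' @param x a \linkS4class{MutationTree}.
#' @param clock a \linkS4class{ClockModel}.
#' @return a \linkS4class{RhoEstimate}
#' @export
dateClade <- function(x, clock = clockModel()) {
  r <- rhoStatistic(x); s <- sigmaStatistic(x)
  cls <- rhoToYears(r, s, clock)
  xr <- recalibrateTree(x, clock)
  rr <- rhoStatistic(xr); sr <- sigmaStatistic(xr)
  rec <- rhoToYears(rr, sr, clock)
  new("RhoEstimate", rho = r, sigma = s, rhoRecal = rr, sigmaRecal = sr,
      age = cls$age, ageCI = cls$ci, ageRecal = rec$age, ageCIRecal = rec$ci,
      nTips = length(x@tree$tip.label), clockRate = clock@rate)
}

setMethod("show", "RhoEstimate", function(object) {
  cat(sprintf(paste0(
    "RhoEstimate (n = %d tips, clock %.3g mut/yr)\n",
    "  classic:      rho = %.3f, sigma = %.3f, age = %.0f yr [%.0f, %.0f]\n",
    "  recalibrated: rho = %.3f, sigma = %.3f, age = %.0f yr [%.0f, %.0f]\n"),
    object@nTips, object@clockRate,
    object@rho, object@sigma, object@age, object@ageCI[1], object@ageCI[2],
    object@rhoRecal, object@sigmaRecal, object@ageRecal,
    object@ageCIRecal[1], object@ageCIRecal[2]))
})

setMethod("show", "MutationTree", function(object) {
  cat(sprintf("MutationTree: %d tips, %d ancient (age > 0)\n",
              length(object@tree$tip.label),
              sum(object@tipAges > 0, na.rm = TRUE)))
})
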