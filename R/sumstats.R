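## ---- shared internals -------------------------------------------------
## All distance-type statistics run through .pairDiff so that observed and
## simulated data take exactly the same code path.

## n x n matrix of pairwise Hamming counts on pairwise-complete columns
## (N and '-' treated as missing; masked columns are assumed already dropped).
## Restricting to columns showing any mismatch against row 1 is exact:
## fully constant columns contribute zero differences.
.pairDiff <- function(m) {
  n <- nrow(m)
  ref <- m[rep(1L, n), , drop = FALSE]
  varCol <- colSums(m != ref) > 0L
  m <- m[, varCol, drop = FALSE]
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (ncol(m) == 0L) return(d)
  valid <- matrix(as.numeric(m %in% c("A", "C", "G", "T")), n, ncol(m))
  comparable <- tcrossprod(valid)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    X <- matrix(as.numeric(m == b), n, ncol(m))
    matches <- matches + tcrossprod(X)
  }
  d[] <- comparable - matches
  diag(d) <- 0
  d
}

.meanOffDiag <- function(d) {
  n <- nrow(d)
  if (n < 2) return(NA_real_)
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
}

#' Number of segregating sites
#'
#' Counts alignment columns carrying at least two distinct non-missing
#' residues (gaps and N are ignored; run \code{\link{applyMask}} first to
#' apply a masking policy).
#'
#' @param aln a \linkS4class{MitoAlignment}
#' @return integer count.
#' @export
segregatingSites <- function(aln) {
  m <- aln@seqs
  ref <- m[rep(1L, nrow(m)), , drop = FALSE]
  candidates <- which(colSums(m != ref) > 0L)
  if (!length(candidates)) return(0L)
  seg <- vapply(candidates, function(j) {
    x <- m[, j]
    x <- x[x %in% c("A", "C", "G", "T")]
    length(unique(x)) >= 2L
  }, logical(1))
  sum(seg)
}

#' Haplotype-level gene diversity of an alignment
#'
#' Collapses the alignment into haplotypes and returns the unbiased gene
#' diversity Hd (see \code{\link{haplotypeDiversity}}). This is the "H"
#' statistic of the haploid summary-statistic vector.
#'
#' @param aln a \linkS4class{MitoAlignment}
#' @return a number in [0, 1].
#' @export
geneDiversity <- function(aln) {
  haplotypeDiversity(collapseHaplotypes(aln))
}

#' Mean within-sample pairwise differences (nucleotide diversity, absolute)
#'
#' @param aln a \linkS4class{MitoAlignment}
#' @return mean Hamming count over all sequence pairs.
#' @export
meanPairwiseDifferences <- function(aln) {
  .meanOffDiag(.pairDiff(aln@seqs))
}

.tajimaConstants <- function(n) {
  n <- unname(n)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' The standard normalised difference between the pairwise-diversity and
#' segregating-sites estimators of theta. Undefined when S = 0 (returned as
#' NA; the reference-table builder imputes 0 with an indicator column).
#'
#' @param aln a \linkS4class{MitoAlignment} with n >= 4 sequences.
#' @return Tajima's D, or NA when there are no segregating sites.
#' @export
tajimasD <- function(aln) {
  n <- nrow(aln@seqs)
  if (n < 4) stop("Tajima's D requires n >= 4 sequences")
  S <- segregatingSites(aln)
  if (S == 0L) return(NA_real_)
  pi <- meanPairwiseDifferences(aln)
  k <- .tajimaConstants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Pairwise FST between two populations of sequences
#'
#' Hudson-type sequence FST: 1 - Hw/Hb, with Hw the average of the two
#' within-population mean pairwise differences and Hb the mean
#' between-population pairwise difference. Negative estimates are reported as
#' computed unless \code{floorZero} is set.
#'
#' @param aln1,aln2 \linkS4class{MitoAlignment}s over the same columns
#'   (same reference positions), each with n >= 2 sequences.
#' @param floorZero floor negative estimates at 0?
#' @return FST in (-Inf, 1]; NA when both populations are monomorphic and
#'   identical (0/0).
#' @export
pairwiseFst <- function(aln1, aln2, floorZero = FALSE) {
  if (nrow(aln1@seqs) < 2 || nrow(aln2@seqs) < 2)
    stop("FST requires n >= 2 in both populations")
  if (!identical(aln1@positions, aln2@positions))
    stop("populations must be aligned over the same columns")
  comp <- .fstComponents(aln1@seqs, aln2@seqs)
  fst <- if (comp$hb == 0) { if (comp$hw == 0) 0 else NA_real_ } else 1 - comp$hw / comp$hb
  if (floorZero && !is.na(fst)) fst <- max(fst, 0)
  fst
}

.fstComponents <- function(m1, m2) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  d <- .pairDiff(rbind(m1, m2))
  w1 <- .meanOffDiag(d[seq_len(n1), seq_len(n1), drop = FALSE])
  w2 <- .meanOffDiag(d[n1 + seq_len(n2), n1 + seq_len(n2), drop = FALSE])
  cross <- d[seq_len(n1), n1 + seq_len(n2), drop = FALSE]
  ## comparing a population with itself: drop same-sample pairs so that
  ## FST(a, a) is exactly 0
  self <- outer(rownames(m1), rownames(m2), "==")
  hb <- if (any(self)) mean(cross[!self]) else mean(cross)
  list(hw = (w1 + w2) / 2, hb = hb)
}

#' Mean between-population pairwise differences
#'
#' @inheritParams pairwiseFst
#' @return mean Hamming count over all cross-population pairs.
#' @export
piBetween <- function(aln1, aln2) {
  if (!identical(aln1@positions, aln2@positions))
    stop("populations must be aligned over the same columns")
  .fstComponents(aln1@seqs, aln2@seqs)$hb
}

#' Fixed-order summary-statistic vector
#'
#' Computes, for each population, the haplotype count K, gene diversity H,
#' segregating sites S and Tajima's D, and for each population pair the
#' Hudson FST and the mean between-population pairwise differences Pi.
#' The ordering is fixed by the order of \code{populations}: all per-population
#' blocks first, then all pairs (i < j). The same function is applied to
#' observed and simulated alignments.
#'
#' @param aln a \linkS4class{MitoAlignment}
#' @param populations named list of sample-id vectors, one per population,
#'   each of size >= 2; at least two populations.
#' @return named numeric vector of length 4 P + 2 P(P-1)/2. Tajima's D is NA
#'   where undefined (S = 0).
#' @export
summaryStatistics <- function(aln, populations) {
  if (length(populations) < 2L) stop("at least two populations are required")
  if (is.null(names(populations))) stop("populations must be named")
  idx <- lapply(populations, function(ids) {
    j <- match(ids, rownames(aln@seqs))
    if (anyNA(j)) stop("population contains unknown sample ids")
    j
  })
  sizes <- unname(lengths(idx))
  if (any(sizes < 2L)) stop("every population needs n >= 2")
  m <- aln@seqs
  d <- .pairDiff(m)
  P <- length(idx)
  pnames <- names(populations)
  per <- lapply(seq_len(P), function(p) {
    rows <- idx[[p]]
    sub <- MitoAlignment(m[rows, , drop = FALSE], positions = aln@positions)
    K <- length(collapseHaplotypes(sub)@counts)
    H <- haplotypeDiversity(collapseHaplotypes(sub))
    S <- segregatingSites(sub)
    D <- if (sizes[p] >= 4L && S > 0L) {
      pi <- .meanOffDiag(d[rows, rows, drop = FALSE])
      k <- .tajimaConstants(sizes[p])
      (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    } else NA_real_
    c(K = K, H = H, S = S, TAJIMAD = D)
  })
  out <- numeric(0)
  for (p in seq_len(P)) {
    v <- per[[p]]
    names(v) <- paste0(names(v), "_", pnames[p])
    out <- c(out, v)
  }
  for (p in seq_len(P - 1)) for (q in seq.int(p + 1L, P)) {
    rp <- idx[[p]]; rq <- idx[[q]]
    wp <- .meanOffDiag(d[rp, rp, drop = FALSE])
    wq <- .meanOffDiag(d[rq, rq, drop = FALSE])
    hb <- mean(d[rp, rq])
    fst <- if (hb == 0) { if ((wp + wq) / 2 == 0) 0 else NA_real_ } else 1 - (wp + wq) / 2 / hb
    v <- c(fst, hb)
    names(v) <- paste0(c("FST_", "PI_"), pnames[p], "_", pnames[q])
    out <- c(out, v)
  }
  out
}

#' Impute missing summary statistics for ABC
#'
#' Tajima's D is undefined on monomorphic samples; to keep the
#' reference-table geometry fixed, undefined statistics are imputed with 0 and
#' one 0/1 indicator column per TAJIMAD statistic is appended recording
#' whether the statistic was defined. Any other (rare) undefined entry is
#' imputed with 0 without an indicator.
#'
#' @param stats a summary vector or a matrix of summary vectors (rows =
#'   simulations).
#' @return imputed vector/matrix with indicator columns appended.
#' @export
imputeSummaries <- function(stats) {
  vec <- is.null(dim(stats))
  m <- if (vec) matrix(stats, 1, dimnames = list(NULL, names(stats))) else stats
  dcols <- grep("^TAJIMAD_", colnames(m))
  ind <- 1 - is.na(m[, dcols, drop = FALSE])
  colnames(ind) <- sub("^TAJIMAD_", "TAJIMAD_OK_", colnames(m)[dcols])
  m[is.na(m)] <- 0
  out <- cbind(m, ind)
  if (vec) out[1, ] else out
}
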