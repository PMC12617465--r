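#' Pairwise FST matrix over groups
#'
#' Computes Hudson-type sequence FST (see \code{\link{pairwiseFst}}) between
#' every pair of groups. Groups smaller than \code{minN} are excluded with a
#' warning (the usual at-least-three-individuals grouping rule; the hard
#' floor is 2, below which FST is undefined). For use as a distance matrix,
#' negative estimates can be floored at 0 via \code{floorZero}; raw values
#' are what the heatmap-style output preserves.
#'
#' @param alignments named list of \linkS4class{MitoAlignment}s, one per
#'   group, all over the same columns.
#' @param minN minimum group size (default 3).
#' @param floorZero floor negative FST at 0?
#' @return symmetric numeric matrix with zero diagonal.
#' @export
fstMatrix <- function(alignments, minN = 3L, floorZero = FALSE) {
  sizes <- vapply(alignments, nSamples, numeric(1))
  small <- sizes < max(2L, minN)
  if (any(small)) {
    warning("excluding groups below the size threshold: ",
            paste(names(alignments)[small], collapse = ", "))
    alignments <- alignments[!small]
  }
  G <- length(alignments)
  if (G < 2L) stop("need at least two groups of sufficient size")
  out <- matrix(0, G, G, dimnames = list(names(alignments), names(alignments)))
  for (i in seq_len(G - 1)) for (j in seq.int(i + 1L, G)) {
    f <- pairwiseFst(alignments[[i]], alignments[[j]], floorZero = floorZero)
    out[i, j] <- out[j, i] <- f
  }
  out
}

#' Classical (metric) multidimensional scaling of a distance matrix
#'
#' Torgerson scaling: double-centering of the squared distances followed by
#' an eigendecomposition, as provided by \code{stats::cmdscale}. When the
#' distances are Euclidean-embeddable in k dimensions the configuration
#' reproduces them exactly; negative eigenvalues are reported otherwise.
#'
#' @param D symmetric distance matrix with zero diagonal (e.g. a floored FST
#'   matrix).
#' @param k number of dimensions (k < nrow(D)).
#' @return list(points, eig): coordinates (n x k) and all eigenvalues.
#' @export
classicalMds <- function(D, k = 2) {
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of groups")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  ## cmdscale warns when fewer than k eigenvalues are positive (e.g. the
  ## all-zero matrix); the padded configuration below is the defined answer
  fit <- suppressWarnings(cmdscale(as.dist(D), k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k)  # degenerate (e.g. all-zero) matrices: pad with zeros
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  rownames(pts) <- rownames(D)
  list(points = pts, eig = fit$eig)
}

#' Correspondence analysis of a contingency table
#'
#' Standard CA: singular value decomposition of the standardised residuals
#' (P - r c^T) / sqrt(r c^T) of the correspondence matrix P = X / n. Row and
#' column coordinates are returned in row-principal normalisation (rows in
#' principal coordinates, columns in standard coordinates); axes are ordered
#' by decreasing inertia and the total inertia equals chi-square / n.
#'
#' @param table nonnegative counts matrix with no all-zero row or column.
#' @return list(rowCoords, colCoords, inertia, totalInertia).
#' @export
correspondenceAnalysis <- function(table) {
  X <- as.matrix(table)
  if (any(X < 0)) stop("counts must be nonnegative")
  rz <- rowSums(X) == 0; cz <- colSums(X) == 0
  if (any(rz)) stop("all-zero row(s): ", paste(rownames(X)[rz], collapse = ", "))
  if (any(cz)) stop("all-zero column(s): ", paste(colnames(X)[cz], collapse = ", "))
  n <- sum(X)
  P <- X / n
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  k <- min(nrow(X), ncol(X)) - 1L
  if (k < 1L) stop("table must have at least two rows and two columns")
  d <- sv$d[seq_len(k)]
  rowCoords <- sweep(sv$u[, seq_len(k), drop = FALSE], 1, sqrt(r), "/") %*% diag(d, k)
  colCoords <- sweep(sv$v[, seq_len(k), drop = FALSE], 1, sqrt(cc), "/")
  dimnames(rowCoords) <- list(rownames(X), paste0("Dim", seq_len(k)))
  dimnames(colCoords) <- list(colnames(X), paste0("Dim", seq_len(k)))
  list(rowCoords = rowCoords, colCoords = colCoords, inertia = d^2,
       totalInertia = sum(d^2))
}

#' Chi-square test of independence on a contingency table
#'
#' Pearson chi-square with (r-1)(c-1) degrees of freedom, either asymptotic
#' or with a Monte-Carlo p-value (margins fixed,
#' p = (1 + #permutations >= observed) / (B + 1)), the recommended choice for
#' the sparse haplogroup tables this package produces.
#'
#' @param table nonnegative counts matrix.
#' @param mode "asymptotic" or "monte_carlo".
#' @param B number of Monte-Carlo replicates (default 9999).
#' @param seed seed for the Monte-Carlo draw.
#' @return list(statistic, df, p.value, mode).
#' @export
chiSquareIndependence <- function(table, mode = c("asymptotic", "monte_carlo"),
                                  B = 9999, seed = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(table)
  if (mode == "monte_carlo") {
    if (!is.null(seed)) set.seed(seed)
    ht <- suppressWarnings(chisq.test(X, simulate.p.value = TRUE, B = B))
    df <- (nrow(X) - 1L) * (ncol(X) - 1L)
  } else {
    ht <- suppressWarnings(chisq.test(X, correct = FALSE))
    df <- unname(ht$parameter)
  }
  list(statistic = unname(ht$statistic), df = df,
       p.value = unname(ht$p.value), mode = mode)
}
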