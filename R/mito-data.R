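#' Construct a MitoAlignment
#'
#' @param seqs character matrix of symbols over \code{A,C,G,T,-,N} with sample
#'   ids as rownames, or a named character vector of equal-length sequence
#'   strings.
#' @param positions optional integer vector of reference coordinates, one per
#'   column; defaults to \code{1:L}.
#' @return a \linkS4class{MitoAlignment}.
#' @examples
#' aln <- MitoAlignment(c(s1 = "ACGT", s2 = "ACGA"))
#' nSamples(aln)
#' @export
MitoAlignment <- function(seqs, positions = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequence vector must be named by sample id")
    w <- unique(nchar(seqs))
    if (length(w) != 1L) stop("aligned sequences must all have the same length")
    m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(names(seqs), NULL))
  } else {
    m <- seqs
  }
  if (is.null(positions)) positions <- seq_len(ncol(m))
  new("MitoAlignment", seqs = m, positions = as.integer(positions))
}

#' @rdname MitoAlignment
#' @param object,x a MitoAlignment
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname MitoAlignment
#' @export
setMethod("nSamples", "MitoAlignment", function(x) nrow(x@seqs))

#' @rdname MitoAlignment
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname MitoAlignment
#' @export
setMethod("nSites", "MitoAlignment", function(x) ncol(x@seqs))

#' @rdname MitoAlignment
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname MitoAlignment
#' @export
setMethod("sampleIds", "MitoAlignment", function(x) rownames(x@seqs))

#' @rdname MitoAlignment
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))
#' @rdname MitoAlignment
#' @export
setMethod("sitePositions", "MitoAlignment", function(x) x@positions)

#' @rdname MitoAlignment
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))
#' @rdname MitoAlignment
#' @export
setMethod("alignmentMatrix", "MitoAlignment", function(x) x@seqs)

setMethod("show", "MitoAlignment", function(object) {
  cat(sprintf("MitoAlignment: %d sequences x %d columns (coords %d..%d)\n",
              nrow(object@seqs), ncol(object@seqs),
              min(object@positions), max(object@positions)))
})

#' Subset a MitoAlignment by sample ids
#'
#' @param x a \linkS4class{MitoAlignment}
#' @param ids character vector of sample ids to keep
#' @return a \linkS4class{MitoAlignment} with the selected rows.
#' @export
subsetSamples <- function(x, ids) {
  miss <- setdiff(ids, rownames(x@seqs))
  if (length(miss)) stop("unknown sample ids: ", paste(head(miss, 5), collapse = ", "))
  new("MitoAlignment", seqs = x@seqs[ids, , drop = FALSE], positions = x@positions)
}

#' Read an aligned FASTA file of mitogenomes
#'
#' Records must be pre-aligned (equal lengths). Symbols are uppercased;
#' anything outside \code{A,C,G,T,-,N} (including IUPAC ambiguity codes) is
#' mapped to \code{N} with a warning.
#'
#' @param path path to a FASTA file.
#' @return a \linkS4class{MitoAlignment}.
#' @export
readMitoFasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  w <- unique(Biostrings::width(ss))
  if (length(w) != 1L)
    stop("records are not aligned: lengths ", paste(sort(w), collapse = ", "))
  ids <- sub("\\s.*$", "", names(ss))
  chr <- toupper(as.character(ss))
  m <- matrix(unlist(strsplit(chr, "", fixed = TRUE), use.names = FALSE),
              nrow = length(ss), byrow = TRUE, dimnames = list(ids, NULL))
  bad <- !(m %in% .MITO_ALPHABET)
  if (any(bad)) {
    warning(sprintf("%d symbols outside {A,C,G,T,-,N} mapped to N (e.g. %s)",
                    sum(bad), paste(unique(m[bad])[seq_len(min(3, length(unique(m[bad]))))],
                                    collapse = ", ")))
    m[bad] <- "N"
  }
  MitoAlignment(m)
}

#' Write a MitoAlignment to FASTA
#'
#' @param x a \linkS4class{MitoAlignment}
#' @param path output path
#' @return invisibly, the path.
#' @export
writeMitoFasta <- function(x, path) {
  seqs <- apply(x@seqs, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(x@seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a MaskPolicy
#'
#' @param excludedPositions integer vector of 1-based reference positions.
#' @param excludeIndels drop any column containing a gap?
#' @return a \linkS4class{MaskPolicy}
#' @export
maskPolicy <- function(excludedPositions = integer(0), excludeIndels = TRUE) {
  new("MaskPolicy", excludedPositions = as.integer(sort(unique(excludedPositions))),
      excludeIndels = excludeIndels)
}

#' The standard mitogenome hotspot mask
#'
#' Excludes the np16519 hotspot transition and the poly-C stretches around
#' np309 (np303--np315) and np16189 (np16182--np16194), and drops indel
#' columns: the standard filtering applied before haplotype comparison and
#' rho dating of complete mitogenomes in rCRS coordinates.
#'
#' @return a \linkS4class{MaskPolicy}
#' @examples
#' 16519 %in% excludedPositions(defaultMask())
#' @export
defaultMask <- function() {
  maskPolicy(c(16519L, 303:315, 16182:16194), excludeIndels = TRUE)
}

#' @rdname maskPolicy
#' @param x a MaskPolicy
#' @export
setGeneric("excludedPositions", function(x) standardGeneric("excludedPositions"))
#' @rdname maskPolicy
#' @export
setMethod("excludedPositions", "MaskPolicy", function(x) x@excludedPositions)

setMethod("show", "MaskPolicy", function(object) {
  cat(sprintf("MaskPolicy: %d excluded positions; excludeIndels = %s\n",
              length(object@excludedPositions), object@excludeIndels))
})

#' Apply a mask policy to an alignment
#'
#' Masked columns are dropped. If \code{excludeIndels} is set, any column
#' containing a gap in any sequence is dropped too. The returned alignment
#' keeps the original reference coordinates of the surviving columns.
#'
#' @param aln a \linkS4class{MitoAlignment}
#' @param policy a \linkS4class{MaskPolicy}
#' @return a masked \linkS4class{MitoAlignment}
#' @export
applyMask <- function(aln, policy) {
  pos <- policy@excludedPositions
  if (length(pos) && max(pos) > max(aln@positions))
    stop("mask positions exceed the alignment coordinate range")
  drop <- aln@positions %in% pos
  if (policy@excludeIndels) {
    hasGap <- colSums(aln@seqs == "-") > 0L
    drop <- drop | hasGap
  }
  if (all(drop)) stop("mask removes every column of the alignment")
  new("MitoAlignment", seqs = aln@seqs[, !drop, drop = FALSE],
      positions = aln@positions[!drop])
}

## columns usable for haplotype identity: complete-case (no N anywhere),
## keeping haplotype equality transitive across the alignment
.completeCols <- function(m) colSums(m == "N") == 0L

.haplotypeKeys <- function(m) {
  keep <- .completeCols(m)
  m2 <- m[, keep, drop = FALSE]
  if (ncol(m2) == 0L) return(rep("", nrow(m)))
  apply(m2, 1L, paste, collapse = "")
}

#' Collapse sequences into haplotypes
#'
#' Sequences identical on all unmasked, complete-case columns (columns with an
#' N in any sequence are dropped alignment-wide, keeping haplotype identity
#' transitive) share a haplotype. The table is sorted by descending count,
#' ties broken by haplotype id (the lexicographically smallest carrier).
#'
#' @param aln a \linkS4class{MitoAlignment}
#' @param policy optional \linkS4class{MaskPolicy} applied first.
#' @return a \linkS4class{HaplotypeTable}
#' @export
collapseHaplotypes <- function(aln, policy = NULL) {
  if (!is.null(policy)) aln <- applyMask(aln, policy)
  keys <- .haplotypeKeys(aln@seqs)
  groups <- split(rownames(aln@seqs), keys)
  ids <- vapply(groups, function(g) sort(g)[1], character(1))
  counts <- lengths(groups)
  ord <- order(-counts, ids)
  new("HaplotypeTable", haplotypeIds = unname(ids[ord]),
      counts = as.integer(unname(counts[ord])), members = unname(groups[ord]))
}

#' @rdname collapseHaplotypes
#' @param x a HaplotypeTable
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))
#' @rdname collapseHaplotypes
#' @export
setMethod("haplotypeCounts", "HaplotypeTable",
  function(x) setNames(x@counts, x@haplotypeIds))

#' @rdname collapseHaplotypes
#' @export
setGeneric("haplotypeFrequencies", function(x) standardGeneric("haplotypeFrequencies"))
#' @rdname collapseHaplotypes
#' @export
setMethod("haplotypeFrequencies", "HaplotypeTable",
  function(x) setNames(x@counts / sum(x@counts), x@haplotypeIds))

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable: %d haplotypes over %d sequences\n",
              length(object@counts), sum(object@counts)))
})

#' Unbiased haplotype (gene) diversity
#'
#' Hd = n/(n-1) * (1 - sum p_i^2): the probability that two sequences drawn
#' without replacement carry different haplotypes.
#'
#' @param x a \linkS4class{HaplotypeTable}, or a bare vector of haplotype
#'   counts.
#' @return a number in [0, 1].
#' @examples
#' haplotypeDiversity(c(rep(1, 10), 2))  # 12 sequences, 11 haplotypes
#' @export
haplotypeDiversity <- function(x) {
  counts <- if (is(x, "HaplotypeTable")) x@counts else x
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity is undefined for n < 2")
  p <- counts / n
  h <- n / (n - 1) * (1 - sum(p^2))
  min(max(h, 0), 1)
}

#' Read or write the sample metadata table
#'
#' Tab-separated with header
#' \code{sample_id group geogroup age_bp age_low age_high haplogroup}.
#' Ages are years before present (0 for modern samples); \code{age_low} and
#' \code{age_high} bracket the 95\% radiocarbon range.
#'
#' @param path file path.
#' @return data.frame of validated metadata.
#' @export
readSampleMetadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  validateSampleMetadata(md)
  md
}

#' @rdname readSampleMetadata
#' @param md metadata data.frame
#' @export
writeSampleMetadata <- function(md, path) {
  validateSampleMetadata(md)
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readSampleMetadata
#' @export
validateSampleMetadata <- function(md) {
  need <- c("sample_id", "group", "geogroup", "age_bp", "age_low", "age_high", "haplogroup")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("sample ids must be unique")
  if (any(md$age_bp < 0)) stop("age_bp must be >= 0")
  ok <- is.na(md$age_low) | is.na(md$age_high) |
    (md$age_low <= md$age_bp & md$age_bp <= md$age_high)
  if (!all(ok)) stop("age_low <= age_bp <= age_high violated for: ",
                     paste(head(md$sample_id[!ok], 5), collapse = ", "))
  invisible(TRUE)
}

#' Macrohaplogroup x group contingency table
#'
#' Collapses fine haplogroup labels (e.g. "U5b2b1") to macrohaplogroups by a
#' longest-matching-prefix map and cross-tabulates them against a grouping
#' column. Samples without a haplogroup label are excluded and reported.
#'
#' @param md metadata data.frame (see \code{\link{readSampleMetadata}}).
#' @param grouping which column to use: "group" or "geogroup".
#' @param prefixMap named character vector mapping label prefixes to
#'   macrohaplogroups, e.g. \code{c(U5 = "U5", K = "U8b/K", U8 = "U8b/K")}.
#'   The longest prefix that matches the start of a label wins; labels with
#'   no matching prefix (and all labels when no map is given) are kept as
#'   they are.
#' @return a counts matrix (rows = groups, columns = macrohaplogroups) with a
#'   \code{"dropped"} attribute listing samples without a label.
#' @export
haplogroupFrequencyTable <- function(md, grouping = c("group", "geogroup"),
                                     prefixMap = NULL) {
  grouping <- match.arg(grouping)
  lab <- md$haplogroup
  dropped <- md$sample_id[is.na(lab) | lab == ""]
  keep <- !(is.na(lab) | lab == "")
  md <- md[keep, , drop = FALSE]
  if (nrow(md) == 0L) {
    tab <- matrix(integer(0), 0, 0)
    attr(tab, "dropped") <- dropped
    return(tab)
  }
  macro <- macroHaplogroup(md$haplogroup, prefixMap)
  tab <- table(md[[grouping]], macro)
  tab <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  attr(tab, "dropped") <- dropped
  tab
}

#' @rdname haplogroupFrequencyTable
#' @param labels character vector of haplogroup labels
#' @export
macroHaplogroup <- function(labels, prefixMap = NULL) {
  if (is.null(prefixMap)) return(labels)
  prefs <- names(prefixMap)[order(-nchar(names(prefixMap)))]
  out <- labels
  done <- rep(FALSE, length(labels))
  for (p in prefs) {
    hit <- !done & startsWith(labels, p)
    out[hit] <- prefixMap[[p]]
    done <- done | hit
  }
  out
}
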