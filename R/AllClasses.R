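#' @import methods
#' @importFrom stats rexp rpois runif rnorm sd setNames
#'   chisq.test cmdscale as.dist hclust cutree predict
#' @importFrom utils read.delim write.table head
NULL

setOldClass("phylo")

.MITO_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' MitoAlignment: an aligned set of haploid mitogenome sequences
#'
#' Rows are samples, columns are alignment positions. Sequences are stored as
#' a character matrix over the symbols \code{A, C, G, T, -, N}. The
#' \code{positions} slot keeps the original 1-based reference coordinate of
#' every retained column, so that masking (column dropping) never loses the
#' coordinate map. Alignments read from reference-aligned FASTA have
#' \code{positions = 1:L} with L the reference length (16,569 for the human
#' mitogenome in rCRS coordinates).
#'
#' @slot seqs character matrix; rownames are unique sample identifiers.
#' @slot positions integer vector, one reference coordinate per column.
#' @exportClass MitoAlignment
setClass("MitoAlignment",
  representation(seqs = "matrix", positions = "integer"))

setValidity("MitoAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  if (nrow(m) < 1L || ncol(m) < 1L) return("alignment must have >= 1 sequence and >= 1 column")
  ids <- rownames(m)
  if (is.null(ids) || anyDuplicated(ids)) return("sample ids (rownames) must be present and unique")
  if (length(object@positions) != ncol(m)) return("positions must have one entry per column")
  if (any(object@positions < 1L)) return("positions must be >= 1")
  bad <- !(m %in% .MITO_ALPHABET)
  if (any(bad)) return(sprintf("invalid symbols in alignment: %s",
                               paste(unique(m[bad])[seq_len(min(5, length(unique(m[bad]))))], collapse = ", ")))
  TRUE
})

#' MaskPolicy: positions and column classes excluded from comparison
#'
#' @slot excludedPositions integer vector of 1-based reference positions to drop.
#' @slot excludeIndels logical; if TRUE, any column containing a gap in any
#'   sequence is dropped as well.
#' @exportClass MaskPolicy
setClass("MaskPolicy",
  representation(excludedPositions = "integer", excludeIndels = "logical"))

setValidity("MaskPolicy", function(object) {
  if (length(object@excludeIndels) != 1L || is.na(object@excludeIndels))
    return("excludeIndels must be TRUE or FALSE")
  if (any(object@excludedPositions < 1L)) return("excluded positions must be >= 1")
  TRUE
})

#' HaplotypeTable: distinct haplotypes with their counts
#'
#' Haplotypes are equivalence classes of sequences identical on all unmasked,
#' complete-case columns. Rows are ordered by descending count, ties broken by
#' haplotype id.
#'
#' @slot haplotypeIds character vector of haplotype labels (the
#'   lexicographically smallest carrier sample id).
#' @slot counts integer vector of per-haplotype sample counts.
#' @slot members list mapping each haplotype to its carrier sample ids.
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(haplotypeIds = "character", counts = "integer", members = "list"))

setValidity("HaplotypeTable", function(object) {
  if (length(object@haplotypeIds) != length(object@counts))
    return("ids and counts must have the same length")
  if (any(object@counts < 1L)) return("counts must be positive")
  if (anyDuplicated(object@haplotypeIds)) return("haplotype ids must be unique")
  TRUE
})

#' DemographicModel: demes, events, epoch-wise migration, generation time
#'
#' A concrete (fully numeric) demographic model for the structured coalescent,
#' parameterised backward in time from the present (time 0) in generations.
#' Events are either \code{"move"} (all lineages currently in deme \code{from}
#' move to deme \code{to}; this encodes both backward merges and
#' replacement/discontinuity events) or \code{"size"} (deme \code{from} takes
#' haploid effective size \code{size} from \code{time} backwards).
#'
#' @slot demes character vector of deme names.
#' @slot ne named numeric vector of haploid effective sizes at time 0.
#' @slot events data.frame with columns time, kind, from, to, size.
#' @slot migrations list of epochs, each \code{list(start, end, M)} where
#'   \code{M[i, j]} is the per-generation backward probability that a lineage
#'   in deme i moves to deme j.
#' @slot generationTime numeric, years per generation.
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(demes = "character", ne = "numeric", events = "data.frame",
                 migrations = "list", generationTime = "numeric"))

setValidity("DemographicModel", function(object) {
  if (length(object@demes) < 1L || anyDuplicated(object@demes))
    return("demes must be unique and non-empty")
  if (!all(object@demes %in% names(object@ne)))
    return("every deme needs an effective size")
  if (any(object@ne[object@demes] <= 0)) return("effective sizes must be > 0")
  ev <- object@events
  if (nrow(ev)) {
    need <- c("time", "kind", "from", "to", "size")
    if (!all(need %in% names(ev))) return("events need columns time, kind, from, to, size")
    if (is.unsorted(ev$time)) return("event times must be non-decreasing backward in time")
    if (any(ev$time < 0)) return("event times must be >= 0")
    if (!all(ev$kind %in% c("move", "size"))) return("event kind must be 'move' or 'size'")
    if (!all(ev$from %in% object@demes)) return("event 'from' deme not in model")
    mv <- ev$kind == "move"
    if (any(mv) && !all(ev$to[mv] %in% object@demes)) return("event 'to' deme not in model")
    if (any(ev$size[ev$kind == "size"] <= 0)) return("size-change sizes must be > 0")
  }
  for (ep in object@migrations) {
    M <- ep$M
    if (!is.matrix(M) || nrow(M) != length(object@demes) || ncol(M) != nrow(M))
      return("migration matrices must be demes x demes")
    if (any(M < 0) || any(M > 1)) return("migration rates must lie in [0, 1]")
    offdiag <- M; diag(offdiag) <- 0
    if (any(rowSums(offdiag) > 1)) return("per-deme total out-migration must be <= 1 per generation")
    if (ep$start >= ep$end) return("migration epoch must satisfy start < end")
  }
  if (object@generationTime <= 0) return("generationTime must be > 0")
  TRUE
})

#' SamplingScheme: serially sampled groups
#'
#' Each row is one sampling group: its deme, the number of sequences and the
#' sampling time, given as a normal prior on the age in years before present
#' (sd = 0 encodes a fixed age). Ages are converted to generations with the
#' model's generation time and truncated at zero.
#'
#' @slot groups data.frame with columns group, deme, n, age_mean, age_sd
#'   (years B.P.).
#' @exportClass SamplingScheme
setClass("SamplingScheme", representation(groups = "data.frame"))

setValidity("SamplingScheme", function(object) {
  g <- object@groups
  need <- c("group", "deme", "n", "age_mean", "age_sd")
  if (!all(need %in% names(g))) return("groups need columns group, deme, n, age_mean, age_sd")
  if (nrow(g) < 1L) return("at least one sampling group is required")
  if (anyDuplicated(g$group)) return("group names must be unique")
  if (any(g$n < 1L)) return("group sizes must be >= 1")
  if (any(g$age_mean < 0) || any(g$age_sd < 0)) return("ages and sds must be >= 0")
  TRUE
})

#' MutationModel: finite-sites mutation overlay
#'
#' Mutations are placed on the genealogy as a Poisson process with per-site,
#' per-generation rate \code{mu}, uniformly over \code{L} sites; repeat hits
#' are allowed. The replacement nucleotide is drawn with transition/
#' transversion weighting \code{tsTv} (1 = unbiased).
#'
#' @slot L integer, number of sites (default 16,569: the full mitogenome).
#' @slot mu numeric, per-site per-generation mutation rate.
#' @slot tsTv numeric, transition/transversion weight.
#' @exportClass MutationModel
setClass("MutationModel",
  representation(L = "integer", mu = "numeric", tsTv = "numeric"))

setValidity("MutationModel", function(object) {
  if (object@L < 1L) return("L must be >= 1")
  if (object@mu < 0) return("mu must be >= 0")
  if (object@tsTv <= 0) return("tsTv must be > 0")
  TRUE
})

#' PriorSpec: independent parameter priors
#'
#' @slot params named list; each element is \code{list(dist, ...)} with
#'   \code{dist} one of "fixed" (value), "uniform" (min, max),
#'   "loguniform" (min, max), "normal" (mean, sd).
#' @exportClass PriorSpec
setClass("PriorSpec", representation(params = "list"))

setValidity("PriorSpec", function(object) {
  p <- object@params
  if (length(p) && is.null(names(p))) return("priors must be named")
  for (nm in names(p)) {
    d <- p[[nm]]
    if (!is.list(d) || is.null(d$dist)) return(sprintf("prior '%s' needs a dist field", nm))
    ok <- switch(d$dist,
      fixed = !is.null(d$value) && is.finite(d$value),
      uniform = is.finite(d$min) && is.finite(d$max) && d$min <= d$max,
      loguniform = is.finite(d$min) && is.finite(d$max) && d$min > 0 && d$min <= d$max,
      normal = is.finite(d$mean) && is.finite(d$sd) && d$sd >= 0,
      FALSE)
    if (!isTRUE(ok)) return(sprintf("prior '%s' is invalid or has unknown dist '%s'", nm, d$dist))
  }
  TRUE
})

#' Genealogy: a serially sampled coalescent realisation
#'
#' @slot tree an \pkg{ape} \code{phylo} tree with branch lengths in
#'   generations.
#' @slot tipTimes numeric, sampling time (generations before present) of each
#'   tip, named by tip label.
#' @slot nodeTimes numeric, time of every node (tips then internal nodes, in
#'   \code{phylo} node numbering).
#' @slot tipDemes character, deme in which each tip was sampled.
#' @exportClass Genealogy
setClass("Genealogy",
  representation(tree = "phylo", tipTimes = "numeric", nodeTimes = "numeric",
                 tipDemes = "character"))

#' DemographicTemplate: a named model family ready to simulate
#'
#' Couples a sampling scheme and a prior specification with a builder that
#' turns one prior draw into a concrete \linkS4class{DemographicModel}.
#'
#' @slot name model name (e.g. "A", "G", "Gpan").
#' @slot priors a \linkS4class{PriorSpec}.
#' @slot scheme a \linkS4class{SamplingScheme}.
#' @slot build function(params) returning a \linkS4class{DemographicModel}.
#' @slot description one-line human description.
#' @exportClass DemographicTemplate
setClass("DemographicTemplate",
  representation(name = "character", priors = "PriorSpec",
                 scheme = "SamplingScheme", build = "function",
                 description = "character"))

#' SimulatedDataset: one simulated study
#'
#' @slot alignment a \linkS4class{MitoAlignment}.
#' @slot metadata data.frame of per-sample metadata (sample_id, group, geogroup,
#'   age_bp, age_low, age_high, haplogroup).
#' @slot params named numeric vector of the drawn model parameters.
#' @slot genealogy the retained \linkS4class{Genealogy}, or NULL.
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(alignment = "MitoAlignment", metadata = "data.frame",
                 params = "numeric", genealogy = "ANY"))

#' ReferenceTable: simulated summary statistics labelled by model
#'
#' @slot stats numeric matrix, one row per simulation (imputed, no missing
#'   values); may include appended LDA axes.
#' @slot model character vector of generating model labels.
#' @slot statNames column names of the raw (pre-LDA) statistics.
#' @slot lda list with the stored LDA projection (or empty list).
#' @slot seed the master seed used.
#' @exportClass ReferenceTable
setClass("ReferenceTable",
  representation(stats = "matrix", model = "character", statNames = "character",
                 lda = "list", seed = "numeric"))

setValidity("ReferenceTable", function(object) {
  if (nrow(object@stats) != length(object@model))
    return("one model label per simulation row is required")
  if (anyNA(object@stats)) return("reference table must contain no missing values (impute first)")
  if (length(unique(object@model)) < 2L) return("at least two model labels are required")
  TRUE
})

#' AbcRfClassifier: trained random-forest model-choice machinery
#'
#' @slot forest the \pkg{ranger} classification forest.
#' @slot errorForest the \pkg{ranger} regression forest trained on the
#'   out-of-bag misclassification indicator (posterior-probability estimator).
#' @slot table the training \linkS4class{ReferenceTable}.
#' @slot oobError numeric, out-of-bag prior error rate.
#' @slot oobPred character, per-row out-of-bag predictions.
#' @slot nTrees number of trees.
#' @exportClass AbcRfClassifier
setClass("AbcRfClassifier",
  representation(forest = "ANY", errorForest = "ANY", table = "ReferenceTable",
                 oobError = "numeric", oobPred = "character", nTrees = "numeric"))

#' ModelChoiceResult: outcome of one ABC-RF model comparison
#'
#' @slot selected name of the winning model (majority of tree votes).
#' @slot votes named numeric vector of votes per model (sums to nTrees).
#' @slot posterior posterior probability of the selected model.
#' @slot oobError out-of-bag prior error rate of the classifier.
#' @slot confusion confusion matrix of out-of-bag predictions
#'   (rows = true model, columns = predicted).
#' @slot ce named numeric vector of per-model classification error rates.
#' @slot ldaProjection coordinates of the observed point on the LDA axes
#'   (numeric(0) when LDA was not used).
#' @slot nTrees number of trees in the forest.
#' @exportClass ModelChoiceResult
setClass("ModelChoiceResult",
  representation(selected = "character", votes = "numeric", posterior = "numeric",
                 oobError = "numeric", confusion = "matrix", ce = "numeric",
                 ldaProjection = "numeric", nTrees = "numeric"))

setValidity("ModelChoiceResult", function(object) {
  if (abs(sum(object@votes) - object@nTrees) > 1e-8)
    return("votes must sum to the number of trees")
  if (object@posterior < 0 || object@posterior > 1)
    return("posterior probability must lie in [0, 1]")
  TRUE
})

#' MutationTree: a rooted tree with per-branch mutation counts
#'
#' Branch lengths are mutation counts (integers for observed trees; real
#' values after recalibration). Tip ages are years before present.
#'
#' @slot tree an \pkg{ape} \code{phylo}; edge lengths are mutation counts.
#' @slot tipAges numeric, years B.P. per tip, named by tip label (NA allowed
#'   until recalibration is requested).
#' @exportClass MutationTree
setClass("MutationTree", representation(tree = "phylo", tipAges = "numeric"))

setValidity("MutationTree", function(object) {
  tr <- object@tree
  if (is.null(tr$edge.length)) return("tree must carry branch lengths (mutation counts)")
  if (any(tr$edge.length < 0)) return("mutation counts must be >= 0")
  n <- length(tr$tip.label)
  if (length(object@tipAges) != n) return("one age per tip is required (NA allowed)")
  if (!is.null(names(object@tipAges)) && !setequal(names(object@tipAges), tr$tip.label))
    return("tipAges names must match tip labels")
  if (any(object@tipAges < 0, na.rm = TRUE)) return("tip ages must be >= 0")
  TRUE
})

#' ClockModel: mutational clock for the counted sequence
#'
#' The default corresponds to one mutation per 3,624 years on the complete
#' mitogenome (Soares-type whole-molecule calibration). The purifying-selection
#' polynomial correction of that calibration is intentionally not applied.
#'
#' @slot rate numeric, mutations per year accumulated on the counted sequence.
#' @exportClass ClockModel
setClass("ClockModel", representation(rate = "numeric"))

setValidity("ClockModel", function(object) {
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("clock rate must be a single positive number")
  TRUE
})

#' RhoEstimate: rho/sigma dating of a clade, classic and recalibrated
#'
#' @slot rho mean root-to-tip mutation count.
#' @slot sigma genealogy-based standard error of rho.
#' @slot rhoRecal rho after adding the expected missing mutations of ancient tips.
#' @slot sigmaRecal sigma computed on the recalibrated counts.
#' @slot age point age in years (classic), with 95\% CI \code{ageCI}.
#' @slot ageCI numeric length 2.
#' @slot ageRecal recalibrated point age in years, with CI \code{ageCIRecal}.
#' @slot ageCIRecal numeric length 2.
#' @slot nTips number of tips in the clade.
#' @slot clockRate mutations per year used for the conversion.
#' @exportClass RhoEstimate
setClass("RhoEstimate",
  representation(rho = "numeric", sigma = "numeric", rhoRecal = "numeric",
                 sigmaRecal = "numeric", age = "numeric", ageCI = "numeric",
                 ageRecal = "numeric", ageCIRecal = "numeric",
                 nTips = "numeric", clockRate = "numeric"))

setValidity("RhoEstimate", function(object) {
  for (s in c("rho", "sigma", "rhoRecal", "sigmaRecal"))
    if (slot(object, s) < 0) return(sprintf("%s must be >= 0", s))
  if (object@ageCI[1] > object@age || object@age > object@ageCI[2])
    return("CI must bracket the point estimate")
  TRUE
})

#' StudyDesign: group sizes and ages of the synthetic study
#'
#' @slot groups data.frame with columns group, n, age_mean, age_low, age_high
#'   (years B.P.).
#' @slot geogroups data.frame with columns geogroup, n partitioning the modern
#'   samples into geographic groups.
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(groups = "data.frame", geogroups = "data.frame"))

setValidity("StudyDesign", function(object) {
  g <- object@groups
  if (!all(c("group", "n", "age_mean", "age_low", "age_high") %in% names(g)))
    return("groups need columns group, n, age_mean, age_low, age_high")
  if (any(g$n < 1L)) return("group sizes must be >= 1")
  if (is.unsorted(rev(g$age_mean))) return("group ages must decrease from oldest to modern")
  if (any(g$age_low > g$age_mean | g$age_mean > g$age_high))
    return("age_low <= age_mean <= age_high is required")
  gg <- object@geogroups
  if (!all(c("geogroup", "n") %in% names(gg)))
    return("geogroups need columns geogroup, n")
  if (sum(gg$n) != g$n[nrow(g)])
    return("geogroup sizes must sum to the modern group size")
  TRUE
})
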