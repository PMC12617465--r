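#' The default ancient-plus-modern study design
#'
#' Eleven chronological groups (sizes 8, 8, 4, 3, 14, 55, 3, 3, 5, 6, 236)
#' from the Late Mesolithic to the present, with the modern samples
#' partitioned into nine geogroups (36, 21, 17, 21, 17, 65, 27, 12, 20).
#' Group age means and 95\% ranges are placed inside the conventional period
#' boundaries (Paleolithic/Mesolithic down to 7,950 yr B.P., Neolithic to
#' 4,450, Bronze to 2,900, Iron to 2,550, Medieval to 458).
#'
#' @return a \linkS4class{StudyDesign}
#' @export
studyDesign <- function() {
  groups <- data.frame(
    group = c("MesolithicUzzo", "NeolithicUzzo", "ChalcolithicBuffa",
              "BronzeAgeBuffa", "BronzeAgeSicily", "IronAge",
              "PhoenicianPunic", "Greek", "IslamicSegesta",
              "ChristianSegesta", "Modern"),
    n = c(8L, 8L, 4L, 3L, 14L, 55L, 3L, 3L, 5L, 6L, 236L),
    age_mean = c(9500, 7000, 4800, 3800, 3600, 2700, 2500, 2450, 1000, 800, 0),
    age_low  = c(8800, 6400, 4500, 3500, 2950, 2550, 2300, 2300,  900, 700, 0),
    age_high = c(10200, 7600, 5100, 4100, 4250, 2899, 2700, 2600, 1100, 900, 0),
    stringsAsFactors = FALSE)
  geogroups <- data.frame(
    geogroup = c("Agrigento", "CaltanissettaEnna", "CataniaSiracusa", "Gela",
                 "Messina", "PalermoCity", "PalermoOuter", "Ragusa", "Trapani"),
    n = c(36L, 21L, 17L, 21L, 17L, 65L, 27L, 12L, 20L),
    stringsAsFactors = FALSE)
  new("StudyDesign", groups = groups, geogroups = geogroups)
}

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d groups (%d sequences), %d modern geogroups\n",
              nrow(object@groups), sum(object@groups$n), nrow(object@geogroups)))
})

#' Generating parameters of the synthetic study
#'
#' One fixed, realistic maternal history rather than a prior draw: a small
#' hunter-gatherer deme (driving the strong differentiation of the oldest
#' group), moderate Sicilian and Mediterranean deme sizes (haploid female
#' effective sizes in the low thousands, the usual mtDNA scale) and mild
#' continuous migration. These are the conditions every study-shaped fixture
#' and recovery experiment is generated under.
#'
#' @return named numeric vector of model parameters.
#' @export
studyParameters <- function() {
  c(ne_SIC = 2000, ne_PHO = 1000, ne_GRE = 1000, ne_ISL = 1000,
    ne_ANC = 5000, ne_LOC = 500, m_ia = 0.002, m_med = 0.002,
    ne_GEO = 1500, m_geo = 0.02)
}

#' Generate a synthetic mitogenome study
#'
#' Simulates a full study-shaped dataset under a chosen generating demography:
#' an alignment sampled per the design's group sizes and ages, metadata with
#' drawn radiocarbon ages and geogroup labels for the modern samples, and
#' synthetic haplogroup labels assigned by single-linkage clustering of the
#' haplotypes (the labels are cluster ids, giving realistically sparse
#' haplogroup tables without a real phylogeny).
#'
#' @param design a \linkS4class{StudyDesign} (default \code{studyDesign()}).
#' @param model generating model name (default "G", a
#'   Mesolithic/Neolithic-replacement demography with migration) or a
#'   \linkS4class{DemographicTemplate}.
#' @param mut a \linkS4class{MutationModel}; the default uses a reduced locus
#'   of 2,000 sites at the whole-molecule per-site rate (statistics scale
#'   linearly in L; the full 16,569 is available by passing
#'   \code{mutationModel()}).
#' @param seed integer seed.
#' @param params named numeric vector of generating parameters; the default
#'   is one fixed, realistic parameterisation rather than a prior draw.
#' @param haplogroupCut single-linkage distance threshold (in mutations) at
#'   or below which haplotypes share a synthetic haplogroup label; the
#'   default of 1 (one-mutation neighbourhoods) produces label counts on the
#'   scale of real macrohaplogroup tables at the default locus length.
#' @param dir optional output directory; when given, writes
#'   \code{modern.fasta}, \code{ancient.fasta} and \code{metadata.tsv}.
#' @return a \linkS4class{SimulatedDataset} (invisibly when \code{dir} is
#'   given).
#' @export
generateStudy <- function(design = studyDesign(), model = "G",
                          mut = mutationModel(L = 2000L), seed,
                          params = NULL, haplogroupCut = 1, dir = NULL) {
  tpl <- if (is(model, "DemographicTemplate")) model
         else modelLibrary(model, config = list(design = design))
  if (is.null(params)) params <- studyParameters()
  need <- names(drawParameters(tpl@priors, seed = 1))
  fixed <- lapply(params[intersect(names(params), need)],
                  function(v) list(dist = "fixed", value = v))
  tpl2 <- if (is(model, "DemographicTemplate")) tpl
          else modelLibrary(model, config = list(design = design, priors = fixed))
  ds <- simulateDataset(tpl2, mut = mut, seed = seed, retainGenealogy = TRUE)

  ## geogroup labels for the modern samples, in design order
  md <- ds@metadata
  modern <- which(md$group == "Modern")
  if (length(modern)) {
    gg <- design@geogroups
    md$geogroup[modern] <- rep(gg$geogroup, gg$n)[seq_along(modern)]
  }
  md$haplogroup <- .syntheticHaplogroups(ds@alignment, haplogroupCut)
  ds@metadata <- md

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeMitoFasta(subsetSamples(ds@alignment, md$sample_id[modern]),
                   file.path(dir, "modern.fasta"))
    writeMitoFasta(subsetSamples(ds@alignment, md$sample_id[-modern]),
                   file.path(dir, "ancient.fasta"))
    writeSampleMetadata(md, file.path(dir, "metadata.tsv"))
    return(invisible(ds))
  }
  ds
}

## haplogroup labels from single-linkage clustering of haplotypes
.syntheticHaplogroups <- function(aln, cut) {
  tab <- collapseHaplotypes(aln)
  reps <- vapply(tab@members, function(g) sort(g)[1], character(1))
  m <- aln@seqs[reps, , drop = FALSE]
  if (length(reps) == 1L) {
    cl <- setNames(1L, reps)
  } else {
    d <- .pairDiff(m)
    hc <- hclust(as.dist(d), method = "single")
    cl <- cutree(hc, h = cut)
  }
  labPerHap <- sprintf("HG%02d", cl)
  out <- character(nrow(aln@seqs))
  names(out) <- rownames(aln@seqs)
  for (i in seq_along(tab@members)) out[tab@members[[i]]] <- labPerHap[i]
  unname(out[rownames(aln@seqs)])
}

#' Hand-checkable toy fixtures
#'
#' Small deterministic datasets used throughout the examples and tests:
#' \describe{
#' \item{\code{"paleolithic_hd"}}{12 sequences with exactly 11 haplotypes
#'   (ten singletons and one pair), the composition giving Hd = 0.98.}
#' \item{\code{"bronze_hd"}}{17 sequences with 16 haplotypes (one pair),
#'   giving Hd = 0.99.}
#' \item{\code{"star_rho"}}{a star \linkS4class{MutationTree} with tip
#'   mutation counts 2, 3, 4 (rho = 3, sigma = 1).}
#' \item{\code{"fixed_diff_pops"}}{two internally monomorphic populations
#'   separated by a fixed difference (FST = 1).}
#' }
#'
#' @param name fixture name.
#' @return the fixture object (alignment, tree or list of alignments).
#' @export
generateToy <- function(name = c("paleolithic_hd", "bronze_hd", "star_rho",
                                 "fixed_diff_pops")) {
  name <- match.arg(name)
  base <- function(L) paste(rep("A", L), collapse = "")
  variant <- function(L, at, to) {
    s <- rep("A", L); s[at] <- to; paste(s, collapse = "")
  }
  switch(name,
    paleolithic_hd = {
      L <- 30L
      seqs <- c(vapply(1:10, function(i) variant(L, i, "G"), character(1)),
                base(L), base(L))
      names(seqs) <- sprintf("P%02d", 1:12)
      MitoAlignment(seqs)
    },
    bronze_hd = {
      L <- 30L
      seqs <- c(vapply(1:15, function(i) variant(L, i, "T"), character(1)),
                base(L), base(L))
      names(seqs) <- sprintf("B%02d", 1:17)
      MitoAlignment(seqs)
    },
    star_rho = {
      tr <- ape::read.tree(text = "(t1:2,t2:3,t3:4);")
      mutationTree(tr, tipAges = c(t1 = 0, t2 = 0, t3 = 0))
    },
    fixed_diff_pops = {
      L <- 20L
      p1 <- setNames(rep(base(L), 3), sprintf("a%d", 1:3))
      p2 <- setNames(rep(variant(L, 5, "C"), 3), sprintf("b%d", 1:3))
      list(pop1 = MitoAlignment(p1), pop2 = MitoAlignment(p2))
    })
}

#' Split metadata into populations for summary statistics
#'
#' Maps each sampling-group name of a scheme to the sample ids carrying that
#' name in the metadata's \code{group} column or, failing that, its
#' \code{geogroup} column (used when modern samples are analysed as
#' geogroups).
#'
#' @param md metadata data.frame.
#' @param scheme a \linkS4class{SamplingScheme}.
#' @return named list of sample-id vectors.
#' @export
populationsFromMetadata <- function(md, scheme) {
  out <- lapply(scheme@groups$group, function(g) {
    ids <- md$sample_id[md$group == g]
    if (!length(ids)) ids <- md$sample_id[md$geogroup == g]
    if (!length(ids)) stop("no samples found for population: ", g)
    ids
  })
  setNames(out, scheme@groups$group)
}
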