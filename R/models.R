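## Demographic model library for the eleven-group ancient-plus-modern design.
##
## All models share a deep ancestral deme ANC into which every lineage is
## merged at tSep, guaranteeing coalescence. "Discontinuity" (replacement)
## models place the pre-discontinuity groups in a local deme LOC whose
## lineages never feed the post-discontinuity Sicilian deme SIC: backward in
## time, SIC is founded from ANC at the discontinuity boundary while LOC
## persists until tSep.

.MODEL_NAMES <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "Gpan", "Gst")

.modelConfig <- function(config) {
  defaults <- list(
    design = studyDesign(),
    generationTime = 25,
    tSepYears = 50000,          # deep common ancestry of all demes
    tGeoYears = 1500,           # depth of the modern geogroup structure (Gpan/Gst)
    ironEpochYears = c(2200, 3000),
    medievalEpochYears = c(458, 1400),
    priors = list())
  defaults[names(config)] <- config
  defaults
}

## boundary of each discontinuity model, years B.P.
.discBoundaryYears <- function(name, design) {
  g <- design@groups
  switch(name,
    C = , G = , Gpan = , Gst = g$age_high[g$group == "NeolithicUzzo"],  # Mesolithic/Neolithic
    D = , H = g$age_high[g$group == "BronzeAgeSicily"],      # pre-Bronze/Bronze
    E = , I = g$age_high[g$group == "IronAge"],              # pre-Iron/Iron
    NA_real_)
}

## group -> deme map per model
.demeMap <- function(name, design) {
  grp <- design@groups$group
  map <- setNames(rep("SIC", length(grp)), grp)
  map[c("PhoenicianPunic", "Greek", "IslamicSegesta")] <- c("PHO", "GRE", "ISL")
  if (name %in% c("C", "G", "Gpan", "Gst")) map["MesolithicUzzo"] <- "LOC"
  if (name %in% c("D", "H"))
    map[c("MesolithicUzzo", "NeolithicUzzo", "ChalcolithicBuffa")] <- "LOC"
  if (name %in% c("E", "I"))
    map[c("MesolithicUzzo", "NeolithicUzzo", "ChalcolithicBuffa",
          "BronzeAgeBuffa", "BronzeAgeSicily")] <- "LOC"
  if (name == "A") map[] <- "SIC"
  map
}

.schemeFromDesign <- function(design, demeMap, geodemes = FALSE) {
  g <- design@groups
  rows <- data.frame(group = g$group, deme = unname(demeMap[g$group]),
                     n = g$n, age_mean = g$age_mean,
                     age_sd = (g$age_high - g$age_low) / (2 * 1.959964),
                     stringsAsFactors = FALSE)
  if (geodemes) {
    rows <- rows[rows$group != "Modern", , drop = FALSE]
    gg <- design@geogroups
    rows <- rbind(rows, data.frame(group = gg$geogroup, deme = gg$geogroup,
                                   n = gg$n, age_mean = 0, age_sd = 0,
                                   stringsAsFactors = FALSE))
  }
  samplingScheme(rows)
}

.defaultPriors <- function(demes, migParams) {
  p <- list()
  for (d in demes)
    p[[paste0("ne_", d)]] <- list(dist = "loguniform", min = 1e2, max = 1e5)
  for (m in migParams)
    p[[m]] <- if (m == "m_geo")
      list(dist = "uniform", min = 0.005, max = 0.05)   # panmixia-scale exchange
    else
      list(dist = "uniform", min = 0, max = 0.01)
  p
}

## blocks of the modern geogroup structure; memberships follow the printed
## grouping, labels assigned geographically
.GEO_EAST <- c("CaltanissettaEnna", "CataniaSiracusa", "Gela", "Messina", "Ragusa")
.GEO_WEST <- c("PalermoCity", "PalermoOuter", "Trapani", "Agrigento")

#' The demographic model library
#'
#' Returns a simulation-ready \linkS4class{DemographicTemplate} for one of the
#' eleven named demographic hypotheses about an ancient-plus-modern eleven
#' group design:
#' \itemize{
#' \item \code{A}: complete genetic continuity, a single deme through time.
#' \item \code{B}--\code{E}: the Phoenician/Punic, Greek and Islamic-period
#'   groups evolve in their own demes separated since a deep split;
#'   \code{B} keeps the local lineage continuous, while \code{C}, \code{D}
#'   and \code{E} add a population replacement (discontinuity) at the
#'   Mesolithic/Neolithic, pre-Bronze/Bronze and pre-Iron/Iron boundaries.
#' \item \code{F}--\code{I}: as \code{B}--\code{E} plus continuous two-way
#'   migration between the Sicilian, Phoenician/Punic and Greek demes during
#'   the Iron Age epoch and between the Sicilian and Islamic demes during the
#'   Medieval epoch. \code{G} is \code{C} plus migration.
#' \item \code{Gpan}/\code{Gst}: variants of \code{G} in which the modern
#'   samples are split into nine geogroup demes, either all exchanging
#'   migrants at the same rate (panmixia) or partitioned into two isolated
#'   east/west blocks.
#' }
#'
#' @param name one of A, B, C, D, E, F, G, H, I, Gpan, Gst.
#' @param config optional list overriding defaults: \code{design}
#'   (a \linkS4class{StudyDesign}), \code{generationTime},
#'   \code{tSepYears}, \code{tGeoYears}, \code{ironEpochYears},
#'   \code{medievalEpochYears}, and \code{priors} (a named list of prior
#'   definitions replacing the shipped defaults).
#' @return a \linkS4class{DemographicTemplate}
#' @examples
#' tpl <- modelLibrary("A")
#' sum(schemeGroups(tpl@scheme)$n)
#' @export
modelLibrary <- function(name, config = list()) {
  if (!name %in% .MODEL_NAMES) stop("unknown model name: ", name)
  cfg <- .modelConfig(config)
  design <- cfg$design
  gt <- cfg$generationTime
  tSep <- cfg$tSepYears / gt
  geodemes <- name %in% c("Gpan", "Gst")
  demeMap <- .demeMap(name, design)
  scheme <- .schemeFromDesign(design, demeMap, geodemes = geodemes)

  if (name == "A") {
    demes <- "SIC"
  } else {
    demes <- c("SIC", "PHO", "GRE", "ISL", "ANC")
    if (any(demeMap == "LOC")) demes <- c(demes, "LOC")
    if (geodemes) demes <- c(demes, design@geogroups$geogroup)
  }

  hasMig <- name %in% c("F", "G", "H", "I", "Gpan", "Gst")
  migParams <- character(0)
  if (hasMig) migParams <- c("m_ia", "m_med")
  if (geodemes) migParams <- c(migParams, "m_geo")
  priors <- .defaultPriors(demes, migParams)
  priors[names(cfg$priors)] <- cfg$priors
  if (geodemes) {
    ## one shared size parameter for the nine geodemes
    priors <- priors[!grepl("^ne_", names(priors)) |
                     names(priors) %in% paste0("ne_", c("SIC", "PHO", "GRE", "ISL", "ANC", "LOC"))]
    priors$ne_GEO <- list(dist = "loguniform", min = 1e2, max = 1e5)
  }

  tDisc <- .discBoundaryYears(name, design) / gt
  ironEpoch <- sort(cfg$ironEpochYears) / gt
  medEpoch <- sort(cfg$medievalEpochYears) / gt
  tGeo <- cfg$tGeoYears / gt
  geoNames <- design@geogroups$geogroup

  build <- function(params) {
    ne <- setNames(numeric(length(demes)), demes)
    for (d in demes)
      ne[d] <- if (geodemes && d %in% geoNames) params[["ne_GEO"]] else params[[paste0("ne_", d)]]
    ev <- NULL
    migs <- list()
    if (name != "A") {
      ev <- data.frame(time = numeric(0), kind = character(0), from = character(0),
                       to = character(0), size = numeric(0), stringsAsFactors = FALSE)
      if (geodemes)
        for (g in geoNames)
          ev <- rbind(ev, data.frame(time = tGeo, kind = "move", from = g,
                                     to = "SIC", size = NA_real_))
      if (!is.na(tDisc))
        ev <- rbind(ev, data.frame(time = tDisc, kind = "move", from = "SIC",
                                   to = "ANC", size = NA_real_))
      for (d in setdiff(demes, c("ANC", geoNames)))
        ev <- rbind(ev, data.frame(time = tSep, kind = "move", from = d,
                                   to = "ANC", size = NA_real_))
      if (hasMig) {
        D <- length(demes)
        Mia <- matrix(0, D, D, dimnames = list(demes, demes))
        for (pair in list(c("SIC", "PHO"), c("SIC", "GRE"), c("PHO", "GRE"))) {
          Mia[pair[1], pair[2]] <- params[["m_ia"]]
          Mia[pair[2], pair[1]] <- params[["m_ia"]]
        }
        Mmed <- matrix(0, D, D, dimnames = list(demes, demes))
        Mmed["SIC", "ISL"] <- params[["m_med"]]
        Mmed["ISL", "SIC"] <- params[["m_med"]]
        migs <- list(list(start = ironEpoch[1], end = ironEpoch[2], M = Mia),
                     list(start = medEpoch[1], end = medEpoch[2], M = Mmed))
      }
      if (geodemes) {
        D <- length(demes)
        Mgeo <- matrix(0, D, D, dimnames = list(demes, demes))
        pool <- if (name == "Gpan") list(geoNames) else list(.GEO_EAST, .GEO_WEST)
        for (block in pool)
          for (g1 in block) for (g2 in setdiff(block, g1))
            Mgeo[g1, g2] <- params[["m_geo"]] / (length(block) - 1)
        migs <- c(migs, list(list(start = 0, end = tGeo, M = Mgeo)))
      }
    }
    demographicModel(demes, ne, events = ev, migrations = migs,
                     generationTime = gt)
  }

  new("DemographicTemplate", name = name, priors = do.call(priorSpec, priors),
      scheme = scheme, build = build,
      description = sprintf("demographic model %s (%d demes)", name, length(demes)))
}

#' Accessor for a SamplingScheme's group table
#'
#' @param x a \linkS4class{SamplingScheme}
#' @return the groups data.frame.
#' @export
schemeGroups <- function(x) x@groups

#' Scale a sampling scheme's group sizes
#'
#' Divides every group size by \code{factor} (rounded), flooring at
#' \code{minN} so that within-population statistics stay defined.
#'
#' @param scheme a \linkS4class{SamplingScheme}
#' @param factor positive divisor.
#' @param minN minimum group size after scaling (default 2).
#' @return a \linkS4class{SamplingScheme}
#' @export
scaleScheme <- function(scheme, factor, minN = 2L) {
  g <- scheme@groups
  g$n <- pmax(as.integer(minN), as.integer(round(g$n / factor)))
  samplingScheme(g)
}

#' Fix a library model's parameters at known values
#'
#' Returns the named library model with its priors replaced by point masses
#' at \code{params}: the template then always simulates the same demography
#' (up to the coalescent and mutational randomness), which is how "observed"
#' datasets with a known generating history are produced.
#'
#' @param name model name, as in \code{\link{modelLibrary}}.
#' @param params named numeric vector of parameter values (extra entries are
#'   ignored).
#' @param config passed through to \code{\link{modelLibrary}}.
#' @return a \linkS4class{DemographicTemplate}
#' @export
fixedParameterTemplate <- function(name, params = studyParameters(),
                                   config = list()) {
  tpl0 <- modelLibrary(name, config)
  need <- names(tpl0@priors@params)
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameter value(s): ", paste(miss, collapse = ", "))
  fixed <- lapply(as.list(params[need]), function(v) list(dist = "fixed", value = v))
  config$priors <- fixed
  modelLibrary(name, config)
}

#' A minimal custom demographic template
#'
#' Builds a \linkS4class{DemographicTemplate} for a set of demes with
#' constant sizes and optional symmetric migration between every deme pair:
#' the workhorse for calibration experiments and simulation studies outside
#' the named model library.
#'
#' @param name template name.
#' @param groups data.frame with columns group, deme, n, age_mean, age_sd.
#' @param nePriors named list of prior definitions, one \code{ne_<deme>}
#'   entry per deme (fixed values may be given as plain numbers).
#' @param migration optional prior definition (or number) for a symmetric
#'   per-pair migration rate applying at all times.
#' @param generationTime years per generation.
#' @return a \linkS4class{DemographicTemplate}
#' @export
customTemplate <- function(name, groups, nePriors, migration = NULL,
                           generationTime = 25) {
  demes <- unique(groups$deme)
  asPrior <- function(v) if (is.numeric(v)) list(dist = "fixed", value = v) else v
  priors <- lapply(nePriors, asPrior)
  if (!all(paste0("ne_", demes) %in% names(priors)))
    stop("nePriors must contain one ne_<deme> entry per deme")
  if (!is.null(migration)) priors$m <- asPrior(migration)
  build <- function(params) {
    ne <- setNames(vapply(demes, function(d) params[[paste0("ne_", d)]],
                          numeric(1)), demes)
    migs <- list()
    if (!is.null(migration) && length(demes) > 1L) {
      M <- matrix(params[["m"]], length(demes), length(demes),
                  dimnames = list(demes, demes))
      diag(M) <- 0
      migs <- list(list(start = 0, end = Inf, M = M))
    }
    demographicModel(demes, ne, migrations = migs,
                     generationTime = generationTime)
  }
  new("DemographicTemplate", name = name, priors = do.call(priorSpec, priors),
      scheme = samplingScheme(groups), build = build,
      description = sprintf("custom model '%s' (%d demes)", name, length(demes)))
}

#' Override a scheme's group sizes and ages, keeping its deme assignments
#'
#' Matches groups by name; groups absent from \code{override} keep their
#' original size and age.
#'
#' @param scheme a \linkS4class{SamplingScheme} (e.g. a model template's).
#' @param override a \linkS4class{SamplingScheme} supplying n, age_mean and
#'   age_sd per group.
#' @return a \linkS4class{SamplingScheme}
#' @export
overrideScheme <- function(scheme, override) {
  g <- scheme@groups
  o <- override@groups
  i <- match(g$group, o$group)
  hit <- !is.na(i)
  for (col in c("n", "age_mean", "age_sd"))
    g[[col]][hit] <- o[[col]][i[hit]]
  samplingScheme(g)
}

setMethod("show", "DemographicTemplate", function(object) {
  cat(sprintf("DemographicTemplate '%s': %s; %d sampling groups, %d parameters\n",
              object@name, object@description, nrow(object@scheme@groups),
              length(object@priors@params)))
})

## deterministic per-simulation seed stream (all values < 2^31)
.deriveSeed <- function(master, modelIdx, simIdx) {
  ((master %% 2147483647) * 48271 + modelIdx * 16807 + simIdx * 69621) %% 2147483629 + 1
}

#' Simulate one dataset under a demographic template
#'
#' Draws parameters from the template priors, draws one sampling age per
#' group from its (truncated) normal radiocarbon prior, realises the
#' structured-coalescent genealogy and overlays finite-sites mutations.
#'
#' @param template a \linkS4class{DemographicTemplate} from
#'   \code{\link{modelLibrary}}.
#' @param mut a \linkS4class{MutationModel}.
#' @param seed integer seed (mandatory for reproducibility).
#' @param retainGenealogy keep the genealogy in the result?
#' @return a \linkS4class{SimulatedDataset}
#' @export
simulateDataset <- function(template, mut = mutationModel(), seed,
                            retainGenealogy = FALSE) {
  set.seed(seed)
  params <- drawParameters(template@priors)
  model <- template@build(params)
  g <- template@scheme@groups
  gt <- model@generationTime
  ageDraw <- pmax(0, rnorm(nrow(g), g$age_mean, g$age_sd))
  tips <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(id = sprintf("%s_%03d", g$group[i], seq_len(g$n[i])),
               deme = g$deme[i], time = ageDraw[i] / gt,
               group = g$group[i], age = ageDraw[i],
               stringsAsFactors = FALSE)
  }))
  gen <- simulateGenealogy(model, tips[, c("id", "deme", "time")])
  aln <- mutateGenealogy(gen, mut)
  md <- data.frame(sample_id = tips$id, group = tips$group,
                   geogroup = "",
                   age_bp = tips$age,
                   age_low = pmax(0, tips$age - 1.959964 * g$age_sd[match(tips$group, g$group)]),
                   age_high = tips$age + 1.959964 * g$age_sd[match(tips$group, g$group)],
                   haplogroup = NA_character_, stringsAsFactors = FALSE)
  new("SimulatedDataset", alignment = aln, metadata = md, params = params,
      genealogy = if (retainGenealogy) gen else NULL)
}

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: %d sequences x %d sites, %d groups\n",
              nSamples(object@alignment), nSites(object@alignment),
              length(unique(object@metadata$group))))
})
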