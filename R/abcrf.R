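#' Build a reference table of simulated summary statistics
#'
#' Runs \code{nSimsPerModel} simulations under each template, summarises each
#' simulated alignment with \code{\link{summaryStatistics}} over the scheme's
#' sampling groups, and stacks the imputed vectors into a model-labelled
#' table (equal simulations per model: uniform prior model probabilities).
#' Per-simulation seeds are derived deterministically from the master seed,
#' the model index and the simulation index, so the table is reproducible
#' and construction is streaming (constant memory per simulation). A failed
#' simulation is retried with an incremented seed (at most 10 times) and
#' logged.
#'
#' @param templates named list of \linkS4class{DemographicTemplate}s sharing
#'   one sampling design.
#' @param mut a \linkS4class{MutationModel}.
#' @param nSimsPerModel simulations per model.
#' @param seed master integer seed.
#' @param scheme optional \linkS4class{SamplingScheme} whose group sizes and
#'   ages override each template's scheme (e.g. a scaled-down design); the
#'   template's own deme assignments are kept.
#' @return a \linkS4class{ReferenceTable}
#' @export
buildReferenceTable <- function(templates, mut = mutationModel(),
                                nSimsPerModel, seed, scheme = NULL) {
  if (is.null(names(templates))) stop("templates must be named by model")
  if (nSimsPerModel < 1) stop("nSimsPerModel must be >= 1")
  rows <- vector("list", length(templates) * nSimsPerModel)
  labels <- character(length(rows))
  r <- 0L
  for (j in seq_along(templates)) {
    tpl <- templates[[j]]
    if (!is.null(scheme)) tpl@scheme <- overrideScheme(tpl@scheme, scheme)
    pops <- .schemePopulations(tpl@scheme)
    for (i in seq_len(nSimsPerModel)) {
      s <- .deriveSeed(seed, j, i)
      attempt <- 0L
      repeat {
        ds <- tryCatch(simulateDataset(tpl, mut = mut, seed = s + attempt),
                       error = function(e) e)
        if (!inherits(ds, "error")) break
        attempt <- attempt + 1L
        if (attempt > 10L)
          stop("simulation kept failing for model ", names(templates)[j],
               ": ", conditionMessage(ds))
        message("resimulating (model ", names(templates)[j], ", sim ", i,
                "): ", conditionMessage(ds))
      }
      r <- r + 1L
      rows[[r]] <- summaryStatistics(ds@alignment, pops)
      labels[r] <- names(templates)[j]
    }
  }
  raw <- do.call(rbind, rows)
  stats <- imputeSummaries(raw)
  new("ReferenceTable", stats = stats, model = labels,
      statNames = colnames(raw), lda = list(), seed = seed)
}

.schemePopulations <- function(scheme) {
  g <- scheme@groups
  ids <- lapply(seq_len(nrow(g)),
                function(i) sprintf("%s_%03d", g$group[i], seq_len(g$n[i])))
  setNames(ids, g$group)
}

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: %d simulations x %d statistics, models: %s%s\n",
              nrow(object@stats), ncol(object@stats),
              paste(unique(object@model), collapse = ", "),
              if (length(object@lda)) " (+LDA axes)" else ""))
})

## ridge-regularised linear discriminant projection (standardised inputs,
## within-class covariance W + eps I); returns loadings in original units
.ldaProjection <- function(x, grp, eps = 1e-8) {
  grp <- as.factor(grp)
  keep <- which(apply(x, 2, sd) > 0)
  xs <- scale(x[, keep, drop = FALSE])
  ctr <- attr(xs, "scaled:center"); scl <- attr(xs, "scaled:scale")
  k <- nlevels(grp)
  p <- ncol(xs)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  gm <- colMeans(xs)
  for (lv in levels(grp)) {
    xi <- xs[grp == lv, , drop = FALSE]
    mi <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, mi))
    B <- B + nrow(xi) * tcrossprod(mi - gm)
  }
  W <- W / (nrow(xs) - k) + diag(eps, p)
  eg <- eigen(solve(W, B), symmetric = FALSE)
  nAxes <- min(k - 1L, p)
  A <- Re(eg$vectors[, seq_len(nAxes), drop = FALSE])
  ## unit within-class variance per axis, as in canonical LDA
  sc <- sqrt(diag(crossprod(A, W %*% A)))
  A <- sweep(A, 2, sc, "/")
  list(keep = keep, center = ctr, scale = scl, loadings = A, nAxes = nAxes)
}

.projectLda <- function(proj, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, 1, dimnames = list(NULL, names(newx)))
  xs <- sweep(sweep(newx[, proj$keep, drop = FALSE], 2, proj$center), 2, proj$scale, "/")
  xs %*% proj$loadings
}

#' Append linear discriminant axes to a reference table
#'
#' Fits a (ridge-regularised) linear discriminant analysis of the summary
#' statistics on the generating model and appends the min(n_models - 1,
#' n_stats) discriminant coordinates as extra predictor columns, storing the
#' projection so the observed vector can be augmented identically. Appending
#' (rather than replacing) follows standard ABC-RF practice; the axes also
#' serve as a visual check of whether the simulations cover the observed
#' point.
#'
#' @param table a \linkS4class{ReferenceTable}
#' @param eps ridge added to a singular within-class covariance (with a
#'   warning).
#' @return the augmented \linkS4class{ReferenceTable}
#' @export
addLdaAxes <- function(table, eps = 1e-8) {
  if (length(table@lda)) stop("LDA axes already added")
  raw <- table@stats[, table@statNames, drop = FALSE]
  if (nrow(raw) <= ncol(raw))
    stop("LDA needs more simulations than statistics")
  proj <- .ldaProjection(raw, table@model, eps = eps)
  ax <- .projectLda(proj, raw)
  colnames(ax) <- paste0("LDA", seq_len(ncol(ax)))
  table@stats <- cbind(table@stats, ax)
  table@lda <- proj
  table
}

#' Project an observed summary vector the way the table was augmented
#'
#' @param table a \linkS4class{ReferenceTable} (with or without LDA axes).
#' @param observed a raw summary vector (pre-imputation).
#' @return the imputed, LDA-augmented numeric vector matching the table's
#'   columns.
#' @export
augmentObserved <- function(table, observed) {
  if (!identical(names(observed), table@statNames))
    stop("observed vector does not match the table's statistics")
  v <- imputeSummaries(observed)
  if (length(table@lda)) {
    ax <- .projectLda(table@lda, observed)
    v <- c(v, setNames(as.numeric(ax), paste0("LDA", seq_len(ncol(ax)))))
  }
  v[colnames(table@stats)]
}

#' Train the ABC-RF model-choice classifier
#'
#' Fits a random-forest classifier of the generating model on the reference
#' table (500 trees by default) and, following the regression-forest
#' posterior estimator, a second forest predicting the out-of-bag
#' misclassification indicator from the same predictors.
#'
#' @param table a \linkS4class{ReferenceTable}
#' @param nTrees number of trees (default 500).
#' @param seed integer seed.
#' @return an \linkS4class{AbcRfClassifier}
#' @export
trainClassifier <- function(table, nTrees = 500, seed = 1) {
  if (length(unique(table@model)) < 2L)
    stop("model choice needs at least two model labels")
  df <- as.data.frame(table@stats)
  df$.model <- factor(table@model)
  forest <- ranger::ranger(dependent.variable.name = ".model", data = df,
                           num.trees = nTrees, seed = seed,
                           respect.unordered.factors = TRUE)
  oobPred <- as.character(forest$predictions)
  oobErr <- mean(oobPred != table@model, na.rm = TRUE)
  dfe <- as.data.frame(table@stats)
  dfe$.err <- as.numeric(oobPred != table@model)
  errForest <- ranger::ranger(dependent.variable.name = ".err", data = dfe,
                              num.trees = nTrees, seed = seed + 1L)
  new("AbcRfClassifier", forest = forest, errorForest = errForest,
      table = table, oobError = oobErr, oobPred = oobPred, nTrees = nTrees)
}

setMethod("show", "AbcRfClassifier", function(object) {
  cat(sprintf("AbcRfClassifier: %d trees, OOB error %.3f, models: %s\n",
              object@nTrees, object@oobError,
              paste(unique(object@table@model), collapse = ", ")))
})

#' Select the best-fitting model for an observed summary vector
#'
#' The winning model takes the majority of the forest's tree votes at the
#' observed point; its posterior probability is estimated as one minus the
#' regression-forest prediction of the local out-of-bag misclassification
#' rate (clamped to [0, 1]). The out-of-bag prior error rate, the confusion
#' matrix and the per-model classification errors are reported alongside.
#'
#' @param clf an \linkS4class{AbcRfClassifier}
#' @param observed a raw summary vector matching the table's pre-LDA
#'   statistics.
#' @return a \linkS4class{ModelChoiceResult}
#' @export
selectModel <- function(clf, observed) {
  tab <- clf@table
  x <- augmentObserved(tab, observed)
  newdf <- as.data.frame(matrix(x, 1, dimnames = list(NULL, names(x))))
  all <- predict(clf@forest, data = newdf, predict.all = TRUE)$predictions
  lev <- levels(clf@forest$forest$levels)
  if (is.null(lev)) lev <- clf@forest$forest$levels
  votes <- tabulate(as.integer(all), nbins = length(lev))
  names(votes) <- lev
  sel <- names(votes)[which.max(votes)]
  postErr <- predict(clf@errorForest, data = newdf)$predictions
  posterior <- min(max(1 - postErr, 0), 1)
  conf <- table(factor(tab@model, levels = sort(unique(tab@model))),
                factor(clf@oobPred, levels = sort(unique(tab@model))))
  confM <- matrix(as.integer(conf), nrow = nrow(conf), dimnames = dimnames(conf))
  ce <- 1 - diag(confM) / rowSums(confM)
  ldaProj <- if (length(tab@lda))
    x[grep("^LDA", names(x))] else numeric(0)
  new("ModelChoiceResult", selected = sel, votes = as.numeric(votes) |>
        setNames(names(votes)), posterior = posterior, oobError = clf@oobError,
      confusion = confM, ce = ce, ldaProjection = as.numeric(ldaProj),
      nTrees = clf@nTrees)
}

setMethod("show", "ModelChoiceResult", function(object) {
  cat(sprintf("ModelChoiceResult: selected %s (posterior %.3f, OOB error %.3f)\n",
              object@selected, object@posterior, object@oobError))
  cat("  votes:", paste(sprintf("%s=%d", names(object@votes), object@votes),
                        collapse = ", "), "\n")
})

#' Hierarchical ABC-RF model comparison
#'
#' Executes an ordered list of model-choice stages, each a character vector
#' of model names; the token \code{"winner:k"} is replaced by the model
#' selected at stage k. The canonical four-stage design is
#' \code{list(c("A","B","C","D","E"), c("F","G","H","I"),
#' c("winner:1","winner:2"), c("Gpan","Gst"))}.
#'
#' @param templates named list of \linkS4class{DemographicTemplate}s covering
#'   every model named in \code{stages}.
#' @param observedStats function(stage models) returning the observed raw
#'   summary vector for that stage, or a single summary vector used for all
#'   stages.
#' @param stages list of character vectors.
#' @param nSimsPerModel simulations per model and stage.
#' @param mut a \linkS4class{MutationModel}.
#' @param seed master seed.
#' @param nTrees trees per forest.
#' @param lda append LDA axes (default TRUE)?
#' @param scheme optional scheme override passed to
#'   \code{\link{buildReferenceTable}}.
#' @return list of \linkS4class{ModelChoiceResult}, one per stage.
#' @export
hierarchicalComparison <- function(templates, observedStats, stages,
                                   nSimsPerModel, mut = mutationModel(),
                                   seed = 1, nTrees = 500, lda = TRUE,
                                   scheme = NULL) {
  if (!length(stages)) stop("empty stage list")
  results <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    models <- stages[[s]]
    if (!length(models)) stop("stage ", s, " is empty")
    tok <- grepl("^winner:", models)
    for (i in which(tok)) {
      k <- as.integer(sub("winner:", "", models[i]))
      if (k >= s || is.null(results[[k]])) stop("winner token refers to an unfinished stage")
      models[i] <- results[[k]]@selected
    }
    models <- unique(models)
    miss <- setdiff(models, names(templates))
    if (length(miss)) stop("no template for model(s): ", paste(miss, collapse = ", "))
    tab <- buildReferenceTable(templates[models], mut = mut,
                               nSimsPerModel = nSimsPerModel,
                               seed = .deriveSeed(seed, s, 0L), scheme = scheme)
    if (lda) tab <- addLdaAxes(tab)
    clf <- trainClassifier(tab, nTrees = nTrees, seed = .deriveSeed(seed, s, 1L))
    obs <- if (is.function(observedStats)) observedStats(models) else observedStats
    results[[s]] <- selectModel(clf, obs)
  }
  names(results) <- vapply(seq_along(stages),
                           function(s) paste0("stage", s), character(1))
  results
}
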