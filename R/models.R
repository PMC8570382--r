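# Random-forest body-position classifiers in the two validation regimes:
# individual (within-infant chronological 60/40 split) and group
# (leave-one-subject-out).

#' Model hyperparameters
#'
#' Defaults follow the validated configuration: 750 trees and the stock
#' mtry (square root of the number of features).
#'
#' @param ntree number of trees (default 750).
#' @param mtry features tried per split; `NULL` means
#'   `floor(sqrt(n_features))`, resolved at fit time.
#' @param seed RNG seed stamped into the model for bit-reproducible fits.
#' @return Named list.
#' @export
modelSpec <- function(ntree = 750, mtry = NULL, seed = 1L) {
  stopifnot(ntree >= 1)
  list(ntree = as.integer(ntree), mtry = mtry, seed = as.integer(seed))
}

#' Chronological within-class train/test split
#'
#' Mimics the intended field use (video-coded morning training, rest-of-day
#' prediction): within each body-position class, windows are ordered by
#' start time and the first `round(trainFrac * n)` go to training, the
#' remainder to testing. Splitting within class keeps every position
#' represented in training despite the sequential task order. A class with
#' a single window goes entirely to training, with a warning.
#'
#' @param ft a labelled [FeatureTable-class].
#' @param trainFrac training fraction (default 0.6).
#' @return List with [FeatureTable-class] elements `train` and `test`.
#' @export
chronologicalSplit <- function(ft, trainFrac = 0.6) {
  lab <- windowLabels(ft)
  if (!length(lab) || all(is.na(lab)))
    stop("empty split: no labelled windows")
  trainIdx <- integer(0)
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    idx <- idx[order(windowStarts(ft)[idx])]
    n <- length(idx)
    if (n == 1L) {
      warning(sprintf("class '%s' has a single window; assigned to training",
                      cl))
      nTrain <- 1L
    } else {
      nTrain <- as.integer(round(trainFrac * n))
    }
    trainIdx <- c(trainIdx, idx[seq_len(nTrain)])
  }
  trainIdx <- sort(trainIdx)
  list(train = ft[trainIdx], test = ft[setdiff(seq_along(lab), trainIdx)])
}

.fitForest <- function(x, y, spec) {
  mtry <- if (is.null(spec$mtry)) floor(sqrt(ncol(x))) else spec$mtry
  stopifnot(mtry >= 1, mtry <= ncol(x))
  d <- as.data.frame(x)
  names(d) <- make.names(names(d))
  d$.class <- factor(y)
  forest <- ranger::ranger(dependent.variable.name = ".class", data = d,
                           num.trees = spec$ntree, mtry = mtry,
                           seed = spec$seed, num.threads = 1L)
  list(forest = forest, mtry = mtry)
}

#' Train an individual body-position model
#'
#' Fits a random forest on one participant's training windows, over exactly
#' the classes present there (positions the infant never exhibited, e.g.
#' upright for a pre-standing infant, are simply absent from the model).
#'
#' @param ft labelled training [FeatureTable-class].
#' @param spec a [modelSpec()].
#' @return A [PositionModel-class].
#' @export
trainIndividual <- function(ft, spec = modelSpec()) {
  lab <- windowLabels(ft)
  keep <- !is.na(lab)
  lab <- lab[keep]
  classes <- sort(unique(lab))
  if (length(classes) < 2L)
    stop(sprintf("degenerate model: training data contain %d class(es)",
                 length(classes)))
  fit <- .fitForest(featureValues(ft)[keep, , drop = FALSE], lab, spec)
  spec$mtry <- fit$mtry
  methods::new("PositionModel", forest = fit$forest, backend = "ranger",
               registryHash = registryHash(ft), classes = classes,
               spec = spec,
               trainingSummary = as.data.frame(table(class = lab),
                                               responseName = "nWindows"))
}

#' Leave-one-subject-out group models
#'
#' For each participant, fits a forest on the full sessions of all the
#' others and predicts the held-out participant's windows. This regime
#' tests generalization to an infant for whom no video-coded training data
#' exist.
#'
#' @param tables named list of per-participant labelled
#'   [FeatureTable-class] objects.
#' @param spec a [modelSpec()].
#' @return Named list, one element per held-out participant:
#'   `model`, `predicted`, `actual`, `starts`.
#' @export
trainGroupLoso <- function(tables, spec = modelSpec()) {
  if (length(tables) < 2L)
    stop("leave-one-subject-out needs at least 2 participants")
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(x) x@participant, "")
  out <- vector("list", length(tables))
  names(out) <- names(tables)
  for (p in names(tables)) {
    train <- bindFeatureTables(tables[names(tables) != p])
    model <- trainIndividual(train, spec)
    held <- tables[[p]]
    out[[p]] <- list(model = model,
                     predicted = predictPositions(model, held),
                     actual = windowLabels(held),
                     starts = windowStarts(held))
  }
  out
}

#' Predict window body positions
#'
#' Applies a trained model to a feature table, one label per row. The
#' model refuses tables produced under a different feature registry.
#'
#' @param model a [PositionModel-class].
#' @param ft a [FeatureTable-class].
#' @param voteFractions if `TRUE`, also return the per-class vote matrix.
#' @return Character vector of predicted labels (with the vote matrix as
#'   attribute `"votes"` when requested).
#' @export
predictPositions <- function(model, ft, voteFractions = FALSE) {
  if (!identical(registryHash(model), registryHash(ft)))
    stop("registry hash mismatch: features were not produced by the model's registry")
  if (!length(ft)) return(character(0))
  d <- as.data.frame(featureValues(ft))
  names(d) <- make.names(names(d))
  pred <- stats::predict(model@forest, data = d, num.threads = 1L,
                         seed = model@spec$seed)
  out <- as.character(pred$predictions)
  if (voteFractions) {
    pv <- stats::predict(model@forest, data = d, num.threads = 1L,
                         predict.all = TRUE, seed = model@spec$seed)$predictions
    votes <- t(apply(pv, 1, function(v)
      tabulate(v, nbins = length(model@forest$forest$levels))))
    colnames(votes) <- model@forest$forest$levels
    attr(out, "votes") <- votes / model@spec$ntree
  }
  out
}
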