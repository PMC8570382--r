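# End-to-end validation on simulated cohorts: the full chain
# simulate -> sync -> window -> featurize -> train -> predict -> evaluate,
# in both modelling regimes, against known ground truth.

#' Run the two-regime validation on a simulated cohort
#'
#' Simulates `n` participants (guided activities + free play, default noise,
#' per-participant orientation jitter), pushes every session through
#' synchronization, windowing, feature extraction, then:
#' \itemize{
#'   \item individual regime: per participant, chronological 60/40
#'     within-class split, model on the training part, evaluation on the
#'     held-out part;
#'   \item group regime (optional): leave-one-subject-out models over the
#'     participants' full sessions, evaluated on each held-out participant.
#' }
#'
#' @param seed master seed for cohort simulation and model fits.
#' @param n cohort size (default 15).
#' @param ntree trees per forest (default 750).
#' @param loso also run the leave-one-subject-out regime (default `TRUE`).
#' @param trainFrac chronological training fraction (default 0.6).
#' @param jitterAngleDeg per-participant placement jitter (default 10).
#' @param ... passed to [simulateCohort()] (e.g. a shorter `schedule`).
#' @return List with:
#'   \item{individual}{data.frame of per-participant accuracy and kappa.}
#'   \item{individualPooled}{[EvaluationReport-class] over all pooled
#'     individual test windows.}
#'   \item{prevalence}{list with participant x class `actual` and
#'     `predicted` prevalence matrices (proportions over each test set).}
#'   \item{group}{data.frame of per-participant LOSO accuracy and kappa
#'     (when `loso`).}
#' @export
cohortValidation <- function(seed, n = 15, ntree = 750, loso = TRUE,
                             trainFrac = 0.6, jitterAngleDeg = 10, ...) {
  coh <- simulateCohort(n = n, seed = seed, jitterAngleDeg = jitterAngleDeg,
                        reliability = TRUE, ...)
  registry <- featureRegistry("lab3")
  tables <- list()
  indiv <- data.frame(participant = names(coh), accuracy = NA_real_,
                      kappa = NA_real_)
  actualAll <- character(0); predAll <- character(0)
  classes <- positionClasses()
  prevA <- prevP <- matrix(NA_real_, n, length(classes),
                           dimnames = list(names(coh), classes))
  for (i in seq_along(coh)) {
    ps <- processSession(coh[[i]], registry)
    tables[[names(coh)[i]]] <- ps$features
    sp <- suppressWarnings(chronologicalSplit(ps$features, trainFrac))
    model <- trainIndividual(sp$train, modelSpec(ntree = ntree, seed = seed))
    pred <- predictPositions(model, sp$test)
    act <- windowLabels(sp$test)
    rep <- evaluatePredictions(act, pred)
    indiv$accuracy[i] <- rep@accuracy
    indiv$kappa[i] <- rep@kappa
    actualAll <- c(actualAll, act); predAll <- c(predAll, pred)
    prevA[i, ] <- prop.table(table(factor(act, classes)))
    prevP[i, ] <- prop.table(table(factor(pred, classes)))
  }
  out <- list(individual = indiv,
              individualPooled = evaluatePredictions(actualAll, predAll),
              prevalence = list(actual = prevA, predicted = prevP))
  if (loso) {
    res <- trainGroupLoso(tables, modelSpec(ntree = ntree, seed = seed))
    out$group <- data.frame(
      participant = names(res),
      accuracy = vapply(res, function(r) mean(r$predicted == r$actual), 0),
      kappa = vapply(res, function(r) cohenKappa(r$actual, r$predicted), 0),
      row.names = NULL)
  }
  out
}

#' Reanalyse the published per-participant validation table
#'
#' From the bundled per-participant accuracy/kappa table of the original
#' validation study ([labValidationResults()]): mean accuracy and kappa
#' under both regimes, Landis-Koch bin counts of the per-participant
#' kappas, and the paired individual-vs-group t-tests.
#'
#' @return List: `means` (accuracy/kappa x individual/group),
#'   `binsIndividual`, `binsGroup` (named bin counts), `tKappa`,
#'   `tAccuracy` (paired-t reports, see [compareModelTypes()]).
#' @export
labValidationReanalysis <- function() {
  tab <- labValidationResults()
  bins <- function(k) table(factor(landisKochBin(k),
    c("Almost Perfect", "Substantial", "Moderate", "Fair", "Slight to Poor")))
  list(means = data.frame(
         metric = c("accuracy", "kappa"),
         individual = c(mean(tab$accuracy_individual),
                        mean(tab$kappa_individual)),
         group = c(mean(tab$accuracy_group), mean(tab$kappa_group))),
       binsIndividual = bins(tab$kappa_individual),
       binsGroup = bins(tab$kappa_group),
       tKappa = compareModelTypes(tab$kappa_individual, tab$kappa_group),
       tAccuracy = compareModelTypes(tab$accuracy_individual,
                                     tab$accuracy_group))
}
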