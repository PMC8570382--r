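# Validation metrics: confusion matrix, accuracy, Cohen's kappa with
# Landis-Koch interpretation, per-class sensitivity/PPV/prevalence,
# prevalence correlations and the paired individual-vs-group comparison.

#' Confusion matrix of actual vs predicted labels
#'
#' @param actual,predicted equal-length character vectors.
#' @param classes class order; default = sorted union.
#' @return Square count matrix, rows = actual, columns = predicted.
#' @export
confusionCounts <- function(actual, predicted,
                            classes = sort(union(actual, predicted))) {
  table(factor(actual, classes), factor(predicted, classes),
        dnn = c("actual", "predicted")) |> unclass()
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po` and expected agreement `pe` from the marginal products.
#'
#' @param actual,predicted equal-length, non-empty label vectors.
#' @return Numeric kappa.
#' @export
cohenKappa <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) > 0)
  cm <- confusionCounts(actual, predicted)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    stop("undefined kappa: expected agreement is 1 (both sequences constant)")
  (po - pe) / (1 - pe)
}

#' Per-class sensitivity, PPV and prevalence from a confusion matrix
#'
#' Sensitivity (recall) is the proportion of actual occurrences of a class
#' that were correctly predicted; positive predictive value (precision) is
#' the proportion of predictions of a class that were correct. A class never
#' predicted has undefined PPV, reported as `NA` (not 0) so that averages
#' are taken over defined values only. Prevalence is the percent of actual
#' windows in each class (sums to 100 over observed classes).
#'
#' @param confusion square count matrix, rows = actual.
#' @return data.frame: `class`, `prevalence`, `sensitivity`, `ppv`.
#' @export
classMetrics <- function(confusion) {
  act <- rowSums(confusion)
  pred <- colSums(confusion)
  tp <- diag(confusion)
  data.frame(class = rownames(confusion),
             prevalence = 100 * act / sum(act),
             sensitivity = ifelse(act > 0, tp / act, NA_real_),
             ppv = ifelse(pred > 0, tp / pred, NA_real_),
             row.names = NULL)
}

#' Evaluate predictions against human-coded ground truth
#'
#' @param actual,predicted equal-length label vectors.
#' @return An [EvaluationReport-class].
#' @export
evaluatePredictions <- function(actual, predicted) {
  cm <- confusionCounts(actual, predicted)
  methods::new("EvaluationReport", confusion = cm,
               accuracy = sum(diag(cm)) / sum(cm),
               kappa = cohenKappa(actual, predicted),
               perClass = classMetrics(cm), nWindows = sum(cm))
}

#' Landis-Koch verbal interpretation of kappa
#'
#' Kappa is rounded to 2 decimals, then binned: 0.81-1.00 Almost Perfect,
#' 0.61-0.80 Substantial, 0.41-0.60 Moderate, 0.21-0.40 Fair, and at or
#' below 0.20 (including negative values) Slight to Poor.
#'
#' @param kappa numeric vector.
#' @return Character vector of bins.
#' @examples
#' landisKochBin(c(0.70, 0.82, 0.805))
#' @export
landisKochBin <- function(kappa) {
  # decimal half-up rounding to 2 places (an epsilon guards against binary
  # representations just under the .xx5 boundary, so 0.805 -> 0.81)
  k <- sign(kappa) * trunc(abs(kappa) * 100 + 0.5 + 1e-9) / 100
  cut(k, breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
      labels = c("Slight to Poor", "Fair", "Moderate", "Substantial",
                 "Almost Perfect")) |> as.character()
}

#' Actual-vs-predicted prevalence correlations
#'
#' Pearson correlations between actual and predicted class prevalences over
#' observation units (participants, or fixed-length time intervals within a
#' session). Returns a per-class r plus the pooled r over all class x unit
#' pairs. Classes with zero variance in either vector get `NA` with a
#' warning.
#'
#' @param actual,predicted numeric unit x class matrices of proportions
#'   (same dimnames), e.g. from [prevalenceByInterval()].
#' @return List: `perClass` (named numeric), `pooled` (numeric), `n` units.
#' @export
prevalenceCorrelation <- function(actual, predicted) {
  stopifnot(identical(dim(actual), dim(predicted)))
  if (nrow(actual) < 3L)
    stop("need at least 3 paired prevalence observations")
  perClass <- vapply(colnames(actual), function(cl) {
    x <- actual[, cl]; y <- predicted[, cl]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("zero prevalence variance for class '%s'; r undefined",
                      cl))
      return(NA_real_)
    }
    stats::cor(x, y)
  }, 0)
  list(perClass = perClass,
       pooled = stats::cor(as.vector(actual), as.vector(predicted)),
       n = nrow(actual))
}

#' Per-interval class prevalence from window labels
#'
#' Partitions the session timeline into fixed-length intervals (default
#' 7.5 min) and computes, within each interval, the proportion of labelled
#' windows in each class.
#'
#' @param starts numeric window start times (s).
#' @param labels window labels (`NA` ignored).
#' @param intervalSec interval length in seconds (default 450).
#' @param classes class order (default [positionClasses()]).
#' @return interval x class proportion matrix (intervals without labelled
#'   windows are dropped).
#' @export
prevalenceByInterval <- function(starts, labels, intervalSec = 450,
                                 classes = positionClasses()) {
  keep <- !is.na(labels)
  starts <- starts[keep]; labels <- labels[keep]
  bin <- floor(starts / intervalSec)
  tab <- table(factor(bin), factor(labels, classes))
  tot <- rowSums(tab)
  m <- unclass(tab / ifelse(tot == 0, 1, tot))
  m[tot > 0, , drop = FALSE]
}

#' Paired comparison of individual vs group models
#'
#' Two-sided paired t-test on a per-participant metric (accuracy or kappa)
#' under the two modelling regimes, reported with df = n - 1 and the two
#' means/SDs.
#'
#' @param individual,group equal-length numeric vectors, one value per
#'   participant.
#' @return List: `t`, `df`, `p`, `means` (2, rounded to 2 decimals), `sds`.
#' @export
compareModelTypes <- function(individual, group) {
  stopifnot(length(individual) == length(group), length(individual) >= 2)
  d <- individual - group
  if (stats::sd(d) == 0)
    stop("undefined t: zero variance of paired differences")
  tt <- stats::t.test(individual, group, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       means = round(c(individual = mean(individual), group = mean(group)), 2),
       sds = c(individual = stats::sd(individual), group = stats::sd(group)))
}

#' Full-day predicted body-position timeline
#'
#' Merges consecutive same-label windows into episodes, renders removal-log
#' intervals as gaps, and reports the percent of classified time per class.
#'
#' @param starts numeric window start times (s).
#' @param labels predicted window labels (`NA` = unclassified gap).
#' @param stepSec window step in seconds (each window contributes one step
#'   of timeline).
#' @param removalLog optional [RemovalLog-class]; windows starting inside a
#'   logged interval become gaps.
#' @return List: `episodes` (data.frame start, end, label) and `totals`
#'   (named percent of classified time; sums to 100).
#' @export
timelineReport <- function(starts, labels, stepSec = 1, removalLog = NULL) {
  if (!is.null(removalLog) && nrow(removalLog@intervals)) {
    iv <- removalLog@intervals
    i <- findInterval(starts, iv$start)
    hit <- i > 0L
    hit[hit] <- starts[hit] < iv$end[i[hit]]
    labels[hit] <- NA_character_
  }
  o <- order(starts)
  starts <- starts[o]; labels <- labels[o]
  lab <- ifelse(is.na(labels), ".gap", labels)
  contiguous <- c(TRUE, diff(starts) > stepSec + 1e-9)
  runId <- cumsum(contiguous | c(TRUE, lab[-1] != lab[-length(lab)]))
  ep <- data.frame(
    start = tapply(starts, runId, min),
    end = tapply(starts, runId, max) + stepSec,
    label = tapply(lab, runId, `[`, 1L), row.names = NULL)
  ep <- ep[ep$label != ".gap", , drop = FALSE]
  rownames(ep) <- NULL
  dur <- tapply(ep$end - ep$start, ep$label, sum)
  totals <- 100 * dur / sum(dur)
  list(episodes = ep, totals = totals[order(-totals)])
}
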