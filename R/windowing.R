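# Overlapping fixed-length windows over the aligned recording, with the
# 3-of-4-s majority labelling rule.

#' Assign a window's label by the majority-coverage rule
#'
#' A window receives a class label only if that class occupies at least
#' `minCoverage` of its samples (3 s of a 4-s window at the default 0.75).
#' Uncoded (`"none"`) samples never count toward any class, so windows over
#' transitions or mixes of two positions are excluded rather than
#' mislabelled.
#'
#' @param labels character label sequence of full window length.
#' @param minCoverage required fraction of window samples (default 0.75).
#' @return The winning class, or `NA_character_` when no class reaches
#'   coverage.
#' @examples
#' assignWindowLabel(rep(c("sitting", "none"), c(160, 40)))   # "sitting"
#' assignWindowLabel(rep(c("sitting", "prone"), c(100, 100))) # NA
#' @export
assignWindowLabel <- function(labels, minCoverage = 0.75) {
  coded <- labels[labels != "none"]
  if (!length(coded)) return(NA_character_)
  tab <- table(coded)
  top <- which.max(tab)
  if (tab[top] >= minCoverage * length(labels)) names(tab)[top]
  else NA_character_
}

#' Extract overlapping labelled windows from an aligned recording
#'
#' Windows of `windowSec` seconds are taken every `stepSec` seconds,
#' anchored at the grid start (the opening sync event, t = 0), for as long
#' as a full window fits. Each window is labelled by
#' [assignWindowLabel()]; windows containing any invalid sample (unbridged
#' dropout) are excluded with reason `invalid_samples`.
#'
#' @param aligned an [AlignedRecording-class].
#' @param windowSec window length in seconds (default 4).
#' @param stepSec step in seconds (default 1); must satisfy
#'   `windowSec >= stepSec > 0`.
#' @param minCoverage majority-rule coverage fraction (default 0.75).
#' @return A [WindowSet-class] (empty, with a warning, if the recording is
#'   shorter than one window).
#' @export
extractWindows <- function(aligned, windowSec = 4, stepSec = 1,
                           minCoverage = 0.75) {
  stopifnot(windowSec >= stepSec, stepSec > 0)
  rate <- aligned@rate
  wlen <- as.integer(round(windowSec * rate))
  step <- as.integer(round(stepSec * rate))
  n <- nSamples(aligned)
  if (n < wlen) {
    warning(sprintf("recording (%d samples) shorter than one window (%d)",
                    n, wlen))
    starts <- integer(0)
  } else {
    starts <- seq.int(1L, n - wlen + 1L, by = step)
  }
  k <- length(starts)
  lab <- rep(NA_character_, k)
  reason <- rep("none", k)
  for (j in seq_len(k)) {
    idx <- starts[j]:(starts[j] + wlen - 1L)
    if (!all(aligned@valid[idx])) {
      reason[j] <- "invalid_samples"
    } else {
      lab[j] <- assignWindowLabel(aligned@labelPrimary[idx], minCoverage)
      if (is.na(lab[j])) reason[j] <- "no_majority"
    }
  }
  methods::new("WindowSet", aligned = aligned, startIdx = starts,
               startTime = aligned@time[starts], windowLen = wlen,
               label = lab, excludedReason = reason, windowSec = windowSec,
               stepSec = stepSec, minCoverage = minCoverage)
}

#' Exclude windows overlapping coder disagreement
#'
#' Any window containing at least one sample where the primary and
#' reliability coders disagreed becomes `excluded(coder_disagreement)`, so
#' only unambiguous events are used for training. By default this is a
#' training-set view; evaluation keeps all labelled windows unless the same
#' mask is applied there too.
#'
#' @param windows a [WindowSet-class].
#' @param mask per-grid-sample logical disagreement mask (see
#'   [disagreementMask()]).
#' @return The window set with disagreeing windows excluded.
#' @export
applyDisagreementExclusion <- function(windows, mask) {
  if (length(mask) != nSamples(windows@aligned))
    stop("mask length must equal the aligned grid length")
  for (j in seq_along(windows@startIdx)) {
    if (windows@excludedReason[j] != "none") next
    idx <- windows@startIdx[j]:(windows@startIdx[j] + windows@windowLen - 1L)
    if (any(mask[idx])) {
      windows@label[j] <- NA_character_
      windows@excludedReason[j] <- "coder_disagreement"
    }
  }
  methods::validObject(windows)
  windows
}

#' Keep only the labelled (non-excluded) windows
#'
#' @param windows a [WindowSet-class].
#' @return Integer indices of assignable windows.
#' @export
assignedWindows <- function(windows) which(windows@excludedReason == "none")
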