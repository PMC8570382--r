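#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn SensorStream placement accessor
#' @param x object.
#' @export
setMethod("placement", "SensorStream", function(x) x@placement)

#' @describeIn SensorStream nominal rate (Hz)
#' @export
setMethod("samplingRate", "SensorStream", function(x) x@rate)

#' @describeIn AlignedRecording grid rate (Hz)
#' @export
setMethod("samplingRate", "AlignedRecording", function(x) x@rate)

#' @describeIn SensorStream number of samples
#' @export
setMethod("nSamples", "SensorStream", function(x) length(x@time))

#' @describeIn AlignedRecording number of grid samples
#' @export
setMethod("nSamples", "AlignedRecording", function(x) length(x@time))

#' @describeIn SensorStream accelerometer matrix (g)
#' @export
setMethod("accel", "SensorStream", function(x) x@accel)

#' @describeIn SensorStream gyroscope matrix (deg/s)
#' @export
setMethod("gyro", "SensorStream", function(x) x@gyro)

#' @describeIn SensorStream timestamps (s)
#' @export
setMethod("timestamps", "SensorStream", function(x) x@time)

#' @describeIn AlignedRecording grid timestamps (s)
#' @export
setMethod("timestamps", "AlignedRecording", function(x) x@time)

#' @describeIn SensorStream validity flags
#' @export
setMethod("validSamples", "SensorStream", function(x) x@valid)

#' @describeIn AlignedRecording validity flags
#' @export
setMethod("validSamples", "AlignedRecording", function(x) x@valid)

#' @describeIn AnnotationTrack events accessor
#' @param x object.
#' @export
setMethod("events", "AnnotationTrack", function(x) x@events)

#' @describeIn AlignedRecording per-sample coded labels
#' @param which `"primary"` or `"reliability"`.
#' @export
setMethod("positionLabels", "AlignedRecording", function(x, which = "primary") {
  if (which == "primary") return(x@labelPrimary)
  if (!length(x@labelReliability))
    stop("no reliability-coder labels attached")
  x@labelReliability
})

#' @describeIn WindowSet assigned labels (`NA` when excluded)
#' @export
setMethod("windowLabels", "WindowSet", function(x) x@label)

#' @describeIn FeatureTable window labels
#' @export
setMethod("windowLabels", "FeatureTable", function(x) x@label)

#' @describeIn WindowSet window start times (s)
#' @export
setMethod("windowStarts", "WindowSet", function(x) x@startTime)

#' @describeIn FeatureTable window start times (s)
#' @export
setMethod("windowStarts", "FeatureTable", function(x) x@windowStart)

#' @describeIn FeatureRegistry registry hash
#' @export
setMethod("registryHash", "FeatureRegistry", function(x) x@hash)

#' @describeIn FeatureTable producing-registry hash
#' @export
setMethod("registryHash", "FeatureTable", function(x) x@registryHash)

#' @describeIn PositionModel training-registry hash
#' @export
setMethod("registryHash", "PositionModel", function(x) x@registryHash)

#' @describeIn FeatureTable feature matrix
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)

#' @describeIn PositionModel classes the model can predict
#' @export
setMethod("modelClasses", "PositionModel", function(x) x@classes)

#' @describeIn EvaluationReport classes in the confusion matrix
#' @export
setMethod("modelClasses", "EvaluationReport",
          function(x) rownames(x@confusion))

#' Number of feature-table rows
#' @param x a [FeatureTable-class].
#' @export
setMethod("length", "FeatureTable", function(x) nrow(x@values))

#' Number of windows
#' @param x a [WindowSet-class].
#' @export
setMethod("length", "WindowSet", function(x) length(x@startIdx))

#' Subset a feature table by row
#'
#' @param x a [FeatureTable-class].
#' @param i row index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  methods::new("FeatureTable", values = x@values[i, , drop = FALSE],
               windowStart = x@windowStart[i], label = x@label[i],
               registryHash = x@registryHash, participant = x@participant)
})

setMethod("show", "SensorStream", function(object) {
  cat(sprintf("SensorStream '%s': %d samples @ %g Hz, %.1f-%.1f s (%d invalid)\n",
              object@placement, nSamples(object), object@rate,
              if (nSamples(object)) min(object@time) else NA,
              if (nSamples(object)) max(object@time) else NA,
              sum(!object@valid)))
})

setMethod("show", "SensorRecording", function(object) {
  cat(sprintf("SensorRecording '%s' (%s): %d sensors [%s]\n",
              object@sessionId, object@profile, length(object@sensors),
              paste(names(object@sensors), collapse = ", ")))
})

setMethod("show", "AnnotationTrack", function(object) {
  ev <- object@events
  cat(sprintf("AnnotationTrack coder '%s' (%s time): %d events, %.1f s coded\n",
              object@coder, object@timeBase, nrow(ev),
              sum(ev$offset - ev$onset)))
})

setMethod("show", "AlignedRecording", function(object) {
  coded <- mean(object@labelPrimary != "none")
  cat(sprintf(
    "AlignedRecording: %d samples @ %g Hz (%.1f s), %d placements, %.0f%% coded%s\n",
    nSamples(object), object@rate,
    if (nSamples(object)) diff(range(object@time)) else 0,
    length(object@placements), 100 * coded,
    if (length(object@labelReliability)) ", dual-coded" else ""))
})

setMethod("show", "WindowSet", function(object) {
  tab <- table(factor(object@excludedReason,
                      c("none", "no_majority", "coder_disagreement",
                        "invalid_samples")))
  cat(sprintf("WindowSet: %d windows of %.3g s every %.3g s (%d samples each)\n",
              length(object), object@windowSec, object@stepSec,
              object@windowLen))
  cat(sprintf("  assigned %d | no_majority %d | coder_disagreement %d | invalid %d\n",
              tab[1], tab[2], tab[3], tab[4]))
})

setMethod("show", "FeatureRegistry", function(object) {
  cat(sprintf("FeatureRegistry '%s': %d features (%d base) over %d placements [%s]\n",
              object@profile, nrow(object@entries),
              sum(object@entries$kind == "base_stat"),
              length(object@placements), substr(object@hash, 1, 8)))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable '%s': %d windows x %d features [%s]\n",
              object@participant, nrow(object@values), ncol(object@values),
              substr(object@registryHash, 1, 8)))
})

setMethod("show", "PositionModel", function(object) {
  cat(sprintf("PositionModel (%s): %d trees, mtry %d, classes [%s]\n",
              object@backend, object@spec$ntree, object@spec$mtry,
              paste(object@classes, collapse = ", ")))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d windows, accuracy %.3f, kappa %.3f (%s)\n",
              object@nWindows, object@accuracy, object@kappa,
              landisKochBin(object@kappa)))
  pc <- object@perClass
  pc[-1] <- round(pc[-1], 3)
  print(pc)
})
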