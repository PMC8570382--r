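#' @include AllClasses.R
NULL

#' Placement label of a sensor stream
#'
#' @param x a [SensorStream-class] object.
#' @return Character scalar, e.g. `"right_hip"`.
#' @export
setGeneric("placement", function(x) standardGeneric("placement"))

#' Sampling rate accessor
#'
#' @param x a sensor-bearing object.
#' @return Numeric scalar in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Number of samples
#'
#' @param x a sensor-bearing object.
#' @return Integer count of samples.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Accelerometer matrix accessor
#'
#' @param x a [SensorStream-class].
#' @return n x 3 numeric matrix in g units (columns x, y, z).
#' @export
setGeneric("accel", function(x) standardGeneric("accel"))

#' Gyroscope matrix accessor
#'
#' @param x a [SensorStream-class].
#' @return n x 3 numeric matrix in deg/s (columns roll, pitch, yaw).
#' @export
setGeneric("gyro", function(x) standardGeneric("gyro"))

#' Timestamp accessor
#'
#' @param x a sensor-bearing object.
#' @return Numeric vector of timestamps in seconds.
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' Valid-sample flags
#'
#' @param x a sensor-bearing object.
#' @return Logical vector; `FALSE` marks samples inside unbridgeable gaps.
#' @export
setGeneric("validSamples", function(x) standardGeneric("validSamples"))

#' Annotation events accessor
#'
#' @param x an [AnnotationTrack-class].
#' @return data.frame with columns `onset`, `offset`, `label` (seconds,
#'   half-open intervals).
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Per-sample position labels of an aligned recording
#'
#' @param x an [AlignedRecording-class].
#' @param which `"primary"` or `"reliability"`.
#' @return Character vector of position labels (`"none"` where uncoded).
#' @export
setGeneric("positionLabels", function(x, which = "primary")
  standardGeneric("positionLabels"))

#' Window labels accessor
#'
#' @param x a [WindowSet-class] or [FeatureTable-class].
#' @return Character vector of assigned labels (`NA` for excluded windows of a
#'   `WindowSet`).
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' Window start times
#'
#' @param x a [WindowSet-class] or [FeatureTable-class].
#' @return Numeric vector of window start times (s, aligned clock).
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' Feature-registry hash
#'
#' @param x a [FeatureRegistry-class], [FeatureTable-class] or
#'   [PositionModel-class].
#' @return Character scalar identifying the registry that produced/consumes the
#'   features.
#' @export
setGeneric("registryHash", function(x) standardGeneric("registryHash"))

#' Feature values matrix
#'
#' @param x a [FeatureTable-class].
#' @return Numeric matrix, one row per window, columns named by the registry.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Classes known to a trained model
#'
#' @param x a [PositionModel-class] or [EvaluationReport-class].
#' @return Character vector of body-position classes.
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))
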