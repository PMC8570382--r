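# Central S4 containers for the body-position measurement pipeline.

#' Body-position vocabulary
#'
#' The five mutually exclusive body-position classes plus the sentinel
#' `"none"`, which marks uncoded spans (transitions, sensor-off periods,
#' removal-log masks). `"none"` is never a trainable class.
#'
#' @return `positionClasses()` returns the five trainable classes;
#'   `positionVocabulary()` additionally includes `"none"`.
#' @examples
#' positionClasses()
#' @export
positionClasses <- function() c("supine", "prone", "sitting", "upright", "held")

#' @rdname positionClasses
#' @export
positionVocabulary <- function() c(positionClasses(), "none")

.validPlacements <- c("right_hip", "right_thigh", "right_ankle",
                      "left_hip", "left_thigh", "left_ankle")

#' SensorStream: one placement's 6-channel IMU timeseries
#'
#' Timestamped tri-axial accelerometer (g units) and gyroscope (deg/s)
#' samples from a single sensor placement. Timestamps are seconds on the
#' device clock, relative to file start; they must be strictly increasing
#' after cleaning. Accelerometer and gyroscope blocks always have the same
#' length.
#'
#' @slot placement character; one of right/left hip, thigh, ankle.
#' @slot time numeric; strictly increasing timestamps (s).
#' @slot accel n x 3 numeric matrix, g units, columns x/y/z.
#' @slot gyro n x 3 numeric matrix, deg/s, columns roll/pitch/yaw.
#' @slot rate numeric; nominal sampling rate in Hz (50 lab, 62.5 home, any
#'   positive value accepted).
#' @slot valid logical; per-sample validity (FALSE inside unbridged gaps
#'   after resampling).
#' @export
setClass("SensorStream",
  representation(placement = "character", time = "numeric",
                 accel = "matrix", gyro = "matrix",
                 rate = "numeric", valid = "logical"))

setValidity("SensorStream", function(object) {
  n <- length(object@time)
  if (nrow(object@accel) != n || nrow(object@gyro) != n)
    return("accel and gyro must have one row per timestamp")
  if (ncol(object@accel) != 3L || ncol(object@gyro) != 3L)
    return("accel and gyro must have 3 columns")
  if (length(object@valid) != n)
    return("valid flag must have one entry per sample")
  if (n > 1L && any(diff(object@time) <= 0))
    return("timestamps must be strictly increasing")
  if (length(object@rate) != 1L || object@rate <= 0)
    return("rate must be a positive scalar")
  if (!object@placement %in% .validPlacements)
    return(sprintf("unknown placement '%s'", object@placement))
  TRUE
})

#' Construct a SensorStream
#'
#' @param placement sensor placement name.
#' @param time numeric timestamps (s).
#' @param accel,gyro n x 3 matrices (g, deg/s).
#' @param rate nominal rate (Hz). If `NULL`, detected from the median
#'   timestamp spacing and snapped to 50 or 62.5 Hz when within 2%.
#' @param valid optional logical validity flags (default all `TRUE`).
#' @return A [SensorStream-class] object.
#' @export
SensorStream <- function(placement, time, accel, gyro, rate = NULL,
                         valid = rep(TRUE, length(time))) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  dimnames(accel) <- list(NULL, c("x", "y", "z"))
  dimnames(gyro) <- list(NULL, c("roll", "pitch", "yaw"))
  if (is.null(rate)) rate <- detectNominalRate(time)
  methods::new("SensorStream", placement = placement, time = as.numeric(time),
               accel = accel, gyro = gyro, rate = rate, valid = valid)
}

#' SensorRecording: a session's set of sensor streams
#'
#' @slot sensors named list of [SensorStream-class], names = placements.
#' @slot sessionId character session identifier.
#' @slot profile character; `"lab3"` (right hip/thigh/ankle), `"home4"`
#'   (both hips and ankles) or `"custom"`.
#' @export
setClass("SensorRecording",
  representation(sensors = "list", sessionId = "character",
                 profile = "character"))

setValidity("SensorRecording", function(object) {
  if (!length(object@sensors)) return("at least one sensor required")
  if (!all(vapply(object@sensors, methods::is, TRUE, "SensorStream")))
    return("all sensors must be SensorStream objects")
  pl <- vapply(object@sensors, placement, "")
  if (anyDuplicated(pl)) return("placements must be unique")
  if (!identical(unname(pl), names(object@sensors)))
    return("sensor list names must equal placements")
  rates <- vapply(object@sensors, samplingRate, 0)
  if (length(unique(rates)) != 1L)
    return("all member streams must share one nominal rate")
  TRUE
})

#' Construct a SensorRecording
#'
#' @param sensors list of [SensorStream-class] objects.
#' @param sessionId session identifier.
#' @param profile placement profile (`"lab3"`, `"home4"`, `"custom"`).
#' @return A [SensorRecording-class].
#' @export
SensorRecording <- function(sensors, sessionId = "session",
                            profile = c("custom", "lab3", "home4")) {
  profile <- match.arg(profile)
  names(sensors) <- vapply(sensors, placement, "")
  methods::new("SensorRecording", sensors = sensors, sessionId = sessionId,
               profile = profile)
}

#' AnnotationTrack: interval-coded body-position events from one coder
#'
#' Events are half-open intervals `[onset, offset)` in seconds,
#' non-overlapping, with gaps allowed (uncoded time). Labels come from
#' [positionVocabulary()].
#'
#' @slot coder character coder identifier.
#' @slot events data.frame with numeric `onset`, `offset` and character
#'   `label`.
#' @slot timeBase `"video"` or `"sensor"` -- which clock the onsets refer to.
#' @export
setClass("AnnotationTrack",
  representation(coder = "character", events = "data.frame",
                 timeBase = "character"))

setValidity("AnnotationTrack", function(object) {
  ev <- object@events
  if (!all(c("onset", "offset", "label") %in% names(ev)))
    return("events need onset, offset, label columns")
  if (nrow(ev)) {
    if (any(ev$offset <= ev$onset)) return("each offset must exceed its onset")
    o <- order(ev$onset)
    if (any(ev$onset[o][-1] < ev$offset[o][-nrow(ev)]))
      return("events must not overlap")
    if (!all(ev$label %in% positionVocabulary()))
      return("labels must be in the position vocabulary")
  }
  if (!object@timeBase %in% c("video", "sensor"))
    return("timeBase must be 'video' or 'sensor'")
  TRUE
})

#' Construct an AnnotationTrack
#'
#' @param events data.frame with `onset`, `offset` (s) and `label`.
#' @param coder coder id.
#' @param timeBase `"video"` (raw coding) or `"sensor"` (post-sync).
#' @return An [AnnotationTrack-class]; events sorted by onset.
#' @export
AnnotationTrack <- function(events, coder = "coder1", timeBase = "video") {
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  methods::new("AnnotationTrack", coder = coder, events = events,
               timeBase = timeBase)
}

#' RemovalLog: caregiver-logged sensor-off intervals
#'
#' Intervals (naps, diaper changes, excursions) during which the garment was
#' off and the motion data must be masked from analysis.
#'
#' @slot intervals data.frame with numeric `start`, `end` (s) and character
#'   `reason`.
#' @export
setClass("RemovalLog", representation(intervals = "data.frame"))

setValidity("RemovalLog", function(object) {
  iv <- object@intervals
  if (!all(c("start", "end", "reason") %in% names(iv)))
    return("intervals need start, end, reason columns")
  if (nrow(iv)) {
    if (any(iv$end <= iv$start)) return("each end must exceed its start")
    o <- order(iv$start)
    if (any(iv$start[o][-1] < iv$end[o][-nrow(iv)]))
      return("intervals must not overlap")
  }
  TRUE
})

#' Construct a RemovalLog
#' @param intervals data.frame with `start`, `end` (s), `reason`.
#' @return A [RemovalLog-class].
#' @export
RemovalLog <- function(intervals = data.frame(start = numeric(),
                                              end = numeric(),
                                              reason = character())) {
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  methods::new("RemovalLog", intervals = intervals)
}

#' AlignedRecording: synchronized multi-sensor matrix with per-sample labels
#'
#' All sensors resampled onto one uniform grid on the aligned clock (the
#' opening synchronization impulse is time 0), with the human-coded position
#' label attached to every sample.
#'
#' @slot time uniform grid (s), spacing 1/rate, starting at 0.
#' @slot data numeric matrix, 6 columns per placement, named
#'   `<placement>.<signal>.<axis>`.
#' @slot valid logical per-sample conjunction of the member streams' flags.
#' @slot labelPrimary character per-sample label from the primary coder.
#' @slot labelReliability character; per-sample label from the reliability
#'   coder, or `character(0)` in single-coder mode.
#' @slot rate numeric grid rate (Hz).
#' @slot placements character placement names in column-block order.
#' @export
setClass("AlignedRecording",
  representation(time = "numeric", data = "matrix", valid = "logical",
                 labelPrimary = "character", labelReliability = "character",
                 rate = "numeric", placements = "character"))

setValidity("AlignedRecording", function(object) {
  n <- length(object@time)
  if (nrow(object@data) != n) return("data must have one row per grid sample")
  if (ncol(object@data) != 6L * length(object@placements))
    return("data must have 6 columns per placement")
  if (length(object@valid) != n || length(object@labelPrimary) != n)
    return("valid and labelPrimary must match the grid length")
  if (length(object@labelReliability) &&
      length(object@labelReliability) != n)
    return("labelReliability must be empty or match the grid length")
  if (n > 1L) {
    dt <- diff(object@time)
    if (max(abs(dt - 1 / object@rate)) > 1e-6)
      return("grid spacing must equal 1/rate")
  }
  TRUE
})

#' WindowSet: overlapping fixed-length windows with majority labels
#'
#' Produced by [extractWindows()]. Each window either carries an assigned
#' position label or an exclusion reason (`no_majority`,
#' `coder_disagreement`, `invalid_samples`).
#'
#' @slot aligned the source [AlignedRecording-class].
#' @slot startIdx integer first-sample index of each window.
#' @slot startTime numeric start time (s) of each window.
#' @slot windowLen integer samples per window (200 at 50 Hz, 4-s windows).
#' @slot label character assigned label or `NA` when excluded.
#' @slot excludedReason character; `"none"` when assigned.
#' @slot windowSec,stepSec,minCoverage numeric windowing parameters.
#' @export
setClass("WindowSet",
  representation(aligned = "AlignedRecording", startIdx = "integer",
                 startTime = "numeric", windowLen = "integer",
                 label = "character", excludedReason = "character",
                 windowSec = "numeric", stepSec = "numeric",
                 minCoverage = "numeric"))

setValidity("WindowSet", function(object) {
  k <- length(object@startIdx)
  if (length(object@startTime) != k || length(object@label) != k ||
      length(object@excludedReason) != k)
    return("per-window slots must have equal length")
  bad <- !object@excludedReason %in%
    c("none", "no_majority", "coder_disagreement", "invalid_samples")
  if (any(bad)) return("unknown exclusion reason")
  if (any(is.na(object@label) & object@excludedReason == "none"))
    return("unlabelled windows must carry an exclusion reason")
  TRUE
})

#' FeatureRegistry: the ordered motion-feature catalogue
#'
#' Enumerates every feature the pipeline computes, in a stable order:
#' 10 summary statistics per placement x signal x axis (180 base features for
#' the 3-sensor lab profile), plus cross-sensor and cross-axis sum/magnitude
#' features (24 for lab3; total 204). Optional pairwise correlation and
#' mean-absolute-difference groups are available but disabled by default.
#' The registry hash is stamped into feature tables and trained models so a
#' model can refuse features produced under a different catalogue.
#'
#' @slot entries data.frame: `name`, `kind`, `placement`, `signal`, `axis`,
#'   `statistic`.
#' @slot profile `"lab3"`, `"home4"` or `"custom"`.
#' @slot placements character placements covered.
#' @slot groups character enabled derived-feature groups.
#' @slot hash character registry fingerprint.
#' @export
setClass("FeatureRegistry",
  representation(entries = "data.frame", profile = "character",
                 placements = "character", groups = "character",
                 hash = "character"))

setValidity("FeatureRegistry", function(object) {
  if (anyDuplicated(object@entries$name)) return("feature names must be unique")
  TRUE
})

#' FeatureTable: per-window motion features
#'
#' @slot values numeric matrix, one row per (assignable) window, columns in
#'   registry order.
#' @slot windowStart numeric window start times (s).
#' @slot label character window labels (may be `NA` for prediction-only
#'   tables).
#' @slot registryHash character hash of the producing registry.
#' @slot participant character participant/session id.
#' @export
setClass("FeatureTable",
  representation(values = "matrix", windowStart = "numeric",
                 label = "character", registryHash = "character",
                 participant = "character"))

setValidity("FeatureTable", function(object) {
  if (nrow(object@values) != length(object@windowStart) ||
      nrow(object@values) != length(object@label))
    return("values, windowStart and label must agree in length")
  if (nrow(object@values) && any(!is.finite(object@values)))
    return("all feature values must be finite")
  TRUE
})

#' PositionModel: a trained random-forest body-position classifier
#'
#' @slot forest the fitted forest (opaque backend object).
#' @slot backend character forest backend identifier.
#' @slot registryHash character hash of the feature registry used in
#'   training; prediction refuses tables with a different hash.
#' @slot classes character classes present in training (classes an infant
#'   never exhibited, e.g. upright for a non-stander, are absent).
#' @slot spec list with `ntree`, `mtry`, `seed`.
#' @slot trainingSummary data.frame of per-class training window counts.
#' @export
setClass("PositionModel",
  representation(forest = "ANY", backend = "character",
                 registryHash = "character", classes = "character",
                 spec = "list", trainingSummary = "data.frame"))

#' EvaluationReport: validation metrics for one test set
#'
#' @slot confusion class x class count matrix (rows = actual,
#'   columns = predicted).
#' @slot accuracy overall fraction of windows whose prediction matched the
#'   human-coded position.
#' @slot kappa unweighted Cohen's kappa.
#' @slot perClass data.frame: class, prevalence (%), sensitivity, ppv
#'   (`NA` when the class was never predicted).
#' @slot nWindows number of evaluated windows.
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 kappa = "numeric", perClass = "data.frame",
                 nWindows = "integer"))

setValidity("EvaluationReport", function(object) {
  if (sum(object@confusion) != object@nWindows)
    return("confusion total must equal nWindows")
  TRUE
})
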