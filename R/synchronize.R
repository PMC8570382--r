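# Impulse-based video-to-sensor clock alignment. The sensors are struck
# together (or the garment dropped) in view of the camera; the acceleration
# peak defines time 0 on each sensor's clock and the video-coded strike
# defines time 0 for the annotations.

#' Detect the synchronization impulse in a sensor stream
#'
#' Finds the time of the maximum of `| ||accel|| - 1 g |` within the search
#' interval (at rest the accelerometer magnitude is 1 g; a strike produces a
#' sharp multi-g excursion).
#'
#' @param stream a [SensorStream-class].
#' @param searchInterval numeric `c(start, end)` seconds on the stream's
#'   clock; must lie within the stream span.
#' @param threshold minimum peak prominence in g (default 2). A peak below
#'   it raises a no-impulse error prompting manual entry.
#' @return Numeric time (s) of the impulse on the stream's clock.
#' @export
detectSyncImpulse <- function(stream, searchInterval = range(stream@time),
                              threshold = 2) {
  t <- stream@time
  if (searchInterval[1] < t[1] - 1e-9 ||
      searchInterval[2] > t[length(t)] + 1e-9)
    stop("search interval must lie within the stream span")
  sel <- which(t >= searchInterval[1] & t <= searchInterval[2])
  if (!length(sel)) stop("search interval contains no samples")
  dev <- abs(sqrt(rowSums(stream@accel[sel, , drop = FALSE]^2)) - 1)
  if (max(dev) < threshold)
    stop(sprintf(
      "no impulse: peak deviation %.2f g below threshold %.2f g in [%g, %g] s; supply the time manually",
      max(dev), threshold, searchInterval[1], searchInterval[2]))
  t[sel[which.max(dev)]]
}

#' Align a recording and its annotations onto one synchronized grid
#'
#' Each sensor's clock is shifted so its own opening impulse is time 0
#' (the sensors were struck together, so per-sensor peaks are treated as
#' simultaneous); all sensors are then resampled onto one shared grid
#' starting at 0; annotation tracks are shifted so the video-coded strike is
#' 0 and sampled to per-grid-sample labels.
#'
#' @param recording a [SensorRecording-class].
#' @param sensorEvents named numeric vector: per-placement opening-impulse
#'   time on each sensor's own clock.
#' @param videoEventTime the strike's time on the video clock (s).
#' @param track primary [AnnotationTrack-class] (video time base).
#' @param reliabilityTrack optional second coder's track.
#' @param removalLog optional [RemovalLog-class] (video time base); masked
#'   intervals become `"none"`.
#' @param rate grid rate in Hz (default: the recording's nominal rate).
#' @param maxGap see [resampleUniform()].
#' @return An [AlignedRecording-class].
#' @export
alignSession <- function(recording, sensorEvents, videoEventTime, track,
                         reliabilityTrack = NULL, removalLog = NULL,
                         rate = NULL, maxGap = 0.5) {
  pls <- names(recording@sensors)
  missing <- setdiff(pls, names(sensorEvents))
  if (length(missing))
    stop(sprintf("alignment error: no opening sync event for placement(s) %s",
                 paste(missing, collapse = ", ")))
  if (is.null(rate)) rate <- samplingRate(recording@sensors[[1]])

  shifted <- lapply(pls, function(p) {
    s <- recording@sensors[[p]]
    SensorStream(p, s@time - sensorEvents[[p]], s@accel, s@gyro,
                 rate = s@rate, valid = s@valid)
  })
  tEnd <- min(vapply(shifted, function(s) max(s@time), 0))
  if (tEnd <= 0) stop("alignment error: no common time span after time 0")
  grid <- (0:floor(tEnd * rate + 1e-9)) / rate

  blocks <- vector("list", length(shifted))
  valid <- rep(TRUE, length(grid))
  for (i in seq_along(shifted)) {
    rs <- resampleUniform(shifted[[i]], rate, maxGap = maxGap)
    idx <- round((grid - rs@time[1]) * rate) + 1L
    ok <- idx >= 1L & idx <= nSamples(rs)
    m <- matrix(0, length(grid), 6)
    chan <- cbind(rs@accel, rs@gyro)
    m[ok, ] <- chan[idx[ok], ]
    v <- rep(FALSE, length(grid)); v[ok] <- rs@valid[idx[ok]]
    valid <- valid & v
    colnames(m) <- paste(pls[i], rep(c("accel", "gyro"), each = 3),
                         c("x", "y", "z", "roll", "pitch", "yaw"), sep = ".")
    blocks[[i]] <- m
  }

  tr <- shiftTrack(track, videoEventTime)
  labP <- sampleLabels(tr, grid)
  labR <- character(0)
  if (!is.null(reliabilityTrack))
    labR <- sampleLabels(shiftTrack(reliabilityTrack, videoEventTime), grid)
  if (!is.null(removalLog)) {
    iv <- removalLog@intervals
    iv$start <- iv$start - videoEventTime
    iv$end <- iv$end - videoEventTime
    shiftedLog <- RemovalLog(iv)
    labP <- applyRemovalLog(labP, shiftedLog, grid)
    if (length(labR)) labR <- applyRemovalLog(labR, shiftedLog, grid)
  }

  methods::new("AlignedRecording", time = grid, data = do.call(cbind, blocks),
               valid = valid, labelPrimary = labP, labelReliability = labR,
               rate = rate, placements = pls)
}

#' Verify clock drift against a closing synchronization event
#'
#' For each sensor, drift is the sensor-elapsed time between the opening and
#' closing impulses minus the video-elapsed time between the same two
#' events. Sensors whose absolute drift exceeds the tolerance are flagged;
#' sensors without a closing event are reported `"unverified"`. No
#' correction is applied by default (sub-tolerance drift over a session
#' needs none).
#'
#' @param opening data.frame with columns `placement`, `sensor_time`,
#'   `video_time` for the opening event.
#' @param closing same layout for the closing event, or `NULL`/partial.
#' @param tolerance flag threshold in seconds (default 0.5).
#' @return data.frame: `placement`, `drift_s`, `status` (`"pass"`,
#'   `"flagged"`, `"unverified"`).
#' @export
checkDrift <- function(opening, closing = NULL, tolerance = 0.5) {
  out <- data.frame(placement = opening$placement, drift_s = NA_real_,
                    status = "unverified", stringsAsFactors = FALSE)
  if (!is.null(closing) && nrow(closing)) {
    m <- match(opening$placement, closing$placement)
    has <- !is.na(m)
    drift <- (closing$sensor_time[m[has]] - opening$sensor_time[has]) -
             (closing$video_time[m[has]] - opening$video_time[has])
    out$drift_s[has] <- drift
    out$status[has] <- ifelse(abs(drift) > tolerance, "flagged", "pass")
  }
  out
}
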