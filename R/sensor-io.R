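# Reading, cleaning and resampling of raw per-sensor IMU CSV files.

#' Detect the nominal sampling rate from timestamp spacing
#'
#' Uses the median inter-sample interval; the result snaps to 50 or
#' 62.5 Hz (the two device rates this pipeline was designed around) when
#' within 2% of either.
#'
#' @param time numeric timestamps in seconds.
#' @return Numeric rate in Hz.
#' @export
detectNominalRate <- function(time) {
  if (length(time) < 2L) stop("need at least 2 samples to detect a rate")
  r <- 1 / stats::median(diff(time))
  for (cand in c(50, 62.5)) if (abs(r - cand) / cand <= 0.02) return(cand)
  r
}

#' Read one sensor's raw IMU CSV
#'
#' Reads, validates and cleans a raw per-sensor export. Non-numeric rows are
#' rejected (and counted), rows are sorted by timestamp, duplicate timestamps
#' are collapsed keeping the first occurrence, and timestamps are rebased to
#' seconds relative to the first sample. A per-file QC summary (rows read /
#' dropped) is emitted as a message.
#'
#' Built-in dialects:
#' \describe{
#'   \item{metamotion}{single file, columns `epoch` (ms), `ax,ay,az` (g),
#'     `gx,gy,gz` (deg/s).}
#'   \item{biostamp}{accelerometer and gyroscope exported as two files with
#'     columns `t,x,y,z`; pass the gyroscope file via `gyroPath`. Samples are
#'     merged on timestamp (inner join).}
#'   \item{custom}{explicit `columns` mapping.}
#' }
#'
#' @param path CSV file path (accelerometer file for `"biostamp"`).
#' @param placement sensor placement name.
#' @param dialect one of `"metamotion"`, `"biostamp"`, `"custom"`.
#' @param gyroPath gyroscope CSV for the split-file biostamp dialect.
#' @param timeUnit `"ms"` or `"s"`; default per dialect.
#' @param accelUnit `"g"` or `"ms2"`; m/s^2 exports are divided by 9.81 so
#'   downstream gravity-orientation features are unit-consistent.
#' @param columns named character vector for `"custom"`: names
#'   `time, ax, ay, az, gx, gy, gz` mapped to file column names.
#' @return A [SensorStream-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(epoch = c(0, 20, 40), ax = 0, ay = 0, az = 1,
#'                      gx = 0, gy = 0, gz = 0), f, row.names = FALSE)
#' readSensorCsv(f, "right_hip")
#' @export
readSensorCsv <- function(path, placement,
                          dialect = c("metamotion", "biostamp", "custom"),
                          gyroPath = NULL, timeUnit = NULL,
                          accelUnit = c("g", "ms2"), columns = NULL) {
  dialect <- match.arg(dialect)
  accelUnit <- match.arg(accelUnit)
  if (!file.exists(path)) stop(sprintf("sensor file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) stop(sprintf("empty sensor file: %s", path))

  if (dialect == "metamotion") {
    need <- c("epoch", "ax", "ay", "az", "gx", "gy", "gz")
    if (is.null(timeUnit)) timeUnit <- "ms"
    cols <- stats::setNames(need, c("time", "ax", "ay", "az", "gx", "gy", "gz"))
  } else if (dialect == "biostamp") {
    if (is.null(gyroPath))
      stop("biostamp dialect needs the gyroscope file via gyroPath")
    if (is.null(timeUnit)) timeUnit <- "ms"
    need <- c("t", "x", "y", "z")
    if (!all(need %in% names(raw)))
      stop(sprintf("missing required columns in %s: %s", path,
                   paste(setdiff(need, names(raw)), collapse = ", ")))
    gy <- utils::read.csv(gyroPath, stringsAsFactors = FALSE)
    if (!all(need %in% names(gy)))
      stop(sprintf("missing required columns in %s", gyroPath))
    raw <- merge(raw, gy, by = "t", suffixes = c(".a", ".g"))
    if (!nrow(raw)) stop("no common timestamps between accel and gyro files")
    cols <- c(time = "t", ax = "x.a", ay = "y.a", az = "z.a",
              gx = "x.g", gy = "y.g", gz = "z.g")
    need <- unname(cols)
  } else {
    if (is.null(columns)) stop("custom dialect needs a 'columns' mapping")
    if (is.null(timeUnit)) timeUnit <- "s"
    cols <- columns
    need <- unname(cols)
  }
  if (!all(need %in% names(raw)))
    stop(sprintf("missing required columns in %s: %s", path,
                 paste(setdiff(need, names(raw)), collapse = ", ")))

  nIn <- nrow(raw)
  d <- raw[, cols]
  names(d) <- names(cols)
  d[] <- lapply(d, function(x) suppressWarnings(as.numeric(x)))
  bad <- !stats::complete.cases(d)
  d <- d[!bad, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no numeric rows in sensor file: %s", path))
  d <- d[order(d$time), , drop = FALSE]
  dup <- duplicated(d$time)
  d <- d[!dup, , drop = FALSE]
  message(sprintf("readSensorCsv[%s %s]: %d rows read, %d non-numeric dropped, %d duplicate timestamps collapsed",
                  placement, basename(path), nIn, sum(bad), sum(dup)))

  time <- d$time
  if (timeUnit == "ms") time <- time / 1000
  time <- time - time[1]
  acc <- as.matrix(d[, c("ax", "ay", "az")])
  if (accelUnit == "ms2") acc <- acc / 9.81
  SensorStream(placement, time, acc, as.matrix(d[, c("gx", "gy", "gz")]))
}

#' Resample a sensor stream onto a uniform grid
#'
#' Linear interpolation of all six channels onto a grid of spacing
#' `1/rate` running from the first to the last timestamp. Dropout gaps
#' longer than `maxGap` seconds are not bridged: grid samples falling
#' strictly inside such a gap are flagged invalid, and the flags propagate
#' through windowing (windows touching them are excluded). Resampling an
#' already-uniform stream at its own rate is the identity.
#'
#' @param stream a [SensorStream-class].
#' @param rate target rate (Hz).
#' @param maxGap longest bridgeable gap in seconds (default 0.5).
#' @return A [SensorStream-class] on the uniform grid, with `valid` flags.
#' @export
resampleUniform <- function(stream, rate, maxGap = 0.5) {
  t <- stream@time
  if (length(t) < 2L)
    stop("insufficient data: resampling needs at least 2 samples")
  m <- floor((t[length(t)] - t[1]) * rate + 1e-9)
  grid <- t[1] + (0:m) / rate
  chan <- cbind(stream@accel, stream@gyro)
  out <- apply(chan, 2, function(y)
    stats::approx(t, y, xout = grid, rule = 2)$y)
  gaps <- which(diff(t) > maxGap)
  valid <- rep(TRUE, length(grid))
  for (i in gaps) valid[grid > t[i] & grid < t[i + 1]] <- FALSE
  valid <- valid & rep(stream@valid[findInterval(grid, t)], length.out = length(grid))
  SensorStream(stream@placement, grid, out[, 1:3, drop = FALSE],
               out[, 4:6, drop = FALSE], rate = rate, valid = valid)
}

#' Write an aligned recording to CSV
#'
#' Internal interchange format: `t_s`, six columns per placement named
#' `<placement>.<signal>.<axis>`, `valid`, `label_primary` and (if present)
#' `label_reliability`. Values round-trip bit-equal at more than 9
#' significant digits.
#'
#' @param aligned an [AlignedRecording-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignedCsv <- function(aligned, path) {
  df <- data.frame(t_s = aligned@time, check.names = FALSE)
  df <- cbind(df, as.data.frame(aligned@data, check.names = FALSE))
  df$valid <- aligned@valid
  df$label_primary <- aligned@labelPrimary
  if (length(aligned@labelReliability))
    df$label_reliability <- aligned@labelReliability
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an aligned recording written by [writeAlignedCsv()]
#'
#' @param path CSV path.
#' @return An [AlignedRecording-class].
#' @export
readAlignedCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  chanCols <- grep("\\.(accel|gyro)\\.", names(df), value = TRUE)
  placements <- unique(sub("\\..*$", "", chanCols))
  rate <- 1 / stats::median(diff(df$t_s))
  for (cand in c(50, 62.5)) if (abs(rate - cand) / cand < 1e-6) rate <- cand
  methods::new("AlignedRecording",
    time = df$t_s, data = as.matrix(df[, chanCols]),
    valid = as.logical(df$valid), labelPrimary = df$label_primary,
    labelReliability = if ("label_reliability" %in% names(df))
      df$label_reliability else character(0),
    rate = rate, placements = placements)
}
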