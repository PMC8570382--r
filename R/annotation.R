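# Interval-coded body-position annotations, removal logs, dual-coder
# agreement and disagreement masking.

#' Default alias table mapping verbose annotation codes to the five classes
#'
#' Behavioral coding schemes often use task-level codes ("crawling",
#' "held_walking", "highchair"). The alias table folds them onto the five
#' trainable body-position classes: crawling is a prone position, floor /
#' highchair / lap sitting are all sitting, standing / walking / cruising are
#' upright, and both stationary and walking carries are held. Codes are
#' lower-cased and non-alphanumerics collapsed to `_` before lookup.
#'
#' @return Named character vector (code -> class).
#' @examples
#' positionAliases()[["crawling"]]
#' @export
positionAliases <- function() {
  c(supine = "supine", lying_supine = "supine", back = "supine",
    prone = "prone", lying_prone = "prone", crawling = "prone",
    tummy = "prone",
    sitting = "sitting", sitting_floor = "sitting", sit = "sitting",
    sitting_highchair = "sitting", highchair = "sitting", lap = "sitting",
    sitting_restrained = "sitting",
    upright = "upright", standing = "upright", walking = "upright",
    cruising = "upright",
    held = "held", held_stationary = "held", held_walking = "held",
    carried = "held",
    none = "none")
}

.normalizeCode <- function(code) {
  gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", tolower(trimws(code))))
}

#' Map raw annotation codes onto the position vocabulary
#'
#' @param codes character vector of raw codes.
#' @param aliases alias table as from [positionAliases()].
#' @return Character vector of classes; unknown codes map to `"none"` with a
#'   warning.
#' @export
resolvePositionCodes <- function(codes, aliases = positionAliases()) {
  key <- .normalizeCode(codes)
  out <- unname(aliases[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sprintf("unknown position codes mapped to 'none': %s",
                    paste(unique(codes[unknown]), collapse = ", ")))
    out[unknown] <- "none"
  }
  out
}

#' Read an interval-coded annotation CSV
#'
#' Expects Datavyu-export style columns `onset`, `offset`, `code` (an
#' optional leading `ordinal` column is ignored). Intervals are half-open
#' `[onset, offset)`.
#'
#' @param path CSV path.
#' @param timeUnit `"ms"` or `"s"`.
#' @param coder coder identifier recorded on the track.
#' @param aliases alias table, see [positionAliases()].
#' @param timeBase clock of the onsets, `"video"` by default.
#' @return An [AnnotationTrack-class].
#' @export
readAnnotationCsv <- function(path, timeUnit = c("ms", "s"), coder = "coder1",
                              aliases = positionAliases(),
                              timeBase = "video") {
  timeUnit <- match.arg(timeUnit)
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset", "offset", "code")
  if (!all(need %in% names(df)))
    stop(sprintf("annotation file %s lacks columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  bad <- which(df$offset <= df$onset)
  if (length(bad))
    stop(sprintf("annotation row %d: offset (%s) <= onset (%s)",
                 bad[1], df$offset[bad[1]], df$onset[bad[1]]))
  scale <- if (timeUnit == "ms") 1000 else 1
  ev <- data.frame(onset = df$onset / scale, offset = df$offset / scale,
                   label = resolvePositionCodes(df$code, aliases))
  AnnotationTrack(ev, coder = coder, timeBase = timeBase)
}

#' Read a garment-removal log CSV
#'
#' @param path CSV with columns `start`, `end` (and optionally `reason`).
#' @param timeUnit `"s"` or `"ms"`.
#' @return A [RemovalLog-class].
#' @export
readRemovalLog <- function(path, timeUnit = c("s", "ms")) {
  timeUnit <- match.arg(timeUnit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start", "end") %in% names(df)))
    stop(sprintf("removal log %s needs start and end columns", path))
  scale <- if (timeUnit == "ms") 1000 else 1
  RemovalLog(data.frame(start = df$start / scale, end = df$end / scale,
                        reason = if ("reason" %in% names(df)) df$reason
                                 else "unspecified"))
}

#' Sample an annotation track onto a time grid
#'
#' Gives every grid sample the label of its containing half-open interval
#' `[onset, offset)`, or `"none"` where uncoded. Output length always equals
#' the grid length; a grid point exactly at an offset boundary takes the
#' following interval's label (or `"none"`).
#'
#' @param track an [AnnotationTrack-class] (on the sensor time base when used
#'   after synchronization).
#' @param grid numeric time grid (s).
#' @return Character vector of labels, one per grid point.
#' @export
sampleLabels <- function(track, grid) {
  out <- rep("none", length(grid))
  ev <- events(track)
  if (!nrow(ev)) return(out)
  i <- findInterval(grid, ev$onset)
  hit <- i > 0L
  hit[hit] <- grid[hit] < ev$offset[i[hit]]
  out[hit] <- ev$label[i[hit]]
  out
}

#' Shift an annotation track onto the aligned sensor clock
#'
#' @param track an [AnnotationTrack-class] on video time.
#' @param videoEventTime the opening synchronization event's time on the
#'   video clock (s); it becomes time 0.
#' @return The track with shifted events and `timeBase = "sensor"`.
#' @export
shiftTrack <- function(track, videoEventTime) {
  ev <- events(track)
  ev$onset <- ev$onset - videoEventTime
  ev$offset <- ev$offset - videoEventTime
  AnnotationTrack(ev, coder = track@coder, timeBase = "sensor")
}

#' Interrater agreement between two coders
#'
#' Samples both tracks on the grid, discards samples where either coder is
#' uncoded (`"none"`), and reports percent agreement together with
#' unweighted Cohen's kappa.
#'
#' @param a,b [AnnotationTrack-class] objects on the same time base.
#' @param grid numeric time grid (s).
#' @return List with `agreement` (percent), `kappa`, and `nCompared`.
#' @export
interraterAgreement <- function(a, b, grid) {
  la <- sampleLabels(a, grid)
  lb <- sampleLabels(b, grid)
  keep <- la != "none" & lb != "none"
  if (!any(keep))
    stop("undefined agreement: no samples coded by both coders")
  la <- la[keep]; lb <- lb[keep]
  list(agreement = 100 * mean(la == lb),
       kappa = cohenKappa(la, lb),
       nCompared = sum(keep))
}

#' Per-sample coder disagreement mask
#'
#' `TRUE` where both coders coded the sample and their labels differ. With a
#' single coder (`b = NULL`) the mask is all `FALSE` and a notice is logged.
#'
#' @param a primary [AnnotationTrack-class].
#' @param b reliability track or `NULL`.
#' @param grid numeric time grid (s).
#' @return Logical vector along the grid.
#' @export
disagreementMask <- function(a, b, grid) {
  if (is.null(b)) {
    message("single-coder mode: no disagreement exclusion applied")
    return(rep(FALSE, length(grid)))
  }
  la <- sampleLabels(a, grid)
  lb <- sampleLabels(b, grid)
  la != "none" & lb != "none" & la != lb
}

#' Mask removal-log intervals out of a label sequence
#'
#' Samples inside any logged garment-off interval are forced to `"none"` so
#' that no window over them can receive a class label.
#'
#' @param labels character label sequence along `grid`.
#' @param log a [RemovalLog-class].
#' @param grid numeric time grid (s).
#' @return The masked label sequence.
#' @export
applyRemovalLog <- function(labels, log, grid) {
  iv <- log@intervals
  if (!nrow(iv)) return(labels)
  i <- findInterval(grid, iv$start)
  hit <- i > 0L
  hit[hit] <- grid[hit] < iv$end[i[hit]]
  labels[hit] <- "none"
  labels
}
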