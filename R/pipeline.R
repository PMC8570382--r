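# Session configuration and the staged pipeline tying the modules together:
# sync -> windows -> featurize -> train -> predict -> evaluate -> report.

#' Build a session configuration
#'
#' All knobs of the pipeline with their validated defaults. The
#' configuration is schema-checked by [validateConfig()] before any stage
#' runs and is serialized (with its hash) into every output's provenance
#' block.
#'
#' @param simulate if `TRUE`, input comes from [simulateSession()] under
#'   `seed`; otherwise `paths` must point at sensor/annotation files.
#' @param seed integer seed for every stochastic step.
#' @param rate grid rate in Hz.
#' @param profile placement profile (`"lab3"`, `"home4"`, `"custom"`).
#' @param placements placements (default per profile).
#' @param windowSec,stepSec,minCoverage windowing parameters.
#' @param trainFrac chronological training fraction.
#' @param ntree,mtry forest parameters (see [modelSpec()]).
#' @param dialect sensor CSV dialect for file input.
#' @param syncSearch numeric `c(start, end)` seconds (on each raw clock)
#'   searched for the opening impulse; `NULL` = first 30 s.
#' @param syncThreshold impulse prominence threshold in g.
#' @param manualSyncTimes optional named per-placement impulse times
#'   overriding detection.
#' @param videoEventTime the strike's video-clock time (file input).
#' @param paths named list for file input: `sensors` (named placement ->
#'   file), `annotation`, optional `annotationReliability`, `removalLog`,
#'   and `outDir`.
#' @return A `sessionConfig` list.
#' @export
sessionConfig <- function(simulate = TRUE, seed = 1L, rate = 50,
                          profile = "lab3", placements = NULL,
                          windowSec = 4, stepSec = 1, minCoverage = 0.75,
                          trainFrac = 0.6, ntree = 750, mtry = NULL,
                          dialect = "metamotion", syncSearch = NULL,
                          syncThreshold = 2, manualSyncTimes = NULL,
                          videoEventTime = NULL,
                          paths = list(outDir = tempfile("imupose_run_"))) {
  cfg <- list(simulate = simulate, seed = as.integer(seed), rate = rate,
              profile = profile, placements = placements,
              windowSec = windowSec, stepSec = stepSec,
              minCoverage = minCoverage, trainFrac = trainFrac,
              ntree = ntree, mtry = mtry, dialect = dialect,
              syncSearch = syncSearch, syncThreshold = syncThreshold,
              manualSyncTimes = manualSyncTimes,
              videoEventTime = videoEventTime, paths = paths)
  class(cfg) <- "sessionConfig"
  cfg
}

#' Read a session configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [sessionConfig()] arguments.
#' @return A validated `sessionConfig`.
#' @export
readSessionConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(sessionConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- do.call(sessionConfig, raw)
  validateConfig(cfg)
  cfg
}

#' Validate a session configuration
#'
#' @param cfg a `sessionConfig`.
#' @return `cfg`, invisibly; stops with a named message on the first
#'   violation.
#' @export
validateConfig <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(sprintf("config error: %s", msg))
  chk(is.numeric(cfg$rate) && cfg$rate > 0, "rate must be positive")
  chk(cfg$profile %in% c("lab3", "home4", "custom"),
      "profile must be lab3, home4 or custom")
  chk(cfg$windowSec >= cfg$stepSec && cfg$stepSec > 0,
      "need windowSec >= stepSec > 0")
  chk(cfg$minCoverage > 0.5 && cfg$minCoverage <= 1,
      "minCoverage must be in (0.5, 1]")
  chk(cfg$trainFrac > 0 && cfg$trainFrac < 1, "trainFrac must be in (0, 1)")
  chk(cfg$ntree >= 1, "ntree must be >= 1")
  chk(is.null(cfg$mtry) || cfg$mtry >= 1, "mtry must be >= 1 or NULL")
  if (!isTRUE(cfg$simulate)) {
    chk(!is.null(cfg$paths$sensors) && length(cfg$paths$sensors) > 0,
        "file input needs paths$sensors")
    chk(!is.null(cfg$paths$annotation), "file input needs paths$annotation")
    chk(!is.null(cfg$videoEventTime),
        "file input needs videoEventTime (the strike's video-clock time)")
  }
  invisible(cfg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full classification pipeline
#'
#' Executes the stages in order -- sync, windows, featurize, train,
#' predict, evaluate, report -- on either a simulated session (exercising
#' the whole chain against known ground truth) or raw sensor/annotation
#' files. Each stage is deterministic given identical inputs and seed.
#' Artifacts (aligned CSV, window table, feature CSV, report JSON with a
#' provenance block) are written under `cfg$paths$outDir`.
#'
#' @param cfg a [sessionConfig()].
#' @param stages which stages to run (prefix of the default order).
#' @return Invisibly, a list with `aligned`, `windows`, `features`,
#'   `split`, `model`, `predicted`, `report`, `reportPath`.
#' @export
runPipeline <- function(cfg, stages = c("sync", "windows", "featurize",
                                        "train", "predict", "evaluate",
                                        "report")) {
  validateConfig(cfg)
  outDir <- cfg$paths$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  registry <- featureRegistry(cfg$profile, placements = cfg$placements)
  res <- list()

  aligned <- .stage("sync", {
    if (isTRUE(cfg$simulate)) {
      sim <- simulateSession(seed = cfg$seed, rate = cfg$rate,
                             placements = registry@placements,
                             reliability = TRUE)
      res$sim <- sim
      ev <- detectSyncEvents(sim$recording, searchSec = cfg$syncSearch,
                             threshold = cfg$syncThreshold)
      alignSession(sim$recording, ev, sim$syncVideo, sim$track,
                   reliabilityTrack = sim$reliabilityTrack, rate = cfg$rate)
    } else {
      streams <- lapply(names(cfg$paths$sensors), function(p)
        readSensorCsv(cfg$paths$sensors[[p]], p, dialect = cfg$dialect))
      rec <- SensorRecording(streams, profile = cfg$profile)
      ev <- if (!is.null(cfg$manualSyncTimes)) unlist(cfg$manualSyncTimes)
            else detectSyncEvents(rec, searchSec = cfg$syncSearch,
                                  threshold = cfg$syncThreshold)
      track <- readAnnotationCsv(cfg$paths$annotation)
      rel <- if (!is.null(cfg$paths$annotationReliability))
        readAnnotationCsv(cfg$paths$annotationReliability,
                          coder = "reliability") else NULL
      rl <- if (!is.null(cfg$paths$removalLog))
        readRemovalLog(cfg$paths$removalLog) else NULL
      alignSession(rec, ev, cfg$videoEventTime, track,
                   reliabilityTrack = rel, removalLog = rl, rate = cfg$rate)
    }
  })
  res$aligned <- aligned
  if (!is.null(outDir)) writeAlignedCsv(aligned, file.path(outDir, "aligned.csv"))
  if (!"windows" %in% stages) return(invisible(res))

  windows <- .stage("windows", {
    w <- extractWindows(aligned, cfg$windowSec, cfg$stepSec, cfg$minCoverage)
    if (length(aligned@labelReliability)) {
      mask <- aligned@labelPrimary != "none" &
        aligned@labelReliability != "none" &
        aligned@labelPrimary != aligned@labelReliability
      w <- applyDisagreementExclusion(w, mask)
    }
    w
  })
  res$windows <- windows
  if (!is.null(outDir))
    utils::write.csv(data.frame(start_s = windows@startTime,
                                label = windows@label,
                                excluded_reason = windows@excludedReason),
                     file.path(outDir, "windows.csv"), row.names = FALSE)
  if (!"featurize" %in% stages) return(invisible(res))

  features <- .stage("featurize", featurize(windows, registry))
  res$features <- features
  if (!is.null(outDir)) {
    df <- data.frame(start_s = windowStarts(features),
                     label = windowLabels(features))
    utils::write.csv(cbind(df, as.data.frame(featureValues(features))),
                     file.path(outDir, "features.csv"), row.names = FALSE)
  }
  if (!"train" %in% stages) return(invisible(res))

  split <- .stage("train", chronologicalSplit(features, cfg$trainFrac))
  model <- .stage("train",
    trainIndividual(split$train,
                    modelSpec(cfg$ntree, cfg$mtry, seed = cfg$seed)))
  res$split <- split; res$model <- model
  if (!"predict" %in% stages) return(invisible(res))

  predicted <- .stage("predict", predictPositions(model, split$test))
  res$predicted <- predicted
  if (!"evaluate" %in% stages) return(invisible(res))

  report <- .stage("evaluate",
                   evaluatePredictions(windowLabels(split$test), predicted))
  res$report <- report
  if (!"report" %in% stages) return(invisible(res))

  res$reportPath <- .stage("report", {
    tl <- timelineReport(windowStarts(split$test), predicted, cfg$stepSec)
    out <- list(
      accuracy = report@accuracy, kappa = report@kappa,
      kappa_interpretation = landisKochBin(report@kappa),
      n_windows = report@nWindows,
      per_class = report@perClass,
      confusion = as.data.frame(as.table(report@confusion)),
      timeline_totals = as.list(tl$totals),
      provenance = list(config = unclass(cfg)[!vapply(cfg, is.null, TRUE)],
                        config_hash = rlang::hash(unclass(cfg)),
                        registry_hash = registry@hash,
                        seed = cfg$seed))
    p <- file.path(if (is.null(outDir)) tempdir() else outDir, "report.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  })
  invisible(res)
}

#' Detect opening sync impulses for every sensor of a recording
#'
#' @param recording a [SensorRecording-class].
#' @param searchSec `c(start, end)` relative to each stream's start
#'   (default first 30 s).
#' @param threshold impulse prominence threshold in g.
#' @return Named numeric vector of per-placement impulse times on each raw
#'   clock.
#' @export
detectSyncEvents <- function(recording, searchSec = NULL, threshold = 2) {
  if (is.null(searchSec)) searchSec <- c(0, 30)
  vapply(recording@sensors, function(s) {
    t0 <- s@time[1]
    detectSyncImpulse(s, c(t0 + searchSec[1],
                           min(t0 + searchSec[2], max(s@time))),
                      threshold = threshold)
  }, 0)
}

#' Synchronize, window and featurize one simulated session
#'
#' Convenience chain used throughout validation: impulse detection on every
#' raw stream, alignment, windowing with coder-disagreement exclusion, and
#' feature extraction.
#'
#' @param sim output of [simulateSession()].
#' @param registry a [FeatureRegistry-class] (default lab3).
#' @param windowSec,stepSec,minCoverage windowing parameters.
#' @return List: `aligned`, `windows`, `features`.
#' @export
processSession <- function(sim, registry = featureRegistry("lab3"),
                           windowSec = 4, stepSec = 1, minCoverage = 0.75) {
  ev <- detectSyncEvents(sim$recording)
  aligned <- alignSession(sim$recording, ev, sim$syncVideo, sim$track,
                          reliabilityTrack = sim$reliabilityTrack,
                          rate = sim$rate)
  windows <- extractWindows(aligned, windowSec, stepSec, minCoverage)
  if (length(aligned@labelReliability)) {
    mask <- aligned@labelPrimary != "none" &
      aligned@labelReliability != "none" &
      aligned@labelPrimary != aligned@labelReliability
    windows <- applyDisagreementExclusion(windows, mask)
  }
  list(aligned = aligned, windows = windows,
       features = featurize(windows, registry,
                            participant = sim$recording@sessionId))
}
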