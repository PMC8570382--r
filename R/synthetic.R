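# Seedable synthetic IMU session generator. Emulates what the classifier
# exploits in real recordings: body positions differ in how gravity projects
# onto each sensor's axes (limb orientation) and in their motion dynamics
# (gait bounce, crawl bursts, caregiver sway), on top of sensor noise,
# per-infant placement variability (orientation jitter), sync impulses and
# coded annotation tracks with uncoded transition gaps.

.roleOf <- function(placement) sub("^(right|left)_", "", placement)

.unit <- function(v) v / sqrt(sum(v^2))

# rotation matrix, axis-angle (degrees)
.rotationMatrix <- function(axis, angleDeg) {
  a <- angleDeg * pi / 180
  u <- .unit(axis)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * cos(a) + sin(a) * ux + (1 - cos(a)) * (u %o% u)
}

#' Default body-position signal signatures
#'
#' Per activity code and sensor role (hip/thigh/ankle), the gravity
#' direction in the sensor frame plus oscillation and gyro-burst dynamics.
#' The defaults encode the biomechanical separability the method relies on:
#' supine and prone differ by the sign of gravity on the anterior axis;
#' sitting and upright differ in thigh/hip orientation (thigh horizontal vs
#' vertical); held adds a low-frequency (~0.8 Hz) whole-body sway (plus a
#' caregiver-gait component when the carrier walks); crawling and walking
#' add alternating leg gyro bursts. Real infant movement is far richer --
#' see the package vignette for what this simulator does and does not
#' emulate.
#'
#' Units: gravity directions are unit vectors (accelerometer reads +1 g
#' opposite gravity at rest); oscillation amplitudes in g; gyro bursts in
#' deg/s.
#'
#' @return Nested list: `signatures[[code]][[role]]` with elements
#'   `gravity`, optional `osc` (amp, freq, axis) and `gyroBurst`
#'   (amp, freq).
#' @export
positionSignatures <- function() {
  g <- function(x, y, z) .unit(c(x, y, z))
  static <- function(hip, thigh, ankle)
    list(hip = list(gravity = hip), thigh = list(gravity = thigh),
         ankle = list(gravity = ankle))
  sway <- list(amp = 0.15, freq = 0.8, axis = 1L)
  gait <- list(amp = 0.25, freq = 2.0, axis = 2L)

  sig <- list()
  sig$supine <- static(g(1, 0, 0), g(1, 0, 0), g(1, 0, 0))
  sig$prone <- static(g(-1, 0, 0), g(-1, 0, 0), g(-1, 0, 0))
  sig$sitting <- static(g(0.26, 0.97, 0), g(0.97, 0.26, 0), g(0.5, 0.5, 0.71))
  sig$upright <- static(g(0, 1, 0), g(0, 1, 0), g(0, 1, 0))
  sig$held <- static(g(0.37, 0.93, 0), g(0.6, 0.8, 0), g(0.71, 0.71, 0))
  for (r in c("hip", "thigh", "ankle")) sig$held[[r]]$osc <- sway

  sig$standing <- sig$upright
  sig$walking <- sig$upright
  for (r in c("thigh", "ankle")) {
    sig$walking[[r]]$osc <- gait
    sig$walking[[r]]$gyroBurst <- list(amp = 120, freq = 2.0)
  }
  sig$crawling <- sig$prone
  for (r in c("thigh", "ankle")) {
    sig$crawling[[r]]$osc <- list(amp = 0.15, freq = 1.0, axis = 2L)
    sig$crawling[[r]]$gyroBurst <- list(amp = 80, freq = 1.0)
  }
  sig$sitting_floor <- sig$sitting
  sig$sitting_highchair <- sig$sitting
  sig$held_stationary <- sig$held
  sig$held_walking <- sig$held
  for (r in c("hip", "thigh", "ankle"))
    sig$held_walking[[r]]$gait <- list(amp = 0.12, freq = 1.8, axis = 2L)
  sig
}

#' The default guided-activity session schedule
#'
#' Nine 60-s guided activity segments (standing, walking, crawling, floor
#' sitting, supine, prone, stationary hold, walking hold, highchair
#' sitting; ~10 min in total) followed by a 300-s free-play block of
#' randomized 5-30 s position bouts, with 2-s uncoded transition gaps
#' between segments. Activities whose class an infant cannot produce (e.g.
#' upright for pre-standers) are dropped via `classes`.
#'
#' Uses the current RNG state for the free-play bouts; seed upstream (or
#' let [simulateSession()] do it) for reproducibility.
#'
#' @param classes the classes this infant can produce.
#' @param freePlaySec free-play duration in seconds (default 300).
#' @param gapSec transition gap between segments (default 2).
#' @return data.frame: `code`, `class`, `duration`, `coded`.
#' @export
defaultGuidedSchedule <- function(classes = positionClasses(),
                                  freePlaySec = 300, gapSec = 2) {
  guided <- data.frame(
    code = c("standing", "walking", "crawling", "sitting_floor", "supine",
             "prone", "held_stationary", "held_walking", "sitting_highchair"),
    class = c("upright", "upright", "prone", "sitting", "supine", "prone",
              "held", "held", "sitting"))
  guided <- guided[guided$class %in% classes, ]
  guided$duration <- 60
  rows <- list()
  addGap <- function() rows[[length(rows) + 1L]] <<- data.frame(
    code = "transition", class = "none", duration = gapSec, coded = FALSE)
  for (i in seq_len(nrow(guided))) {
    rows[[length(rows) + 1L]] <- cbind(guided[i, ], coded = TRUE)
    addGap()
  }
  remaining <- freePlaySec
  while (remaining > 5) {
    d <- min(stats::runif(1, 5, 30), remaining)
    cl <- sample(classes, 1)
    rows[[length(rows) + 1L]] <- data.frame(code = cl, class = cl,
                                            duration = d, coded = TRUE)
    remaining <- remaining - d
    if (remaining > gapSec) {
      addGap(); remaining <- remaining - gapSec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one multi-sensor session
#'
#' Generates a raw [SensorRecording-class] (per-sensor device clocks with
#' random offsets), the coded [AnnotationTrack-class] on the video clock,
#' optionally a boundary-jittered reliability track, and per-sample ground
#' truth on the aligned clock. Per sample, acceleration is the (jitter-
#' rotated) gravity direction plus the activity's oscillation plus white
#' noise; gyro is bursts/oscillation plus noise. 8-g impulses are injected
#' at the opening (aligned t = 0) and closing sync events; transition gaps
#' blend gravity between neighbouring positions and stay uncoded. The same
#' seed reproduces the session bit-for-bit.
#'
#' @param seed integer RNG seed.
#' @param schedule a schedule data.frame (see [defaultGuidedSchedule()]);
#'   `NULL` builds the default under `seed`.
#' @param classes classes for the default schedule.
#' @param placements sensor placements (default lab 3-sensor set).
#' @param rate sampling rate in Hz (default 50).
#' @param signatures signature set; must cover every scheduled code.
#' @param noiseAccel,noiseGyro white-noise SDs (g, deg/s). Defaults 0.05 g
#'   and 5 deg/s.
#' @param jitterAngleDeg max orientation-jitter angle (deg) emulating
#'   placement variability; 0 disables.
#' @param reliability if `TRUE`, also generate a reliability-coder track
#'   with ±0.2 s boundary jitter.
#' @param sessionId id stamped on the recording.
#' @return List: `recording`, `track`, `reliabilityTrack`, `truth`
#'   (data.frame time/label on the aligned clock), `syncSensor` (named
#'   per-placement opening impulse times on each raw clock), `syncVideo`,
#'   `closingSensor`, `closingVideo`, `schedule`, `rate`, `seed`.
#' @export
simulateSession <- function(seed, schedule = NULL,
                            classes = positionClasses(),
                            placements = c("right_hip", "right_thigh",
                                           "right_ankle"),
                            rate = 50, signatures = positionSignatures(),
                            noiseAccel = 0.05, noiseGyro = 5,
                            jitterAngleDeg = 0, reliability = FALSE,
                            sessionId = sprintf("sim%06d", seed)) {
  set.seed(seed)
  if (is.null(schedule)) schedule <- defaultGuidedSchedule(classes)
  # an explicit schedule is still constrained to this infant's repertoire
  schedule <- schedule[schedule$class %in% c(classes, "none"), , drop = FALSE]
  missing <- setdiff(schedule$code[schedule$coded], names(signatures))
  if (length(missing))
    stop(sprintf("configuration error: no signature for scheduled code(s) %s",
                 paste(unique(missing), collapse = ", ")))

  leadIn <- 3; tail <- 4
  segEnd <- leadIn + cumsum(schedule$duration)
  segStart <- c(leadIn, segEnd[-length(segEnd)])
  closingTime <- segEnd[length(segEnd)] + 3
  total <- closingTime + tail
  n <- floor(total * rate) + 1L
  grid <- (0:(n - 1L)) / rate

  segIdx <- findInterval(grid, c(segStart, Inf))  # 0 = lead-in
  inSeg <- segIdx >= 1 & segIdx <= nrow(schedule) & grid < segEnd[pmax(segIdx, 1L)]
  truth <- rep("none", n)
  coded <- inSeg & schedule$coded[pmax(segIdx, 1L)]
  truth[coded] <- schedule$class[segIdx[coded]]

  jitter <- diag(3)
  if (jitterAngleDeg > 0)
    jitter <- .rotationMatrix(stats::rnorm(3),
                              stats::runif(1, 0, jitterAngleDeg))
  videoOffset <- stats::runif(1, 5, 15)
  offsets <- stats::setNames(stats::runif(length(placements), 5, 20),
                             placements)

  # per-sample activity code (transitions keep code "transition")
  codeIdx <- rep(0L, n)
  codeIdx[inSeg] <- segIdx[inSeg]

  sensors <- list()
  for (p in placements) {
    role <- .roleOf(p)
    grav <- matrix(0, n, 3)
    osc <- matrix(0, n, 3)
    gyr <- matrix(stats::rnorm(n * 3, 0, noiseGyro), n, 3)
    for (s in seq_len(nrow(schedule))) {
      sel <- which(codeIdx == s)
      if (!length(sel)) next
      sg <- signatures[[schedule$code[s]]][[role]]
      if (schedule$coded[s]) {
        grav[sel, ] <- matrix(sg$gravity, length(sel), 3, byrow = TRUE)
        tloc <- grid[sel] - segStart[s]
        for (w in c("osc", "gait")) {
          if (!is.null(sg[[w]])) {
            osc[sel, sg[[w]]$axis] <- osc[sel, sg[[w]]$axis] +
              sg[[w]]$amp * sin(2 * pi * sg[[w]]$freq * tloc)
          }
        }
        if (!is.null(sg$gyroBurst)) {
          burst <- sg$gyroBurst$amp *
            pmax(sin(2 * pi * sg$gyroBurst$freq * tloc), 0)
          gyr[sel, 2] <- gyr[sel, 2] + burst *
            (if (grepl("^left", p)) -1 else 1)
        }
      }
    }
    # bridge uncoded spans (lead-in, transitions, tail) by linear gravity
    # blend between neighbouring positions, renormalized to 1 g
    un <- which(rowSums(grav^2) == 0)
    if (length(un)) {
      for (j in 1:3)
        grav[un, j] <- stats::approx(grid[-un], grav[-un, j], xout = grid[un],
                                     rule = 2)$y
      nr <- sqrt(rowSums(grav[un, , drop = FALSE]^2))
      nr[nr < 1e-6] <- 1
      grav[un, ] <- grav[un, , drop = FALSE] / nr
    }
    acc <- t(jitter %*% t(grav)) + osc +
      matrix(stats::rnorm(n * 3, 0, noiseAccel), n, 3)

    # sync impulses: 8-g excursions, 2 samples wide
    for (tc in c(0, closingTime)) {
      i0 <- round(tc * rate) + 1L
      for (i in i0:min(i0 + 1L, n))
        acc[i, ] <- 8 * .unit(acc[i, ] + c(0.3, 0.3, 0.3))
    }
    sensors[[p]] <- SensorStream(p, grid + offsets[[p]], acc, gyr,
                                 rate = rate)
  }

  events <- data.frame(onset = segStart[schedule$coded] + videoOffset,
                       offset = segEnd[schedule$coded] + videoOffset,
                       label = schedule$class[schedule$coded])
  track <- AnnotationTrack(events, coder = "primary", timeBase = "video")
  relTrack <- NULL
  if (reliability) {
    # boundary jitter plus occasional short mislabelled sub-spans: how two
    # human coders actually differ (frame-level onset disputes, brief
    # confusions), rather than whole-event relabellings
    rows <- list()
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (stats::runif(1) < 0.25 && e$offset - e$onset > 8) {
        d <- stats::runif(1, 2, 6)
        s <- stats::runif(1, e$onset + 1, e$offset - d - 1)
        wrong <- sample(setdiff(positionClasses(), e$label), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          onset = c(e$onset, s, s + d), offset = c(s, s + d, e$offset),
          label = c(e$label, wrong, e$label))
      } else {
        rows[[length(rows) + 1L]] <- e
      }
    }
    ev <- do.call(rbind, rows)
    jit <- stats::runif(nrow(ev), -0.2, 0.2)
    ev$onset <- ev$onset + jit
    ev$offset <- ev$offset + c(jit[-1], stats::runif(1, -0.2, 0.2))
    ev <- ev[order(ev$onset), ]
    for (i in seq_len(nrow(ev))[-1])
      ev$onset[i] <- max(ev$onset[i], ev$offset[i - 1] + 1e-6)
    ev <- ev[ev$offset > ev$onset, ]
    relTrack <- AnnotationTrack(ev, coder = "reliability", timeBase = "video")
  }

  list(recording = SensorRecording(sensors, sessionId = sessionId,
                                   profile = if (identical(sort(placements),
                                     sort(c("right_hip", "right_thigh",
                                            "right_ankle")))) "lab3"
                                     else "custom"),
       track = track, reliabilityTrack = relTrack,
       truth = data.frame(time = grid, label = truth),
       syncSensor = offsets, syncVideo = videoOffset,
       closingSensor = offsets + closingTime,
       closingVideo = videoOffset + closingTime,
       schedule = schedule, rate = rate, seed = seed)
}

#' Simulate a cohort of participants
#'
#' Profiles control which classes each infant can produce (a `"young"`
#' profile omits upright, mirroring pre-standing infants for whom that
#' class is dropped) and each participant gets an independent orientation
#' jitter emulating placement variability across infants.
#'
#' @param n number of participants (default 15).
#' @param seed master seed; per-participant seeds are derived from it.
#' @param profiles character vector recycled over participants:
#'   `"mobile"` (all five classes) or `"young"` (no upright). Default: a
#'   third of the cohort young.
#' @param jitterAngleDeg per-participant max orientation jitter (default
#'   10 deg).
#' @param ... passed to [simulateSession()].
#' @return Named list of session lists (`P01`, `P02`, ...).
#' @export
simulateCohort <- function(n = 15, seed = 1, profiles = NULL,
                           jitterAngleDeg = 10, ...) {
  set.seed(seed)
  seeds <- sample.int(1e6, n)
  if (is.null(profiles))
    profiles <- rep(c("mobile", "mobile", "young"), length.out = n)
  profiles <- rep(profiles, length.out = n)
  out <- vector("list", n)
  names(out) <- sprintf("P%02d", seq_len(n))
  for (i in seq_len(n)) {
    classes <- if (profiles[i] == "young")
      setdiff(positionClasses(), "upright") else positionClasses()
    out[[i]] <- simulateSession(seed = seeds[i], classes = classes,
                                jitterAngleDeg = jitterAngleDeg,
                                sessionId = names(out)[i], ...)
  }
  out
}
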