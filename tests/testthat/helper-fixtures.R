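# Fixtures built in code: tiny aligned recordings, label sequences and CSVs.

# Minimal aligned recording: `labels` per sample at `rate`, one placement,
# constant signal unless `data` given.
makeAligned <- function(labels, rate = 50, valid = rep(TRUE, length(labels)),
                        reliability = character(0), data = NULL,
                        placements = "right_hip") {
  n <- length(labels)
  if (is.null(data)) {
    data <- matrix(0, n, 6 * length(placements))
    colnames(data) <- paste(rep(placements, each = 6),
                            rep(c("accel", "gyro"), each = 3),
                            c("x", "y", "z", "roll", "pitch", "yaw"),
                            sep = ".")
  }
  methods::new("AlignedRecording", time = (0:(n - 1)) / rate, data = data,
               valid = valid, labelPrimary = labels,
               labelReliability = reliability, rate = rate,
               placements = placements)
}

makeTrack <- function(onsets, offsets, labels, coder = "c1",
                      timeBase = "sensor") {
  AnnotationTrack(data.frame(onset = onsets, offset = offsets,
                             label = labels),
                  coder = coder, timeBase = timeBase)
}

# Labelled feature table with k windows per class, 1-s spaced, class means
# separated by `sep` in feature space. `muSeed` fixes the class geometry so
# different `seed`s play the role of different participants drawn from the
# same population.
makeFeatureTable <- function(classes, k = 20, p = 12, sep = 3, seed = 7,
                             hash = "testhash", participant = "t",
                             muSeed = 100) {
  set.seed(muSeed)
  lab <- rep(classes, each = k)
  mu <- matrix(stats::rnorm(length(classes) * p, sd = sep),
               length(classes), p)
  set.seed(seed)
  vals <- mu[match(lab, classes), ] + matrix(stats::rnorm(length(lab) * p),
                                             length(lab), p)
  colnames(vals) <- sprintf("f%02d", seq_len(p))
  methods::new("FeatureTable", values = vals,
               windowStart = as.numeric(seq_along(lab)),
               label = lab, registryHash = hash, participant = participant)
}

writeSensorFixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Fast small session: shortened guided segments, no free play
shortSchedule <- function(classes = positionClasses(), segSec = 20) {
  sch <- defaultGuidedSchedule(classes, freePlaySec = 0)
  sch$duration[sch$coded] <- segSec
  sch
}
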