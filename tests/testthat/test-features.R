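# Window statistics, feature counts, and derived cross-sensor/cross-axis
# features.

# independent brute-force oracle for the 10 per-channel statistics
statOracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu,
    sd = sqrt(sum((x - mu)^2) / (n - 1)),
    skew = if (m2 > 0) m3 / m2^(3 / 2) else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    min = min(x),
    median = unname(stats::quantile(x, 0.5, type = 7)),
    max = max(x),
    p25 = unname(stats::quantile(x, 0.25, type = 7)),
    p75 = unname(stats::quantile(x, 0.75, type = 7)),
    sum = sum(x))
}

# feature table of one window whose hip accel-x channel is `x`
oneWindowFeatures <- function(x, registry = featureRegistry("lab3")) {
  n <- length(x)
  data <- matrix(0, n, 18)
  colnames(data) <- paste(rep(c("right_hip", "right_thigh", "right_ankle"),
                              each = 6),
                          rep(c("accel", "gyro"), each = 3),
                          c("x", "y", "z", "roll", "pitch", "yaw"), sep = ".")
  data[, "right_hip.accel.x"] <- x
  al <- makeAligned(rep("sitting", n), data = data,
                    placements = c("right_hip", "right_thigh", "right_ankle"))
  featurize(extractWindows(al), registry)
}

test_that("a constant channel yields the degenerate statistics", {
  ft <- oneWindowFeatures(rep(3.5, 200))
  v <- featureValues(ft)[1, ]
  pick <- function(st) unname(v[paste("right_hip.accel.x", st, sep = ".")])
  expect_equal(pick("mean"), 3.5)
  expect_equal(pick("median"), 3.5)
  expect_equal(pick("min"), 3.5)
  expect_equal(pick("max"), 3.5)
  expect_equal(pick("p25"), 3.5)
  expect_equal(pick("p75"), 3.5)
  expect_equal(pick("sd"), 0)
  expect_equal(pick("skew"), 0)      # defined 0, not NaN
  expect_equal(pick("kurtosis"), 0)
  expect_equal(pick("sum"), 3.5 * 200)
})

test_that("window statistics match the brute-force oracle", {
  set.seed(4)
  cases <- list(sin(2 * pi * (0:199) / 200) * 2.5,
                stats::rnorm(200),
                stats::rexp(200) - 1)
  for (x in cases) {
    v <- featureValues(oneWindowFeatures(x))[1, ]
    got <- v[paste("right_hip.accel.x",
                   c("mean", "sd", "skew", "kurtosis", "min", "median",
                     "max", "p25", "p75", "sum"), sep = ".")]
    expect_equal(unname(got), unname(statOracle(x)), tolerance = 1e-12)
  }
})

test_that("the lab3 registry enumerates 180 base and 204 total features", {
  reg <- featureRegistry("lab3")
  expect_equal(sum(reg@entries$kind == "base_stat"), 180L)
  expect_equal(nrow(reg@entries), 204L)
  expect_false(anyDuplicated(reg@entries$name) > 0)
  # stable order across constructions
  expect_identical(reg@entries$name, featureRegistry("lab3")@entries$name)
  expect_identical(reg@hash, featureRegistry("lab3")@hash)
})

test_that("registry sizes follow the construction for other profiles", {
  # home4: 10 x 4 x 2 x 3 = 240 base; 12 cross-sensor + 16 cross-axis derived
  home <- featureRegistry("home4")
  expect_equal(sum(home@entries$kind == "base_stat"), 240L)
  expect_equal(nrow(home@entries), 240L + 12L + 16L)

  # single placement: no cross-sensor group; 60 base + 4 cross-axis
  solo <- featureRegistry("custom", placements = "right_hip")
  expect_equal(nrow(solo@entries), 64L)

  # optional correlation/difference groups enlarge lab3 by 18 + 18 + 18 + 18
  full <- featureRegistry("lab3", groups = c("cross_sum", "cross_magnitude",
                                             "axis_correlation",
                                             "axis_difference",
                                             "sensor_correlation",
                                             "sensor_difference"))
  expect_equal(nrow(full@entries), 204L + 72L)
  expect_false(identical(full@hash, featureRegistry("lab3")@hash))
})

test_that("derived features are sums and root-sum-of-squares of window sums", {
  set.seed(8)
  n <- 200
  data <- matrix(stats::rnorm(n * 18), n, 18)
  colnames(data) <- paste(rep(c("right_hip", "right_thigh", "right_ankle"),
                              each = 6),
                          rep(c("accel", "gyro"), each = 3),
                          c("x", "y", "z", "roll", "pitch", "yaw"), sep = ".")
  al <- makeAligned(rep("prone", n), data = data,
                    placements = c("right_hip", "right_thigh", "right_ankle"))
  v <- featureValues(featurize(extractWindows(al), featureRegistry("lab3")))[1, ]
  sums <- sapply(colnames(data), function(cn) sum(data[, cn]))
  hips <- paste(c("right_hip", "right_thigh", "right_ankle"), "accel.x",
                sep = ".")
  expect_equal(unname(v["xsensor.accel.x.sum"]), sum(sums[hips]))
  expect_equal(unname(v["xsensor.accel.x.magnitude"]),
               sqrt(sum(sums[hips]^2)))
  axs <- paste("right_ankle.gyro", c("roll", "pitch", "yaw"), sep = ".")
  expect_equal(unname(v["xaxis.gyro.right_ankle.sum"]), sum(sums[axs]))
  expect_equal(unname(v["xaxis.gyro.right_ankle.magnitude"]),
               sqrt(sum(sums[axs]^2)))

  # all-zero window: every derived feature is 0
  v0 <- featureValues(oneWindowFeatures(rep(0, 200)))[1, ]
  derived <- grep("^(xsensor|xaxis)\\.", names(v0))
  expect_true(all(v0[derived] == 0))
})

test_that("features are shift-invariant and scale equivariant", {
  set.seed(14)
  x <- stats::rnorm(400)
  ftA <- featureValues(oneWindowFeatures(x[1:200]))[1, ]

  # same samples placed later in the session give identical features
  n <- 450
  data <- matrix(0, n, 18)
  colnames(data) <- paste(rep(c("right_hip", "right_thigh", "right_ankle"),
                              each = 6),
                          rep(c("accel", "gyro"), each = 3),
                          c("x", "y", "z", "roll", "pitch", "yaw"), sep = ".")
  data[251:450, "right_hip.accel.x"] <- x[1:200]
  al <- makeAligned(rep("sitting", n), data = data,
                    placements = c("right_hip", "right_thigh", "right_ankle"))
  ftB <- featurize(extractWindows(al), featureRegistry("lab3"))
  vB <- featureValues(ftB)[windowStarts(ftB) == 5, ]
  expect_equal(unname(vB), unname(ftA))

  # scaling by k scales location/scale statistics by k, leaves shape alone
  k <- 3.7
  vS <- featureValues(oneWindowFeatures(k * x[1:200]))[1, ]
  linear <- paste("right_hip.accel.x",
                  c("mean", "sd", "min", "median", "max", "p25", "p75", "sum"),
                  sep = ".")
  expect_equal(unname(vS[linear]), unname(k * ftA[linear]), tolerance = 1e-12)
  shape <- paste("right_hip.accel.x", c("skew", "kurtosis"), sep = ".")
  expect_equal(unname(vS[shape]), unname(ftA[shape]), tolerance = 1e-9)
})

test_that("featurize omits excluded windows and orders rows by start", {
  labels <- rep(c("sitting", "none", "prone"), c(300, 120, 300))
  al <- makeAligned(labels)
  reg <- featureRegistry("custom", placements = "right_hip")
  w <- extractWindows(al)
  ft <- featurize(w, reg)
  expect_equal(length(ft), sum(w@excludedReason == "none"))
  expect_false(is.unsorted(windowStarts(ft)))
  expect_equal(ncol(featureValues(ft)), 64L)
  expect_identical(registryHash(ft), reg@hash)

  # empty window set -> empty table
  suppressWarnings(w0 <- extractWindows(makeAligned(rep("held", 100))))
  expect_equal(length(featurize(w0, reg)), 0L)

  # registry/recording placement mismatch is refused
  expect_error(featurize(w, featureRegistry("lab3")), "not in recording")
})
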