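# Raw sensor CSV ingestion, cleaning and uniform resampling.

metamotionFixture <- function(epoch_ms, ax = 0, ay = 0, az = 1,
                              gx = 0, gy = 0, gz = 0) {
  writeSensorFixture(data.frame(epoch = epoch_ms, ax = ax, ay = ay, az = az,
                                gx = gx, gy = gy, gz = gz))
}

test_that("well-formed files read into clean monotone streams", {
  f <- metamotionFixture(c(0, 20, 40), ax = c(0.1, 0.2, 0.3))
  s <- suppressMessages(readSensorCsv(f, "right_hip"))
  expect_s4_class(s, "SensorStream")
  expect_equal(nSamples(s), 3L)
  expect_equal(timestamps(s), c(0, 0.02, 0.04))
  expect_equal(accel(s)[, "x"], c(0.1, 0.2, 0.3))
  expect_equal(samplingRate(s), 50)

  # 20-ms spacing detects the 50 Hz nominal rate even with jitter
  f2 <- metamotionFixture(seq(0, 2000, by = 20) + rep(c(0, 1, 0), length.out = 101))
  expect_equal(samplingRate(suppressMessages(readSensorCsv(f2, "right_hip"))), 50)
})

test_that("duplicate timestamps collapse keeping the first row", {
  f <- metamotionFixture(c(0, 20, 20, 40), ax = c(1, 2, 9, 4))
  s <- suppressMessages(readSensorCsv(f, "right_hip"))
  expect_equal(nSamples(s), 3L)
  expect_equal(accel(s)[, "x"], c(1, 2, 4))  # the 9 (second dup) is dropped
})

test_that("out-of-order rows are sorted and non-numeric rows rejected", {
  f <- writeSensorFixture(data.frame(
    epoch = c("40", "0", "oops", "20"), ax = c("3", "1", "x", "2"),
    ay = 0, az = 1, gx = 0, gy = 0, gz = 0))
  s <- suppressMessages(readSensorCsv(f, "right_ankle"))
  expect_equal(nSamples(s), 3L)
  expect_equal(accel(s)[, "x"], c(1, 2, 3))
})

test_that("format problems raise named errors", {
  bad <- writeSensorFixture(data.frame(epoch = 1:3, ax = 0))
  expect_error(suppressMessages(readSensorCsv(bad, "right_hip")),
               "missing required columns")
  empty <- writeSensorFixture(data.frame(epoch = numeric(), ax = numeric(),
                                         ay = numeric(), az = numeric(),
                                         gx = numeric(), gy = numeric(),
                                         gz = numeric()))
  expect_error(suppressMessages(readSensorCsv(empty, "right_hip")), "empty")
  expect_error(readSensorCsv(tempfile(), "right_hip"), "not found")
})

test_that("biostamp split accel/gyro files merge on timestamp", {
  fa <- writeSensorFixture(data.frame(t = c(0, 16, 32), x = 1:3, y = 0, z = 0))
  fg <- writeSensorFixture(data.frame(t = c(16, 32, 48), x = 4:6, y = 0, z = 0))
  s <- suppressMessages(readSensorCsv(fa, "left_hip", dialect = "biostamp",
                                      gyroPath = fg))
  expect_equal(nSamples(s), 2L)      # inner join on t = 16, 32
  expect_equal(accel(s)[, "x"], c(2, 3))
  expect_equal(gyro(s)[, "roll"], c(4, 5))
})

test_that("m/s^2 dialects convert to g on input", {
  f <- writeSensorFixture(data.frame(t = c(0, 1), a1 = c(9.81, 0), a2 = 0,
                                     a3 = 0, g1 = 0, g2 = 0, g3 = 0))
  s <- suppressMessages(readSensorCsv(
    f, "right_hip", dialect = "custom", accelUnit = "ms2",
    columns = c(time = "t", ax = "a1", ay = "a2", az = "a3",
                gx = "g1", gy = "g2", gz = "g3")))
  expect_equal(accel(s)[, "x"], c(1, 0))
})

test_that("resampling an already-uniform stream at its own rate is identity", {
  t <- (0:200) / 50
  acc <- cbind(sin(t), cos(t), rep(1, 201))
  s <- SensorStream("right_hip", t, acc, matrix(0, 201, 3), rate = 50)
  r <- resampleUniform(s, 50)
  expect_equal(nSamples(r), 201L)
  expect_lt(max(abs(accel(r) - acc)), 1e-9)
  expect_true(all(validSamples(r)))
})

test_that("linear interpolation fills jittered samples", {
  s <- SensorStream("right_hip", c(0, 0.1), cbind(c(0, 1), 0, 0),
                    matrix(0, 2, 3), rate = 50)
  r <- resampleUniform(s, 50)
  expect_equal(unname(accel(r)[timestamps(r) == 0.04, "x"]), 0.4)
  expect_error(resampleUniform(SensorStream("right_hip", 0, t(c(0, 0, 1)),
                                            t(c(0, 0, 0)), rate = 50), 50),
               "insufficient")
})

test_that("gaps longer than 0.5 s are flagged invalid, not interpolated", {
  t <- c(seq(0, 1, by = 0.02), seq(3, 4, by = 0.02))
  s <- SensorStream("right_hip", t, cbind(1, 0, 0)[rep(1, length(t)), ],
                    matrix(0, length(t), 3), rate = 50)
  r <- resampleUniform(s, 50)
  inGap <- timestamps(r) > 1 & timestamps(r) < 3
  expect_true(all(!validSamples(r)[inGap]))
  expect_true(all(validSamples(r)[!inGap]))
})

test_that("grid properties hold over random spans", {
  set.seed(11)
  for (i in 1:20) {
    t <- sort(stats::runif(stats::rpois(1, 80) + 10, 0, 10))
    t <- t[c(TRUE, diff(t) > 1e-4)]
    s <- SensorStream("right_hip", t,
                      matrix(stats::rnorm(length(t) * 3), ncol = 3),
                      matrix(0, length(t), 3), rate = 50)
    r <- resampleUniform(s, 50)
    expect_equal(unique(round(diff(timestamps(r)), 12)), 1 / 50)
    expect_lte(sum(validSamples(r)),
               ceiling((max(t) - min(t)) * 50) + 1)
  }
})

test_that("aligned CSV round-trips values, flags and labels", {
  al <- makeAligned(rep(c("sitting", "none"), c(150, 50)),
                    reliability = rep("sitting", 200),
                    data = NULL)
  al@data[] <- stats::rnorm(length(al@data))
  p <- tempfile(fileext = ".csv")
  writeAlignedCsv(al, p)
  back <- readAlignedCsv(p)
  expect_equal(back@data, al@data, tolerance = 1e-12)
  expect_identical(back@labelPrimary, al@labelPrimary)
  expect_identical(back@labelReliability, al@labelReliability)
  expect_identical(back@valid, al@valid)
  expect_equal(samplingRate(back), 50)
})
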