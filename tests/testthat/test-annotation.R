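# Interval-coded annotations, alias mapping, grid sampling, dual-coder
# agreement and removal-log masking.

annotationFixture <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}

test_that("annotation CSVs parse with ms->s conversion and alias mapping", {
  p <- annotationFixture(data.frame(onset = c(0, 5000), offset = c(5000, 8000),
                                    code = c("sitting", "prone")))
  tr <- readAnnotationCsv(p, timeUnit = "ms")
  expect_equal(events(tr)$onset, c(0, 5))
  expect_equal(events(tr)$offset, c(5, 8))
  expect_equal(events(tr)$label, c("sitting", "prone"))

  # crawling is a prone position; highchair and lap are sitting
  p2 <- annotationFixture(data.frame(onset = c(0, 10, 20),
                                     offset = c(10, 20, 30),
                                     code = c("Crawling", "highchair",
                                              "held-walking")))
  tr2 <- readAnnotationCsv(p2, timeUnit = "s")
  expect_equal(events(tr2)$label, c("prone", "sitting", "held"))

  # unknown codes map to none with a warning
  p3 <- annotationFixture(data.frame(onset = 0, offset = 5, code = "zooming"))
  expect_warning(tr3 <- readAnnotationCsv(p3, timeUnit = "s"), "zooming")
  expect_equal(events(tr3)$label, "none")
})

test_that("malformed annotation rows are rejected", {
  p <- annotationFixture(data.frame(onset = c(0, 8), offset = c(5, 6),
                                    code = c("sitting", "prone")))
  expect_error(readAnnotationCsv(p, timeUnit = "s"), "row 2")
  p2 <- annotationFixture(data.frame(onset = c(0, 3), offset = c(5, 8),
                                     code = c("sitting", "prone")))
  expect_error(readAnnotationCsv(p2, timeUnit = "s"), "overlap")
})

test_that("sampling labels follows the half-open interval convention", {
  tr <- makeTrack(0, 2, "sitting")
  expect_equal(sampleLabels(tr, 0:3), c("sitting", "sitting", "none", "none"))

  # boundary sample takes the following interval's label
  tr2 <- makeTrack(c(0, 2), c(2, 4), c("sitting", "prone"))
  expect_equal(sampleLabels(tr2, 2), "prone")

  # empty track -> all none; output length always equals grid length
  empty <- AnnotationTrack(data.frame(onset = numeric(), offset = numeric(),
                                      label = character()))
  for (g in list(numeric(0), 0, seq(0, 10, 0.5)))
    expect_equal(sampleLabels(empty, g), rep("none", length(g)))
})

test_that("interrater agreement reproduces a hand-computed 2x2 kappa", {
  # confusion {AA:45, AB:5, BA:5, BB:45}: po = 0.9, pe = 0.5, kappa = 0.8
  grid <- (0:99)
  a <- makeTrack(c(0, 50), c(50, 100), c("sitting", "prone"))
  b <- makeTrack(c(0, 45, 50, 95), c(45, 50, 95, 100),
                 c("sitting", "prone", "prone", "sitting"))
  res <- interraterAgreement(a, b, grid + 0.5)
  expect_equal(res$agreement, 90)
  expect_equal(res$kappa, 0.8)
  expect_equal(res$nCompared, 100L)

  # identical tracks -> perfect agreement
  res2 <- interraterAgreement(b, b, grid + 0.5)
  expect_equal(res2$agreement, 100)
  expect_equal(res2$kappa, 1)

  # agreement is symmetric in its arguments
  expect_equal(interraterAgreement(b, a, grid + 0.5)$kappa, res$kappa)

  # an entirely uncoded coder gives an undefined-agreement error
  empty <- AnnotationTrack(data.frame(onset = numeric(), offset = numeric(),
                                      label = character()))
  expect_error(interraterAgreement(a, empty, grid), "undefined agreement")
})

test_that("disagreement mask marks exactly the doubly-coded mismatches", {
  grid <- seq(0, 10 - 1 / 50, by = 1 / 50)
  a <- makeTrack(0, 10, "sitting")
  b <- makeTrack(c(0, 4), c(4, 5), c("sitting", "prone"))
  m <- disagreementMask(a, b, grid)
  expect_equal(sum(m), 50L)   # one mismatching second at 50 Hz
  expect_true(all(m[grid >= 4 & grid < 5]))

  expect_false(any(disagreementMask(a, a, grid)))
  expect_message(m0 <- disagreementMask(a, NULL, grid), "single-coder")
  expect_false(any(m0))
})

test_that("removal-log masking forces logged spans to none", {
  grid <- seq(0, 99) + 0.5
  labels <- rep("sitting", 100)
  emptyLog <- RemovalLog()
  expect_identical(applyRemovalLog(labels, emptyLog, grid), labels)

  log1 <- RemovalLog(data.frame(start = 10, end = 20, reason = "nap"))
  out <- applyRemovalLog(labels, log1, grid)
  expect_equal(sum(out == "none"), 10L)
  expect_true(all(out[grid > 10 & grid < 20] == "none"))

  fullLog <- RemovalLog(data.frame(start = 0, end = 100, reason = "off"))
  expect_true(all(applyRemovalLog(labels, fullLog, grid) == "none"))
})

test_that("masked sample counts track logged in-grid duration", {
  set.seed(3)
  rate <- 50
  grid <- seq(0, 600 - 1 / rate, by = 1 / rate)
  for (i in 1:10) {
    s <- sort(stats::runif(2, 0, 580))
    s <- c(s[1], max(s[2], s[1] + 1))
    log <- RemovalLog(data.frame(start = s[1], end = s[2], reason = "x"))
    masked <- sum(applyRemovalLog(rep("held", length(grid)), log, grid) ==
                  "none")
    expect_lte(abs(masked - (s[2] - s[1]) * rate), 1)
  }
})
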