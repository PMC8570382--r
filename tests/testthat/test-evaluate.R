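# Kappa, per-class metrics, Landis-Koch bins, prevalence correlations,
# paired model comparison, timelines.

# independent kappa oracle straight from the definition
kappaOracle <- function(actual, predicted) {
  cls <- sort(union(actual, predicted))
  n <- length(actual)
  po <- mean(actual == predicted)
  pe <- 0
  for (cl in cls)
    pe <- pe + (sum(actual == cl) / n) * (sum(predicted == cl) / n)
  (po - pe) / (1 - pe)
}

labelsFromConfusion <- function(cm) {
  act <- rep(rownames(cm), rowSums(cm))
  pred <- unlist(lapply(seq_len(nrow(cm)), function(i)
    rep(colnames(cm), cm[i, ])))
  list(actual = act, predicted = pred)
}

test_that("Cohen's kappa matches hand-computed reference cases", {
  # {AA:45, AB:5, BA:5, BB:45}: po = 0.9, pe = 0.5 -> kappa = 0.8
  l <- labelsFromConfusion(matrix(c(45, 5, 5, 45), 2, 2, byrow = TRUE,
                                  dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(cohenKappa(l$actual, l$predicted), 0.8)

  # perfect agreement with >= 2 classes
  expect_equal(cohenKappa(c("a", "b", "a"), c("a", "b", "a")), 1)

  # chance-level agreement with matched marginals -> 0
  l0 <- labelsFromConfusion(matrix(c(25, 25, 25, 25), 2, 2,
                                   dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(cohenKappa(l0$actual, l0$predicted), 0)

  # both sequences constant and identical -> undefined
  expect_error(cohenKappa(rep("a", 5), rep("a", 5)), "undefined kappa")
})

test_that("kappa, sensitivity and PPV agree with brute-force oracles over
          random confusion matrices", {
  set.seed(99)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    cm <- matrix(stats::rpois(k * k, 4) + diag(k) * 5, k, k,
                 dimnames = list(letters[1:k], letters[1:k]))
    l <- labelsFromConfusion(cm)
    if (length(unique(l$actual)) < 2 && all(l$actual == l$predicted)) next
    expect_equal(cohenKappa(l$actual, l$predicted),
                 kappaOracle(l$actual, l$predicted), tolerance = 1e-12)
    pm <- classMetrics(cm)
    for (j in seq_len(k)) {
      expect_equal(pm$sensitivity[j], cm[j, j] / sum(cm[j, ]))
      predTot <- sum(cm[, j])
      if (predTot > 0) expect_equal(pm$ppv[j], cm[j, j] / predTot)
      expect_lte(cm[j, j], min(sum(cm[j, ]), max(predTot, cm[j, j])))
    }
    expect_true(all(stats::na.omit(c(pm$sensitivity, pm$ppv)) >= 0))
    expect_true(all(stats::na.omit(c(pm$sensitivity, pm$ppv)) <= 1))
    expect_equal(sum(pm$prevalence), 100)

    # class order permutation leaves accuracy and kappa unchanged
    perm <- sample(k)
    expect_equal(cohenKappa(l$actual, l$predicted),
                 cohenKappa(letters[perm][match(l$actual, letters[1:k])],
                            letters[perm][match(l$predicted, letters[1:k])]))
  }
})

test_that("per-class metrics reproduce the published worked examples", {
  # 9 windows predicted upright, 7 truly upright -> PPV 0.778
  cm <- matrix(c(7, 0, 2, 21), 2, 2, byrow = TRUE,
               dimnames = list(c("upright", "held"), c("upright", "held")))
  pm <- classMetrics(cm)
  expect_equal(round(pm$ppv[pm$class == "upright"], 3), 0.778)

  # 31 actual supine windows, 22 predicted supine -> sensitivity 0.71
  cm2 <- matrix(c(22, 9, 0, 50), 2, 2, byrow = TRUE,
                dimnames = list(c("supine", "sitting"),
                                c("supine", "sitting")))
  pm2 <- classMetrics(cm2)
  expect_equal(round(pm2$sensitivity[pm2$class == "supine"], 2), 0.71)

  # diagonal confusion: all sensitivities and PPVs 1
  d <- diag(c(5, 9, 2)); dimnames(d) <- list(letters[1:3], letters[1:3])
  expect_true(all(classMetrics(d)$sensitivity == 1))
  expect_true(all(classMetrics(d)$ppv == 1))

  # a never-predicted class has missing (not zero) PPV
  cm3 <- matrix(c(0, 3, 0, 7), 2, 2, byrow = TRUE,
                dimnames = list(c("prone", "held"), c("prone", "held")))
  expect_true(is.na(classMetrics(cm3)$ppv[1]))
})

test_that("Landis-Koch binning rounds to 2 decimals first", {
  expect_equal(landisKochBin(0.70), "Substantial")
  expect_equal(landisKochBin(0.82), "Almost Perfect")
  expect_equal(landisKochBin(0.805), "Almost Perfect")  # rounds to 0.81
  expect_equal(landisKochBin(c(0.604, 0.15, -0.2, 0.35)),
               c("Moderate", "Slight to Poor", "Slight to Poor", "Fair"))
})

test_that("prevalence correlations match a brute-force Pearson oracle", {
  set.seed(42)
  classes <- positionClasses()
  actual <- matrix(stats::runif(17 * 5), 17, 5,
                   dimnames = list(NULL, classes))
  actual <- actual / rowSums(actual)
  predicted <- actual + matrix(stats::rnorm(17 * 5, 0, 0.05), 17, 5)
  res <- prevalenceCorrelation(actual, predicted)
  for (cl in classes) {
    x <- actual[, cl]; y <- predicted[, cl]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(res$perClass[cl]), r, tolerance = 1e-12)
  }
  expect_equal(res$pooled, stats::cor(c(actual), c(predicted)))

  # identity -> r = 1 for every class
  r1 <- prevalenceCorrelation(actual, actual)
  expect_equal(unname(r1$perClass), rep(1, 5))

  # constant actual prevalence -> missing r with a warning
  const <- actual; const[, "held"] <- 0.2
  expect_warning(rc <- prevalenceCorrelation(const, predicted), "held")
  expect_true(is.na(rc$perClass[["held"]]))
  expect_error(prevalenceCorrelation(actual[1:2, ], predicted[1:2, ]),
               "at least 3")
})

test_that("interval prevalence partitions the timeline into fixed bins", {
  starts <- seq(0, 1799, by = 1)
  labels <- rep(c("sitting", "held"), c(900, 900))
  m <- prevalenceByInterval(starts, labels, intervalSec = 450)
  expect_equal(nrow(m), 4L)
  expect_equal(unname(m[, "sitting"]), c(1, 1, 0, 0))
  expect_equal(unname(rowSums(m)), rep(1, 4))
})

test_that("the paired model-type comparison is a two-sided paired t", {
  # hand-computed: diffs d = x - y, t = mean(d)/(sd(d)/sqrt(n))
  x <- c(0.95, 0.90, 0.99)
  y <- c(0.80, 0.85, 0.90)
  d <- x - y
  tHand <- mean(d) / (stats::sd(d) / sqrt(3))
  res <- compareModelTypes(x, y)
  expect_equal(res$t, tHand)
  expect_equal(res$df, 2)
  expect_equal(res$means, c(individual = 0.95, group = 0.85))

  # identical pairs have zero-variance differences -> undefined t
  expect_error(compareModelTypes(x, x), "undefined t")
})

test_that("timeline reports merge episodes and account for removals", {
  # constant prediction -> a single episode covering everything
  tl <- timelineReport(0:99, rep("sitting", 100))
  expect_equal(nrow(tl$episodes), 1L)
  expect_equal(tl$episodes$end - tl$episodes$start, 100)
  expect_equal(unname(tl$totals["sitting"]), 100)

  # alternating labels -> one episode per window step
  tl2 <- timelineReport(0:9, rep(c("held", "prone"), 5))
  expect_equal(nrow(tl2$episodes), 10L)
  expect_equal(sum(tl2$totals), 100)

  # removal interval renders as a gap splitting an episode
  log <- RemovalLog(data.frame(start = 40, end = 60, reason = "nap"))
  tl3 <- timelineReport(0:99, rep("sitting", 100), removalLog = log)
  expect_equal(nrow(tl3$episodes), 2L)
  expect_equal(unname(tl3$totals["sitting"]), 100)
})
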