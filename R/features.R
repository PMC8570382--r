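# The per-window motion-feature set: 10 summary statistics per
# placement x signal x axis, plus cross-sensor and cross-axis sum/magnitude
# features. lab3 profile: 180 base + 24 derived = 204 features.

.statNames <- c("mean", "sd", "skew", "kurtosis", "min", "median", "max",
                "p25", "p75", "sum")
.axesFor <- function(signal) {
  if (signal == "accel") c("x", "y", "z") else c("roll", "pitch", "yaw")
}

#' Build the feature registry for a placement profile
#'
#' Enumerates, in a stable order, every feature computed per window:
#' \itemize{
#'   \item base statistics: mean, standard deviation, skew, kurtosis,
#'     minimum, median, maximum, 25th and 75th percentiles, and sum, for
#'     each placement x signal (accel/gyro) x axis -- 10 x 3 x 2 x 3 = 180
#'     for the lab 3-sensor profile;
#'   \item `cross_sum` / `cross_magnitude`: per signal x axis, the sum and
#'     the root-sum-of-squares of the per-placement window sums
#'     (cross-sensor movement), and per signal x placement, the same across
#'     axes (cross-axis movement) -- 24 for lab3, total 204;
#'   \item optional groups (disabled by default): `axis_correlation`,
#'     `axis_difference`, `sensor_correlation`, `sensor_difference` --
#'     pairwise Pearson correlations and mean absolute differences.
#' }
#'
#' Statistic conventions (recorded via the registry hash): sample standard
#' deviation (n-1 denominator), Fisher-Pearson skewness g1, excess kurtosis
#' g2, linear-interpolation percentiles; zero-variance channels get
#' skew = kurtosis = 0. The hash is stamped into feature tables and models.
#'
#' @param profile `"lab3"` (right hip/thigh/ankle), `"home4"` (both hips and
#'   ankles) or `"custom"`.
#' @param placements placement names; defaults follow the profile.
#' @param groups enabled derived groups (default sum + magnitude).
#' @return A [FeatureRegistry-class].
#' @examples
#' nrow(featureRegistry("lab3")@entries)  # 204
#' @export
featureRegistry <- function(profile = c("lab3", "home4", "custom"),
                            placements = NULL,
                            groups = c("cross_sum", "cross_magnitude")) {
  profile <- match.arg(profile)
  if (is.null(placements))
    placements <- switch(profile,
      lab3 = c("right_hip", "right_thigh", "right_ankle"),
      home4 = c("right_hip", "left_hip", "right_ankle", "left_ankle"),
      stop("custom profile needs explicit placements"))
  signals <- c("accel", "gyro")

  rows <- list()
  for (p in placements) for (s in signals) for (a in .axesFor(s))
    for (st in .statNames)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(p, s, a, st, sep = "."), kind = "base_stat",
        placement = p, signal = s, axis = a, statistic = st)

  addDerived <- function(kind, p, s, a, tag) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = tag, kind = kind, placement = p, signal = s, axis = a,
      statistic = sub("^.*_", "", kind))
  }
  if (length(placements) > 1L && "cross_sum" %in% groups)
    for (s in signals) for (a in .axesFor(s))
      addDerived("cross_sensor_sum", "all", s, a,
                 paste("xsensor", s, a, "sum", sep = "."))
  if (length(placements) > 1L && "cross_magnitude" %in% groups)
    for (s in signals) for (a in .axesFor(s))
      addDerived("cross_sensor_magnitude", "all", s, a,
                 paste("xsensor", s, a, "magnitude", sep = "."))
  if ("cross_sum" %in% groups)
    for (s in signals) for (p in placements)
      addDerived("cross_axis_sum", p, s, "all",
                 paste("xaxis", s, p, "sum", sep = "."))
  if ("cross_magnitude" %in% groups)
    for (s in signals) for (p in placements)
      addDerived("cross_axis_magnitude", p, s, "all",
                 paste("xaxis", s, p, "magnitude", sep = "."))
  if ("axis_correlation" %in% groups || "axis_difference" %in% groups) {
    for (p in placements) for (s in signals) {
      ax <- .axesFor(s)
      for (i in 1:2) for (j in (i + 1):3) {
        if ("axis_correlation" %in% groups)
          addDerived("axis_correlation", p, s, paste(ax[i], ax[j], sep = "_"),
                     paste("corr", s, p, ax[i], ax[j], sep = "."))
        if ("axis_difference" %in% groups)
          addDerived("axis_difference", p, s, paste(ax[i], ax[j], sep = "_"),
                     paste("diff", s, p, ax[i], ax[j], sep = "."))
      }
    }
  }
  if (length(placements) > 1L &&
      ("sensor_correlation" %in% groups || "sensor_difference" %in% groups)) {
    np <- length(placements)
    for (s in signals) for (a in .axesFor(s))
      for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
        if ("sensor_correlation" %in% groups)
          addDerived("sensor_correlation",
                     paste(placements[i], placements[j], sep = "_"), s, a,
                     paste("corr", s, a, placements[i], placements[j], sep = "."))
        if ("sensor_difference" %in% groups)
          addDerived("sensor_difference",
                     paste(placements[i], placements[j], sep = "_"), s, a,
                     paste("diff", s, a, placements[i], placements[j], sep = "."))
      }
  }

  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  hash <- rlang::hash(list(entries$name, entries$kind,
                           conventions = c(sd = "n-1", skew = "g1",
                                           kurtosis = "excess g2",
                                           percentile = "type7")))
  methods::new("FeatureRegistry", entries = entries, profile = profile,
               placements = placements, groups = groups, hash = hash)
}

# 10 base statistics for every column of M (wlen x k matrix of windows).
# Returns a 10 x k matrix in .statNames order. Zero-variance columns get
# skew = kurtosis = 0 rather than NaN.
.windowStats <- function(M) {
  wlen <- nrow(M)
  mu <- colMeans(M)
  D <- M - rep(mu, each = wlen)
  m2 <- colMeans(D^2)
  m3 <- colMeans(D^3)
  m4 <- colMeans(D^4)
  sd <- sqrt(m2 * wlen / (wlen - 1))
  pos <- m2 > 0
  skew <- kurt <- numeric(ncol(M))
  skew[pos] <- m3[pos] / m2[pos]^1.5
  kurt[pos] <- m4[pos] / m2[pos]^2 - 3
  S <- apply(M, 2, sort)
  q7 <- function(p) {
    h <- (wlen - 1) * p + 1
    lo <- floor(h)
    S[lo, ] + (h - lo) * (S[pmin(lo + 1, wlen), ] - S[lo, ])
  }
  rbind(mean = mu, sd = sd, skew = skew, kurtosis = kurt,
        min = S[1, ], median = q7(0.5), max = S[wlen, ],
        p25 = q7(0.25), p75 = q7(0.75), sum = mu * wlen)
}

#' Compute the feature table for a window set
#'
#' Computes every registry feature for each assignable window (excluded
#' windows are omitted); rows are ordered by window start time. The
#' registry hash is stamped into the table.
#'
#' @param windows a [WindowSet-class].
#' @param registry a [FeatureRegistry-class] whose placements match the
#'   recording.
#' @param participant id recorded on the table.
#' @return A [FeatureTable-class].
#' @export
featurize <- function(windows, registry, participant = "session") {
  al <- windows@aligned
  if (!all(registry@placements %in% al@placements))
    stop(sprintf("registry placements not in recording: %s",
                 paste(setdiff(registry@placements, al@placements),
                       collapse = ", ")))
  keep <- assignedWindows(windows)
  wlen <- windows@windowLen
  k <- length(keep)
  reg <- registry@entries
  vals <- matrix(NA_real_, k, nrow(reg), dimnames = list(NULL, reg$name))
  if (k) {
    idx <- outer(seq_len(wlen) - 1L, windows@startIdx[keep], "+")
    chanStats <- list()   # per channel: 10 x k stats matrix
    chanMat <- list()
    for (p in registry@placements) for (s in c("accel", "gyro"))
      for (a in .axesFor(s)) {
        cn <- paste(p, s, a, sep = ".")
        M <- matrix(al@data[idx, cn], wlen, k)
        chanMat[[cn]] <- M
        st <- .windowStats(M)
        chanStats[[cn]] <- st
        vals[, paste(cn, .statNames, sep = ".")] <- t(st)
      }
    sumOf <- function(p, s, a) chanStats[[paste(p, s, a, sep = ".")]]["sum", ]
    for (r in which(reg$kind != "base_stat")) {
      kind <- reg$kind[r]; s <- reg$signal[r]
      vals[, reg$name[r]] <- switch(kind,
        cross_sensor_sum = {
          Reduce(`+`, lapply(registry@placements, sumOf, s = s, a = reg$axis[r]))
        },
        cross_sensor_magnitude = {
          sqrt(Reduce(`+`, lapply(registry@placements, function(p)
            sumOf(p, s, reg$axis[r])^2)))
        },
        cross_axis_sum = {
          Reduce(`+`, lapply(.axesFor(s), sumOf, p = reg$placement[r], s = s))
        },
        cross_axis_magnitude = {
          sqrt(Reduce(`+`, lapply(.axesFor(s), function(a)
            sumOf(reg$placement[r], s, a)^2)))
        },
        axis_correlation = {
          ax <- strsplit(reg$axis[r], "_")[[1]]
          .safeColCor(chanMat[[paste(reg$placement[r], s, ax[1], sep = ".")]],
                      chanMat[[paste(reg$placement[r], s, ax[2], sep = ".")]])
        },
        axis_difference = {
          ax <- strsplit(reg$axis[r], "_")[[1]]
          colMeans(abs(chanMat[[paste(reg$placement[r], s, ax[1], sep = ".")]] -
                       chanMat[[paste(reg$placement[r], s, ax[2], sep = ".")]]))
        },
        sensor_correlation = {
          pp <- strsplit(reg$placement[r], "_(?=left|right)", perl = TRUE)[[1]]
          .safeColCor(chanMat[[paste(pp[1], s, reg$axis[r], sep = ".")]],
                      chanMat[[paste(pp[2], s, reg$axis[r], sep = ".")]])
        },
        sensor_difference = {
          pp <- strsplit(reg$placement[r], "_(?=left|right)", perl = TRUE)[[1]]
          colMeans(abs(chanMat[[paste(pp[1], s, reg$axis[r], sep = ".")]] -
                       chanMat[[paste(pp[2], s, reg$axis[r], sep = ".")]]))
        },
        stop(sprintf("unknown feature kind '%s'", kind)))
    }
  }
  methods::new("FeatureTable", values = vals,
               windowStart = windows@startTime[keep],
               label = windows@label[keep], registryHash = registry@hash,
               participant = participant)
}

# column-wise Pearson correlation of two wlen x k matrices; 0 when either
# column is constant (correlation undefined, no co-movement evidence)
.safeColCor <- function(A, B) {
  wlen <- nrow(A)
  da <- A - rep(colMeans(A), each = wlen)
  db <- B - rep(colMeans(B), each = wlen)
  den <- sqrt(colSums(da^2) * colSums(db^2))
  out <- numeric(ncol(A))
  ok <- den > 0
  out[ok] <- colSums(da * db)[ok] / den[ok]
  out
}

#' Combine feature tables from several sessions/participants
#'
#' @param tables list of [FeatureTable-class] objects sharing one registry
#'   hash.
#' @return A single [FeatureTable-class]; the `participant` slot keeps the
#'   per-row origin via `attr(x, "participants")` on the values matrix.
#' @export
bindFeatureTables <- function(tables) {
  hashes <- unique(vapply(tables, registryHash, ""))
  if (length(hashes) != 1L)
    stop("cannot bind feature tables from different registries")
  vals <- do.call(rbind, lapply(tables, featureValues))
  part <- unlist(lapply(tables, function(x)
    rep(x@participant, length(x))))
  attr(vals, "participants") <- part
  methods::new("FeatureTable", values = vals,
               windowStart = unlist(lapply(tables, windowStarts)),
               label = unlist(lapply(tables, windowLabels)),
               registryHash = hashes, participant = "pooled")
}
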