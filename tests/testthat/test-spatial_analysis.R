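test_that("hand-computed occupancy toy map gives exact rates", {
  # 4 s in four quadrants (1 s each), spikes 2/0/4/0, 2x2 bins, no smoothing
  fs <- 50
  qx <- c(rep(11.25, 50), rep(33.75, 50), rep(11.25, 50), rep(33.75, 50))
  qy <- c(rep(11.25, 100), rep(33.75, 100))
  tr <- trajectory(seq_len(200) / fs - 1 / fs, qx, qy, 45)
  spikes <- c(0.2, 0.5,            # quadrant 1 (low-x, low-y): 2 spikes
              2.1, 2.3, 2.5, 2.7)  # quadrant 3 (low-x, high-y): 4 spikes
  rm_ <- rate_map(spikes, tr, bin_cm = 22.5, smooth_cm = 0)
  expect_equal(rm_$rate[1, 1], 2)
  expect_equal(rm_$rate[1, 2], 0)
  expect_equal(rm_$rate[2, 1], 4)
  expect_equal(rm_$rate[2, 2], 0)
  expect_equal(sum(rm_$occupancy), 4)
})

test_that("empty inputs are handled: no spikes, empty trajectory", {
  tr <- synth_trajectory(30, 45, seed = 1)
  rm_ <- rate_map(numeric(0), tr)
  expect_equal(max(rm_$rate, na.rm = TRUE), 0)
  expect_error(rate_map(1, tr[0, ]), "empty")
})

test_that("uniform spiking on a well-covered trajectory gives a flat map", {
  tr <- synth_trajectory(600, 45, seed = 2)
  spikes <- seq(0.05, max(tr$t), by = 0.2)   # steady 5 Hz
  rm_ <- rate_map(spikes, tr, bin_cm = 3, smooth_cm = 3)
  v <- rm_$rate[!is.na(rm_$rate)]
  expect_equal(stats::median(v), 5, tolerance = 0.25)
  expect_lt(stats::sd(v) / mean(v), 0.6)
})

test_that("autocorrelogram has unit central peak and handles edge cases", {
  m <- synth_rate_map("hex", 40, 6, arena = 100)
  ac <- autocorrelogram(m)
  ctr <- (dim(ac) + 1) / 2
  expect_equal(ac[ctr[1], ctr[2]], 1)
  # constant map: zero variance everywhere, correlation 0 by convention
  cm <- structure(list(rate = matrix(5, 20, 20), bin_cm = 3),
                  class = "rate_map")
  acc <- autocorrelogram(cm)
  expect_true(all(acc[!is.na(acc)] == 0))
  expect_equal(acc[20, 20], 0)
})

test_that("ideal hexagonal map shows six autocorrelogram peaks at 60 degrees", {
  m <- synth_rate_map("hex", 36, 5, arena = 120)
  ac <- autocorrelogram(m)
  ny <- nrow(ac); nx <- ncol(ac)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  # brute-force local maxima beyond the central peak
  peaks <- NULL
  for (r in 3:(ny - 2)) for (c in 3:(nx - 2)) {
    w <- ac[(r - 2):(r + 2), (c - 2):(c + 2)]
    if (!any(is.na(w)) && ac[r, c] == max(w) && ac[r, c] > 0.3) {
      d <- sqrt((r - cy)^2 + (c - cx)^2)
      if (d > 4 && d < 36 / 3 * 1.5) peaks <- rbind(peaks, c(r, c, d))
    }
  }
  expect_gte(nrow(peaks), 6)
  six <- peaks[order(peaks[, 3]), , drop = FALSE][1:6, ]
  angs <- sort(atan2(six[, 1] - cy, six[, 2] - cx) %% (2 * pi)) * 180 / pi
  gaps <- diff(c(angs, angs[1] + 360))
  expect_true(all(abs(gaps - 60) < 10))
})

test_that("grid score separates hexagonal, square and radial patterns", {
  hex <- grid_score(autocorrelogram(synth_rate_map("hex", 44, 6, arena = 100)))
  expect_gt(hex, 0.2)
  sq <- grid_score(autocorrelogram(synth_rate_map("square", 44, 6, arena = 100)))
  expect_lt(sq, 0)
  rings <- grid_score(autocorrelogram(
    synth_rate_map("rings", 30, arena = 150, shape = "circle")))
  expect_lt(abs(rings), 0.1)
})

test_that("grid score is invariant under uniform rate scaling", {
  m <- synth_rate_map("hex", 40, 6, arena = 100)
  g1 <- grid_score(autocorrelogram(m))
  m$rate <- m$rate * 7.3
  expect_equal(as.numeric(grid_score(autocorrelogram(m))), as.numeric(g1),
               tolerance = 1e-10)
})

test_that("grid score degrades monotonically with map noise", {
  set.seed(21)
  levels <- seq(0, 30, length.out = 10)
  mean_scores <- vapply(levels, function(amp) {
    mean(vapply(1:5, function(s) {
      m <- synth_rate_map("hex", 30, 5, arena = 150)
      set.seed(1000 + s + round(amp * 17))
      m$rate <- pmax(m$rate + matrix(rnorm(length(m$rate), 0, amp),
                                     nrow(m$rate)), 0)
      as.numeric(grid_score(autocorrelogram(m)))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_scores[1], 1)
  expect_lt(mean_scores[10], 0.2)
  expect_lt(stats::cor(levels, mean_scores, method = "spearman"), -0.8)
})

test_that("field detection recovers analytic size of a single Gaussian bump", {
  for (sig in c(4, 6, 10)) {
    m <- synth_rate_map("hex", 1000, sig, arena = 60)   # one central bump
    fl <- detect_fields(m, threshold = 0.2, min_bins = 4)
    expect_equal(nrow(fl$fields), 1)
    expect_lt(abs(fl$fields$size_cm - 2 * sig * sqrt(2 * log(5))), m$bin_cm)
  }
  # empty map
  m0 <- structure(list(rate = matrix(0, 10, 10), bin_cm = 3),
                  class = "rate_map")
  expect_equal(nrow(detect_fields(m0)$fields), 0)
})

test_that("field spacing is recovered within a bin across fixture spacings", {
  for (sp in c(20, 30, 44, 60, 80)) {
    m <- synth_rate_map("hex", sp, sp / 7, arena = 2.6 * sp)
    fl <- detect_fields(m, min_bins = 4)
    expect_lt(abs(fl$spacing_cm - sp), m$bin_cm + 0.5)
  }
})

test_that("rotating a fixture rotates the measured orientation modulo 60", {
  base <- detect_fields(synth_rate_map("hex", 40, 5, arena = 120),
                        min_bins = 4)$orientation_deg
  for (th in c(10, 25, 40)) {
    rot <- detect_fields(synth_rate_map("hex", 40, 5, arena = 120,
                                        orientation_deg = th),
                         min_bins = 4)$orientation_deg
    d <- (rot - base - th) %% 60
    expect_lt(min(d, 60 - d), 3)
  }
})

test_that("rank-sum comparison matches exact enumeration and echoes inputs", {
  # identical samples: no evidence of a difference
  same <- suppressWarnings(compare_metric_distributions(1:10, 1:10))
  expect_gt(same$p_value, 0.9)
  # exhaustive enumeration for {1,2,3} vs {10,20,30}: all 3 low ranks on
  # one side is the most extreme of choose(6,3)=20 assignments -> p = 0.1
  ext <- compare_metric_distributions(c(1, 2, 3), c(10, 20, 30))
  expect_equal(ext$p_value, 2 / choose(6, 3))
  # medians and IQRs echo the inputs
  cmp <- compare_metric_distributions(c(1, 2, 3, 4, 5), c(2, 4, 6))
  expect_equal(unname(cmp$median["real"]), 3)
  expect_equal(unname(cmp$iqr["real"]), 2)
  expect_error(compare_metric_distributions(c(1, 2), c(1, 2, 3)), "at least 3")
})
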