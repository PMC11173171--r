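test_that("trajectory validation rejects malformed inputs", {
  expect_error(trajectory(c(0, 0.1, 0.1), c(1, 2, 3), c(1, 2, 3), 45),
               "strictly increasing")
  expect_error(trajectory(c(0, 0.1, 0.3), c(1, 2, 3), c(1, 2, 3), 45),
               "constant")
  expect_error(trajectory(c(0, 0.1, 0.2), c(1, 2, 50), c(1, 2, 3), 45),
               "bounds")
})

test_that("plain tracking tables load, interpolate gaps and resample", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t\tx\ty", "0\t10\t10", "0.02\t11\t12", "0.04\t12\t14",
               "0.06\t13\t16"), f)
  tr <- load_trajectory(f, arena = 45)
  expect_s3_class(tr, "trajectory")
  expect_equal(nrow(tr), 4)
  expect_equal(tr$x, 10:13)
  # a NaN gap is filled with the midpoint of its neighbours
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,10,10", "0.02,NaN,NaN", "0.04,12,14"), f2)
  tr2 <- load_trajectory(f2, arena = 45, max_missing = 0.5)
  expect_equal(tr2$x[2], 11)
  expect_equal(tr2$y[2], 12)
  # non-monotonic timestamps refuse to load
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,1", "0.04,2,2", "0.02,3,3"), f3)
  expect_error(load_trajectory(f3), "non-monotonic")
  # excessive missingness refuses to load
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,1", "0.02,NaN,NaN", "0.04,NaN,NaN", "0.06,2,2"), f4)
  expect_error(load_trajectory(f4, max_missing = 0.05), "missing")
})

test_that("trajectories round-trip through the plain text format", {
  tr <- synth_trajectory(10, arena = 45, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  tr2 <- load_trajectory(f, arena = 45)
  expect_equal(tr2$x, tr$x, tolerance = 1e-6)
  expect_equal(tr2$y, tr$y, tolerance = 1e-6)
})

test_that("stationary trajectories have zero speed everywhere", {
  tr <- still_trajectory(2)
  kin <- traj_kinematics(tr)
  expect_true(all(kin$speed == 0))
})

test_that("synthetic foraging respects duration, bounds and speed caps", {
  tr <- synth_trajectory(60, arena = 45, fs = 50, seed = 1)
  expect_equal(nrow(tr), 3000)
  expect_true(all(tr$x >= 0 & tr$x <= 45 & tr$y >= 0 & tr$y <= 45))
  # fast outliers are rare across seeds: < 2% of samples above 90 cm/s
  for (s in 1:5) {
    kin <- traj_kinematics(synth_trajectory(120, 45, seed = s))
    expect_lt(mean(kin$speed > 90), 0.02)
  }
  expect_error(synth_trajectory(10, arena = 5), "10 cm")
  expect_error(synth_trajectory(0, arena = 45), "positive")
  expect_identical(synth_trajectory(20, 45, seed = 9),
                   synth_trajectory(20, 45, seed = 9))
})

test_that("zero turn noise with no wall contact gives a straight path", {
  tr <- synth_trajectory(1.5, arena = 200, speed_mean = 10, speed_sd = 0,
                         turn_sd = 0, seed = 3)
  dx <- diff(tr$x); dy <- diff(tr$y)
  expect_lt(stats::sd(atan2(dy, dx)), 1e-10)
})

test_that("600-s foraging covers most of the arena", {
  for (s in 1:3) {
    tr <- synth_trajectory(600, arena = 45, seed = s)
    bx <- floor(tr$x / 3); by <- floor(tr$y / 3)
    covered <- length(unique(bx * 100 + by)) / (15 * 15)
    expect_gte(covered, 0.8)
  }
})

test_that("conjunctive drive implements rectified cosine speed tuning", {
  ang <- c(E = 0, N = pi / 2, W = pi, S = 3 * pi / 2)
  # stationary: every cell receives exactly the baseline
  tr0 <- still_trajectory(1)
  d0 <- conjunctive_drive(tr0, ang, I_base = 150, g_speed = 4)
  expect_true(all(d0 == 150))
  # due-east movement at constant speed
  n <- 50
  tr <- trajectory(seq_len(n) / 50, seq_len(n) * 0.4, rep(10, n), 45)
  d <- conjunctive_drive(tr, ang, I_base = 150, g_speed = 4)
  mid <- 25
  expect_equal(d["E", mid], 150 + 4 * 20, ignore_attr = TRUE)
  expect_equal(d["N", mid], 150, ignore_attr = TRUE)
  expect_equal(d["S", mid], 150, ignore_attr = TRUE)
  expect_equal(d["W", mid], 150, ignore_attr = TRUE)
})

test_that("total conjunctive drive is non-decreasing in speed at fixed heading", {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  tot <- sapply(c(0, 5, 10, 20, 40), function(s) {
    n <- 50
    tr <- trajectory(seq_len(n) / 50, pmin(10 + seq_len(n) * s / 50, 4000),
                     rep(10, n), 4000)
    sum(conjunctive_drive(tr, ang, 150, 4)[, 25])
  })
  expect_true(all(diff(tot) >= 0))
})

test_that("place drive follows the Gaussian field geometry", {
  centers <- as.matrix(expand.grid(x = seq(2.5, 42.5, 5), y = seq(2.5, 42.5, 5)))
  n <- 50
  tr <- trajectory(seq_len(n) / 50, rep(22.5, n), rep(22.5, n), 45)
  d <- place_drive(tr, centers, g_place = 200, sigma_p = 5)
  at_center <- which(centers[, 1] == 22.5 & centers[, 2] == 22.5)
  expect_equal(d[at_center, 1], 200)
  d15 <- sqrt((centers[, 1] - 22.5)^2 + (centers[, 2] - 22.5)^2)
  far <- which(abs(d15 - 15) < 1e-9)[1]   # at 3 sigma
  expect_equal(d[far, 1], 200 * exp(-4.5))
  # fraction of cells above half-max drive ~ half-max disk area / arena
  # area (uniform field tiling): r_half = sigma * sqrt(2 ln 2)
  frac <- mean(d[, 1] > 100)
  expect_equal(frac, pi * (5 * sqrt(2 * log(2)))^2 / 45^2, tolerance = 0.35)
})

test_that("drive signals are deterministic functions of the trajectory", {
  tr <- synth_trajectory(5, 45, seed = 6)
  ang <- c(0, pi / 2, pi, 3 * pi / 2)
  expect_identical(conjunctive_drive(tr, ang, 150, 4),
                   conjunctive_drive(tr, ang, 150, 4))
  centers <- place_field_centers(build_sheets(
    stats::setNames(rep(100L, 6), default_neuron_params()$name))[["CA1 Pyramidal"]], 45)
  expect_identical(place_drive(tr, centers, 200, 5),
                   place_drive(tr, centers, 200, 5))
})
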