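#' Trajectory object
#'
#' A uniformly sampled animal path in an open-field arena.
#'
#' @param t timestamps (s), uniform sampling.
#' @param x,y positions (cm), within the arena.
#' @param arena arena size (cm), scalar (square) or c(width, height).
#' @return An object of class `trajectory` (data frame `t`, `x`, `y`
#'   with attributes `arena` and `fs`).
#' @export
trajectory <- function(t, x, y, arena) {
  if (length(arena) == 1L) arena <- c(arena, arena)
  if (length(t) < 2L) stop("trajectory: need at least 2 samples")
  dts <- diff(t)
  if (any(dts <= 0)) stop("trajectory: timestamps must be strictly increasing")
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
    stop("trajectory: sampling interval must be constant; resample first")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("trajectory: positions must be finite")
  if (any(x < 0 | x > arena[1] | y < 0 | y > arena[2]))
    stop("trajectory: positions outside arena bounds")
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "arena") <- arena
  attr(out, "fs") <- 1 / stats::median(dts)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Speed and heading along a trajectory
#'
#' Central-difference velocity; speed (cm/s) and heading (radians,
#' atan2 convention). Heading is carried over from the previous sample
#' where the speed is zero.
#'
#' @param traj a [trajectory].
#' @return Data frame with `speed` and `heading` per sample.
#' @export
traj_kinematics <- function(traj) {
  n <- nrow(traj)
  dt <- 1 / attr(traj, "fs")
  ix <- c(2:n, n); il <- c(1, 1:(n - 1))
  span <- (ix - il) * dt
  vx <- (traj$x[ix] - traj$x[il]) / span
  vy <- (traj$y[ix] - traj$y[il]) / span
  speed <- sqrt(vx^2 + vy^2)
  heading <- atan2(vy, vx)
  still <- speed < 1e-9
  if (any(still)) {
    h <- heading
    for (i in seq_len(n)) if (still[i] && i > 1) h[i] <- h[i - 1]
    heading <- h
  }
  data.frame(speed = speed, heading = heading)
}

#' Load a tracking trajectory from a text file
#'
#' Reads a plain delimited table of timestamped positions. The `"xyt"`
#' format expects columns t (s), x (cm), y (cm) — with or without a
#' header; comma, tab or whitespace separated. Gaps (NA positions) are
#' linearly interpolated; the path is then resampled to a uniform rate.
#'
#' @param path file path.
#' @param format `"xyt"`.
#' @param arena arena size (cm); inferred from the data extent
#'   (rounded up) when `NULL`.
#' @param fs resampling rate (Hz); `NULL` keeps the median native rate.
#' @param max_missing maximal tolerated fraction of missing samples.
#' @return A [trajectory].
#' @export
load_trajectory <- function(path, format = "xyt", arena = NULL, fs = NULL,
                            max_missing = 0.05) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("load_trajectory: no such file: ", path)
  l1 <- readLines(path, n = 1L)
  sep <- if (grepl(",", l1)) "," else ""
  header <- grepl("[A-Za-z]", l1)
  tab <- utils::read.table(path, header = header, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("load_trajectory: expected columns t, x, y")
  t <- as.numeric(tab[[1]]); x <- as.numeric(tab[[2]]); y <- as.numeric(tab[[3]])
  if (any(diff(t) <= 0)) stop("load_trajectory: non-monotonic timestamps")
  miss <- !is.finite(x) | !is.finite(y)
  if (mean(miss) > max_missing)
    stop(sprintf("load_trajectory: %.1f%% missing samples exceeds %.1f%%",
                 100 * mean(miss), 100 * max_missing))
  if (any(miss)) {
    x <- stats::approx(t[!miss], x[!miss], xout = t, rule = 2)$y
    y <- stats::approx(t[!miss], y[!miss], xout = t, rule = 2)$y
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  tt <- seq(t[1], t[length(t)], by = 1 / fs)
  xx <- stats::approx(t, x, xout = tt, rule = 2)$y
  yy <- stats::approx(t, y, xout = tt, rule = 2)$y
  if (is.null(arena)) arena <- c(ceiling(max(xx)), ceiling(max(yy)))
  trajectory(tt - tt[1], xx, yy, arena)
}

#' Write a trajectory back to a plain text table
#'
#' @param traj a [trajectory].
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj)[, c("t", "x", "y")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Synthetic open-field foraging trajectory
#'
#' Smooth heading random walk with a Rayleigh-like speed distribution,
#' emulating a mouse foraging in a square arena: speeds are generated by
#' an Ornstein-Uhlenbeck pair (Rayleigh marginal, rescaled to the
#' requested mean and SD), clipped so that well under 2% of samples
#' exceed 90 cm/s; walls reflect both position and heading.
#'
#' @param duration duration (s).
#' @param arena arena size (cm), scalar or c(width, height); >= 10 cm.
#' @param speed_mean mean speed (cm/s).
#' @param speed_sd speed SD (cm/s).
#' @param turn_sd heading diffusion (rad per sqrt(s)).
#' @param fs sampling rate (Hz).
#' @param seed integer seed; the generator is fully reproducible.
#' @param speed_max clip speed (cm/s).
#' @return A [trajectory].
#' @export
#' @examples
#' tr <- synth_trajectory(60, arena = 45, seed = 1)
#' nrow(tr)
synth_trajectory <- function(duration, arena = 45, speed_mean = 15,
                             speed_sd = 8, turn_sd = 1.5, fs = 50,
                             seed = 1L, speed_max = 90) {
  if (duration <= 0) stop("synth_trajectory: duration must be positive")
  if (length(arena) == 1L) arena <- c(arena, arena)
  if (any(arena < 10)) stop("synth_trajectory: arena smaller than 10 cm")
  set.seed(as.integer(seed))
  n <- as.integer(round(duration * fs))
  dt <- 1 / fs
  tau_s <- 1.5                        # speed correlation time (s)
  f <- exp(-dt / tau_s); g <- sqrt(1 - f^2)
  z1 <- z2 <- numeric(n)
  z1[1] <- stats::rnorm(1); z2[1] <- stats::rnorm(1)
  e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
  for (i in 2:n) {
    z1[i] <- z1[i - 1] * f + g * e1[i]
    z2[i] <- z2[i - 1] * f + g * e2[i]
  }
  ray <- sqrt(z1^2 + z2^2)            # Rayleigh(1): mean 1.2533, sd 0.6551
  speed <- speed_mean + speed_sd * (ray - sqrt(pi / 2)) / sqrt(2 - pi / 2)
  speed <- pmin(pmax(speed, 0), speed_max)
  heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n - 1, 0, turn_sd * sqrt(dt))))
  x <- y <- numeric(n)
  x[1] <- arena[1] / 2; y[1] <- arena[2] / 2
  th <- heading
  for (i in 2:n) {
    nx <- x[i - 1] + speed[i] * dt * cos(th[i])
    ny <- y[i - 1] + speed[i] * dt * sin(th[i])
    if (nx < 0 || nx > arena[1]) {          # reflect off vertical walls
      th[i:n] <- pi - th[i:n]
      nx <- if (nx < 0) -nx else 2 * arena[1] - nx
    }
    if (ny < 0 || ny > arena[2]) {          # reflect off horizontal walls
      th[i:n] <- -th[i:n]
      ny <- if (ny < 0) -ny else 2 * arena[2] - ny
    }
    x[i] <- min(max(nx, 0), arena[1])
    y[i] <- min(max(ny, 0), arena[2])
  }
  trajectory(seq_len(n) * dt - dt, x, y, arena)
}

#' Conjunctive (speed-by-direction) drive currents
#'
#' Current into conjunctive cell i at time t:
#' \deqn{I_i(t) = I_{base} + g_{speed}\, s(t)\, \max(0, \cos(\theta(t) - \theta_i))}
#' with s the running speed, theta the movement heading and theta_i the
#' cell's preferred direction. The baseline keeps conjunctive cells
#' tonically active; the rectified cosine targets cells whose preferred
#' direction matches the movement.
#'
#' @param traj a [trajectory], resampled to the drive frame rate.
#' @param preferred_dirs direction labels (from
#'   [assign_preferred_directions()]) or angles (radians) per cell.
#' @param I_base baseline current (pA).
#' @param g_speed speed gain (pA per cm/s).
#' @param I_max current ceiling (pA).
#' @return A `drive_signal`: matrix cells x samples (pA), with `fs`
#'   attribute.
#' @export
conjunctive_drive <- function(traj, preferred_dirs, I_base, g_speed,
                              I_max = 2000) {
  ang <- if (is.character(preferred_dirs)) attr(preferred_dirs, "angle")
         else preferred_dirs
  kin <- traj_kinematics(traj)
  mod <- outer(ang, kin$heading, function(a, h) pmax(0, cos(h - a)))
  I <- I_base + g_speed * sweep(mod, 2, kin$speed, "*")
  I <- pmin(pmax(I, 0), I_max)
  structure(I, fs = attr(traj, "fs"), class = "drive_signal")
}

#' Place-field centers tiling the arena
#'
#' Field centers on the place-cell sheet lattice mapped to arena
#' coordinates by the identity on the sheet indexing, so place cell j
#' anchors the bump phase of the matching stellate cell.
#'
#' @param pop a place population from [build_sheets()].
#' @param arena arena size (cm), scalar or c(width, height).
#' @return Matrix cells x 2 of centers (cm).
#' @export
place_field_centers <- function(pop, arena) {
  if (length(arena) == 1L) arena <- c(arena, arena)
  cbind(pop$pos[, 1] * arena[1], pop$pos[, 2] * arena[2])
}

#' Place-cell drive currents
#'
#' Gaussian spatial tuning: \eqn{I_j(t) = g\, e^{-\|p(t)-c_j\|^2 / 2\sigma_p^2}}.
#'
#' @param traj a [trajectory].
#' @param centers field centers (cm), cells x 2; see
#'   [place_field_centers()].
#' @param g_place peak current at the field center (pA).
#' @param sigma_p field width (cm).
#' @return A `drive_signal` matrix cells x samples (pA).
#' @export
place_drive <- function(traj, centers, g_place, sigma_p = 5) {
  d2 <- outer(centers[, 1], traj$x, "-")^2 + outer(centers[, 2], traj$y, "-")^2
  I <- g_place * exp(-d2 / (2 * sigma_p^2))
  structure(I, fs = attr(traj, "fs"), class = "drive_signal")
}
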