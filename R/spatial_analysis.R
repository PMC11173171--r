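# Gaussian kernel 2-D convolution with renormalisation over valid bins.
# `valid` marks bins allowed to contribute; output bins are sums of
# kernel-weighted contributions divided by the kernel mass that fell on
# valid bins (so edges and holes are handled without bleed-in of zeros).
smooth2d <- function(m, sigma_bins, valid = NULL) {
  if (sigma_bins <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_bins))
  g <- stats::dnorm(-r:r, sd = sigma_bins)
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(m), ncol(m))
  mm <- m; mm[!valid] <- 0
  vv <- matrix(as.numeric(valid), nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  num <- den <- matrix(0, nr, nc)
  for (i in -r:r) {
    rs <- max(1, 1 - i):min(nr, nr - i)
    rt <- rs + i
    for (j in -r:r) {
      cs <- max(1, 1 - j):min(nc, nc - j)
      ct <- cs + j
      w <- kern[i + r + 1, j + r + 1]
      num[rt, ct] <- num[rt, ct] + w * mm[rs, cs]
      den[rt, ct] <- den[rt, ct] + w * vv[rs, cs]
    }
  }
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Spatial firing rate map
#'
#' Bins spike and occupancy counts over the arena, Gaussian-smooths
#' both, and takes their ratio. Bins whose raw occupancy falls below
#' `occ_threshold` are flagged unvisited (NA) and excluded from all
#' downstream statistics.
#'
#' @param spike_times spike times (s) of one cell, on the trajectory
#'   time base.
#' @param traj a [trajectory].
#' @param bin_cm spatial bin (cm).
#' @param smooth_cm Gaussian smoothing width, sigma (cm); 0 disables.
#' @param occ_threshold minimum raw occupancy (s) for a visited bin.
#' @return An object of class `rate_map`: list with `rate` (matrix,
#'   rows = y bins, cols = x bins, spikes/s, NA unvisited), `occupancy`
#'   (s), `spike_count`, `bin_cm`, `smooth_cm`, `arena`.
#' @export
rate_map <- function(spike_times, traj, bin_cm = 3, smooth_cm = 3,
                     occ_threshold = 0.1) {
  if (nrow(traj) == 0L) stop("rate_map: empty trajectory")
  arena <- attr(traj, "arena")
  fs <- attr(traj, "fs")
  nx <- max(1L, ceiling(arena[1] / bin_cm))
  ny <- max(1L, ceiling(arena[2] / bin_cm))
  bx <- pmin(pmax(floor(traj$x / bin_cm), 0), nx - 1)
  by <- pmin(pmax(floor(traj$y / bin_cm), 0), ny - 1)
  occ <- matrix(tabulate(by * nx + bx + 1L, nbins = nx * ny) / fs, ny, nx,
                byrow = TRUE)
  sx <- stats::approx(traj$t, traj$x, xout = spike_times, rule = 2)$y
  sy <- stats::approx(traj$t, traj$y, xout = spike_times, rule = 2)$y
  sbx <- pmin(pmax(floor(sx / bin_cm), 0), nx - 1)
  sby <- pmin(pmax(floor(sy / bin_cm), 0), ny - 1)
  cnt <- matrix(tabulate(sby * nx + sbx + 1L, nbins = nx * ny), ny, nx,
                byrow = TRUE)
  visited <- occ >= occ_threshold
  sig <- smooth_cm / bin_cm
  sm_cnt <- smooth2d(cnt, sig, visited)
  sm_occ <- smooth2d(occ, sig, visited)
  rate <- ifelse(visited & sm_occ > 0, sm_cnt / sm_occ, NA_real_)
  structure(list(rate = rate, occupancy = occ, spike_count = cnt,
                 bin_cm = bin_cm, smooth_cm = smooth_cm, arena = arena,
                 n_spikes = length(spike_times),
                 duration_s = nrow(traj) / fs),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map: %dx%d bins of %g cm; mean %.2f peak %.2f spikes/s\n",
              nrow(x$rate), ncol(x$rate), x$bin_cm,
              mean(x$rate, na.rm = TRUE), max(x$rate, na.rm = TRUE)))
  invisible(x)
}

#' Plot a rate map
#'
#' @param x a [rate_map].
#' @param ... passed to [graphics::image()].
#' @export
plot.rate_map <- function(x, ...) {
  graphics::image(t(x$rate), useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Spatial autocorrelogram
#'
#' Pearson correlation of a rate map with itself at every 2-D lag,
#' computed over the overlapping visited bins only. Lags with fewer
#' than `min_overlap` overlapping bins, or with zero variance in either
#' copy, are set to NA (a fully constant map correlates as 0 by
#' convention).
#'
#' @param map a [rate_map] or a plain matrix (NA = unvisited).
#' @param min_overlap minimum overlapping bin count per lag.
#' @return Matrix of size (2*ny-1) x (2*nx-1); the center element is
#'   the zero lag. Class `autocorrelogram`, with `bin_cm` attribute if
#'   available.
#' @export
autocorrelogram <- function(map, min_overlap = 20) {
  m <- if (inherits(map, "rate_map")) map$rate else map
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, 2 * ny - 1, 2 * nx - 1)
  const_map <- stats::var(as.numeric(m), na.rm = TRUE) == 0
  for (dy in -(ny - 1):(ny - 1)) {
    r1 <- max(1, 1 - dy):min(ny, ny - dy)
    r2 <- r1 + dy
    for (dx in -(nx - 1):(nx - 1)) {
      c1 <- max(1, 1 - dx):min(nx, nx - dx)
      c2 <- c1 + dx
      a <- m[r1, c1]; b <- m[r2, c2]
      ok <- !is.na(a) & !is.na(b)
      nok <- sum(ok)
      if (nok < min_overlap) next
      av <- a[ok]; bv <- b[ok]
      va <- stats::var(av); vb <- stats::var(bv)
      out[dy + ny, dx + nx] <-
        if (va == 0 || vb == 0) {
          if (const_map) 0 else NA_real_
        } else stats::cor(av, bv)
    }
  }
  attr(out, "bin_cm") <- if (inherits(map, "rate_map")) map$bin_cm else NA_real_
  class(out) <- c("autocorrelogram", "matrix")
  out
}

# bilinear interpolation of matrix m at fractional (row, col) positions;
# NA outside or where any of the four corners is NA
bilinear <- function(m, rr, cc) {
  ny <- nrow(m); nx <- ncol(m)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  ok <- r0 >= 1 & r0 + 1 <= ny & c0 >= 1 & c0 + 1 <= nx
  v <- rep(NA_real_, length(rr))
  i <- which(ok)
  if (length(i)) {
    i00 <- cbind(r0[i], c0[i]); i01 <- cbind(r0[i], c0[i] + 1)
    i10 <- cbind(r0[i] + 1, c0[i]); i11 <- cbind(r0[i] + 1, c0[i] + 1)
    v[i] <- m[i00] * (1 - fr[i]) * (1 - fc[i]) + m[i01] * (1 - fr[i]) * fc[i] +
      m[i10] * fr[i] * (1 - fc[i]) + m[i11] * fr[i] * fc[i]
  }
  v
}

# rotational correlation of an autocorrelogram annulus: Pearson between
# two bilinear samplings of the annulus rotated by -angle/2 and
# +angle/2. Splitting the rotation keeps the interpolation loss equal
# across angles (a one-sided rotation is lattice-exact at 90 degrees
# but lossy elsewhere, which biases radially symmetric maps negative).
rotcor <- function(ac, r_in, r_out, angle_deg) {
  ny <- nrow(ac); nx <- ncol(ac)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  rr <- row(ac) - cy; cc <- col(ac) - cx
  dist <- sqrt(rr^2 + cc^2)
  sel <- which(dist >= r_in & dist <= r_out & !is.na(ac))
  if (length(sel) < 10) return(NA_real_)
  y0 <- rr[sel]; x0 <- cc[sel]
  sample_rot <- function(th) {
    xr <- x0 * cos(th) - y0 * sin(th)
    yr <- x0 * sin(th) + y0 * cos(th)
    bilinear(ac, yr + cy, xr + cx)
  }
  th <- angle_deg * pi / 180
  v1 <- sample_rot(-th / 2)
  v2 <- sample_rot(th / 2)
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 10) return(NA_real_)
  stats::cor(v1[ok], v2[ok])
}

# radius (bins) of the central autocorrelogram peak: first ring whose
# mean correlation drops below `level`
central_peak_radius <- function(ac, level = 0.2) {
  ny <- nrow(ac); nx <- ncol(ac)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  dist <- sqrt((row(ac) - cy)^2 + (col(ac) - cx)^2)
  max_r <- floor(min(nx, ny) / 2) - 1
  for (r in seq_len(max_r)) {
    ringv <- ac[dist >= r - 0.5 & dist < r + 0.5]
    if (all(is.na(ringv))) next
    if (mean(ringv, na.rm = TRUE) < level) return(r)
  }
  max(1, floor(max_r / 3))
}

#' Grid score of an autocorrelogram
#'
#' Rotational-symmetry statistic: an annulus around the central peak is
#' correlated with itself rotated by 30, 60, 90, 120 and 150 degrees;
#' the score is min(corr 60, corr 120) minus max(corr 30, 90, 150), in
#' [-2, 2]. Hexagonal patterns give positive scores (60-degree symmetry
#' beats 90-degree), square lattices negative ones. The annulus outer
#' radius is swept and the best score returned (robust to the exact
#' peak-detection radius); the inner radius excludes the central peak.
#'
#' @param ac an [autocorrelogram] (or matrix).
#' @param n_radii number of outer radii swept.
#' @return The grid score (numeric scalar), with attribute `r_out` (the
#'   chosen outer radius, bins) and `r_in`.
#' @export
grid_score <- function(ac, n_radii = 10) {
  ny <- nrow(ac); nx <- ncol(ac)
  r_in <- central_peak_radius(ac)
  r_max <- floor(min(nx, ny) / 2) - 1
  if (r_in >= r_max) return(structure(NA_real_, r_in = r_in, r_out = r_max))
  # annuli must reach the first ring of surrounding peaks: locate it as
  # the ring-averaged correlation maximum beyond the central peak
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  dist <- sqrt((row(ac) - cy)^2 + (col(ac) - cx)^2)
  ring_mean <- vapply((r_in + 2):r_max, function(r)
    mean(ac[dist >= r - 0.5 & dist < r + 0.5], na.rm = TRUE), numeric(1))
  r_peak <- if (all(is.na(ring_mean))) r_in + 2
            else (r_in + 1) + which.max(ring_mean)
  radii <- unique(round(seq(min(r_peak, r_max), r_max, length.out = n_radii)))
  best <- -Inf; best_r <- NA_real_
  for (ro in radii) {
    cs <- vapply(c(30, 60, 90, 120, 150), function(ang)
      rotcor(ac, r_in, ro, ang), numeric(1))
    if (any(is.na(cs))) next
    sc <- min(cs[2], cs[4]) - max(cs[1], cs[3], cs[5])
    if (sc > best) { best <- sc; best_r <- ro }
  }
  if (!is.finite(best)) best <- 0
  structure(best, r_in = r_in, r_out = best_r)
}

#' Detect firing fields in a rate map
#'
#' Fields are connected components (8-neighbourhood) of visited bins
#' above a threshold fraction of the map peak, with at least `min_bins`
#' bins. Field size is the diameter of the circle with the same area.
#' Spacing is the median distance from the field nearest the map center
#' to its nearest-neighbour fields (neighbours within 1.5x the smallest
#' center-to-center distance).
#'
#' @param map a [rate_map].
#' @param threshold field threshold as a fraction of the peak rate.
#' @param min_bins minimum field area (bins).
#' @return A list with `fields` (data frame: `x`, `y` centers in cm,
#'   `area_cm2`, `size_cm`, `peak_rate`), `spacing_cm` (NA if fewer
#'   than 2 fields), and `orientation_deg`.
#' @export
detect_fields <- function(map, threshold = 0.2, min_bins = 9) {
  m <- map$rate
  peak <- suppressWarnings(max(m, na.rm = TRUE))
  empty <- list(fields = data.frame(x = numeric(0), y = numeric(0),
                                    area_cm2 = numeric(0),
                                    size_cm = numeric(0),
                                    peak_rate = numeric(0)),
                spacing_cm = NA_real_, orientation_deg = NA_real_)
  if (!is.finite(peak) || peak <= 0) return(empty)
  above <- !is.na(m) & m >= threshold * peak
  lab <- label_components(above)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  bin <- map$bin_cm
  rows <- row(m); cols <- col(m)
  fields <- do.call(rbind, lapply(seq_len(nlab), function(l) {
    sel <- lab == l
    if (sum(sel) < min_bins) return(NULL)
    w <- m[sel]
    data.frame(x = sum((cols[sel] - 0.5) * bin * w) / sum(w),
               y = sum((rows[sel] - 0.5) * bin * w) / sum(w),
               area_cm2 = sum(sel) * bin^2,
               size_cm = 2 * sqrt(sum(sel) * bin^2 / pi),
               peak_rate = max(w))
  }))
  if (is.null(fields) || nrow(fields) == 0L) return(empty)
  spacing <- NA_real_
  orientation <- NA_real_
  if (nrow(fields) >= 2) {
    ctr <- c(ncol(m), nrow(m)) * bin / 2
    d_ctr <- sqrt((fields$x - ctr[1])^2 + (fields$y - ctr[2])^2)
    ci <- which.min(d_ctr)
    d <- sqrt((fields$x - fields$x[ci])^2 + (fields$y - fields$y[ci])^2)
    d <- d[-ci]
    nn <- d[d <= 1.5 * min(d)]
    spacing <- stats::median(nn)
    ang <- atan2(fields$y - fields$y[ci], fields$x - fields$x[ci]) * 180 / pi
    ang <- ang[-ci][d <= 1.5 * min(d)]
    orientation <- min(ang %% 60)
  }
  list(fields = fields, spacing_cm = spacing, orientation_deg = orientation)
}

# two-pass-free queue flood fill; 8-connectivity component labels
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% ny + 1L
      c <- (q - 1L) %/% ny + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > ny || cc < 1 || cc > nx) next
        idx <- (cc - 1L) * ny + rr
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- cur
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}

#' Grid metrics of one cell
#'
#' Full single-cell measurement: rate map, autocorrelogram, grid score,
#' fields, spacing, orientation, mean and peak rate.
#'
#' @param spike_times spike times (s).
#' @param traj a [trajectory].
#' @param ... passed to [rate_map()].
#' @return A list of class `grid_metrics`.
#' @export
grid_metrics <- function(spike_times, traj, ...) {
  rm_ <- rate_map(spike_times, traj, ...)
  ac <- autocorrelogram(rm_)
  gs <- grid_score(ac)
  fl <- detect_fields(rm_)
  structure(list(
    grid_score = as.numeric(gs),
    mean_rate = length(spike_times) / (nrow(traj) / attr(traj, "fs")),
    peak_rate = suppressWarnings(max(rm_$rate, na.rm = TRUE)),
    field_sizes = fl$fields$size_cm,
    field_size = if (nrow(fl$fields)) stats::median(fl$fields$size_cm)
                 else NA_real_,
    spacing = fl$spacing_cm,
    orientation = fl$orientation_deg,
    n_fields = nrow(fl$fields),
    map = rm_, autocorr = ac),
    class = "grid_metrics")
}

#' @export
print.grid_metrics <- function(x, ...) {
  cat(sprintf("grid_metrics: G=%.3f m=%.2f p=%.2f spikes/s, %d fields, spacing %.1f cm\n",
              x$grid_score, x$mean_rate, x$peak_rate, x$n_fields, x$spacing))
  invisible(x)
}

#' Synthetic rate-map fixture
#'
#' Idealised bump maps with known geometry for validating the metric
#' pipeline: hexagonal or square lattices of Gaussian bumps, or
#' radially symmetric concentric rings.
#'
#' @param pattern `"hex"`, `"square"` or `"rings"`.
#' @param spacing_cm lattice spacing (ring period for `"rings"`).
#' @param sigma_cm bump width (sigma).
#' @param arena arena side (cm).
#' @param bin_cm bin size.
#' @param orientation_deg lattice rotation.
#' @param phase_cm 2-vector lattice offset.
#' @param peak_rate peak firing rate (spikes/s).
#' @param shape `"square"` arena, or `"circle"` for a disk-shaped
#'   visited region (bins outside the inscribed disk are unvisited).
#'   A rotation-invariance null is only well posed on an isotropic
#'   window: a square window itself breaks rotational symmetry.
#' @return A `rate_map` object (uniform occupancy over the visited
#'   region).
#' @export
synth_rate_map <- function(pattern = c("hex", "square", "rings"),
                           spacing_cm = 40, sigma_cm = 6, arena = 100,
                           bin_cm = 3, orientation_deg = 0,
                           phase_cm = c(0, 0), peak_rate = 10,
                           shape = c("square", "circle")) {
  shape <- match.arg(shape)
  pattern <- match.arg(pattern)
  nx <- ceiling(arena / bin_cm); ny <- nx
  xs <- (seq_len(nx) - 0.5) * bin_cm
  ys <- (seq_len(ny) - 0.5) * bin_cm
  ctr <- arena / 2
  m <- matrix(0, ny, nx)
  if (pattern == "rings") {
    d <- sqrt(outer(ys - ctr, xs - ctr, function(a, b) a^2 + b^2))
    m <- peak_rate * (0.5 + 0.5 * cos(2 * pi * d / spacing_cm))
  } else {
    basis <- if (pattern == "hex") {
      rbind(c(1, 0), c(0.5, sqrt(3) / 2)) * spacing_cm
    } else {
      rbind(c(1, 0), c(0, 1)) * spacing_cm
    }
    th <- orientation_deg * pi / 180
    rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    basis <- basis %*% t(rot)
    rng <- ceiling(2 * arena / spacing_cm)
    for (i in -rng:rng) for (j in -rng:rng) {
      c_ <- c(ctr, ctr) + phase_cm + i * basis[1, ] + j * basis[2, ]
      if (c_[1] < -3 * sigma_cm || c_[1] > arena + 3 * sigma_cm ||
          c_[2] < -3 * sigma_cm || c_[2] > arena + 3 * sigma_cm) next
      m <- m + peak_rate *
        exp(-(outer(ys - c_[2], xs - c_[1], function(a, b) a^2 + b^2)) /
              (2 * sigma_cm^2))
    }
  }
  occ <- matrix(1, ny, nx)
  if (shape == "circle") {
    d <- sqrt(outer(ys - ctr, xs - ctr, function(a, b) a^2 + b^2))
    m[d > arena / 2] <- NA_real_
    occ[d > arena / 2] <- 0
  }
  structure(list(rate = m, occupancy = occ,
                 spike_count = m, bin_cm = bin_cm, smooth_cm = 0,
                 arena = c(arena, arena), n_spikes = NA_integer_,
                 duration_s = NA_real_),
            class = "rate_map")
}

#' Compare metric distributions between cohorts
#'
#' Non-parametric two-sided Wilcoxon rank-sum comparison of per-cell
#' metric values (firing rate, field size, spacing, ...), with medians
#' and interquartile ranges.
#'
#' @param real_values,sim_values numeric samples (n >= 3 each).
#' @return A list with `p_value`, `statistic` (rank-sum W), `median`
#'   and `iqr` per group.
#' @export
compare_metric_distributions <- function(real_values, sim_values) {
  real_values <- real_values[is.finite(real_values)]
  sim_values <- sim_values[is.finite(sim_values)]
  if (length(real_values) < 3 || length(sim_values) < 3)
    stop("compare_metric_distributions: need at least 3 values per group")
  # exact where possible; with ties wilcox.test falls back to the
  # normal approximation (its tie warning is expected, not actionable)
  wt <- suppressWarnings(
    stats::wilcox.test(real_values, sim_values, exact = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median = c(real = stats::median(real_values),
                  sim = stats::median(sim_values)),
       iqr = c(real = stats::IQR(real_values),
               sim = stats::IQR(sim_values)))
}
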