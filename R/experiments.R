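#' Designated analysis cells
#'
#' Local indices of the central 3x3 block of the stellate sheet; sweep
#' and preset runs summarise grid scores over these cells (median).
#'
#' @param network a [build_network()] result (or a sheet side).
#' @return Integer vector of 9 local stellate indices.
#' @export
designated_cells <- function(network) {
  s <- if (is.numeric(network)) as.integer(network)
       else network$config$sheet
  ctr <- s %/% 2
  rows0 <- (ctr - 1):(ctr + 1)          # 0-based sheet rows
  cols0 <- (ctr - 1):(ctr + 1)
  as.integer(outer(rows0 * s, cols0 + 1L, "+"))
}

#' Metrics for a set of cells from one simulation
#'
#' @param spikes a `spike_data` object.
#' @param traj the driving [trajectory].
#' @param cells local stellate indices.
#' @param ... passed to [rate_map()].
#' @return Data frame: one row per cell with `cell`, `grid_score`,
#'   `mean_rate`, `peak_rate`, `field_size`, `spacing`, `n_fields`.
#' @export
cells_metrics <- function(spikes, traj, cells, ...) {
  rows <- lapply(cells, function(cl) {
    st <- cell_spike_times(spikes, "MEC LII Stellate", cl, unit = "s")
    gm <- grid_metrics(st, traj, ...)
    data.frame(cell = cl, grid_score = gm$grid_score,
               mean_rate = gm$mean_rate, peak_rate = gm$peak_rate,
               field_size = gm$field_size, spacing = gm$spacing,
               n_fields = gm$n_fields)
  })
  do.call(rbind, rows)
}

#' Run one scale-preset experiment
#'
#' Full simulate-then-analyse pipeline for a dorsoventral scale preset:
#' builds the network for the preset, runs it on the trajectory, and
#' measures the designated stellate cells.
#'
#' @param preset `"large"`, `"intermediate"` or `"small"`.
#' @param traj a [trajectory].
#' @param seed integer seed (connections and initial jitter).
#' @param sheet stellate sheet side.
#' @param config optional [network_config] to use (its preset is
#'   replaced); defaults to `network_config(sheet = sheet, scale = preset)`.
#' @return A list with `metrics` (from [cells_metrics()]), `spacing`
#'   (median over designated cells), `spikes`, `network`.
#' @export
run_scale_preset <- function(preset, traj, seed = 1L, sheet = 20,
                             config = NULL) {
  if (is.null(config)) {
    config <- network_config(sheet = sheet, scale = preset,
                             arena = attr(traj, "arena")[1])
  } else {
    config$preset <- scale_preset(preset)
  }
  net <- build_network(config, seed = seed)
  spikes <- run_simulation(net, traj, seed = seed,
                           record = "MEC LII Stellate")
  cells <- designated_cells(net)
  met <- cells_metrics(spikes, traj, cells)
  list(metrics = met, spacing = stats::median(met$spacing, na.rm = TRUE),
       grid_score = stats::median(met$grid_score, na.rm = TRUE),
       spikes = spikes, network = net)
}

#' Sweep specification
#'
#' One or two parameters, nine values each by convention; parameters
#' may be stellate IM constants (`k`, `a`, `b`, `d`, `C`, `Vr`, `Vt`,
#' `Vpeak`, `Vmin`) or stellate-to-interneuron TM constants (`g`,
#' `tau_d`, `tau_u`, `tau_x`; all three glutamatergic classes are
#' varied together).
#'
#' @param params character vector of 1 or 2 parameter names.
#' @param values list of numeric grids (one per parameter); each must
#'   contain the default value.
#' @param bio_range list of c(lo, hi) biologically realistic bounds per
#'   parameter (config inputs, bracketing the reference values).
#' @param threshold grid-score acceptability threshold.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(params, values, bio_range = NULL, threshold = 0.2) {
  im_names <- c("k", "a", "b", "d", "C", "Vr", "Vt", "Vpeak", "Vmin")
  tm_names <- c("g", "tau_d", "tau_u", "tau_x")
  if (!all(params %in% c(im_names, tm_names)))
    stop("sweep_spec: unknown parameter(s): ",
         paste(setdiff(params, c(im_names, tm_names)), collapse = ", "))
  if (length(params) > 2) stop("sweep_spec: at most two parameters")
  if (length(values) != length(params))
    stop("sweep_spec: one value grid per parameter")
  if (!is.null(bio_range)) {
    for (b in bio_range) if (b[1] > b[2]) stop("sweep_spec: bad bio range")
  }
  structure(list(params = params, values = values, bio_range = bio_range,
                 threshold = threshold,
                 kind = ifelse(params %in% im_names, "IM", "TM")),
            class = "sweep_spec")
}

# build override lists for one sweep point
sweep_overrides <- function(spec, point) {
  neuron_ov <- list()
  synapse_ov <- list()
  stell_in <- c("MEC LII Stellate to EC LII Axo-Axonic",
                "MEC LII Stellate to MEC LII Basket",
                "MEC LII Stellate to EC LII Basket Multipolar")
  for (i in seq_along(spec$params)) {
    p <- spec$params[i]; v <- point[i]
    if (spec$kind[i] == "IM") {
      field <- if (p == "Vmin") "c" else p
      cur <- neuron_ov[["MEC LII Stellate"]]
      cur[[field]] <- v
      neuron_ov[["MEC LII Stellate"]] <- cur
    } else {
      field <- switch(p, g = "g_fast", tau_d = "tau_d_fast",
                      tau_u = "tau_u", tau_x = "tau_x")
      for (cl in stell_in) {
        cur <- synapse_ov[[cl]]
        cur[[field]] <- v
        synapse_ov[[cl]] <- cur
      }
    }
  }
  list(neuron = if (length(neuron_ov)) neuron_ov else NULL,
       synapse = if (length(synapse_ov)) synapse_ov else NULL)
}

#' Run a parameter-robustness sweep
#'
#' For every point of the (1-D or 2-D) parameter grid the network is
#' rebuilt with the modified stellate IM or stellate-to-interneuron TM
#' parameters and re-run on the same (shortened) trajectory; the grid
#' score is the median over the designated stellate cells. A simulation
#' failure (numerical blow-up) marks the cell as NA rather than
#' aborting the sweep.
#'
#' @param spec a [sweep_spec].
#' @param base_config a [network_config] (reduced sheets recommended).
#' @param traj the driving [trajectory] for every point.
#' @param seed integer seed shared across points.
#' @return A list of class `sweep_result`: `scores` (matrix n1 x n2, or
#'   n1 x 1), `above` (threshold mask), `bio` (biological-range mask,
#'   NULL if no ranges), `intersection`, `spec`.
#' @export
run_sweep <- function(spec, base_config, traj, seed = 1L) {
  v1 <- spec$values[[1]]
  v2 <- if (length(spec$values) > 1) spec$values[[2]] else NA
  n1 <- length(v1); n2 <- if (length(spec$values) > 1) length(v2) else 1L
  scores <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    point <- if (n2 > 1L) c(v1[i], v2[j]) else v1[i]
    ov <- sweep_overrides(spec, point)
    sc <- tryCatch({
      net <- build_network(base_config, seed = seed,
                           neuron_overrides = ov$neuron,
                           synapse_overrides = ov$synapse)
      spikes <- run_simulation(net, traj, seed = seed,
                               record = "MEC LII Stellate")
      met <- cells_metrics(spikes, traj, designated_cells(net))
      stats::median(met$grid_score, na.rm = TRUE)
    }, error = function(e) NA_real_)
    scores[i, j] <- sc
  }
  above <- !is.na(scores) & scores > spec$threshold
  bio <- NULL
  if (!is.null(spec$bio_range)) {
    in1 <- v1 >= spec$bio_range[[1]][1] & v1 <= spec$bio_range[[1]][2]
    in2 <- if (n2 > 1L)
      v2 >= spec$bio_range[[2]][1] & v2 <= spec$bio_range[[2]][2]
    else TRUE
    bio <- outer(in1, if (n2 > 1L) in2 else TRUE, "&")
  }
  structure(list(scores = scores, above = above, bio = bio,
                 intersection = if (is.null(bio)) NULL else above & bio,
                 values = spec$values, spec = spec),
            class = "sweep_result")
}

#' Plot a sweep heatmap
#'
#' Bilinear display interpolation of the score matrix with the
#' above-threshold contour; display only.
#'
#' @param x a `sweep_result`.
#' @param ... passed to [graphics::image()].
#' @export
plot.sweep_result <- function(x, ...) {
  sc <- x$scores
  graphics::image(seq_len(nrow(sc)), seq_len(ncol(sc)), sc,
                  xlab = x$spec$params[1],
                  ylab = if (length(x$spec$params) > 1) x$spec$params[2] else "",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  if (any(x$above))
    graphics::contour(seq_len(nrow(sc)), seq_len(ncol(sc)),
                      matrix(as.numeric(x$above), nrow(sc)),
                      levels = 0.5, add = TRUE, drawlabels = FALSE)
  invisible(x)
}

#' Compare simulated and real grid-cell cohorts
#'
#' Wilcoxon rank-sum comparison of per-cell metric distributions
#' (firing rate, field size, spacing), with medians and IQRs per
#' group, mirroring the standard cohort report.
#'
#' @param real_metrics,sim_metrics data frames with matching metric
#'   columns (e.g. `mean_rate`, `field_size`, `spacing`).
#' @param metrics columns to compare; defaults to the intersection.
#' @return Data frame: one row per metric with medians, IQRs and p.
#' @export
cohort_comparison <- function(real_metrics, sim_metrics, metrics = NULL) {
  if (is.null(metrics))
    metrics <- intersect(names(real_metrics), names(sim_metrics))
  metrics <- setdiff(metrics, "cell")
  if (!length(metrics))
    stop("cohort_comparison: no shared metric columns")
  rows <- lapply(metrics, function(m) {
    cmp <- suppressWarnings(
      compare_metric_distributions(real_metrics[[m]], sim_metrics[[m]]))
    data.frame(metric = m,
               median_real = cmp$median[["real"]],
               iqr_real = cmp$iqr[["real"]],
               median_sim = cmp$median[["sim"]],
               iqr_sim = cmp$iqr[["sim"]],
               p_value = cmp$p_value)
  })
  do.call(rbind, rows)
}

#' Calibrate the path-integration gain on constant-velocity runs
#'
#' Drives the network with the conjunctive input a constant virtual
#' velocity would produce (no place anchoring) and measures the
#' attractor pattern's translation speed by subpixel correlation
#' tracking. For a faithful spatial map the pattern should translate at
#' `speed / arena` normalized sheet units per second; the returned
#' table compares measured against target so the speed gain and
#' connection offset can be tuned.
#'
#' @param config a [network_config].
#' @param speeds virtual speeds to probe (cm/s).
#' @param heading_deg movement direction.
#' @param duration probe length per speed (s), after a 3-s settling.
#' @param seed integer seed.
#' @return Data frame with `speed`, `vx`, `vy` (measured, units/s) and
#'   `target` (units/s).
#' @export
calibrate_path_integration <- function(config, speeds = c(5, 15, 25),
                                       heading_deg = 0, duration = 8,
                                       seed = 1L) {
  net <- build_network(config, seed = seed)
  fs <- config$fs
  ang <- attr(net$dirs, "angle")
  n_conj <- net$pops[["EC LI-II Multipolar Pyramidal"]]$count
  mod <- pmax(0, cos(heading_deg * pi / 180 - ang))
  rows <- lapply(speeds, function(spd) {
    conj <- cbind(matrix(config$I_base, n_conj, 3 * fs),
                  matrix(config$I_base + config$g_speed * spd * mod,
                         n_conj, duration * fs))
    sp <- run_network_drives(net, conj_drive = conj, seed = seed)
    tp <- track_pattern(sp, net$pops, window_ms = 500, t_start = 3500,
                        t_end = (3 + duration) * 1000)
    n <- nrow(tp)
    span <- (tp$t[n] - tp$t[1]) / 1000
    data.frame(speed = spd, vx = (tp$x[n] - tp$x[1]) / span,
               vy = (tp$y[n] - tp$y[1]) / span,
               target = spd / config$arena)
  })
  do.call(rbind, rows)
}

#' Stratify cells relative to a reference cohort
#'
#' Grouping rule used when matching simulated cells to a real cohort:
#' values at or below 50% of the reference mean are `"small"`/`"low"`,
#' values above are `"large"`/`"high"`.
#'
#' @param values per-cell metric values.
#' @param reference_mean mean of the real cohort for the metric.
#' @param labels the two stratum labels.
#' @return Factor of strata.
#' @export
cohort_strata <- function(values, reference_mean,
                          labels = c("low", "high")) {
  factor(ifelse(values <= reference_mean, labels[1], labels[2]),
         levels = labels)
}
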