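#' Network configuration
#'
#' Assembles the tunable parameters of a simulation: sheet size, scale
#' preset, arena, integration settings, drive gains and the
#' per-connection-class synaptic weight multipliers (the printed
#' per-synapse conductances are scaled to the simulated population
#' size through these multipliers).
#'
#' @param sheet stellate sheet side; 40 is the full-scale network, 20
#'   the reduced desk-scale network. Interneuron counts scale with the
#'   sheet area.
#' @param scale scale preset name or a [scale_preset] object.
#' @param arena arena side (cm).
#' @param fs drive frame rate (Hz).
#' @param dt integration step (ms).
#' @param substeps membrane sub-iterations per step.
#' @param delay_ms synaptic delay (ms).
#' @param settle_s settling period with stationary drive before the
#'   trajectory starts (s); excluded from analysis.
#' @param I_base conjunctive baseline current (pA).
#' @param g_speed conjunctive speed gain (pA per cm/s).
#' @param g_place peak place-cell current (pA).
#' @param sigma_p place-field width (cm).
#' @param w_scale named numeric multipliers applied on top of the
#'   Table-class conductances; names must match connection-class short
#'   keys `conj`, `place`, `stell_in`, `in_stell`.
#' @param jitter_mv half-width of the uniform initial voltage jitter (mV).
#' @return A list of class `network_config`.
#' @export
network_config <- function(sheet = 20, scale = "intermediate", arena = 90,
                           fs = 50, dt = 0.5, substeps = 2L, delay_ms = 1,
                           settle_s = 2,
                           I_base = 250, g_speed = 8, g_place = 400,
                           sigma_p = 5,
                           w_scale = c(conj = 10, place = 5,
                                       stell_in = 40, in_stell = 8),
                           jitter_mv = 2) {
  preset <- if (is.character(scale)) scale_preset(scale) else scale
  cfg <- list(sheet = as.integer(sheet), preset = preset, arena = arena,
              fs = fs, dt = dt, substeps = as.integer(substeps),
              delay_ms = delay_ms, settle_s = settle_s,
              I_base = I_base, g_speed = g_speed, g_place = g_place,
              sigma_p = sigma_p, w_scale = w_scale, jitter_mv = jitter_mv)
  class(cfg) <- "network_config"
  cfg
}

# population counts for a config: principal sheets are sheet^2, the
# interneuron counts scale from the printed 40x40 values by area
config_counts <- function(cfg) {
  f <- (cfg$sheet / 40)^2
  n_pr <- cfg$sheet^2
  inn <- round(cfg$preset$in_counts * f)
  stats::setNames(
    c(n_pr, n_pr, n_pr, inn),
    c("MEC LII Stellate", "EC LI-II Multipolar Pyramidal", "CA1 Pyramidal",
      "EC LII Axo-Axonic", "MEC LII Basket", "EC LII Basket Multipolar"))
}

#' Build the full network
#'
#' Sheets, preferred directions and the center-surround connection set
#' for a configuration.
#'
#' @param config a [network_config].
#' @param seed integer seed for connection sampling.
#' @param neuron_overrides optional named list: per neuron-type name, a
#'   named list of IM parameters to replace (used by the sweep).
#' @param synapse_overrides optional named list: per connection-class
#'   name, a named list of TM parameters to replace.
#' @return A list of class `can_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L,
                          neuron_overrides = NULL,
                          synapse_overrides = NULL) {
  pops <- build_sheets(config_counts(config))
  if (!is.null(neuron_overrides)) {
    for (nm in names(neuron_overrides)) {
      p <- pops[[nm]]$params
      for (f in names(neuron_overrides[[nm]])) p[[f]] <- neuron_overrides[[nm]][[f]]
      pops[[nm]]$params <- do.call(neuron_params,
        c(p[c("C", "k", "Vr", "Vt", "a", "b", "Vpeak", "c", "d")],
          list(name = nm)))
    }
  }
  dirs <- assign_preferred_directions(pops[["MEC LII Stellate"]])
  conns <- build_cs_connectivity(pops, dirs, config$preset, seed = seed)
  if (!is.null(synapse_overrides)) {
    for (nm in names(synapse_overrides)) {
      i <- match(nm, conns$classes$name)
      if (is.na(i)) stop("unknown connection class in override: ", nm)
      for (f in names(synapse_overrides[[nm]]))
        conns$classes[[f]][i] <- synapse_overrides[[nm]][[f]]
    }
  }
  structure(list(pops = pops, dirs = dirs, conns = conns, config = config,
                 seed = as.integer(seed)),
            class = "can_network")
}

#' @export
print.can_network <- function(x, ...) {
  cat(sprintf("can_network: %dx%d stellate sheet, preset '%s', %d synapses\n",
              x$config$sheet, x$config$sheet, x$config$preset$name,
              nrow(x$conns$edges)))
  invisible(x)
}

# map connection-class index to its weight-multiplier key
class_scale_key <- c("conj", "stell_in", "stell_in", "stell_in",
                     "in_stell", "in_stell", "in_stell", "place")

# assemble flat engine inputs from a network
engine_inputs <- function(network) {
  pops <- network$pops
  cfg <- network$config
  counts <- vapply(pops, `[[`, integer(1), "count")
  offs <- network$conns$offsets
  n <- sum(counts)
  expand <- function(field) {
    unlist(lapply(pops, function(p) rep(p$params[[field]], p$count)),
           use.names = FALSE)
  }
  classes <- network$conns$classes
  n_class <- nrow(classes)
  class_par <- cbind(U = classes$U, tau_u = classes$tau_u,
                     tau_x = classes$tau_x, tau_f = classes$tau_d_fast,
                     tau_s = rep(150, n_class), gf = classes$g_fast,
                     gs = classes$g_slow,
                     Ef = ifelse(classes$sign == "excitatory", 0, -70),
                     Es = ifelse(classes$sign == "excitatory", 0, -90),
                     exc = as.numeric(classes$sign == "excitatory"))
  class_lo <- vapply(classes$post, function(p) offs[[p]], numeric(1))
  class_hi <- class_lo + vapply(classes$post, function(p) counts[[p]],
                                numeric(1))
  e <- network$conns$edges
  w <- e$weight * cfg$w_scale[class_scale_key[e$class]]
  ord <- order(e$pre, e$post)
  syn_ptr <- c(0L, cumsum(tabulate(e$pre[ord], nbins = n)))
  list(n = n, counts = counts, offs = offs,
       C = expand("C"), k = expand("k"), Vr = expand("Vr"),
       Vt = expand("Vt"), a = expand("a"), b = expand("b"),
       Vpeak = expand("Vpeak"), Vreset = expand("c"), d = expand("d"),
       syn_ptr = as.integer(syn_ptr), syn_post = as.integer(e$post[ord] - 1L),
       syn_w = as.numeric(w[ord]), syn_class = as.integer(e$class[ord] - 1L),
       class_par = class_par, class_lo = as.integer(class_lo),
       class_hi = as.integer(class_hi))
}

#' Run the network under trajectory-derived drive
#'
#' Full pipeline step: computes the conjunctive and place drive from the
#' trajectory, prepends a settling period with stationary drive at the
#' starting position, integrates the network and returns spikes with
#' times aligned to the trajectory (settling excluded).
#'
#' @param network a [build_network()] result.
#' @param traj a [trajectory] sampled at the config frame rate.
#' @param seed integer seed for the initial-voltage jitter.
#' @param monitors global neuron indices to record voltage and
#'   per-receptor currents for (optional).
#' @param mon_stride recording stride (steps) for monitors.
#' @param record population names whose spikes are kept (`NULL` = all;
#'   restricting the raster to the populations under analysis keeps
#'   long runs within memory).
#' @return A `spike_data` object: data frame of `id` (global), `pop`,
#'   `local` (index within population), `t` (ms from trajectory start),
#'   plus attributes (`duration_ms`, `dt`, `network` populations,
#'   monitor traces).
#' @export
run_simulation <- function(network, traj, seed = 1L, monitors = integer(0),
                           mon_stride = 1L, record = NULL) {
  cfg <- network$config
  if (abs(attr(traj, "fs") - cfg$fs) > 1e-6)
    stop("run_simulation: trajectory rate differs from config fs")
  conj <- conjunctive_drive(traj, network$dirs, cfg$I_base, cfg$g_speed)
  centers <- place_field_centers(network$pops[["CA1 Pyramidal"]],
                                 attr(traj, "arena"))
  plc <- place_drive(traj, centers, cfg$g_place, cfg$sigma_p)
  # stationary settling frames: zero speed, starting position
  n_settle <- round(cfg$settle_s * cfg$fs)
  if (n_settle > 0) {
    conj <- cbind(matrix(cfg$I_base, nrow(conj), n_settle), conj)
    plc <- cbind(matrix(plc[, 1], nrow(plc), n_settle), plc)
  }
  run_network_drives(network, conj, plc, seed = seed,
                     settle_ms = n_settle / cfg$fs * 1000,
                     monitors = monitors, mon_stride = mon_stride,
                     record = record)
}

#' Run the network under explicit drive matrices
#'
#' Lower-level entry point used by [run_simulation()], by the
#' path-integration calibration and by tests: takes prebuilt drive
#' matrices (cells x frames, pA) for the conjunctive and place
#' populations.
#'
#' @param network a [build_network()] result.
#' @param conj_drive,place_drive drive matrices (may be `NULL` for no
#'   drive); columns are frames at the config frame rate.
#' @param seed seed for initial-voltage jitter.
#' @param settle_ms initial span (ms) subtracted from spike times and
#'   dropped from the returned raster.
#' @param monitors,mon_stride monitor selection as in [run_simulation()].
#' @param I_const optional constant per-neuron current vector (pA).
#' @param record population names whose spikes are kept (`NULL` = all).
#' @return A `spike_data` object.
#' @export
run_network_drives <- function(network, conj_drive = NULL, place_drive = NULL,
                               seed = 1L, settle_ms = 0,
                               monitors = integer(0), mon_stride = 1L,
                               I_const = NULL, record = NULL) {
  cfg <- network$config
  ei <- engine_inputs(network)
  n <- ei$n
  offs <- ei$offs
  frame_steps <- max(1L, as.integer(round(1000 / cfg$fs / cfg$dt)))
  dmat <- NULL; didx <- integer(0)
  if (!is.null(conj_drive)) {
    nc <- nrow(conj_drive)
    dmat <- conj_drive
    didx <- offs[["EC LI-II Multipolar Pyramidal"]] + seq_len(nc) - 1L
  }
  if (!is.null(place_drive)) {
    np <- nrow(place_drive)
    if (!is.null(dmat) && ncol(dmat) != ncol(place_drive))
      stop("run_network_drives: drive matrices must have equal frame counts")
    dmat <- if (is.null(dmat)) place_drive else rbind(dmat, place_drive)
    didx <- c(didx, offs[["CA1 Pyramidal"]] + seq_len(np) - 1L)
  }
  n_frames <- if (is.null(dmat)) 0L else ncol(dmat)
  n_steps <- if (n_frames > 0) n_frames * frame_steps
             else stop("run_network_drives: no drive given; supply matrices")
  if (is.null(I_const)) I_const <- numeric(n)
  pop_of <- rep(names(ei$counts), ei$counts)
  rec_flag <- if (is.null(record)) rep(1L, n)
              else as.integer(pop_of %in% record)
  set.seed(as.integer(seed))
  v0 <- ei$Vr + stats::runif(n, -cfg$jitter_mv, cfg$jitter_mv)
  res <- cpp_run_network(ei$C, ei$k, ei$Vr, ei$Vt, ei$a, ei$b, ei$Vpeak,
                         ei$Vreset, ei$d, v0, numeric(n),
                         ei$syn_ptr, ei$syn_post, ei$syn_w, ei$syn_class,
                         ei$class_par, ei$class_lo, ei$class_hi,
                         if (is.null(dmat)) matrix(0, 1, 1) else dmat,
                         as.integer(didx), frame_steps,
                         I_const, as.integer(n_steps), cfg$dt, cfg$substeps,
                         max(1L, as.integer(round(cfg$delay_ms / cfg$dt))),
                         as.integer(monitors - 1L), as.integer(mon_stride),
                         1000, rec_flag)
  if (!res$ok) {
    cond <- simpleError(sprintf(
      "run_network_drives: numerical blow-up at neuron %d, step %d (t = %.1f ms)",
      res$blow_neuron, res$blow_step, res$blow_step * cfg$dt))
    # last 100 steps of all membrane voltages, rows chronological
    cond$vdump <- res$vdump
    stop(cond)
  }
  id <- res$spike_id + 1L
  t_ms <- res$spike_t - settle_ms
  keep <- t_ms > 0
  sd <- data.frame(id = id[keep], t = t_ms[keep],
                   pop = pop_of[id[keep]],
                   local = id[keep] - offs[pop_of[id[keep]]])
  attr(sd, "duration_ms") <- n_steps * cfg$dt - settle_ms
  attr(sd, "dt") <- cfg$dt
  attr(sd, "counts") <- ei$counts
  attr(sd, "offsets") <- offs
  attr(sd, "settle_ms") <- settle_ms
  if (length(monitors)) {
    attr(sd, "monitors") <- list(idx = monitors, stride = mon_stride,
                                 t = (seq_len(ncol(res$mon_v)) - 1) *
                                   mon_stride * cfg$dt - settle_ms,
                                 v = res$mon_v, ampa = res$mon_ampa,
                                 nmda = res$mon_nmda, gabaa = res$mon_gabaa,
                                 gabab = res$mon_gabab)
  }
  class(sd) <- c("spike_data", "data.frame")
  sd
}

#' Spike times of one cell
#'
#' @param spikes a `spike_data` object.
#' @param pop population name.
#' @param cell local (within-population) cell index.
#' @param unit `"s"` or `"ms"`.
#' @return Numeric vector of spike times.
#' @export
cell_spike_times <- function(spikes, pop, cell, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  t <- spikes$t[spikes$pop == pop & spikes$local == cell]
  if (unit == "s") t / 1000 else t
}

#' Sheet snapshot of population spiking
#'
#' Spike counts within a time window arranged on the population's sheet
#' (the multi-bump attractor state is visible in such snapshots).
#'
#' @param spikes a `spike_data` object.
#' @param pops populations the spikes came from (for sheet geometry).
#' @param pop population name.
#' @param t_start,t_end window (ms).
#' @return Matrix rows x cols of spike counts.
#' @export
sheet_snapshot <- function(spikes, pops, pop = "MEC LII Stellate",
                           t_start, t_end) {
  p <- pops[[pop]]
  sel <- spikes$pop == pop & spikes$t >= t_start & spikes$t < t_end
  counts <- tabulate(spikes$local[sel], nbins = p$count)
  m <- matrix(0, p$rows, p$cols)
  idx <- seq_len(p$count) - 1L
  m[cbind(idx %/% p$cols + 1L, idx %% p$cols + 1L)] <- counts
  m
}

#' Population-vector bump phase
#'
#' Phase of the first spatial Fourier mode of a sheet snapshot, in
#' normalized sheet coordinates [0, 1): the centroid of the (periodic)
#' bump pattern, usable to track attractor translation.
#'
#' @param snapshot matrix from [sheet_snapshot()].
#' @return c(x, y) phase in [0, 1).
#' @export
bump_phase <- function(snapshot) {
  rows <- nrow(snapshot); cols <- ncol(snapshot)
  cx <- (col(snapshot) - 0.5) / cols
  cy <- (row(snapshot) - 0.5) / rows
  px <- Arg(sum(snapshot * exp(2i * pi * cx))) / (2 * pi)
  py <- Arg(sum(snapshot * exp(2i * pi * cy))) / (2 * pi)
  c(x = px %% 1, y = py %% 1)
}

#' Subpixel translation between two sheet snapshots
#'
#' Estimates the toroidal shift that best aligns pattern `b` to pattern
#' `a` by FFT cross-correlation with parabolic sub-bin interpolation.
#' Used to track attractor translation (a multi-bump pattern has almost
#' no power in the first Fourier mode, so centroid-style phase tracking
#' fails; correlation tracking uses all modes).
#'
#' @param a,b matrices of equal size (spike-count snapshots).
#' @return c(dx, dy) shift in normalized sheet units, in (-0.5, 0.5].
#' @export
pattern_shift <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  A <- stats::fft(a - mean(a))
  B <- stats::fft(b - mean(b))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ny <- nrow(a); nx <- ncol(a)
  sub <- function(v, i, n) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    den <- v[im] - 2 * v[i] + v[ip]
    if (den == 0) 0 else 0.5 * (v[im] - v[ip]) / den
  }
  dy <- (pk[1] - 1) + sub(cc[, pk[2]], pk[1], ny)
  dx <- (pk[2] - 1) + sub(cc[pk[1], ], pk[2], nx)
  dx <- dx / nx; dy <- dy / ny
  c(x = ((dx + 0.5) %% 1) - 0.5, y = ((dy + 0.5) %% 1) - 0.5)
}

#' Track attractor translation over time
#'
#' Accumulated subpixel pattern shift between consecutive windows of a
#' run, giving the attractor's translation trajectory in normalized
#' sheet units.
#'
#' @param spikes a `spike_data` object.
#' @param pops populations (sheet geometry).
#' @param window_ms snapshot window.
#' @param t_start,t_end span (ms).
#' @param pop population to track.
#' @return Data frame `t` (ms, window centers), `x`, `y` cumulative
#'   shift (normalized sheet units).
#' @export
track_pattern <- function(spikes, pops, window_ms = 500, t_start = 0,
                          t_end = attr(spikes, "duration_ms"),
                          pop = "MEC LII Stellate") {
  edges <- seq(t_start, t_end, by = window_ms)
  if (length(edges) < 3) stop("track_pattern: span too short")
  snaps <- lapply(seq_len(length(edges) - 1), function(i)
    sheet_snapshot(spikes, pops, pop, edges[i], edges[i + 1]))
  sh <- vapply(seq_len(length(snaps) - 1), function(i)
    pattern_shift(snaps[[i + 1]], snaps[[i]]), numeric(2))
  data.frame(t = edges[-c(1, length(edges))] + window_ms / 2,
             x = cumsum(sh[1, ]), y = cumsum(sh[2, ]))
}

#' Raster plot of network spiking
#'
#' All populations stacked by global index over a time window.
#'
#' @param spikes a `spike_data` object.
#' @param t_start,t_end window (ms); defaults to the full run.
#' @param max_points subsample cap for plotting.
#' @export
plot_raster <- function(spikes, t_start = 0,
                        t_end = attr(spikes, "duration_ms"),
                        max_points = 2e5) {
  sel <- which(spikes$t >= t_start & spikes$t <= t_end)
  if (length(sel) > max_points) sel <- sort(sample(sel, max_points))
  graphics::plot(spikes$t[sel], spikes$id[sel], pch = ".", cex = 0.8,
                 xlab = "time (ms)", ylab = "neuron",
                 main = "network raster")
  offs <- attr(spikes, "offsets")
  graphics::abline(h = offs[-1], col = "grey70")
  invisible(NULL)
}
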