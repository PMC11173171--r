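# Shared fixtures: tiny networks and cached simulation runs so several
# test files can reuse one integration without re-running it.

.fixture_env <- new.env(parent = emptyenv())

# small desk network used by engine tests: 10x10 stellate sheet
tiny_config <- function(settle_s = 1, ...) {
  cfg <- network_config(sheet = 10, arena = 45, settle_s = settle_s, ...)
  cfg$preset$ring_radius <- 0.21
  cfg$preset$ring_width <- 0.12
  cfg$preset$in_sigma <- 0.06
  cfg
}

# one cached stationary run (uniform conjunctive drive, place anchor on)
# reused by the drift, interneuron-lag and snapshot tests
stationary_run <- function() {
  if (!is.null(.fixture_env$station)) return(.fixture_env$station)
  cfg <- network_config(sheet = 20, arena = 90)
  net <- build_network(cfg, seed = 1)
  fs <- cfg$fs
  n_frames <- 12 * fs
  conj <- matrix(cfg$I_base, 400, n_frames)
  centers <- place_field_centers(net$pops[["CA1 Pyramidal"]], 90)
  d2 <- (centers[, 1] - 45)^2 + (centers[, 2] - 45)^2
  plc <- matrix(cfg$g_place * exp(-d2 / (2 * cfg$sigma_p^2)), 400, n_frames)
  sp <- run_network_drives(net, conj_drive = conj, place_drive = plc, seed = 1)
  .fixture_env$station <- list(spikes = sp, net = net, dur_s = 12)
  .fixture_env$station
}

# build a minimal synthetic spike_data object for analysis-level tests
make_spike_data <- function(id, t_ms, counts, duration_ms) {
  pop_of <- rep(names(counts), counts)
  offs <- cumsum(c(0, counts))[seq_along(counts)]
  names(offs) <- names(counts)
  sd <- data.frame(id = id, t = t_ms, pop = pop_of[id],
                   local = id - offs[pop_of[id]])
  attr(sd, "duration_ms") <- duration_ms
  attr(sd, "counts") <- counts
  attr(sd, "offsets") <- offs
  attr(sd, "settle_ms") <- 0
  class(sd) <- c("spike_data", "data.frame")
  sd
}

# constant-position trajectory helper
still_trajectory <- function(duration, arena = 45, fs = 50) {
  n <- round(duration * fs)
  trajectory(seq_len(n) / fs - 1 / fs, rep(arena / 2, n), rep(arena / 2, n),
             arena)
}
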