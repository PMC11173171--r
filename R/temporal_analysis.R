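#' Population firing-rate series
#'
#' Binned combined spiking of one population, normalised to spikes/s
#' per neuron.
#'
#' @param spikes a `spike_data` object.
#' @param pop population name (`NULL` = all neurons).
#' @param bin_ms bin width (ms).
#' @return A list of class `rate_series`: `t` (ms, bin centers), `rate`
#'   (spikes/s per neuron), `fs` (Hz), `n_neurons`.
#' @export
population_rate <- function(spikes, pop = NULL, bin_ms = 1) {
  dur <- attr(spikes, "duration_ms")
  counts <- attr(spikes, "counts")
  n_neurons <- if (is.null(pop)) sum(counts) else sum(counts[pop])
  tt <- if (is.null(pop)) spikes$t else spikes$t[spikes$pop %in% pop]
  n_bins <- max(1L, ceiling(dur / bin_ms))
  h <- tabulate(pmin(floor(tt / bin_ms), n_bins - 1) + 1L, nbins = n_bins)
  structure(list(t = (seq_len(n_bins) - 0.5) * bin_ms,
                 rate = h / (bin_ms / 1000) / n_neurons,
                 fs = 1000 / bin_ms, n_neurons = n_neurons),
            class = "rate_series")
}

# sine-taper multitaper power spectral density (Riedel-Sidorenko
# tapers; closed form, orthonormal). Returns one-sided spectrum.
mtm_psd <- function(x, fs, n_tapers = 7) {
  n <- length(x)
  x <- x - mean(x)
  k <- seq_len(n_tapers)
  tgrid <- seq_len(n)
  P <- 0
  for (ki in k) {
    taper <- sqrt(2 / (n + 1)) * sin(pi * ki * tgrid / (n + 1))
    X <- stats::fft(x * taper)
    P <- P + Mod(X)^2
  }
  P <- P / n_tapers / fs
  half <- floor(n / 2)
  list(freq = (seq_len(half) - 1) * fs / n, power = P[seq_len(half)])
}

#' Spectral band power fractions of a population rate
#'
#' Multitaper (sine-taper) spectral estimate of the population rate
#' series, optionally pre-smoothed with a short Gaussian window to
#' suppress binning harmonics, integrated over the canonical bands:
#' delta 1-4, theta 4-12, beta 12-25 and gamma 25-100 Hz. Fractions are
#' band power over total power in 1-100 Hz.
#'
#' @param series a [population_rate()] result, or a numeric vector with
#'   `fs` supplied.
#' @param fs sampling rate (Hz), taken from `series` when available.
#' @param smooth_ms Gaussian smoothing of the rate series (sigma, ms);
#'   3 ms by default, 0 disables.
#' @param n_tapers number of sine tapers.
#' @param bands named list of c(lo, hi) band edges (Hz).
#' @return A list of class `band_power`: `fractions` (named, in [0,1]),
#'   `peak_freq` per band, `psd` (freq/power), `total_band` = c(1, 100).
#' @export
psd_band_fractions <- function(series, fs = NULL, smooth_ms = 3,
                               n_tapers = 7,
                               bands = list(delta = c(1, 4),
                                            theta = c(4, 12),
                                            beta = c(12, 25),
                                            gamma = c(25, 100))) {
  if (inherits(series, "rate_series")) {
    x <- series$rate; fs <- series$fs
  } else {
    x <- as.numeric(series)
    if (is.null(fs)) stop("psd_band_fractions: fs required for plain vectors")
  }
  if (length(x) / fs < 10)
    stop("psd_band_fractions: series shorter than 10 s")
  if (smooth_ms > 0) {
    sig <- smooth_ms / 1000 * fs
    r <- max(1L, ceiling(3 * sig))
    kern <- stats::dnorm(-r:r, sd = sig)
    kern <- kern / sum(kern)
    x <- stats::filter(x, kern, sides = 2)
    x <- x[!is.na(x)]
  }
  psd <- mtm_psd(x, fs, n_tapers)
  tot_sel <- psd$freq >= 1 & psd$freq <= 100
  total <- sum(psd$power[tot_sel])
  fr <- vapply(bands, function(b) {
    sel <- psd$freq >= b[1] & psd$freq < b[2]
    sum(psd$power[sel]) / total
  }, numeric(1))
  pk <- vapply(bands, function(b) {
    sel <- which(psd$freq >= b[1] & psd$freq < b[2])
    psd$freq[sel[which.max(psd$power[sel])]]
  }, numeric(1))
  structure(list(fractions = fr, peak_freq = pk, psd = psd,
                 total_band = c(1, 100)), class = "band_power")
}

# analytic signal via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# brick-wall FFT band-pass
bandpass_fft <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # mirrored frequency axis
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Mean resultant vector length
#'
#' Magnitude of the average unit phase vector; 0 for uniform phases, 1
#' for perfect locking.
#'
#' @param phases phases (radians).
#' @return MRVL in [0, 1].
#' @export
mrvl <- function(phases) {
  Mod(mean(exp(1i * phases)))
}

#' Rayleigh test of circular uniformity
#'
#' Tests spike phases against uniformity on the circle. Uses
#' Z = n R^2 with the standard series-corrected p approximation.
#'
#' @param phases phases (radians).
#' @return A list with `mrvl`, `z` and `p_value`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  R <- mrvl(phases)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(mrvl = R, z = Z, p_value = max(min(p, 1), 0))
}

#' Spike-phase coupling to a population rhythm
#'
#' Band-passes the reference population rate around its spectral peak
#' inside `band`, extracts the instantaneous phase by the analytic
#' signal, assigns each spike a phase, and quantifies coupling by the
#' mean resultant vector length with a Rayleigh significance test.
#'
#' @param spike_times spike times (ms).
#' @param reference a [population_rate()] result (the phase reference;
#'   typically the combined stellate rate).
#' @param band c(lo, hi) Hz; default the beta band.
#' @param bandwidth half-width (Hz) of the pass band around the peak.
#' @param min_overlap_s required overlap between spikes and reference.
#' @return A list of class `phase_coupling`: `mrvl`, `p_value`, `z`,
#'   `peak_freq`, `phases`, `n_spikes`.
#' @export
spike_phase_coupling <- function(spike_times, reference, band = c(12, 25),
                                 bandwidth = 3, min_overlap_s = 60) {
  if (length(spike_times) < 10)
    stop("spike_phase_coupling: fewer than 10 spikes")
  dur_s <- (max(reference$t) - min(reference$t)) / 1000
  span_s <- (min(max(spike_times), max(reference$t)) -
               max(min(spike_times), min(reference$t))) / 1000
  if (min(dur_s, span_s) < min_overlap_s)
    stop(sprintf(
      "spike_phase_coupling: overlap %.1f s below required %.1f s",
      min(dur_s, span_s), min_overlap_s))
  psd <- mtm_psd(reference$rate - mean(reference$rate), reference$fs)
  sel <- which(psd$freq >= band[1] & psd$freq < band[2])
  peak <- psd$freq[sel[which.max(psd$power[sel])]]
  xf <- bandpass_fft(reference$rate, reference$fs,
                     max(band[1], peak - bandwidth),
                     min(band[2], peak + bandwidth))
  an <- analytic_signal(xf)
  # interpolate the analytic signal, not the wrapped phase
  re <- stats::approx(reference$t, Re(an), xout = spike_times, rule = 2)$y
  im <- stats::approx(reference$t, Im(an), xout = spike_times, rule = 2)$y
  sp_ph <- atan2(im, re)
  rt <- rayleigh_test(sp_ph)
  structure(list(mrvl = rt$mrvl, p_value = rt$p_value, z = rt$z,
                 peak_freq = peak, phases = sp_ph,
                 n_spikes = length(spike_times), band = band),
            class = "phase_coupling")
}
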