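#' Tsodyks-Markram synapse parameter set
#'
#' Parameters of one connection class: short-term plasticity constants
#' (`U`, `tau_u`, `tau_x`) plus conductance amplitudes and decay
#' constants of the fast (AMPA or GABA-A) and slow (NMDA or GABA-B)
#' receptor components. Reversal potentials default to 0 mV for
#' excitatory classes and -70 / -90 mV (GABA-A / GABA-B) for inhibitory
#' ones; the slow excitatory component carries the NMDA magnesium-block
#' voltage dependence.
#'
#' @param g_fast peak fast conductance per unit release (nS).
#' @param tau_d_fast fast decay constant (ms).
#' @param U baseline utilisation, in (0, 1].
#' @param tau_u facilitation time constant (ms).
#' @param tau_x resource recovery time constant (ms).
#' @param g_slow slow-receptor conductance (nS).
#' @param tau_d_slow slow decay constant (ms); 150 ms default for both
#'   NMDA and GABA-B.
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @param E_rev_fast,E_rev_slow reversal potentials (mV); defaults by sign.
#' @param name optional connection-class label.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(g_fast, tau_d_fast, U, tau_u, tau_x,
                           g_slow = 0, tau_d_slow = 150,
                           sign = c("excitatory", "inhibitory"),
                           E_rev_fast = NULL, E_rev_slow = NULL,
                           name = NULL) {
  sign <- match.arg(sign)
  if (is.null(E_rev_fast)) E_rev_fast <- if (sign == "excitatory") 0 else -70
  if (is.null(E_rev_slow)) E_rev_slow <- if (sign == "excitatory") 0 else -90
  if (!is.finite(U) || U <= 0 || U > 1)
    stop("synapse_params: U must lie in (0, 1]")
  if (any(c(tau_d_fast, tau_u, tau_x, tau_d_slow) <= 0))
    stop("synapse_params: all time constants must be positive")
  if (g_fast < 0 || g_slow < 0)
    stop("synapse_params: conductances must be non-negative")
  structure(list(g_fast = g_fast, tau_d_fast = tau_d_fast, U = U,
                 tau_u = tau_u, tau_x = tau_x, g_slow = g_slow,
                 tau_d_slow = tau_d_slow, sign = sign,
                 E_rev_fast = E_rev_fast, E_rev_slow = E_rev_slow,
                 name = name),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("TM synapse", if (!is.null(x$name)) paste0("[", x$name, "]"),
      sprintf("(%s)\n", x$sign))
  cat(sprintf("  g_fast=%g nS tau_d_fast=%g ms  g_slow=%g nS tau_d_slow=%g ms\n",
              x$g_fast, x$tau_d_fast, x$g_slow, x$tau_d_slow))
  cat(sprintf("  U=%g tau_u=%g ms tau_x=%g ms  E_fast=%g mV E_slow=%g mV\n",
              x$U, x$tau_u, x$tau_x, x$E_rev_fast, x$E_rev_slow))
  invisible(x)
}

# Connection-class table. Counts are per presynaptic cell (mean +/- SD);
# the conductances of the center-surround classes are per synapse, with
# simulation-scale multipliers applied in the network config.
.synapse_table <- data.frame(
  name = c("EC LI-II Multipolar Pyramidal to MEC LII Stellate",
           "MEC LII Stellate to EC LII Axo-Axonic",
           "MEC LII Stellate to MEC LII Basket",
           "MEC LII Stellate to EC LII Basket Multipolar",
           "EC LII Axo-Axonic to MEC LII Stellate",
           "MEC LII Basket to MEC LII Stellate",
           "EC LII Basket Multipolar to MEC LII Stellate",
           "CA1 Pyramidal to MEC LII Stellate"),
  pre  = c("EC LI-II Multipolar Pyramidal", "MEC LII Stellate",
           "MEC LII Stellate", "MEC LII Stellate", "EC LII Axo-Axonic",
           "MEC LII Basket", "EC LII Basket Multipolar", "CA1 Pyramidal"),
  post = c("MEC LII Stellate", "EC LII Axo-Axonic", "MEC LII Basket",
           "EC LII Basket Multipolar", rep("MEC LII Stellate", 4)),
  n_mean = c(1, 12, 12, 12, 142, 142, 142, 1),
  n_sd   = c(0, 2, 2, 2, 66, 66, 66, 0),
  g_fast = c(11.627, 1.050, 1.050, 1.050, 0.626, 0.626, 0.626, 9.248),
  tau_d_fast = c(3.380, 3.085, 2.887, 2.641, 4.561, 4.488, 4.948, 3.380),
  U      = c(0.180, 0.167, 0.167, 0.197, 0.145, 0.151, 0.162, 0.123),
  tau_u  = c(49.920, 49.920, 49.920, 49.920, 27.306, 27.810, 30.543, 49.710),
  tau_x  = c(152.856, 167.686, 152.857, 136.570, 420.838, 443.499, 382.485,
             153.400),
  g_slow = c(7.126, 0.644, 0.644, 0.644, 0.383, 0.383, 0.383, 5.668),
  sign   = c("excitatory", "excitatory", "excitatory", "excitatory",
             "inhibitory", "inhibitory", "inhibitory", "excitatory"),
  stringsAsFactors = FALSE
)

#' Default connection-class table
#'
#' The eight modelled connection classes with their TM constants,
#' receptor conductances and per-cell connection counts (mean +/- SD).
#'
#' @param class optional connection-class name; if given, returns that
#'   row as a [synapse_params] object.
#' @return A data frame (or a `synapse_params` when `class` is given).
#' @export
#' @examples
#' default_synapse_params()$name
#' default_synapse_params("MEC LII Stellate to EC LII Axo-Axonic")
default_synapse_params <- function(class = NULL) {
  if (is.null(class)) return(.synapse_table)
  i <- match(class, .synapse_table$name)
  if (is.na(i))
    stop("unknown connection class '", class, "'")
  r <- .synapse_table[i, ]
  synapse_params(r$g_fast, r$tau_d_fast, r$U, r$tau_u, r$tau_x,
                 g_slow = r$g_slow, sign = r$sign, name = r$name)
}

#' Initial (rest) state of a TM synapse
#'
#' Utilisation at 0, resources full, conductances zero.
#'
#' @return A state list with `u`, `x`, `g_syn_fast`, `g_syn_slow`.
#' @export
tm_rest_state <- function() {
  list(u = 0, x = 1, g_syn_fast = 0, g_syn_slow = 0)
}

#' Apply a presynaptic spike to a TM synapse
#'
#' Jump-then-release order: utilisation jumps first,
#' \eqn{u \leftarrow u + U (1 - u)}, then the released fraction
#' \eqn{R = u x} depletes the resources, \eqn{x \leftarrow x - R}, and
#' both receptor conductances increment by their amplitude times `R`.
#'
#' @param state a TM state list (see [tm_rest_state()]).
#' @param params a [synapse_params] object.
#' @return Updated state, with the released fraction attached as `R`.
#' @export
tm_on_spike <- function(state, params) {
  u <- state$u + params$U * (1 - state$u)
  R <- u * state$x
  list(u = u, x = state$x - R,
       g_syn_fast = state$g_syn_fast + params$g_fast * R,
       g_syn_slow = state$g_syn_slow + params$g_slow * R,
       R = R)
}

#' Relax a TM synapse over a spike-free interval
#'
#' Exact exponential update, so the result is independent of how an
#' interval is subdivided: `u` decays toward 0 with `tau_u`, `x`
#' recovers toward 1 with `tau_x`, and each conductance decays with its
#' own `tau_d`.
#'
#' @param state a TM state list.
#' @param params a [synapse_params] object.
#' @param dt interval length (ms), positive.
#' @return Updated state.
#' @export
tm_decay <- function(state, params, dt) {
  stopifnot(dt > 0)
  list(u = state$u * exp(-dt / params$tau_u),
       x = 1 - (1 - state$x) * exp(-dt / params$tau_x),
       g_syn_fast = state$g_syn_fast * exp(-dt / params$tau_d_fast),
       g_syn_slow = state$g_syn_slow * exp(-dt / params$tau_d_slow))
}

#' NMDA magnesium-block voltage dependence
#'
#' Quadratic sigmoid \eqn{s(v) = ((v+80)/60)^2 / (1 + ((v+80)/60)^2)}
#' applied to the slow excitatory (NMDA) conductance; the slow
#' inhibitory (GABA-B) component is voltage-independent.
#'
#' @param v membrane potential (mV).
#' @return Scaling factor in [0, 1).
#' @export
nmda_gate <- function(v) {
  z <- ((v + 80) / 60)^2
  z / (1 + z)
}

#' Receptor current from instantaneous conductances
#'
#' \deqn{I = g_{fast} (E_{fast} - v) + s(v)\, g_{slow} (E_{slow} - v)}
#' with \eqn{s(v)} the NMDA gate for excitatory classes and 1 for
#' inhibitory (GABA-B) classes. Positive current depolarises.
#'
#' @param g_syn_fast,g_syn_slow instantaneous conductances (nS), >= 0.
#' @param v postsynaptic membrane potential (mV).
#' @param params a [synapse_params] object.
#' @return Current (pA).
#' @export
receptor_current <- function(g_syn_fast, g_syn_slow, v, params) {
  if (any(g_syn_fast < 0) || any(g_syn_slow < 0))
    stop("receptor_current: conductances must be non-negative")
  s <- if (params$sign == "excitatory") nmda_gate(v) else 1
  g_syn_fast * (params$E_rev_fast - v) + s * g_syn_slow * (params$E_rev_slow - v)
}

#' Simulate a TM synapse over a spike train
#'
#' Steps the synapse through an arbitrary presynaptic spike train using
#' the exact relaxation between events, optionally sampling the
#' conductance on a regular grid.
#'
#' @param params a [synapse_params] object.
#' @param spike_times presynaptic spike times (ms), increasing.
#' @param duration total time (ms).
#' @param dt sampling step for the returned conductance traces (ms).
#' @return List with `t`, `g_fast`, `g_slow` sampled traces, and
#'   per-spike `release` fractions.
#' @export
tm_train <- function(params, spike_times, duration, dt = 0.5) {
  n <- as.integer(round(duration / dt))
  t_grid <- seq_len(n) * dt
  gf <- gs <- numeric(n)
  release <- numeric(length(spike_times))
  state <- tm_rest_state()
  t_cur <- 0
  k <- 1L
  for (i in seq_len(n)) {
    t_next <- t_grid[i]
    while (k <= length(spike_times) && spike_times[k] <= t_next) {
      if (spike_times[k] > t_cur)
        state <- tm_decay(state, params, spike_times[k] - t_cur)
      state <- tm_on_spike(state, params)
      release[k] <- state$R
      t_cur <- spike_times[k]
      k <- k + 1L
    }
    if (t_next > t_cur) state <- tm_decay(state, params, t_next - t_cur)
    t_cur <- t_next
    gf[i] <- state$g_syn_fast
    gs[i] <- state$g_syn_slow
  }
  list(t = t_grid, g_fast = gf, g_slow = gs, release = release)
}

#' Steady-state release under periodic stimulation
#'
#' Fixed point of the discrete inter-spike map of (`u`, `x`) under a
#' periodic presynaptic train: per period `T = 1000/rate_hz`, the state
#' relaxes exponentially then takes the spike jump. Iterated to
#' convergence; returns the asymptotic released fraction per spike.
#'
#' @param params a [synapse_params] object.
#' @param rate_hz stimulation rate (Hz).
#' @param tol convergence tolerance on (`u`, `x`).
#' @param max_iter iteration cap.
#' @return List with steady-state `u`, `x` (pre-jump values) and release `R`.
#' @export
tm_steady_state <- function(params, rate_hz, tol = 1e-12, max_iter = 10000L) {
  T <- 1000 / rate_hz
  fu <- exp(-T / params$tau_u)
  fx <- exp(-T / params$tau_x)
  u <- 0; x <- 1
  for (i in seq_len(max_iter)) {
    up <- u + params$U * (1 - u)      # post-jump utilisation
    R <- up * x
    u_new <- up * fu                  # relax over the period
    x_new <- 1 - (1 - (x - R)) * fx
    if (abs(u_new - u) < tol && abs(x_new - x) < tol) {
      u <- u_new; x <- x_new; break
    }
    u <- u_new; x <- x_new
  }
  up <- u + params$U * (1 - u)
  list(u = u, x = x, R = up * x)
}
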