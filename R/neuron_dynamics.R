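#' Advance an Izhikevich neuron by one time step
#'
#' Forward-Euler update of the two-variable quadratic model with
#' `substeps` membrane sub-iterations per step (two by default, the usual
#' stabilisation at these capacitances). A spike is assigned to the step
#' in which `v` first reaches `Vpeak`; the reported `v` is clamped to
#' `Vpeak` for that step and the reset is applied internally so the next
#' step starts from (`c`, `u + d`).
#'
#' @param state list with members `v` (mV), `u` (pA) and logical `spiked`;
#'   see [im_rest_state()].
#' @param params a [neuron_params] object.
#' @param I_syn injected plus synaptic current (pA), positive depolarising.
#' @param dt step (ms), positive.
#' @param substeps number of membrane sub-iterations (>= 1).
#' @param neuron,step optional identifiers used in error messages.
#' @return Updated state list (`v`, `u`, `spiked`, and `v_next` holding the
#'   internal post-reset voltage carried into the next step).
#' @export
im_step <- function(state, params, I_syn, dt, substeps = 2L,
                    neuron = NA_integer_, step = NA_integer_) {
  stopifnot(dt > 0, substeps >= 1L)
  v <- if (!is.null(state$v_next)) state$v_next else state$v
  u <- state$u
  if (!is.finite(v) || !is.finite(u) || !is.finite(I_syn))
    stop(sprintf("im_step: non-finite state or input (neuron %s, step %s): v=%g u=%g I=%g",
                 neuron, step, v, u, I_syn))
  h <- dt / substeps
  spiked <- FALSE
  for (s in seq_len(substeps)) {
    v <- v + h * (params$k * (v - params$Vr) * (v - params$Vt) - u + I_syn) / params$C
    if (v >= params$Vpeak) { spiked <- TRUE; break }
  }
  u <- u + dt * params$a * (params$b * (v - params$Vr) - u)
  if (spiked) {
    v_rep <- params$Vpeak
    v_next <- params$c
    u <- u + params$d
  } else {
    v_rep <- v
    v_next <- v
  }
  list(v = v_rep, u = u, spiked = spiked, v_next = v_next)
}

#' Resting state of an Izhikevich neuron
#'
#' (`v = Vr`, `u = 0`) is the exact fixed point of the model at zero
#' input current.
#'
#' @param params a [neuron_params] object.
#' @return A state list usable with [im_step()].
#' @export
im_rest_state <- function(params) {
  list(v = params$Vr, u = 0, spiked = FALSE, v_next = params$Vr)
}

#' Simulate a single Izhikevich neuron under a current trace
#'
#' Reference (pure R) integrator for one neuron, used for rheobase and
#' f-I characterisation and as the subthreshold oracle for the network
#' engine. `I` may be a scalar (constant current) or a vector with one
#' value per step.
#'
#' @param params a [neuron_params] object.
#' @param I injected current (pA), scalar or per-step vector.
#' @param duration simulated time (ms); ignored when `I` is a vector.
#' @param dt step (ms).
#' @param state initial state; defaults to rest.
#' @param substeps membrane sub-iterations per step.
#' @return A list with `t` (ms), `v` (mV, clamped at `Vpeak` on spike
#'   steps), `u`, `spikes` (spike times, ms) and the final `state`.
#' @export
im_simulate <- function(params, I, duration = 1000, dt = 0.5,
                        state = im_rest_state(params), substeps = 2L) {
  n <- if (length(I) > 1L) length(I) else max(1L, as.integer(round(duration / dt)))
  Ivec <- if (length(I) > 1L) I else rep(I, n)
  v <- u <- numeric(n)
  spikes <- numeric(0)
  for (i in seq_len(n)) {
    state <- im_step(state, params, Ivec[i], dt, substeps,
                     neuron = 1L, step = i)
    v[i] <- state$v
    u[i] <- state$u
    if (state$spiked) spikes <- c(spikes, i * dt)
  }
  list(t = seq_len(n) * dt, v = v, u = u, spikes = spikes, state = state)
}

#' Closed-form rheobase of the Izhikevich model
#'
#' Saddle-node current from the nullcline tangency: at
#' \eqn{v^* = (V_r + V_t)/2 + b/(2k)} the quadratic v-nullcline and the
#' linear u-nullcline touch, giving the minimal constant current
#' \deqn{I^* = -k (v^* - V_r)(v^* - V_t) + b (v^* - V_r).}
#' Above \eqn{I^*} no subthreshold equilibrium exists and the neuron
#' fires repetitively.
#'
#' @param params a [neuron_params] object.
#' @return Rheobase current (pA).
#' @export
im_rheobase <- function(params) {
  vstar <- (params$Vr + params$Vt) / 2 + params$b / (2 * params$k)
  -params$k * (vstar - params$Vr) * (vstar - params$Vt) +
    params$b * (vstar - params$Vr)
}

#' Subthreshold equilibrium at a holding current
#'
#' Solves \eqn{k (v - V_r)(v - V_t) - b (v - V_r) + I = 0} (the fixed
#' point with `u` on its nullcline) and returns the lower root, or
#' `NULL` when no equilibrium exists (current above the saddle-node).
#'
#' @param params a [neuron_params] object.
#' @param I holding current (pA).
#' @return State list at the equilibrium, or `NULL`.
#' @export
im_equilibrium <- function(params, I) {
  A <- params$k
  B <- -params$k * (params$Vr + params$Vt) - params$b
  C2 <- params$k * params$Vr * params$Vt + params$b * params$Vr + I
  disc <- B^2 - 4 * A * C2
  if (disc < 0) return(NULL)
  v <- (-B - sqrt(disc)) / (2 * A)
  list(v = v, u = params$b * (v - params$Vr), spiked = FALSE, v_next = v)
}

#' Simulated rheobase by bisection
#'
#' Minimal constant current that elicits a spike within the window.
#' For each tested current the neuron starts from its subthreshold
#' equilibrium when one exists (the standard rheobase protocol:
#' rheobase is the current at which the resting equilibrium
#' disappears); with no equilibrium it starts from rest. Resonator
#' parameter sets (large `b`, e.g. stellate cells) fire transiently
#' from a cold rest start well below the saddle-node current, which is
#' why the equilibrium initialisation matters.
#'
#' @param params a [neuron_params] object.
#' @param I_range search bracket (pA).
#' @param window_ms spike-detection window (ms).
#' @param dt step (ms).
#' @param tol bisection tolerance (pA).
#' @return Estimated rheobase (pA).
#' @export
im_rheobase_sim <- function(params, I_range = c(0, 1000), window_ms = 1000,
                            dt = 0.5, tol = 0.5) {
  fires <- function(I) {
    st <- im_equilibrium(params, I)
    if (is.null(st)) st <- im_rest_state(params)
    length(im_simulate(params, I, window_ms, dt, state = st)$spikes) > 0
  }
  lo <- I_range[1]; hi <- I_range[2]
  if (fires(lo)) return(lo)
  if (!fires(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulated frequency-current curve
#'
#' Firing rate of a neuron under constant current steps, from rest, over
#' a fixed window.
#'
#' @param params a [neuron_params] object.
#' @param I_values currents to test (pA).
#' @param duration window per current (ms).
#' @param dt step (ms).
#' @return Data frame with `I` (pA) and `rate` (spikes/s).
#' @export
im_fi_curve <- function(params, I_values, duration = 1000, dt = 0.5) {
  rate <- vapply(I_values, function(I) {
    length(im_simulate(params, I, duration, dt)$spikes) / (duration / 1000)
  }, numeric(1))
  data.frame(I = I_values, rate = rate)
}
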