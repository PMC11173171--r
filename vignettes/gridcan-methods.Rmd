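---
title: "Model and methods behind gridcan"
author: "gridcan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind gridcan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridcan)
```

`gridcan` simulates a spiking continuous attractor network (CAN) of
medial entorhinal cortex grid cells and measures its output with the
standard grid-cell physiology pipeline. This vignette is the package's
account of the science: the model and its assumptions, the parameters
that matter, the synthetic-data generators, the numerical choices, and
what the desk-scale tests do and do not establish.

## 1. Neuron model

Every neuron follows the 9-parameter Izhikevich quadratic model

$$C\,\dot v = k\,(v - V_r)(v - V_t) - u + I,\qquad
  \dot u = a\,\bigl(b\,(v - V_r) - u\bigr),$$

with a spike recorded when $v \ge V_{peak}$, followed by $v \leftarrow
c$ and $u \leftarrow u + d$. Six neuron types are modelled
(`default_neuron_params()`): MEC LII stellate cells play the grid
cells; EC LI-II multipolar pyramidal cells the conjunctive
(speed-by-direction) cells; CA1 pyramidal cells the place cells; and
three fast-spiking parvalbumin-positive interneuron classes
(axo-axonic, basket, basket multipolar) share standard fast-spiking
constants, since interneuron-specific measurements are too scarce to
constrain separate fits. CA1 pyramidal cells carry a negative `b`, so
the recovery variable is allowed below zero.

**Integration.** Forward Euler with `dt = 0.5` ms and two membrane
sub-iterations per step; `u` advances once per step. A spike is
assigned to the step in which $v$ first reaches $V_{peak}$; the
reported trace is clamped at $V_{peak}$ for that step. At the working
step, fast-spiking 1-s spike counts carry a few percent rate error;
counts converge to within one spike per halving from `dt = 0.125` ms
(the tests assert exactly this). The working step is a deliberate
trade: the network-level phenomena studied here (pattern formation,
translation, rhythms) are insensitive to it, and it keeps a 10-minute
session of ~2,000 neurons inside a few minutes of wall time.

**Rheobase.** `im_rheobase()` returns the closed-form saddle-node
current $I^* = -k(v^*-V_r)(v^*-V_t) + b(v^*-V_r)$ at the nullcline
tangency $v^* = (V_r+V_t)/2 + b/2k$. One subtlety matters for the
stellate parameters: because $b/C \gg a$, the cell is a resonator —
the subthreshold equilibrium loses stability (Hopf) well below $I^*$,
and a cold start from rest fires transiently at even lower currents
because $u$ lags $v$. The minimal current at which *no subthreshold
equilibrium exists* is $I^*$, so `im_rheobase_sim()` initialises each
probe at the subthreshold equilibrium when one exists. Under that
standard protocol the simulated and closed-form rheobase agree to
within 1 pA for every modelled type.

## 2. Synapse model

Connections use Tsodyks–Markram short-term plasticity. On each
presynaptic spike, utilisation jumps first,
$u \leftarrow u + U(1-u)$, the released fraction is $R = u\,x$, and
resources deplete, $x \leftarrow x - R$ (facilitation-capable variant;
baseline $u = 0$). Between spikes $u$, $x$ and both conductances relax
with exact exponentials (`tm_decay()`), so spike-free intervals are
step-size independent and the stepped trace equals the event-driven
closed form to machine precision — the test suite holds it to 1e-9
over a 20 Hz train.

Each connection class carries a fast and a slow receptor:
AMPA + NMDA for excitatory classes, GABA-A + GABA-B for inhibitory.
Currents are conductance-based,
$I = g_f\,(E_f - v) + s(v)\,g_s\,(E_s - v)$, with reversal potentials
0 mV (AMPA/NMDA), −70 mV (GABA-A), −90 mV (GABA-B); these standard
values are package choices, as are the 150 ms slow decay constants.
The NMDA magnesium block is the quadratic sigmoid
$s(v) = z/(1+z)$, $z = ((v+80)/60)^2$; GABA-B is voltage-independent.
The per-class constants (`default_synapse_params()`) are the measured
mouse values for the eight modelled connection classes; the printed
conductances are per synapse and are brought to simulation scale by
the per-class multipliers in `network_config()` (section 4).

## 3. Network architecture

Populations live on 2-D sheets spanning a common normalized coordinate
space with periodic (toroidal) boundaries; principal populations
(stellate, conjunctive, place) are square sheets aligned one-to-one,
interneurons use the smallest near-square sheet holding their count.
Stellate cells are labelled with N/S/E/W preferred directions in 2×2
blocks, so every direction is equally represented and locally
interleaved.

**Center-surround rings.** Each stellate cell contacts interneurons
lying on an annulus whose center is the cell's position shifted by
`offset` along its preferred direction; each interneuron projects back
onto stellate cells in a Gaussian neighbourhood of itself
(`in_sigma`), weighted by the Gaussian. The composite disynaptic
kernel is an annulus with Gaussian falloff and an untouched inner
disk: bump centers survive through the *absence* of inhibition (there
are no stellate–stellate excitatory connections), and the directional
ring displacement is what converts asymmetric drive into pattern
motion.

**Counts and sampling.** Connection counts per cell are drawn to the
published means ± SDs (12 ± 2 stellate→interneuron per type at the
intermediate scale, 142 ± 66 back, one-to-one for conjunctive and
place inputs), and stellate→interneuron connectivity is capped at the
reported 25.9% ceiling. Membership, in contrast, is deliberately
low-discrepancy: the k ring targets are spread evenly around the
annulus at a random rotation, and the interneuron's m stellate targets
are the nearest m. With only ~12 samples per ring, unstructured
sampling leaves ~30% frozen azimuthal noise in each cell's inhibitory
footprint; that quenched disorder pins the attractor pattern to the
sheet and defeats velocity-driven translation. Spreading the samples
preserves every censused statistic while keeping the mean kernel
smooth. All draws derive from one integer seed, in fixed row-major
order, so a connection set is exactly reproducible.

**Scale presets.** The dorsoventral axis is modelled by three presets
(`scale_preset()`): ring radius 0.15 / 0.21 / 0.30 of the sheet for
small / intermediate / large, with ring width $= 4/7$ radius and
inhibitory footprint $\sigma = 2/7$ radius (geometric similarity), 16
/ 12 / 5 stellate→interneuron connections, and 1200 interneurons per
type at the large scale (834/833/833 otherwise). Radii were chosen
from pattern-formation screens (bump counts and sheet-lattice spacing
under uniform drive); the measured map spacing then orders as small <
intermediate < large (≈37 / 49 / 60 cm on a 110 cm arena) without
further adjustment.

## 4. External drive and path integration

Conjunctive cells receive
$I_i(t) = I_{base} + g_{speed}\, s(t)\, \max(0, \cos(\theta(t) -
\theta_i))$ — a tonic baseline plus rectified-cosine direction tuning
of the running (not head) direction. Place cells receive Gaussian
spatial tuning $g_{place} \exp(-\|p - c_j\|^2 / 2\sigma_p^2)$ with
field centers on the sheet lattice mapped identically to arena
coordinates, so place input anchors the attractor phase to position
and corrects path-integration drift; its known side effect, visible in
the simulated maps, is extra firing in the anchored field relative to
the others.

Defaults (`network_config()`): `I_base` 250 pA (conjunctive cells
tonically active near 11 Hz), `g_speed` 8 pA/(cm/s), `g_place` 400 pA,
`sigma_p` 5 cm, and weight multipliers (conj 10, place 5,
stellate→IN 40, IN→stellate 8) scaling the per-synapse conductances to
the simulated population sizes. These were calibrated in two stages:
first pattern-translation probes under constant virtual velocity
(`calibrate_path_integration()`, which tracks the pattern by subpixel
FFT correlation — the first Fourier mode of a multi-bump pattern is
near zero, so centroid phase tracking is uninformative), then
full-pipeline grid-score runs. Translation in the reduced network is
thresholded and noisy rather than cleanly linear in speed — lattice
pinning on a 20×20 sheet is strong — which is precisely why the place
anchor matters at desk scale.

## 5. Simulation engine

The C++ core steps the whole network per `dt`: decay per-class
conductance accumulators, deliver spikes after a 1 ms axonal delay
(event-driven TM update per synapse, elapsed-time exponentials),
accumulate receptor currents, advance all neurons, record. Monitors
capture voltage and the four receptor-group currents for selected
neurons. The engine contains no random numbers; the only stochastic
inputs are the connectivity seed and a ±2 mV uniform initial-voltage
jitter drawn in R, so a (seed, config) pair yields bit-identical spike
rasters. Numerical blow-up (|v| > 1000 mV) aborts with the last 100
steps of all membrane voltages attached. Spike recording can be
restricted to the populations under analysis; interneurons fire near
100 Hz, and a full 10-minute raster of all types would dominate
memory.

A 2-s settling period with stationary drive at the starting position
precedes every trajectory and is excluded from all analyses.

## 6. Measurement pipeline

Rate maps bin spikes and occupancy (defaults: 3 cm bins, 3 cm Gaussian
smoothing, 0.1 s occupancy threshold), smooth both with
mass-renormalised kernels over visited bins, and divide. The
autocorrelogram is the per-lag Pearson correlation over overlapping
visited bins (≥ 20 bins per lag; a constant map correlates as 0 by
convention). The grid score correlates an annulus around the central
peak with itself rotated by 30–150°: score = min(corr 60°, 120°) −
max(corr 30°, 90°, 150°). Two implementation details are worth
recording. First, the rotation is split ±angle/2 and both copies are
bilinearly resampled, so interpolation loss is identical across
angles; a one-sided rotation is lattice-exact at 90° and systematically
biases radially symmetric maps negative. Second, the annulus sweep
(the outer radius is swept and the best score kept) starts at the
first ring of autocorrelogram peaks, located as the ring-averaged
correlation maximum; annuli that end before the first peak ring
contain only featureless background and would inflate square-lattice
scores toward zero. A genuinely radially symmetric null is only well
posed on an isotropic window — a square window itself breaks
rotational symmetry of the autocorrelogram — so the concentric-ring
fixture supports a circular (disk-masked) arena.

Fields are 8-connected components above 0.2 of the map peak with ≥ 9
bins (fixtures in the tests use a smaller minimum because their maps
are unsmoothed); field size is the equal-area-circle diameter, and
spacing is the median distance from the field nearest the map center
to its nearest-neighbour fields (within 1.5× the smallest
center-to-center distance, which excludes the √3-ring of a hexagonal
lattice). On noiseless fixtures the pipeline recovers spacing within a
bin across 20–80 cm and Gaussian field size $2\sigma\sqrt{2\ln 5}$
within a bin across $\sigma$ = 2–10 cm.

Population rhythms use 1-ms binned population rates, a 3-ms Gaussian
pre-smoothing, and a sine-taper (Riedel–Sidorenko) multitaper spectrum
with 7 tapers; band fractions integrate delta 1–4, theta 4–12, beta
12–25 and gamma 25–100 Hz against total 1–100 Hz power. Sine tapers
are used because they have closed forms (no large eigenproblem) and
orthonormality; the estimator choice is configurable at the smoothing
and taper-count level. Spike-phase coupling band-passes the reference
population rate around its in-band spectral peak, extracts phase by
the analytic signal (interpolating the complex signal, not the wrapped
phase), and reports the mean resultant vector length with the Rayleigh
test ($Z = nR^2$ with the standard series correction).

## 7. Synthetic data

`synth_trajectory()` emulates open-field foraging: a smooth heading
random walk (default diffusion 1.5 rad/√s), speeds from a smoothed
Ornstein–Uhlenbeck pair with Rayleigh marginal rescaled to mean 15 and
SD 8 cm/s (clipped at 90 cm/s; well under 2% of samples approach the
clip), and reflective walls. Ten minutes covers ≥ 80% of 3-cm bins in
a 45-cm arena. What it does not emulate: wall-following and thigmotaxis,
pauses and grooming bouts, reward-directed runs, and head direction
distinct from movement direction. Fixture rate maps
(`synth_rate_map()`) provide ideal hexagonal, square-lattice and
concentric-ring patterns with known spacing, bump width, orientation
and phase. Passing tests on these generators establishes that the
*pipeline* is correct and that the *model* can produce grid-like maps
under realistic foraging statistics — not that it reproduces every
property of any particular animal's recordings.

## 8. Desk-scale experiments and their limits

The reduced network used throughout the tests is a 20×20 stellate
sheet (400 grid cells, ~1,800 neurons in total) driven by a 10-minute
synthetic trajectory in a 90-cm arena, with metrics summarised as the
median over the central 3×3 "designated" stellate cells. With the
default seed pair this run yields a median grid score of 0.29 (above
the 0.2 acceptability threshold), stellate mean rates near 1.4
spikes/s, multi-bump population snapshots, and interneuron activity
lagging stellate activity by a few milliseconds. Across other seed
pairs the median fluctuates around the threshold (roughly −0.1 to
0.3): at this scale the attractor's mirror-degenerate lattice
configurations occasionally remap mid-session and smear the
non-anchored fields. This variability is a real property of the
reduced network, not averaged away, and is the main reason the
full-scale network (40×40 sheet, 9,300 neurons, hours-long sessions)
gives cleaner statistics.

Parameter-robustness sweeps (`run_sweep()`) rebuild the network at
each of up to 9×9 grid points — stellate IM constants or
stellate→interneuron TM constants, all three glutamatergic classes
varied together — on a shortened trajectory, score the designated
cells, and mask the matrix by the 0.2 threshold and by
biologically-realistic ranges supplied as configuration (the package
does not re-derive those ranges; deriving them requires fitting firing
patterns to experimental recordings, which is out of scope). Heatmap
interpolation is bilinear and display-only.

## 9. Known limitations

- Path integration in the reduced network relies on place-cell
  anchoring; pure velocity-driven translation is thresholded by
  lattice pinning and is not metrically calibrated across the full
  speed range.
- Euler integration at 0.5 ms carries a few percent firing-rate bias
  for fast-spiking cells (quantified in section 1).
- No long-term plasticity, no stochastic vesicle release, no theta
  oscillator, no boundary cells or visual landmarks, no
  grid-to-place feedback; speed coding is purely excitatory.
- The square-torus sheet quantizes admissible lattice spacings and
  admits mirror-degenerate configurations; large-scale rings that
  overlap around the torus compress the realized spacing below the
  kernel's natural wavelength.
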