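# gridcan

Spiking continuous attractor network (CAN) model of medial entorhinal
cortex (MEC) grid cells, with the full grid-cell physiology analysis
suite.

## The scientific problem

Grid cells in MEC layer II fire at the vertices of a hexagonal lattice
tiling the environment. Continuous attractor models explain this by a
sheet of recurrently coupled neurons whose stable states are multi-bump
activity patterns: center-surround inhibition makes bumps form, and
velocity-tuned input translates the pattern as the animal moves, so each
cell's firing traces a spatial grid. `gridcan` implements this model at
the level of spiking neurons with measured biophysics:

- **Izhikevich neurons** — the 9-parameter quadratic model
  `C v' = k (v - V_r)(v - V_t) - u + I`, `u' = a (b (v - V_r) - u)`,
  with type-specific constants for MEC LII stellate cells (the grid
  cells), EC LI-II multipolar pyramidal cells (conjunctive
  speed-by-direction cells), CA1 pyramidal cells (place cells), and
  three fast-spiking parvalbumin interneuron types (axo-axonic, basket,
  basket multipolar).
- **Tsodyks–Markram synapses** — short-term facilitation/depression
  (`U`, `tau_u`, `tau_x`) with conductance-based AMPA, NMDA, GABA-A and
  GABA-B receptor currents per connection class.
- **Center-surround connectivity** — each stellate cell excites
  interneurons on an annulus whose center is displaced along the cell's
  preferred direction (N/S/E/W); interneurons inhibit the stellate
  sheet around themselves. The disynaptic composite is ring-shaped
  inhibition with a quiet center, the CAN ingredient; the directional
  displacement converts asymmetric conjunctive drive into bump motion.
- **External drive** — conjunctive cells receive
  `I = I_base + g_speed * s(t) * max(0, cos(heading - preferred))`;
  place cells receive Gaussian spatial tuning and anchor the attractor
  phase against drift. Trajectories come from plain tracking tables or
  a built-in smooth-heading foraging generator.
- **Analysis** — occupancy-normalised rate maps, spatial
  autocorrelograms, the 60-vs-90-degree rotational grid score, field
  detection (size, spacing, orientation), rank-sum cohort comparisons,
  sine-taper multitaper band power (delta/theta/beta/gamma), and
  spike-phase coupling (MRVL + Rayleigh test).
- **Experiments** — dorsoventral scale presets (large / intermediate /
  small rings with 5 / 12 / 16 stellate-to-interneuron connections),
  and 1-D/2-D robustness sweeps over stellate IM and stellate-to-IN TM
  parameters against the 0.2 grid-score acceptability threshold.

## Worked example

```r
library(gridcan)

## single-cell physiology: stellate rheobase, closed form vs simulated
st <- default_neuron_params("MEC LII Stellate")
im_rheobase(st)        # 177.8 pA  (saddle-node of the nullclines)
im_rheobase_sim(st)    # 178.0 pA  (bisection on simulated spiking)

## full-scale intermediate network and its connectivity census
cfg <- network_config(sheet = 40, scale = "intermediate")
net <- build_network(cfg, seed = 1)
cen <- connectivity_census(net$conns, net$pops)
cen[c(2, 5), c("class", "n_syn", "out_mean", "out_sd")]
#                                  class  n_syn out_mean out_sd
#  MEC LII Stellate to EC LII Axo-Axonic  19070    11.92   2.06
#  EC LII Axo-Axonic to MEC LII Stellate 118857   142.51  65.36

## measurement pipeline on a known hexagonal fixture
m <- synth_rate_map("hex", spacing_cm = 44, sigma_cm = 6, arena = 100)
grid_score(autocorrelogram(m))   # 1.40  (> 0.2 threshold)
detect_fields(m)$spacing_cm      # 43.9 cm

## reduced simulation: grids from 10 minutes of synthetic foraging
cfg  <- network_config(sheet = 20, arena = 90)
net  <- build_network(cfg, seed = 1)
traj <- synth_trajectory(600, arena = 90, speed_mean = 15, seed = 2)
sp   <- run_simulation(net, traj, seed = 1, record = "MEC LII Stellate")
met  <- cells_metrics(sp, traj, designated_cells(net))
median(met$grid_score)           # 0.289 over the 9 central cells
```

The census means land on the published connection counts (12 ± 2
stellate-to-axo-axonic, 142 ± 66 back), the fixture pipeline recovers
its ground truth, and the reduced network's central cells pass the 0.2
grid-score acceptability criterion after ten minutes of simulated
foraging (2–3 minutes of wall time).

A thin command-line front end is installed at `exec/gridcan`
(`simulate`, `analyze`, `census`, `sweep` subcommands).

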