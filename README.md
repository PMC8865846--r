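# swrnet

Sharp wave-ripples (SWRs) are brief population bursts of the hippocampus,
carrying a 150-220 Hz "ripple" oscillation, during which place-cell firing
sequences from previous exploration are replayed in either direction.
`swrnet` is an R package that simulates how both phenomena can arise from
one substrate: the recurrent excitatory synapses of a CA3-like network,
structured by spike-timing-dependent plasticity (STDP) during exploration.

It is aimed at computational neuroscientists who want a self-contained,
tested implementation of the full chain

```
place-cell spike synthesis -> STDP learning -> spiking-network simulation
      -> LFP & spectral analysis -> Bayesian replay decoding
```

together with the structural perturbations that dissect the mechanism
(weight scaling / binarization / column shuffling, asymmetric-kernel
learning, non-adapting cells, interneuron-only networks, cued replay).

## The model in brief

**Exploration.** A population of 8000 cells runs a 3 m linear track at
32.5 cm/s; 4000 random cells get Gaussian place fields (common width
`sigma` solving `exp(-(l/2)^2 / 2 sigma^2) = 0.1`, i.e. the rate falls to
10% of its 20 Hz peak at the edges of the 30 cm field). A place cell's
rate is

```
lambda_i(t) = lambda_max * tau_i(x(t)) * cos(2 pi f_theta t + pi/l_PF (x(t) - s_i))
```

(7 Hz theta, phase precessing through 180 degrees across the field;
negative values clipped), realized as an inhomogeneous Poisson process by
thinning with a 5 ms dead time.

**Learning.** Pair-based additive STDP with all-to-all exponential-trace
pairing on a fixed sparse random graph (10% connectivity, no self-edges):
`dw = A exp(-|dt|/tau)` with the broad *symmetric* kernel
(`A+ = A- = 80 pA`, `tau = 62.5 ms`) measured between CA3 pyramidal
cells, weights cropped to [0, 20 nS] online.

**Offline network.** 8000 adapting exponential integrate-and-fire
pyramidal cells (PCs) + 150 fast-spiking basket cells (PVBCs), biexponential
conductance synapses with per-pathway delays, and 15 Hz Poisson
mossy-fiber drive. Forward Euler at dt = 0.1 ms (convergence-tested).

**Analysis.** High-activity events are runs of 20 ms PC-rate bins above
2 Hz lasting >= 260 ms. An LFP estimate sums the synaptic currents of 400
sampled PCs. Welch spectra with Fisher-g peak significance quantify gamma
(30-100 Hz) and ripple (150-220 Hz) content. A memoryless Bayesian
decoder (50 x 6 cm position bins, 10 ms time bins) feeds an exhaustive
constant-velocity path search (`R(v, x0)` = mean posterior mass within
18 cm of the line), with significance from 100 cell-identity shuffles.

## Worked example

The full-scale pipeline (8000 cells, 400 s of simulated exploration, one
10 s offline simulation; ~6 minutes on one CPU). Sharp-wave generation is
an ignition phenomenon that needs the full recurrent in-degree, so there
is no miniature version of this particular output - scaled-down fixtures
are used throughout the unit tests for everything mechanistic.

```r
library(swrnet)

cfg    <- exploration_config()          # 8000 cells, 3 m track, 400 s
map    <- assign_place_fields(cfg, seed = 42)
spikes <- generate_spike_trains(map, cfg, seed = 42)
graph  <- sample_connectivity(cfg$n_cells, cfg$n_cells, 0.1, seed = 42)
W      <- learn_weights(spikes, graph, stdp_kernel("symmetric"))
print(W)
#> weight_matrix: 8000 x 8000 with 6399185 edges, 6399185 nonzero; mean 0.2048 nS, max 7.2758 nS

spec <- build_network(network_config(), W, seed = 1)
sim  <- simulate_network(spec, duration = 10, seed = 1)
rep  <- analyze_simulation(sim, map, decode = TRUE, seed = 1)
print(rep)
#> analysis_report (baseline, seed 1): 7 events; PC in/out 3.82/0.81 Hz, PVBC in-event 94.2 Hz;
#>   7 significant replays (7 fwd, 0 bwd); ripple: significant (175.8 Hz, p = 1.12e-12)
```

Reading the output: a few strong (> 1 nS) synapses between cells with
overlapping fields emerge from a weak background (mean 0.2 nS), and the
resting-state network then alternates between quiet periods (PC rate
0.8 Hz) and seven self-generated population bursts with in-event PC rates
near 3.5 Hz; during the bursts the PVBC population oscillates in the
ripple band (peak ~176 Hz, Fisher-g significant), and decoding each burst
against the exploration tuning curves yields significant constant-velocity
replay trajectories (all forward in this seed; other seeds give both
directions). Event durations stay below 800 ms because replay terminates
on reaching the track end.

Perturbations follow the same pattern, e.g. destroying the weight
*structure* while keeping every outgoing weight:

```r
Ws   <- shuffle_postsynaptic(W, seed = 42)   # column shuffle
simS <- simulate_network(build_network(network_config(), Ws, seed = 1),
                         10, seed = 1)
nrow(analyze_simulation(simS, map, decode = FALSE)$events)
#> [1] 0                                       # no sharp waves at all
```

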