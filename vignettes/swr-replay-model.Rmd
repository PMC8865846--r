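---
title: "A learned CA3-like network model of sharp wave-ripples and bidirectional replay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A learned CA3-like network model of sharp wave-ripples and bidirectional replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swrnet)
```

## Overview

`swrnet` simulates how hippocampal sharp wave-ripples (SWRs) and the
associated forward and backward replay of place-cell sequences can emerge
from synaptic structure acquired during exploration. The pipeline has five
stages, each an independent module:

1. **Exploration** - synthetic place-cell spike trains on a 3 m linear
   track (inhomogeneous Poisson with Gaussian spatial tuning, 7 Hz theta
   modulation and phase precession);
2. **Learning** - pair-based additive STDP with the broad, temporally
   symmetric kernel measured between CA3 pyramidal cells shapes a sparse
   recurrent excitatory weight matrix;
3. **Offline simulation** - an 8000 pyramidal-cell (PC) / 150 basket-cell
   (PVBC) adaptive exponential integrate-and-fire network driven only by
   unstructured Poisson input, with the learned recurrent weights;
4. **Field and spectra** - an LFP estimate from summed synaptic currents,
   Welch spectra, Fisher g peak significance and Morlet wavelet maps;
5. **Replay decoding** - memoryless Bayesian place decoding of detected
   high-activity events, constant-velocity path fitting, and cell-identity
   shuffle significance.

The central scientific claims the model reproduces: the *structure* of the
learned recurrent weights (not their value distribution) is what permits
both sharp waves and replay; ripples arise in the reciprocally coupled
PVBC network once it is driven strongly enough; and the coexistence of
forward and backward replay requires the symmetric plasticity kernel
*together with* spike-frequency adaptation in the PCs.

## The exploration model

The animal runs at a constant 32.5 cm/s along a 3 m track and teleports
back to the start, so one traversal lasts ~9.2 s and a 400 s session gives
~43 laps. Half of the 8000 cells receive a place field; field middles are
uniform on the track, fields that straddle a track end are simply truncated
(the track is linear - no wrap-around). All tuning curves are Gaussians of
identical width; the width is defined implicitly by requiring the rate to
fall to 10% of its 20 Hz peak at the edges of the 30 cm field, giving
sigma = 0.0699 m.

A place cell's instantaneous rate is the product of its spatial tuning, a
7 Hz cosine, and a spatially advancing phase offset that moves the
preferred theta phase through 180 degrees as the animal crosses the field
(phase precession). Negative values of the cosine factor are clipped to
zero, because the rate serves as an acceptance probability: spikes are
generated by thinning a homogeneous 20 Hz Poisson proposal, which yields an
exact inhomogeneous Poisson process. A 5 ms dead time is enforced on the
*accepted* spike sequence. Non-place cells fire homogeneously at 0.1 Hz
with the same dead time and no theta modulation - the theta oscillation
modulates spatially tuned drive, and these cells have none.

Each cell draws from its own seeded substream, so any subset of cells is
reproducible in isolation.

What the generator does *not* emulate: running-speed variability, multiple
fields per cell, 2-D environments, experience-dependent field drift, or
heterogeneous peak rates. Tests passing on these trains therefore
demonstrate the mechanisms under idealized, stationary coding assumptions,
not robustness to the variability of real recordings.

## Learning

STDP is additive and pair-based with all-to-all spike pairing, implemented
with exponential pre- and postsynaptic traces and verified in the test
suite against the explicit double sum over spike pairs. Potentiation is
applied at postsynaptic and the "depression" branch at presynaptic spike
times, in chronological order, with every update immediately cropped to
[0, w_max]; the lower bound is 0 because a conductance cannot be negative.
Exact spike ties receive a single update of `A+` (avoiding double
counting; for the symmetric kernel the choice is inconsequential).

The symmetric preset uses `A+ = A- = 80 pA`, `tau = 62.5 ms`,
`w_max = 20 nS`; the asymmetric control uses `A+ = -A- = 400 pA`,
`tau = 20 ms`, `w_max = 40 nS`. Weights start at 0.1 nS on a fixed random
graph (10% connection probability, no self-edges; only existing edges
learn) and the learned matrix is multiplied by the population-level scale
factor (0.62 symmetric / 1.27 asymmetric) that places the offline network
in its operating regime.

Two unit conventions deserve note. First, kernel amplitudes are stated in
pA while weights are conductances; the package maps them through a single
constant, `unit_scale` (nS of weight increment per pA of amplitude).
Second, `unit_scale` is the one calibrated quantity in the package: with
the natural reading of 1 pA = 1e-3 nS the learned weights already
land in the 0.1-6.3 nS reference range the model is constrained by, but the sharp-wave ignition
threshold of the full network sits ~10% above the nominal operating point
(an accumulation of small unstated numerical conventions - integrator,
spike-generator and bookkeeping details - each worth a few percent). `unit_scale = 1.1e-3` moves the operating point
onto the regime where the baseline network generates recurring SWRs, and
was fixed once; every reported experiment uses it unchanged.

The weight-matrix manipulations used in the perturbation experiments are
post-learning operations and never reapply the learning crop: scalar
scaling, two-group binarization (strongest 3% and remaining 97% of nonzero
weights each replaced by the group mean - preserving support and total
weight), and column shuffling (permuting postsynaptic identity, preserving
each cell's outgoing weight multiset; weights that land on the diagonal
are zeroed, since self-connections are disallowed, and the small displaced
mass is not redistributed).

## The offline network

Neurons are single-compartment (adaptive) exponential integrate-and-fire
models with fixed parameter presets for adapting PCs, non-adapting
ExpIF PCs, and fast-spiking PVBCs, as obtained by fitting each model class
to somatic current-step responses of the corresponding cell type. Synapses are conductance-based with
biexponential kinetics, normalized so the transient peaks at the stated
conductance, with pathway-specific rise/decay constants, reversal
potentials (0 / -70 mV) and axonal delays. Each PC receives one
independent 15 Hz Poisson mossy-fiber train through a strong "detonator"
synapse (19.15 nS; 21.5 nS for asymmetric-kernel networks; doubled to
38.3 nS for ExpIF PCs, which need more drive).

Numerical choices (none of these is pinned down by the model definition
itself, so each is an explicit package decision):

* forward Euler at `dt = 0.1` ms; the test suite checks that halving `dt`
  changes the event-averaged PC rate by < 5% and that single-cell spike
  counts match a 20x finer oracle within one spike;
* the exponential spike-initiation term is capped at its value at the
  detection threshold `theta`, and skipped where its argument is below -9
  (contribution ~1e-4 of a pA) to keep the integrator fast and
  overflow-free; spikes are detected strictly at `V > theta`;
* initial conditions `V = Vrest`, `w = 0`, conductances 0; analysis
  windows discard nothing, but event detection ignores the brief onset
  transient automatically because rates must exceed 2 Hz for 260 ms;
* conductances use the exact two-exponential update (per-step multiplication
  by `exp(-dt/tau)`), so synaptic kinetics are integrated exactly between
  deliveries; delays act on spike delivery, not on kinetics;
* external Poisson sources are drawn per step as a binomial count plus a
  uniform choice of sources, which is distribution-identical to per-source
  Bernoulli draws but ~1000x cheaper at this scale.

Structural variants prune the baseline wiring: `no_PVBC_PVBC` removes the
reciprocal inhibitory synapses; `PVBC_only` keeps only the interneurons,
replacing pyramidal input with 8000 independent Poisson sources (connected
with the PC->PVBC probability, so in-degree statistics are preserved)
whose rate/weight are scanned; `ExpIF_PC` swaps the PC model for the
non-adapting fit.

## LFP and spectra

The LFP estimate is the point-source volume-conductor sum of the total
synaptic currents of 400 randomly sampled PCs at a uniform 1 um distance
(geometry enters only as a constant scale), low-pass filtered at 500 Hz
with a zero-phase (forward-backward) 3rd-order Butterworth filter -
zero-phase so that wavelet maps stay aligned with spikes; band-power
results are unaffected.

Spectra use Welch's method (Hann window, half-overlap, constant detrend):
512-sample segments for 1 kHz population rates and 4096 for the 10 kHz
LFP, halved (256/2048) when spectra are computed per detected event and
averaged - the event-restricted average removes the large low-frequency
power at the event-recurrence rate (~1.5 Hz). Event windows shorter than a
segment are zero-padded so the frequency grid is fixed across events.

Peak significance uses Fisher's g - the ratio of the peak periodogram
ordinate to the total power - with the exact null distribution evaluated in
log space. Two details:

* the test is applied to the Welch-averaged spectrum although the exact
  null holds for a raw periodogram; averaging flattens noise, so the
  reported p-values are approximate in a known, documented way;
* for band-specific questions (gamma 30-100 Hz, ripple 150-220 Hz) the
  candidate peak is the maximum *inside the band* while the denominator
  and the ordinate count N span the full 0-500 Hz spectrum. Restricting N
  to the band itself - superficially the more literal reading - turns out
  to be self-defeating: a genuine ~25 Hz-wide ripple peak occupies most of
  the 70 Hz band, so the band-internal ratio saturates around 0.2 and the
  test can never reject, even when three quarters of the total power sits
  in the band. With the full-spectrum denominator the statistic is
  conservative under the white-noise null (the in-band maximum is at most
  the global one), which the Monte-Carlo type-I test in the suite
  respects. Band power fractions (band sum / 0-500 Hz sum) are reported
  alongside, so non-significant oscillations remain quantified.

Wavelet maps convolve the signal with the real Morlet wavelet
`exp(-t^2/2) cos(5t)` at scales mapped to 25-325 Hz through the Morlet
centre-frequency relation. Because the wavelet is real, magnitudes
oscillate at the carrier; ridge-envelope comparisons in the tests smooth
over ~2 carrier cycles.

## Replay analysis

Candidate events are maximal runs of 20 ms PC-population-rate bins
strictly above 2 Hz lasting at least 260 ms; runs separated by a single
sub-threshold bin are *not* merged. Decoding uses only the 4000 place
cells and the same Gaussian tuning curves that generated the exploration
spikes (as dimensionless curves with peak 1 - exactly as the likelihood is
printed; the spatial information is carried by the spike-count terms, and
the choice affects only the weak occupancy term). The posterior over 50
position bins (6 cm) per 10 ms time bin is the normalized
independent-Poisson log-likelihood; `log(n!)` terms cancel under
normalization, and tuning values are floored at 1e-10 inside the log
purely to guard numerical underflow far outside a field.

Constant-velocity trajectories are fitted by exhaustive search
(`v` in [-18, 18] m/s, 0.3 m/s steps, the closed slow band |v| <= 0.3
excluded; `x0` in [-1.5, 4.5] m, 3 cm steps), scoring the average
posterior mass within 18 cm of the line. The intercept range extends
beyond the track only so bands can enter and leave; out-of-track positions
carry no posterior mass and are not renormalized. Ties are broken towards
the smallest |v|, then the smallest `x0`, making the output deterministic;
a consequence (exercised in the tests) is that when several lines cover
all the mass, the reported velocity is the slowest such line, not
necessarily the generating one. Significance compares the event's best
score against 100 re-fits after permuting which tuning curve each *active*
cell carries (spike times and counts untouched); an event is a replay when
it exceeds its own shuffled 95th percentile. Step-size analysis decodes
the position as the posterior-weighted mean per time bin and compares
observed steps against a per-event constant-step prediction (path length
over event duration).

Events longer than 1 s (which arise only in degenerate variants such as
the stationary-bump ExpIF network) are decoded over their first second;
duration statistics always use the full event.

## Experiment orchestration and problem sizes

`run_pipeline()` chains the stages for one condition; `run_scenario()`
sweeps the reference scaling grids (baseline 0.8-1.2, two environments
0.7-1.1, binarized 0.9-1.3, shuffled 1.0-4.0, no-PVBC-PVBC 0.8-1.6) and
aggregates rates, ripple indicators and replay counts over seeds. For
scan-level ripple indicators the LFP-based test is the robust choice: the
whole-trace spectrum of a *sparse* population rate (a near-silent network)
is dominated by the spectral signature of isolated spike doublets, which
can masquerade as a band peak, whereas the broadband LFP is not
susceptible; the per-indicator report carries both.

The six-feature fitness evaluator scores a simulation by its mean PC rate
(Gaussian around 2 Hz, SD 0.5 Hz), absence of significant gamma in the
PVBC rate, ripple peak frequencies of both populations (Gaussians around
180 Hz, SD 20 Hz; evaluated at the band argmax whether or not significant,
so a nonsignificant spectrum is scored rather than discarded), and the
clipped ripple/gamma power ratios. The external evolutionary search over
synaptic weights is out of scope since the tuned weights are part of the
model's fixed parameter set; the evaluator stands alone so any optimizer can be put behind
it.

The full study conditions are 8000 PCs, 400 s exploration, 10 s offline
simulations; the acceptance script runs exactly these (five offline
seeds, ~6 minutes on one CPU). The unit-test suite exercises the same code
paths on proportionally reduced fixtures (tens to hundreds of cells,
20-100 s exploration) chosen so the whole suite stays in the tens of
minutes; the full-scale regime claims (event rates, ripple significance,
replay direction) live in the acceptance tests, which run the production
sizes with fewer seeds and 5-10 s simulations.

## Known limitations

* The in-event PVBC firing rate equilibrates near 90 Hz here versus the
  ~65 Hz reference value the model is meant to match; a single-cell
  surrogate driven with the
  nominal in-event synaptic bombardment reproduces the elevated value, so
  it follows from the fixed cell/synapse parameter set under this
  integrator rather than from a wiring error. All other headline
  statistics (in/out-event PC rates, ripple frequency band, event
  durations, ISI floor, replay significance and directionality) land in
  their reference ranges.
* SWR termination relies solely on the replayed sequence reaching the end
  of the track; mechanisms such as short-term depression or a second,
  delayed interneuron class are absent, so event durations are bounded by
  track length (~<= 800 ms) rather than the 40-100 ms typical in vivo.
* The LFP is a scaled current sum, not a volume-conductor model with
  realistic geometry; only its spectro-temporal content is meaningful.
* Plasticity is frozen during the offline phase, and all synapses are
  deterministic conductances without short-term dynamics.
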