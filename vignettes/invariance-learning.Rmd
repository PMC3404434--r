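---
title: "Invariance learning in a spiking network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariance learning in a spiking network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeinvar)
```

## The problem

Neurons late in the primate ventral visual stream respond to objects across
large changes in retinal position. Two biologically plausible routes to such
transformation invariance have been proposed for self-organizing networks:

* **continuous-transformation (CT) learning** — successive views of an object
  overlap spatially, so a purely associative rule with lateral competition
  maps the whole sequence of overlapping views onto the same output cells;
  temporal order is irrelevant;
* **trace learning** — successive views follow each other closely in time,
  so a memory trace of recent activity lets temporally adjacent views be
  associated even when they share no input neurons.

`spikeinvar` implements both mechanisms in a single spiking network in which
the synapses self-organize through spike-timing-dependent plasticity (STDP),
and provides the stimulus regimes and information-theoretic analyses that
dissociate them.

## Network model

Two layers, each with `N_E` excitatory pyramidal cells and `N_I` inhibitory
interneurons (400 and 100 at full size). Within a layer, excitatory and
inhibitory pools are fully reciprocally connected and the inhibitory pool is
fully self-connected; all of these synapses are non-plastic. The input
layer's excitatory cells project all-to-all onto the output layer's
excitatory cells through the only plastic synapses in the model.

Each cell is a conductance-based leaky integrate-and-fire neuron,

$$\tau_m \frac{dV_i}{dt} = V_0 - V_i + R\,I_i + R\,I^{ext}_i
  + \sigma \xi \sqrt{\tau_m},$$

with `tau_m = C_m/g_0`, threshold `Theta`, post-spike reset to the
hyperpolarization potential `V_H`, an absolute refractory period of 2 ms,
and Gaussian membrane noise of standard deviation
`sigma = 0.015 (Theta - V_H)`. Synaptic current is a sum of conductances
times driving forces, `I_i = sum_j g_ij (Vhat - V_i)`, with reversal
potentials 0 mV (excitatory) and -70 mV (inhibitory). Each conductance
decays with its projection's time constant `tau_g` and jumps by
`lambda * Dg_ij` when a presynaptic spike arrives.

The default constants (see `population_params()` and `network_config()`)
are: excitatory `C_m` 500 pF, `g_0` 25 nS (`tau_m` 20 ms), rest -74 mV,
threshold -53 mV, `V_H` -57 mV; inhibitory `C_m` 214 pF, `g_0` 18 nS, rest
-82 mV, `V_H` -58 mV. Non-plastic per-spike increments are 5 nS (E→I and
I→I) and 2.5 nS (I→E; lowered to 0.5 nS in the inhibition experiments), with
`tau_g` of 2 ms (E→I) and 5 ms (I→E, I→I).

### The single switch between mechanisms

The feed-forward synaptic time constant `tau_EE` selects the mechanism. At
2 ms (CT regime), feed-forward drive is temporally precise, so learning can
only bind views that share input neurons. At 150 ms (trace regime), the
conductance left by one view is still "bleeding" current into the output
cells when the next view appears, so temporally adjacent orthogonal views
become associated. Because the long time constant accumulates much more
excitation, the plastic conductance cap is lowered from 4 nS to 1.25 nS in
the trace regime.

### STDP

Plasticity at the feed-forward synapses is multiplicative and event-driven.
A presynaptic trace `C` (neurotransmitter concentration) and a postsynaptic
trace `D` (NMDA-receptor unblocking) decay with `tau_C`/`tau_D` (defaults
15/25 ms; 3/5 and 75/125 ms in the temporal-specificity experiments) and
jump by `alpha (1 - x)` at their spike events. At a postsynaptic spike the
efficacy gains `rho (1 - Dg) C` (LTP); at a presynaptic spike it loses
`rho Dg D` (LTD); `rho = 0.1`. Both updates shrink as the weight approaches
its bound, so `Dg` remains in [0, 1] for any spike train and training
reshapes the initially uniform weight distribution into a peaked one rather
than splitting it to the extremes.

## Numerics

* Forward Euler with `dt = 0.02` ms throughout; delta-pulse inputs are
  discrete increments (the `1/dt` of the discrete delta is absorbed so a
  spike adds exactly `lambda * Dg`).
* The noise term is integrated by Euler–Maruyama: each non-refractory cell
  receives `sigma * sqrt(dt/tau_m) * N(0,1)` mV per step, which keeps the
  stationary membrane variance independent of `dt` and correctly scales the
  noise with the membrane speed. Refractory cells are clamped at `V_H` and
  receive neither input nor noise; conductances keep evolving during the
  clamp.
* Threshold crossings are detected by `V >= Theta` after the update, with no
  sub-step interpolation — at `dt = 0.02` ms the interpolation error is far
  below the noise floor.
* Conduction delays are uniform per projection and default to 0 ms, realized
  as a one-step (0.02 ms) pipeline: a spike emitted at step `t` reaches its
  target conductances at step `t + 1` (conductances advance before membranes
  within a step, so a same-step effect is impossible by construction).
  Larger delays use a ring buffer of spike lists.
* Within a step the order is fixed and tested: (1) conductances decay and
  receive delayed spikes, (2) synaptic currents, (3) membranes and spike
  detection, (4) STDP trace decay and jumps, then weight updates (LTP before
  LTD when both land in one step). Traces jump before the weight updates
  that read them.
* The engine exploits full connectivity with uniform projection parameters:
  non-plastic projections deliver identical summed conductance to every
  target, so one scalar trace per projection suffices; the plastic
  projection keeps one summed conductance per postsynaptic cell incremented
  by `lambda * Dg_ij` at spike time. Both are algebraically identical to the
  naive per-synapse update (not an approximation), and the test suite
  asserts exact agreement with a per-synapse reference simulator on a small
  network. Likewise, with uniform delays the per-synapse presynaptic trace
  `C_ij` depends only on presynaptic neuron `j` and is stored as a vector.
* Non-finite membrane potentials abort the run naming the neuron and time,
  surfacing parameter-induced blow-ups immediately.

## Stimuli and schedules

A stimulus is a sequence of "transforms": blocks of `width` contiguous input
neurons displaced by `shift` per step within that stimulus's partition of
the input layer, each driven by a constant 1 nA somatic current for the
whole cue period (100 ms during training, 250 ms during testing). The CT
geometry (13 transforms, 56 wide, shift 12) gives 44 neurons of overlap
between consecutive transforms; keeping every 2nd or 3rd transform lowers
the overlap to 32 or 20. The trace geometry (10 transforms, 20 wide, shift
20) has zero overlap — orthogonal transforms that only temporal continuity
can link.

Training presents all transforms of one stimulus consecutively, stimuli in
random order, five epochs by default. Variants: *interleaved* (stimuli
alternate transform by transform), *randomized* (transform order shuffled),
or both. Testing presents every transform of every stimulus for 250 ms with
a reset first. "Reset" means membrane potentials to rest, synaptic
conductances and STDP traces to zero, weights untouched; the trace regime
also resets between training stimuli ("settling") so that the conductance
trace cannot artificially associate the two stimuli, except in the
interleaving experiment, where removing that protection is the point.

## Performance measures

After training, learning is switched off and spikes from the test sweep are
converted to rates per (cell, stimulus, transform) window.

**Single-cell stimulus-specific information.** Each cell's rates are
discretized into equal-width bins spanning [0, max] of that cell's
responses; the default bin count equals the number of transforms per
stimulus, tying response resolution to trial count (the literature the
measure comes from leaves the bin count open). With equiprobable stimuli,
`I(s, R) = sum_r P(r|s) log2(P(r|s)/P(r))` is evaluated per stimulus and the
cell's score is the maximum over stimuli; the ceiling is `log2(N_S)` (1 bit
for two stimuli). A cell that fires at one level for every transform of one
stimulus and at another level otherwise reaches the ceiling.

**Multiple-cell information.** The single-cell measure cannot tell whether
*different* stimuli are represented by different cells, so an ensemble
measure decodes stimulus identity from population rate vectors: the pool is
the top five cells per stimulus by per-stimulus information; for each
ensemble size, random subsets are decoded by leave-one-transform-out
Gaussian likelihoods per cell, multiplied across cells with a uniform prior
and normalized; the argmax prediction (ties broken uniformly at random)
accumulates a confusion table over 100 iterations, whose mutual information
`I(s, s')` is reported against ensemble size. Standard deviations are
floored at `1e-3` of the table's maximum rate so constant responders keep
finite likelihoods; a soft (full-posterior) accumulation variant is
available behind a flag.

**Firing-rate regime.** `responsive_rate()` summarizes the output layer's
characteristic driven rate: cells whose peak windowed rate exceeds 10
spikes/s are "responsive" and contribute the rate of their most strongly
driven window. This captures the rate a responding output cell attains —
about 50 spikes/s in the CT regime versus about 200 spikes/s in the trace
regime, where the slow conductances accumulate far more excitation.

**Volley rate.** Lateral inhibition makes the stimulated input cells fire in
near-synchronous waves. `count_volleys()` clusters population spike times at
silent gaps above 3 ms and counts clusters recruiting at least a quarter of
the stimulated cells; under the standard parameters one 100 ms presentation
carries about five volleys (50 Hz).

## Scaling down

`scale` multiplies the cell counts and the stimulus geometry by a factor and
divides every per-spike conductance increment by it, preserving each
neuron's summed synaptic drive. Quarter scale (100 E + 25 I per layer)
preserves the qualitative phenomena — volley synchronization, CT and trace
invariance learning, and the orderings across the experimental
manipulations — at roughly 1/16th the cost, and is what the test suite uses
for the training experiments (full-size runs appear in the acceptance
script and take on the order of a minute each). Quantitative details (e.g.
exact information values per cell) are noisier at reduced scale because
each volley carries 4x fewer spikes.

The allowed scales are those that keep the stimulus geometry integral
(1, 0.5, 0.25).

## What the synthetic stimuli do and do not show

The translating current-injection blocks isolate each mechanism cleanly:
overlap can be controlled exactly and temporal continuity can be severed by
resets. They lack the structure of natural images — distributed, partially
overlapping features, multiple simultaneous objects, realistic first-layer
tuning — so passing results demonstrate the learning mechanisms, not
performance on natural vision. Rotation, scaling, occlusion, firing-rate
adaptation, lateral excitatory connections and deeper hierarchies are out of
scope.

## Reproducibility

All randomness — weight initialization, schedule shuffling, membrane noise,
decoding subsets and tie-breaks — flows from R's RNG, so a single
`set.seed()` (or the `seed` argument of `run_experiment()`) makes runs
bit-reproducible: identical seeds give identical spike records and weight
matrices. Learning-off runs leave the weight matrix bit-identical.

## A minimal session

```{r example, eval = FALSE}
library(spikeinvar)

# quarter-scale CT baseline: ~20 s
ex <- run_experiment("ct_baseline", seed = 1, scale = 0.25)
ex$summary
#> $max_single_bits    1
#> $top_decile_bits    0.63
#> $multi_bits         1
#> $responsive_rate_hz 48

plot_single_cell_info(ex$info)
plot_multi_cell_info(ex$info)
plot_weight_histogram(ex$state)
```
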