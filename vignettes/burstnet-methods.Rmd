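---
title: "Methods: bursting synchrony and effective connectivity in cultured neuronal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bursting synchrony and effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`burstnet` quantifies how cultured neuronal networks fire *together*. This
vignette is the package's own account of the models and estimators it
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic fixtures do and do not show
about real recordings.

## 1. From fluorescence to spikes

**DFF.** Calcium fluorescence is normalized per neuron as
`DFF = 100 * (F - F0) / F0` (percent), with `F0` the running 10th
percentile of the raw trace over a centred 30-s window. A low percentile is
a rest-level proxy that is robust to transients; the window tracks slow
drift. For efficiency the percentile is evaluated on a strided grid (a
tenth of the window) and interpolated — the baseline varies on the window
timescale, so nothing is lost. Note one bias worth knowing about: under
additive noise of SD sigma, the 10th percentile sits roughly 1.3 sigma
below the true rest level, so the resting DFF is slightly positive. The
trigger below is built to be insensitive to this.

**Schmitt trigger on the rise signal.** Onsets are detected by a
two-threshold hysteresis applied to the *rise* of the trace: the DFF is
smoothed with a trailing moving average of `smooth_frames = 4` frames and
differenced over the same span; an event opens when this rise signal
reaches `theta_high = 3.5` robust SDs (MAD) of itself, closes below
`theta_low = 1` SD, and must last at least `min_frames = 2` frames. The
onset time is the opening frame corrected for the smoothing lag.

Running the hysteresis on the rise rather than on the absolute DFF level is
a deliberate estimator choice, made after measuring two failure modes of
the absolute-level variant on synthetic ground truth: (i) the baseline bias
above shifts absolute thresholds; (ii) with a slow decay (`tau_decay`
around 0.8 s) an absolute trigger stays "open" for 1-2 s per transient, so
any spike landing on the decay shoulder of its predecessor is invisible —
at realistic event rates this alone caps recovery near 93%, below the
package's own 95% round-trip requirement. A calcium transient announces
itself as a fast upstroke, which the rise signal isolates; stacked
transients produce separate upstrokes and are resolved. With the defaults,
the synthesis-then-detection round trip at signal-to-noise 5 (transient
peak over noise SD) recovers 95-97% of ground-truth onsets within 2 frames
with 3-5% false positives.

Manual curation of non-neuronal ROIs is replaced by an automatic filter:
ROIs whose noise estimate exceeds a configurable ceiling are dropped.

## 2. Collective dynamics

**GNA.** The global network activity is the fraction of *active* neurons
(those with at least one onset anywhere in the recording — silent ROIs are
excluded from the normalization) that co-activate within a sliding 1-s
window, computed at one-frame stride on the 20-Hz grid. Windows are
half-open `[t, t + 1)`; a neuron firing twice in a window counts once. GNA
is 0 for silence and exactly 1 for a full-network activation.

**Burst catalog.** The background level is found by iterating "compute
mean + 2 SD over retained samples, drop samples above it" to a fixed point.
Burst peaks are strict local maxima of the original series above the final
threshold; plateaus contribute their first frame, and peaks are thinned
greedily by descending amplitude (ties to the earlier peak) so that kept
peaks are at least one window apart. A constant series yields an empty
catalog with the constant as background.

**Extreme events.** Control recordings' peak amplitudes are pooled into a
reference (`a_ctr`, `sd_ctr`); a burst is extreme when its amplitude
exceeds `a_ctr + 2 * sd_ctr`, and `R_EE` is the fraction of a recording's
peaks that are extreme. The reference is always an explicit input — never
implicitly global — so the grouping of control recordings is the caller's
decision. A quantile-style variant of the cutoff
(`a_ctr + 1.645 * sd_ctr`) is available via `rule = "quantile95"` for
sensitivity checks. Because the control defines the threshold, control
recordings sit near `R_EE = 0` by construction and two-state recordings
dominated by whole-network events approach 1.

One property of this adaptive definition deserves emphasis: with *any*
Poisson background, the iterative threshold self-normalizes downward until
upper-tail coincidences of the background count as small "bursts" — about a
hundred of them in a 15-min recording, independent of the rate. Real
catalogs therefore always mix genuine bursts with threshold-level peaks;
this is inherent to the method, not a bug, and is why the PD-like preset
(below) is quiescent between events.

## 3. Effective connectivity

Spike trains are binarized at one frame (50 ms): a bin is 1 iff the neuron
has an onset in it. The directed interaction from X to Y is a plug-in
generalized transfer entropy at Markov order `k = 2`,

`TE(X->Y) = sum p(y_{t+1}, Y_t, X_t) log2 [ p(y_{t+1}|Y_t, X_t) / p(y_{t+1}|Y_t) ]`,

with `Y_t = (y_t, y_{t-1})` and, with instant feedback on (the default),
the source window shifted one bin forward, `X_t = (x_{t+1}, x_t)`, so
same-bin interactions are visible. Probabilities are raw state-histogram
frequencies pooled over all valid bins; no bias correction is applied —
the significance decision is relative, so the common plug-in bias cancels.
The estimator is exact in the sense that it equals an independent
brute-force enumeration of the state histogram to 1e-12, and on
deterministic one-bin copies it is maximally asymmetric
(`TE(Y->X) = 0` exactly).

Scoring runs on a random subsample of 340 active neurons (all of them,
with a warning, if fewer are active), and only on recordings whose catalog
shows at least 10 network bursts — connectivity is meant to capture
interactions during bursting episodes, and recordings failing the filter
are refused outright. An edge is significant when its score exceeds
mean + 1 SD of the pooled distribution of all off-diagonal pair scores of
the same network; mean + 2.5 SD is provided as the sparser display
variant. The pooled null is the one reading of "the joint distribution of
all inputs and outputs" that defines a single threshold per network; no
conditioning on global activity is applied by default.

Degree distributions default to total degree (in + out) of the unweighted
directed graph, optionally expressed as percent of network (per-direction
degree over `n - 1`, summed). `D_KL(P||S) = sum P(i) ln(P(i)/S(i))` is in
nats, with `P(i) = 0` terms contributing zero and `S(i) = 0` where
`P(i) > 0` an explicit error after supports are aligned on their union; the
two-sample Kolmogorov-Smirnov test runs on the raw per-neuron degree
samples via `stats::ks.test`.

## 4. Functional communities

Community detection symmetrizes the thresholded network (an edge exists if
either direction does), restricts to the largest weakly connected component
(size ties broken by the smallest member id), and runs Louvain modularity
maximization (igraph), deterministic under a seed. The community statistic
`Q = sum_c (e_cc - a_c^2)` is evaluated in-package from the definition and
cross-checked against both `igraph::modularity` and exhaustive partition
search on small graphs. `Q` of the single-community partition is exactly 0
for any graph with edges; an edgeless component yields singleton
communities with `Q` undefined (the sum is 0/0 without edges — the informal
"Q = 1 when all neurons are disconnected" limit is not given a numeric
value).

## 5. Synthetic data: what it emulates, and what it does not

`gen_raster()` superimposes per-neuron homogeneous Poisson background on
network bursts at Poisson times; each burst recruits
`ceiling(p * n)` distinct neurons (without replacement) with Gaussian onset
jitter (50 ms SD). Two presets pin the study conditions at the assay's
scale (~500 neurons, 15 min at 20 Hz):

- `ctr_like` — background 0.05 spikes/s/neuron, 0.08 bursts/s,
  participation 10-40%, recruitment concentrated on one of 8 fixed
  assemblies per burst (non-members recruited at weight 0.15). The
  assemblies emulate the microcircuit coactivations that give healthy
  networks their functional community structure; without them the
  functional network is statistically homogeneous and there is no
  community contrast to detect.
- `pd_like` — 0.02 bursts/s at 80-100% participation and *no* background:
  the quiescent limit of the two-state dynamic. This is deliberate — see
  the remark in section 2: any Poisson background floods the adaptive
  catalog with coincidence peaks and would dilute `R_EE` to ~0.1 for a
  recording whose every real burst is extreme.

The calcium forward model is a difference of exponentials
(`tau_rise = 0.02 s`, `tau_decay = 0.8 s`, amplitude 1 in DFF units on
baseline `f0 = 100`) with white Gaussian noise. Saturation, photobleaching,
motion artifacts and correlated noise are *not* modeled, so the detection
round-trip property bounds performance only under these favorable
conditions; the recording noise statistics of real data are a free
parameter here, not a claim.

## 6. The in silico model

**Structure.** `build_network()` places `n = 300` neurons uniformly (or
subsampled from supplied ROI positions) in a 2800 x 2100 um field, types
assigned at random in fractions 0.55/0.25/0.20
(excitatory/DA/inhibitory, largest-remainder rounding — exactly 165/75/60
by default). Each neuron grows an axon as a chain of 10-um segments with
Gaussian angular increments (SD 0.1 rad) and Rayleigh-distributed total
length (mean 1100 um), terminated at the field walls; each has a circular
dendritic tree of Gaussian radius (150 +/- 20 um, floored at 10 um). A
directed edge from axon owner to dendrite owner is created with
probability 0.5 whenever the axon crosses the disk (exact point-to-segment
distances; the edge stores the arc length of the first crossing and the
minimal axon-to-soma distance).

**Pruning.** A fraction `f` of DA neurons is selected uniformly;
axon shortening truncates the axon at a cut chosen on the sorted
first-crossing arc lengths of that neuron's out-edges so that the realized
connection loss is as close as possible to the 80% target (dendrite
shrinkage does the analogous thing on in-edges via the stored minimal
distances; random edge deletion removes `round(0.8 m)` edges exactly).
Because the per-neuron edge count is small (median ~7), the achievable
loss grid is coarse and the realized mean lands near 82-84% rather than
exactly 80 — within the intended "about 80%" band. Only edges incident to
selected DA neurons are ever touched, and a network can be pruned once.

**Dynamics.** Each neuron is a single-compartment conductance-based model:
Wang-Buzsaki-type Na/K spiking currents (instantaneous Na activation,
`phi = 5`), leak (`g_L = 0.1 mS/cm2`, `E_L = -65 mV`), a slow
spike-triggered K adaptation conductance (increment 2.5 mS/cm2 per spike,
decay 5 s) that terminates bursts and gates re-participation, exponential
synaptic conductances routed through the structural adjacency (DA neurons
synapse as excitatory; increments `w_ee = w_ei = 0.3`, `w_ie = 0.2`,
`w_ii = 0.05 mS/cm2`; decays 5/10 ms), and an independent 2-Hz Poisson
train of excitatory events (0.2 mS/cm2) per neuron. Two sources of
per-neuron heterogeneity are essential: a lognormal spread of the
adaptation time constant (CV 0.4) and Gaussian leak-reversal jitter
(1.5 mV). They stagger the post-burst recovery clocks; without them the
network relaxes into periodic whole-network bursts because every neuron
recovers at once. At this operating point the control network reproduces
the healthy phenotype: GNA background near 0.05 with bursts recruiting
10-40% of the network every few seconds.

Integration is fixed-step Heun (RK2) at `dt = 0.1 ms` (the maximum the
interface accepts), with gating rates tabulated over voltage and linearly
interpolated; spikes are upward crossings of 0 mV with a 3-ms refractory
for detection. External Poisson event times are drawn by exponential
skipping, so the drive realization is independent of `dt`; halving `dt`
changes the spike count of a 10-s control run by under 2%. The first 15 s
of every run are discarded (near-identical initial conditions make the
first event an artificially synchronized burst). Simulations for testing
run 120 s; longer horizons are a parameter, not a design change.

**Pruning experiment.** `run_experiment()` builds, prunes (0/10/30/50% of
DA neurons by default), simulates 4 realizations per condition, and
analyzes the rasters identically to recordings, with the non-pruned
condition's pooled burst amplitudes as the extreme-event reference. Under
10% axon pruning the burst-amplitude distribution acquires a heavier upper
tail and the mean `R_EE` rises above the control's, and the pruned
condition's functional degree CDF rises faster at low degree.

## 7. Known limitations

- The conductance-based model is a reduced stand-in tuned to reproduce the
  qualitative regimes, not a parameter-faithful reconstruction of a
  published cortical model; its full parameterization is exposed in
  `neuron_params()`.
- At 30-50% pruning the direct loss of excitation outweighs the
  recovery-pool effect and the simulated `R_EE` falls back toward the
  control level, whereas the experimental claim is a plateau; the package
  reports what the model does.
- Removing inhibition in this model does not lower spontaneous activity;
  the inhibition-sustains-activity effect reported for richer cortical
  models is not reproduced. The suite instead verifies the elementary
  property that inhibitory synapses suppress their targets.
- The burst catalog's adaptive threshold counts upper-tail background
  coincidences as peaks (section 2); comparisons should therefore always
  be relative to a control reference processed identically.
- KL divergence on degree distributions is undefined when the comparison
  distribution has empty support where the reference has mass; the
  Kolmogorov-Smirnov comparison has no such restriction and is the more
  robust of the two.

## 8. Reproducibility and problem sizes

Every stochastic stage takes an explicit seed and restores the RNG state;
identical configuration and seed reproduce every artifact byte for byte
(`run_full()` writes a manifest with the configuration, seed and package
version). The shipped tests run the synthetic presets at 400-500 neurons x
600-900 s, the detection round trip at 40 neurons x 120 s over three
seeds, and the pruning experiment at 4 conditions x 4 realizations x
120 s; these sizes were chosen as the smallest at which the group
contrasts are stable across seeds.
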