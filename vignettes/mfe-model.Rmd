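---
title: "Multiple-firing events in a clustered model of V1: model, methods and design choices"
author: "MFEsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-firing events in a clustered model of V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(MFEsim)
```

## The model

MFEsim simulates a patch of layer 2/3 of primary visual cortex as a network
of conductance-based integrate-and-fire point neurons.  Neurons are grouped
into *clusters* (orientation domains) of `N_E = N_I = 128` excitatory and
inhibitory cells; three clusters of distinct orientation preference form a
*hypercolumn*, and the default network has eight hypercolumns (24 clusters,
6144 neurons), all pairs of hypercolumns treated as adjacent.

Each neuron's membrane voltage obeys, in dimensionless units,

$$\tau_V \frac{dV}{dt} = -(V - V_L)
  - g^{\mathrm{input}}_{\mathrm{fast}}(V - V_E)
  - g^{\mathrm{syn},E}_{\mathrm{slow}}(V - V_E)
  - g^{\mathrm{syn},E}_{\mathrm{fast}}(V - V_E)
  - g^{\mathrm{syn},I}_{\mathrm{fast}}(V - V_I),$$

with $V_L = 0$, $V_E = 14/3$, $V_I = -2/3$, threshold $V_T = 1$, reset
potential $0$, $\tau_V = 20$ ms, and an absolute refractory period
$\tau_{\mathrm{ref}} = 1$ ms during which the voltage is clamped at reset
and all synaptic input is ignored.
Synaptic kernels are unit-integral exponentials with instantaneous rise:
slow (NMDA-like) excitation decays with $\tau_{\mathrm{slow}} = 128$ ms;
fast (AMPA/GABA-A-like) kernels are taken in the formal limit
$\tau_{\mathrm{fast}} \to 0^+$ with
$\tau_{\mathrm{ref}} \gg \tau_{\mathrm{fast}}$, so each neuron can fire at
most once at any instant.  A finite-$\tau_{\mathrm{fast}}$ integration mode
(a few ms) is provided to verify that the phenomenology is not an artifact
of the limit.

Connectivity is random and statistically homogeneous by class: within a
cluster the connection probability is 20 % from excitatory and 50 % from
inhibitory presynaptic neurons; across clusters of one hypercolumn both are
halved; long-range connections run only between same-orientation clusters
of different hypercolumns, only from excitatory senders, with the same
halved probability.  Connected pairs carry class weights: six local
parameters ($S^{QQ'}_{\mathrm{fast}}$, $S^{QE}_{\mathrm{slow}}$) and four
long-range parameters ($L^{QE}_{\mathrm{fast}}$, $L^{QE}_{\mathrm{slow}}$).
Inhibitory neurons make no slow synapses.

The ~20 %/~50 % figures attach to the presynaptic side in this package
(a deliberate reading: inhibitory neurons arborize more densely, which
describes axonal output).

Every neuron receives an independent Poisson feedforward train delivered
through the fast-excitatory jump rule with weight $S^Q_{\mathrm{drive}}$.
The rate is
$\eta_{Q,j,k,l}(t) = \eta^{\mathrm{bkg}}_Q + \eta^{\mathrm{stim}}_{Q,j,k,l}(t)$
with the drifting-grating stimulus
$\eta^{\mathrm{stim}}(t) = C_{Q,j,k}\,\eta^{\mathrm{bkg}}_Q (1 +
\sin(2\pi\omega(t - \phi_l)))$, $\omega = 4$ Hz, per-neuron spatial phases
$\phi_l$ uniform over one period, and $C_E = 3 C_I$ for targeted clusters.
A phase-free variant replaces the sinusoid by its time average
$C\,\eta^{\mathrm{bkg}}$.

## Exact cascade resolution

With instantaneous fast synapses, a threshold crossing can recruit further
crossings at the same instant: a *multiple-firing event* (MFE).  Because
every fast kernel shares one exponential decay, the within-instant dynamics
have a closed form.  Rescaling time by $\tau_{\mathrm{fast}}$ and letting
$s \in (0,1]$ be the fraction of pending kernel area still undelivered, a
neuron holding excitatory area $a$ and inhibitory area $b$ follows

$$V(s) = V^* + (V(1) - V^*)\, e^{c (s - 1)}, \qquad
  c = \frac{a + b}{\tau_V}, \quad
  V^* = \frac{a V_E + b V_I}{a + b},$$

monotone toward $V^*$.  Threshold-crossing instants are therefore available
in closed form, and `resolveCascade()` resolves the event exactly and
event-driven: find the earliest crossing among all touched neurons, fire
it, add its outgoing fast weights to its targets' pending areas, repeat;
finally deliver all remaining area.  The fired set *and* firing order equal
the $\tau_{\mathrm{fast}} \to 0^+$ limit of the conductance-based dynamics
by construction; the test suite verifies this against brute-force
simulations at $\tau_{\mathrm{fast}} = 10^{-2}$–$10^{-4}$ ms on randomized
small instances.

This is a deliberate design choice.  A simpler rule -- apply full jumps
sequentially, largest voltage surplus first -- approximates the same limit
but can disagree with it when an inhibitory crossing falls between two
near-simultaneous excitatory ones: the limit orders crossings by required
kernel-area fraction, not by post-jump surplus.  Since the exact rule costs
no more, we use it.  Surplus ordering (with a seeded per-instant random
tie-break) is retained only for the degenerate case of several neurons
sitting at/above threshold when an instant opens, where the limit does not
prescribe an order.

Two further conventions close the within-instant semantics: slow-conductance
increments earned during a cascade are applied only after the instant (the
instant has zero duration, so they cannot influence within-instant jumps),
and neurons refractory at the end of the instant -- in particular every
neuron that fired in it -- receive none, since the refractory contract is
that all synaptic input is ignored.  A feedforward arrival landing exactly
on a cascade time is processed after the cascade.

## The engine

Between instants each neuron relaxes under leak and its decaying slow
conductance.  The engine advances in substeps of at most 0.1 ms; within a
substep the slow conductance is frozen at its midpoint value and the
voltage takes an exact exponential step toward the frozen equilibrium
$(V_L + g V_E)/(1 + g)$; crossing times inside a substep are solved in
closed form from that expression (not linearly interpolated, which would be
strictly less accurate at the same cost).  Poisson arrivals are applied as
jumps at their exact times, splitting substeps as needed; thinning against
the per-neuron rate supremum makes the inhomogeneous sampling exact.  Any
crossing triggers whole-network cascade resolution at that instant.
Halving the substep changes the total spike count of a 10 s reference run
by well under 0.5 % (regression-tested).

All randomness -- initial voltages, each neuron's drive stream, stimulus
phases, tie-breaks -- derives from the master seed through independent
counter-seeded streams, so runs are bit-reproducible and independent of
event interleaving.  Initial voltages are uniform in $[0, 0.95\,V_T]$ to
avoid startup synchrony; initial conditions and burn-in are package
conventions -- analyses discard a configurable burn-in (500 ms default) and
the run manifest records the choice.  With a horizontal delay
configured (~10 ms robustness option), long-range deliveries -- fast and
slow -- are queued and applied as jumps/increments at their arrival times.

## Analysis statistics

**Binning and the 95 % rule.**  Spiking is summarized in 1 ms, left-closed
bins.  Under the null that all neurons fire independently and uniformly in
time, a bin's count is Binomial($n$, rate $\times$ bin).  A bin is an
*MFE-bin* iff its count strictly exceeds the smallest integer at which the
binomial CDF reaches 0.95; spikes in MFE-bins are *MFE-spikes*, and their
fraction measures the homogeneity of population firing.  The rate entering
the null is the time-averaged population rate over the analyzed epoch (the
estimation window is a package convention: the whole epoch after
burn-in).  E and I populations are detected separately.

**Cross-covariance.**  $C(Q, Q', A, B, \tau)$ sums lagged products of
binned spike trains over all ordered neuron pairs whose orientation match
is $A$ and hypercolumn match is $B$, excluding self-pairs.  The printed
formula is a raw product sum and hence nonnegative, yet background
anticorrelation between unlike orientations is an expected feature; the
package therefore returns both the raw sum and a mean-subtracted variant
and uses the latter for inspection.  The implementation reduces the pair
sum to sums over cluster count series (with a per-neuron autocorrelation
correction for the same-cluster class) computed by direct shifted products:
binned counts are integers, so this is bit-exact against the naive
double-loop sum, which the tests assert.

**Spike-triggered voltage (STV).**  For each trigger spike of a population
and each lag $\tau$, the voltages of all partner-class neurons at $t -
\tau$ are histogrammed, with per-lag mean and SD.  (The quantity sometimes appears
under the label "SVD"; it is the same object.)  Voltage
sampling must cover the lag window; triggers without coverage either raise
an error or are trimmed on request.

**LFP proxy and spectra.**  The population-mean voltage of a cluster
stands in for the LFP.  Its PSD is the periodogram averaged over
non-overlapping 512 ms windows (resolution ~2 Hz); gamma-band comparisons
use the mean power in 25–90 Hz.

**Trial variability and rate curves.**  `trialCV()` computes per-neuron
coefficients of variation of spike counts across aligned trials (neurons
with zero mean are excluded from the summary and reported separately).
`rateCurves()` reports per-condition center-cluster rates with the
I-population (and E) split into MFE/non-MFE spike rates — an exact
partition of the total.

**Background episodes.**  "Sustained activity patterns" are
operationalized by a declared convention: per-orientation summed E
activity, smoothed with a 25 ms moving average; an episode is a maximal
run (≥ 25 ms) in which one orientation leads the runner-up by a ratio of
at least 1.5.  The median episode duration estimates the persistence
timescale $\tau_{\mathrm{persist}}$.  The margin is configurable; 1.5 is
the package convention, chosen to demand clear dominance yet tolerate the
MFE-driven choppiness of cluster activity.

**Coherence.**  The onset coherence shift is probed by a simplified
stand-in: Welch magnitude-squared coherence between the summed counts of
two random halves of a population, compared across bands pre/post onset;
the estimator choice is a declared convention of the package.

## The shipped regimes and their provenance

The model's reference coupling values are not publicly available, so the
package ships its own regimes, tuned by the authors against the
qualitative benchmark checklist, and labels them as such:

* `mfe-single` — one cluster (128 E + 128 I) in a clearly MFE-dominated
  regime: barrages of correlated E and I firing separated by 10–25 ms
  recharge lulls.
* `mfe-default` — the full 24-cluster network, with long-range coupling
  favoring inhibitory targets ("horizontal excitation affects I-neurons
  more than E-neurons").  Background firing is fluctuation-driven and
  MFE-rich with plausible rates (~2 Hz E, ~12 Hz I); same-orientation
  clusters across hypercolumns are positively correlated at zero lag and
  unlike orientations anticorrelated; iso-oriented stimulation of all
  eight hypercolumns suppresses center-cluster E firing by roughly 40 %
  relative to single-cluster stimulation; trial-to-trial variability drops
  sharply at stimulus onset.
* `mfe-bkgpatterns` — a variant whose long-range coupling favors
  excitatory targets.  It develops sustained background orientation
  patterns (episodes of dominance of one orientation, tens to hundreds of
  ms by the episode convention, sometimes locking for seconds) with the
  full correlated-background covariance structure — but full-row
  stimulation destabilizes it, so it is unsuitable for surround
  suppression.  It is shipped, clearly labeled, for background-activity
  experiments.

Tuning followed a staged recipe: constrain the drive first ($S^E_{\mathrm{drive}} \approx 0.5\,S^{EE}$, background rate
250–500 Hz, here 300 Hz with $S^E_{\mathrm{drive}}/S^{EE} = 0.62$ — within
the "approximately half" reading), then pit excitation against inhibition
in guided sweeps.  The sweeps exposed a genuine tension that shapes the
defaults.  Background orientation patterns require the *net* long-range
interaction along a row of same-orientation clusters to be excitatory at
spontaneous rates — they appear only in a pocket a few percent wide in
$L^{EE}_{\mathrm{slow}}$, between pattern-free asynchrony and runaway
synchrony.  Iso-oriented surround suppression requires the same long-range
pathway to be net *suppressive* under sustained drive.  In our searched
neighborhood the two requirements did not overlap: every pattern-forming
point exploded under full-row drive (center E rates an order of magnitude
above the single-cluster condition), and every suppression-capable point
lost its patterns.  The model's reference regime evidently threads this needle with coupling
values unavailable to us; we ship the two sides separately rather than a
single point that does neither well, and the
default regime is the suppression-capable one.  Its stored checklist
records honestly which benchmarks it meets: plausible rates, surround
suppression and the variability drop hold; sustained 50–500 ms background
episodes and gamma-band elevation under drive do not.  On the gamma point:
in this regime strong drive accelerates the inter-MFE rhythm of the driven
cluster beyond the gamma band (power rises in 90–200 Hz while 25–90 Hz
power falls slightly below the MFE-rich background's), so the elevation
criterion fails even though the underlying mechanism — a stochastic
MFE rhythm whose frequency tracks drive — is present.  The regime files
carry checksums; `regimeChecklist()` recomputes the stored qualitative
statuses from scaled-down protocol runs.

The surround-suppression variant in which center I-firing *increases* with
stimulus size corresponds to a different parameter region; shipping a
second regime for it is best-effort and its absence is deliberate here —
the package's regime realizes the decreasing-I case.

## Problem sizes and numerical choices

Acceptance-level checks run the full 24-cluster network for 8–12 s of
simulated time per protocol (about a minute of wall time each), with 8
trials of 3 s for the variability benchmark; these sizes are the package's
chosen trade-off between statistical stability of the checklist quantities
and the cost of routine re-runs.  Unit-level statistics (detector
calibration, thinning, cascade equivalence) use small populations where
the relevant null distributions are exact.  Numerical conventions:
substep 0.1 ms; cascade candidate crossings require the closed-form
equilibrium to exceed threshold strictly; ties among simultaneous
initiators are broken by a seeded permutation; the runaway guard aborts a
run whose mean rate exceeds a configurable bound, as a diagnostic for
epileptic parameter regions.

## What the synthetic fixtures do and do not show

`makePlantedRaster()` generates the detector's null — independent
homogeneous Poisson neurons — with optional synchronous events of known
times and sizes.  It validates calibration (false-flag rate at the
binomial tail mass) and recovery (planted events well above cutoff are
found with sensitivity 1).  It does *not* emulate the correlated,
refractory, rate-modulated structure of simulated rasters: passing
calibration on the fixture says the detector's null arithmetic is right,
not that real background activity is binomial.  Conclusions about the
model's dynamics rest on the simulator runs, not on the fixtures.

## Known limitations

* Point neurons, no synaptic depression/facilitation, no conduction delays
  within a cluster, no spatially extended topology or realistic orientation
  maps: all outside the model's scope.
* The engine is serial; the full network runs at roughly 5–10× real time
  per simulated second on one core in background regimes.
* No single shipped regime satisfies all five qualitative benchmarks at
  once (see above): the default trades background-pattern persistence and
  gamma elevation for robust surround suppression, and `mfe-bkgpatterns`
  trades the reverse.  Both sit in the competition-sensitive region where
  ±10 % on slow couplings can tip the dynamics into asynchrony or runaway
  — background patterns are, in our experience, the model's most
  constraining benchmark.
* Natural-movie stimuli, avalanche power-law exponent estimation, and
  LGN/receptive-field front-ends are out of scope.
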