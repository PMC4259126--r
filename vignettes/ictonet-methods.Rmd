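---
title: "Modeling seizure transitions on functional networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling seizure transitions on functional networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictonet)
```

## The scientific question

Resting-state functional networks inferred from scalp EEG differ between
people with idiopathic generalized epilepsy and healthy controls; in
particular the mean node degree (MD) of patient networks tends to be
higher.  `ictonet` implements a computational test of whether that
structural difference alone is enough to make a network more prone to
generating seizure dynamics.  The strategy: strip each network down to a
binary graph that preserves only its MD, randomize everything else about
its topology, use the result as the connectivity of a network of bistable
model neurons (mass-level units, not cells), and measure how much time the
stochastic dynamics spend in the seizure-like state.

## The node model

Each node is an abstract bistable oscillator in one complex variable,

$$\frac{dZ}{dt} = \left(a|Z|^4 + b|Z|^2 + c + i\omega\right) Z + \epsilon(t),$$

whose radial part $r = |Z|$ obeys $\dot r = r(a r^4 + b r^2 + c)$.  With
$u = r^2$ the non-trivial equilibria are roots of $a u^2 + b u + c$.  At
the operating point used throughout the package,
$\{a, b, c, \omega\} = \{-1, 2, -0.9, 1\}$, the node is bistable:

```{r equilibria}
radial_equilibria(node_parameters(-1, 2, -0.9, 1))
```

The stable origin is the "background" state; the stable circular limit
cycle at $r \approx 1.147$ is the "seizure" state; the unstable circle at
$r \approx 0.827$ is the separatrix between their basins.  Complex white
noise $\epsilon(t)$ lets trajectories escape the background basin
spontaneously, which is the model's mechanism for seizure onset.

The network couples $N$ such units linearly through an adjacency matrix
$G$,

$$\frac{dZ_i}{dt} = \left(a|Z_i|^4 + b|Z_i|^2 + c + i\omega_i\right) Z_i +
  s\sum_{j} G_{ij} Z_j + \epsilon_i(t),$$

with noise independent across nodes and a global scale $s = 0.1$ applied
to $G$ so that coupled nodes remain inside the bistable regime.  The
coupling is the literal linear form $\sum_j G_{ij} Z_j$ (not a diffusive
$Z_j - Z_i$): input from active neighbors is excitatory outward drive,
which is why better-connected networks escape faster.  Node frequencies
are jittered as $\omega_i = \omega_0 + \delta\omega_i$ with
$\delta\omega_i \sim U[-0.2, 0.2]$ to avoid artificial phase locking of
identical oscillators; the jitter is redrawn for every simulation
replicate.

## Numerical integration

The SDE is integrated by Euler–Maruyama with default step
$dt = 0.01$ (the rotation period is $2\pi/\omega \approx 6.3$, so
~630 steps per cycle) for a default duration of 500 model time units.
Both are package choices: they are not dictated by the model, and the
tests verify first-order convergence in $dt$.  One consequence of a
first-order scheme worth knowing: on the limit cycle the tangential Euler
error inflates the radius by
$\approx \omega^2 dt\, r / (2|\lambda_r|)$ against the radial contraction
rate $\lambda_r$; at $dt = 0.005$ this bias is about $1.7\times10^{-3}$,
shrinking linearly with $dt$.  It is far below the 0.5 classification
threshold and has no effect on state labeling.  A guard aborts
integration if any $|Z_i|$ exceeds 10; with $a < 0$ the drift is
contracting at large $|Z|$, so the guard only trips for user-supplied
non-contracting parameter sets.

The noise amplitude is $\sigma = 0.3$ per component per unit time.  The
model itself does not fix $\sigma$; it was calibrated once so that a
single uncoupled node at the operating point has a finite but non-trivial
escape time within the default duration — measured across replicates, a
solo node spends on average roughly half of a 500-unit simulation in the
limit-cycle state, leaving room on both sides for coupling to matter.
All tests and shipped defaults use this value; it is deliberately not a
per-analysis tuning knob.

Initial conditions default to `random_disk`: each node starts uniformly
on the disk of radius 1.5, independently, which covers both basins of
attraction.  With this choice the BNI includes both escape-time effects
and basin-occupancy effects; the `at_steady_state` and `on_limit_cycle`
modes provide the deterministic boundary cases (BNI exactly 0 and 1 with
$\sigma = 0$) used by the tests.

## Brain network ictogenicity

A node is in the seizure state when its oscillation has local extrema of
magnitude above 0.5.  Because the limit cycle is circular ($|Z|$ constant
on it), the extrema of $x = \mathrm{Re}(Z)$ exceed 0.5 exactly when the
envelope $|Z|$ does, so the default classifier thresholds the modulus
directly; a windowed local-extrema mode (window defaulting to one
oscillation period) is retained for non-circular regimes and agrees with
the modulus rule on circular dynamics.  No burn-in is discarded: the BNI
is meant to be sensitive to how quickly the system escapes the background
state, so the transient is the signal, not an artifact.

Per node, the time fraction spent in the seizure state is computed over
the whole record; the BNI is the mean of these fractions over nodes, and
ensemble BNI averages over independent replicates (fresh initial
conditions, frequency jitter, and noise per replicate).

## Functional-network inference

For signal data, networks are built channel-pair by channel-pair from the
phase-locking factor

$$c_{ij} = \left|\frac{1}{N_s}\sum_{k=1}^{N_s}
  e^{i\Delta\phi_{ij}(t_k)}\right|,$$

with instantaneous phases from the Hilbert analytic signal of the
band-passed data.  Implementation choices, all package decisions:

* Filters are zero-phase forward–backward Butterworth of order 4
  (band-pass and band-stop); pass-band gain and stop-band rejection are
  verified to within 5% in the tests.
* The recommended preprocessing chain mirrors standard resting-state EEG
  practice: 1–70 Hz band-pass, 48–52 Hz notch, then the 6–9 Hz low-alpha
  analysis band.
* The first and last 0.5 s of the phase series are discarded before the
  PLF sum to suppress filter and Hilbert end-transients.
* The self-PLF (identically 1) is excluded: the diagonal is zero so that
  degrees count only true edges.

## Graph measures and artificial networks

Degrees are weighted row sums (edge counts for binary graphs); MD and DV
are their mean and population variance.  The binary clustering
coefficient is Watts–Strogatz (zero for degree below 2); for weighted
networks the Onnela geometric-mean variant is used, since no single
weighted CC definition is canonical — this choice only affects weighted
descriptive summaries, not the modeling pipeline, which runs on binary
networks.

Binarization preserving MD scans thresholds over the distinct
off-diagonal weights, keeps edges strictly above threshold, and picks the
threshold minimizing $|MD_{bin} - MD_w|$, breaking ties toward the lower
threshold (denser network).  Adjacent thresholds move MD by $2/N$ per
edge, so the achieved gap is at most about one edge increment — on
19-node networks with continuous weights, at most $2/19 \approx 0.105$.
An input that is already 0/1 is returned unchanged.

Degree-preserving randomization uses double-edge swaps (reject any swap
creating self-loops or duplicate edges), the standard well-defined
procedure that provably preserves every node's degree while scrambling
higher-order topology; the default budget of $10\times$ the edge count in
attempted swaps is a common mixing heuristic.  Connectivity of the result
is *not* enforced — nothing in the modeling protocol requires connected
graphs.  That the surrogates genuinely differ in topology from their
source is confirmed through the adjacency spectrum, which is invariant
under relabeling but not under rewiring.

## Synthetic data: what it emulates and what it does not

The cohort generator draws, per subject, a target weighted MD uniformly
from a group-specific range and realizes it exactly (to $10^{-6}$) by
rescaling symmetric Beta(2, 2) weights in $[0,1]$.  The shipped presets —
control MD in $[4, 6]$, patient MD in $[7, 9]$, 19 nodes, 20 subjects per
group — emulate the *kind* of separation reported for clinical
resting-state cohorts; the clinical per-subject values are not published
as numbers, so these ranges are package conventions, stated once and used
everywhere.  Note what the generator does not emulate: clustering
structure, hubs, spatial electrode correlations, or any weight structure
beyond the targeted MD.  Passing tests therefore demonstrate the
MD-to-ictogenicity mechanism, not fidelity to clinical network topology.
A second generator produces exact-MD binary graphs (uniform over graphs
with a fixed edge count) for degree sweeps beyond what $[0,1]$ weights
can reach (MD above $\approx 9$ at 19 nodes cannot be realized by
Beta-rescaled weights).

The signal generator drives Kuramoto-style phase dynamics: all channels
share a common 7.5 Hz carrier, independence comes from per-channel phase
diffusion (`noise_level` rad/$\sqrt{s}$), and dependence from pairwise
phase pulling with strength $\kappa_{ij} \in [0,1]$ and gain 5 rad/s.
The phase-difference concentration grows with
$g\kappa/\sigma_\theta^2$, so estimated PLF rises monotonically with
$\kappa$, reaching 1 in the fully coupled noiseless limit (all phases
identical, since carriers and initial phases are common) and falling to
the small-sample floor for $\kappa = 0$.  These signals have controllable
PLF ground truth by construction; they are not EEG morphology emulations.

## Statistics and the experiment runner

Group comparisons use the Kruskal–Wallis rank test (chi-squared
approximation, tie-corrected; identical observations give $H = 0$,
$p = 1$ by convention), with Bonferroni-corrected pairwise rank
comparisons at family-wise level 0.05.  An exact-enumeration permutation
check is kept alongside for small groups; at five observations per group
the chi-squared approximation tracks the exact null to within about 0.1
and agrees on the 0.05 decision in the tested fixtures.

`run_experiment()` summarizes each subject as the mean BNI over the
`n_networks` $\times$ `n_sims` grid before group testing (mean of all
replicates; the alternative, averaging per network first, changes nothing
for equal-sized grids), then tests binary MD, DV, mean CC and mean BNI
between groups.  All seeds derive deterministically from one master seed,
so reports regenerate bit-identically.  Failed subjects are recorded in
the report rather than silently dropped.

Two empirical notes from the shipped configuration, both visible in the
test suite: the programmed MD separation survives binarization
emphatically (Kruskal–Wallis $p < 10^{-7}$ at 20 subjects per group),
while the DV difference between groups — which is emergent rather than
programmed, and is exactly invariant under degree-preserving
randomization — has reduced effect size at this cohort size, so only its
direction (patient above control) is asserted.

## Problem sizes

The reference protocol (30 surrogate networks per subject, 30 simulations
each) is a configuration default.  The shipped analyses use reduced grids
chosen once: the acceptance analysis runs 20 + 20 subjects with 5
surrogate networks and 10 simulations per network at full duration 500,
and the degree sweep uses 10 networks $\times$ 10 simulations per MD
level.  At these sizes the group separation in mean BNI is already
decisive, and the BNI ensemble means across MD $\in \{2, 6, 10, 14\}$
order strictly.

## Known limitations

* The model is phenomenological: nodes are normal-form oscillators, not
  physiological neural masses, and edges are functional couplings, not
  axonal connections.
* BNI as defined measures time-fraction only; event durations and
  inter-event intervals are outside its scope.
* With the default `random_disk` initialization and calibrated noise, BNI
  saturates near 1 for dense networks (MD $\gtrsim$ 10); the mechanism's
  ordering remains detectable, but contrasts between two dense networks
  compress.
* The weighted clustering coefficient is one of several reasonable
  definitions; comparisons against other software should check which
  variant is in use.
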