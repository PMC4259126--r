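# ictonet

Does a brain network's wiring alone make it more likely to generate
seizures?  `ictonet` implements a computational approach to that question
for functional networks inferred from resting-state EEG: each network node
is an abstract bistable oscillator whose steady state represents
background activity and whose high-amplitude limit cycle represents
seizure dynamics, and the network's **brain network ictogenicity (BNI)**
is the average fraction of simulation time its nodes spend in the
seizure state.  The central mechanism the package reproduces: networks
with higher mean node degree transition into seizure dynamics more
readily.

## The model

Each of the N nodes evolves as a complex variable

    dZ_i/dt = (a|Z_i|^4 + b|Z_i|^2 + c + iω_i) Z_i + s Σ_j G_ij Z_j + ε_i(t)

with {a, b, c, ω} = {−1, 2, −0.9, 1 + δω}, δω ~ U[−0.2, 0.2] per node,
coupling matrix G scaled by s = 0.1, and independent complex white noise
ε_i of amplitude σ = 0.3.  At these parameters each node is bistable: a
stable fixed point at the origin coexists with a stable limit cycle at
|Z| ≈ 1.147, separated by an unstable circle at |Z| ≈ 0.827.  Noise
drives spontaneous escapes from background to seizure; input from coupled
neighbors accelerates them.  A node is in the seizure state when its
oscillation exceeds magnitude 0.5, and

    BNI = mean over nodes of (time in seizure state / simulation time).

Around the model, the package provides:

* **Functional-network inference** — zero-phase Butterworth filtering,
  Hilbert instantaneous phase, and the phase-locking factor
  `c_ij = |mean_k exp(iΔφ_ij(t_k))|` for every channel pair
  (`build_functional_network()`).
* **Graph measures and surrogates** — mean degree (MD), degree variance,
  clustering (`graph_measures()`); MD-preserving binarization
  (`binarize_preserving_md()`); exact degree-preserving randomization by
  double-edge swaps (`degree_preserving_randomize()`,
  `make_artificial_ensemble()`); adjacency spectra.
* **Simulation and scoring** — Euler–Maruyama integration in compiled
  code (`simulate_network()`), state classification and BNI
  (`classify_states()`, `compute_bni()`, `bni_ensemble()`).
* **Synthetic data** — weighted-network cohorts with programmed MD
  separation and phase-coupled oscillatory signals with PLF ground truth
  (`generate_weighted_cohort()`, `generate_coupled_signals()`).
* **Statistics** — Kruskal–Wallis group tests with Bonferroni post hoc
  comparisons and a deterministic end-to-end experiment runner
  (`run_experiment()`).

## Worked example

Score a sparse and a dense random network, then run a small two-group
experiment:

```r
library(ictonet)

radial_equilibria(node_parameters(-1, 2, -0.9, 1))
#>      radius stability
#> 1 0.0000000    stable
#> 2 0.8269052  unstable
#> 3 1.1472697    stable

sparse <- random_binary_network(19, mean_degree = 2, seed = 1)
dense  <- random_binary_network(19, mean_degree = 10, seed = 1)
bni_ensemble(coupling_matrix(sparse), n_sims = 10, seed = 7)$bni
#> [1] 0.8173241
bni_ensemble(coupling_matrix(dense), n_sims = 10, seed = 7)$bni
#> [1] 0.9992484

cohort <- c(
  generate_weighted_cohort(cohort_spec(6, md_range = c(4, 6), seed = 1)),
  generate_weighted_cohort(cohort_spec(6, md_range = c(7, 9), seed = 2)))
report <- run_experiment(cohort, rep(c("control", "patient"), each = 6),
                         experiment_config(n_networks = 2, n_sims = 3,
                                           seed = 5))
report
#> <experiment_report> 12 subjects, groups: control, patient
#>   binary_md  H =  8.337  p = 0.003885  means: control=4.789 patient=8.316
#>   binary_dv  H =  0.000  p = 1  means: control=3.757 patient=3.729
#>   binary_cc  H =  5.026  p = 0.02497  means: control=0.307 patient=0.458
#>   mean_bni   H =  8.308  p = 0.003948  means: control=0.977 patient=0.999
```

The BNI of the dense network (mean degree 10) is far higher than that of
the sparse one (mean degree 2): with more edges per node, activity in any
seizing neighbor drives the rest of the network out of the background
state sooner.  In the cohort experiment the patient-like group (mean
degree 7–9) shows significantly higher mean BNI than the control-like
group (4–6) even at this reduced protocol — the package's headline
mechanism.

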