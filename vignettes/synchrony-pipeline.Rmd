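---
title: "State-dependent synchrony and functional connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent synchrony and functional connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`synconn` analyses simultaneously recorded spike trains from a 16-contact,
50 µm-pitch single-shaft probe spanning cortical layers 2/3–5, and asks how
sensory stimulation changes the synchrony structure of the recorded
population. The pipeline runs from unit quality control through pairwise
synchrony metrics and a three-criterion functional-connectivity
classification to network topology, tuning congruence and recovery
dynamics. Because no public recording accompanies the analysis, the package
ships a synthetic-session generator with a closed-form correlation oracle;
every statistical claim the test suite makes is made against that generator
or against hand-enumerable fixtures.

## States and pairwise synchrony

Stimulus events (200 ms ramp-and-hold whisker deflections delivered at
0.5 Hz, or ~1.82 s artificial-whisking trains of 10 cycles at 5.5 Hz)
segment the session into a *spontaneous* state (the 600 ms preceding each
onset) and an *evoked* state (the stimulus window). Same-state windows are
pooled across trials.

For every unordered pair of units and every state the pipeline computes:

* the Pearson correlation of binned spike counts (default bin 10 ms; the
  bin width is a free parameter — 10 ms is wide enough that counts are not
  dominated by the few-millisecond spike jitter, and narrow enough to
  reflect the same fast synchrony the correlogram criterion targets), with
  a two-sided p-value from the `t = r sqrt((n-2)/(1-r^2))` transform;
* the cross-correlogram over ±50 ms at 1 ms resolution, restricted to
  spikes inside the state's windows, summarised by
  `peak_z = (peak − mean)/SD` over all lag bins.

A pair is *functionally connected* in a state when (1) `r ≥ 0.2` in that
state, (2) `peak_z > 2`, and (3) both units exceed 3,000 spikes over the
session and 1,000 spikes in each of the two states. The correlation and
correlogram thresholds are applied within the state being classified
(the two states legitimately have different edge sets); the count floors
are a property of the units and apply to both states at once. A unit's
*connectivity index* is the percentage of the other `N − 1` analysed units
it is connected to; we read "percent of the total recorded neurons" with
the self excluded, since a self-connection is not a meaningful edge.

One calibration fact is worth stating explicitly: the correlogram peak is
a maximum over ~101 lag bins, so under full independence `peak_z` already
concentrates around the expected maximum of that many standardized draws
(≈2.5), and criterion (2) alone is permissive. The classification draws
its selectivity from the conjunction with the `r ≥ 0.2` criterion, which
independent pairs essentially never meet at the bin counts involved
(`SE(r) ≈ 1/sqrt(n_bins)` is of order 0.01 here).

Undefined correlations (a unit silent in a state) flag the pair
not-evaluable and never abort a run; such pairs are simply not connected.

## The synthetic generator

Correlated trains come from a multiple-interaction-process construction:
each assembly owns a latent Poisson *mother* process of rate λ_m, every
member unit independently copies each mother spike with probability `p_u`,
jitters it with a Gaussian of SD σ_j, and superposes an independent
Poisson background `b_u`. For count bins much wider than σ_j the expected
pairwise correlation has the closed form

ρ = p_i p_j λ_m / sqrt((p_i λ_m + b_i)(p_j λ_m + b_j)),

which the acceptance suite verifies empirically (±0.03 at 600 s of data
and 20 ms bins). This closed form is why the mechanism was chosen: the
generator can be validated against arithmetic rather than against itself.
At finite bin widths the jitter attenuates the realised correlation by
roughly `1 − E|Δ|/bin` (lag SD `sqrt(2) σ_j`); with the default
σ_j = 1.5 ms and 10 ms bins that factor is ≈0.85, which the default
parameters anticipate.

Stimulation affects the generator in two separate ways, deliberately
dissociating firing rate from synchrony:

* **Synchrony**: during an evoked window each unit's copy probability is
  multiplied by `γ_eff = γ (1 − d·dist/100 µm)(1 − i·incongruent)`, where
  `dist` is the unit's depth distance to its assembly centre and the
  incongruence term applies when the unit's tuning preference differs from
  its assembly's. After offset the factor relaxes back to 1 as
  `1 − (1 − γ_eff) exp(−t/τ)`, applied in 100 ms piecewise-constant steps
  so the whole generator remains a simple inhomogeneous thinning.
* **Rate**: an independent Poisson component of rate
  `gain · exp(−Δ²/2w²)` is added during evoked windows, where Δ is the
  circular distance between the trial's deflection angle and the unit's
  preferred angle (width `w`, default 60°), or the grade-index distance
  for textures. Rates can therefore rise while synchrony falls.

Every generated train passes through an absolute refractory filter
(default 2.5 ms): superposed Poisson processes otherwise violate the
minimum-ISI criterion of the quality-control battery for every unit,
which no real well-sorted single unit would.

### Default study conditions

The defaults in `session_config()` define the conditions under which all
pipeline-level tests run, chosen once from the closed form above:
16 units (one per contact, 200–950 µm depth) in 4 assemblies interleaved
across depth; λ_m = 10 Hz; per-unit copy probabilities uniform on
[0.55, 0.9]; log-normal backgrounds with median 5 Hz clipped to [2, 20] Hz
(per-layer rate distributions are not constrained by published data; a
log-normal with a few-Hz median is the field's usual description of
cortical rates); σ_j = 1.5 ms; γ = 0.9 with distance penalty 0.05 per
100 µm and incongruence penalty 0.2; recovery τ = 1.2 s; tuned evoked gain
2 Hz. Under these conditions spontaneous same-assembly correlations fall
around 0.25–0.45 and evoked ones around 0.15–0.3, so stimulation
disconnects the weaker third-to-half of the edges — a graded 30–50%
connectivity-index reduction with the evoked edge set a near-subset of the
spontaneous one, the regime the analyses are designed to resolve. Ramp
sessions default to 600 trials and whisking sessions to 200 trials at a
6 s period (the whisking inter-train interval is not a constrained
quantity; 6 s leaves ≈3.5 recovery time constants between trains), sizes
at which the 3,000/1,000 count floors are attainable for units in the
2–20 Hz range rather than vacuously failing.

Desynchronization sweeps (γ ∈ {0.9, 0.6, 0.3}) use the whisking protocol:
with the ramp protocol's 2 s period the post-offset gap is only 1.5 τ, so
at small γ the "spontaneous" pre-stimulus window is itself substantially
desynchronized and the spontaneous/evoked contrast collapses — a real
phenomenon, but not the contrast under study.

What the generator does **not** emulate: biophysical membrane dynamics,
oscillatory or state-switching background (up/down states), spike
waveforms beyond scalar summary streams, bursting, and rate
non-stationarities other than the stimulus terms. Passing tests therefore
show that the pipeline recovers the statistical structure it claims to
measure — not that anesthetized cortex satisfies the thinning model.

## Unit quality control

The acceptance battery mirrors standard extracellular practice: firing
rate > 0.5 Hz; minimum ISI > 2 ms; an exponential-like ISI distribution —
operationalised as R² ≥ 0.8 of a log-linear single-exponential fit to the
2–500 ms ISI histogram (10 ms bins, non-empty bins only), since "smooth
exponential-like" is otherwise qualitative; waveform stability between the
first and last 20% of spikes (two-group one-way ANOVA per measure, α =
0.05, no multiplicity correction — two underpowered tests are deliberately
conservative gates here); cluster separation by one-way MANOVA (Wilks' Λ
with the F approximation) on the waveform feature cloud of each contact;
and four cluster-validity indices (Dunn, Davies–Bouldin, pseudo-F =
Calinski–Harabasz, J3 = between/within scatter) of which at least two must
be in the "good" band and none "poor". The pseudo-F and J3 magnitudes
depend on the feature units; the conventional absolute bands (100,000 /
50,000 for pseudo-F) are kept as configurable defaults applied to raw
feature values. Duplicate detection treats a pair with zero-lag 1 ms
binned-count correlation > 0.9 as one neuron recorded twice ("zero-lag
bin" is our reading of the criterion; a peak-anywhere variant would only
be more aggressive) and excludes the lower-count member. Criteria that
cannot be evaluated (no waveform streams, single-unit contacts) are
reported as not-evaluable and do not reject a unit.

## Topology, distance, layers, congruence

All topology statistics operate on the per-state graphs. The
common-neighbor statistic partitions pairs by whether they share at least
one connected neighbor *in the same graph being scored* and compares each
partition's connection probability with the Erdős–Rényi expectation at
the observed edge count (graph density) — the simplest null consistent
with "random connectivity"; a degree-preserving rewiring null is
available as an option (`rewire_null`). Pair distance is the absolute
depth difference (single vertical shaft; no lateral information exists),
binned at the 50 µm pitch. Layers default to L2/3 = [200, 550), L4 =
[550, 750), L5 = [750, 1050] µm when labels are absent, spanning the probe
geometry. Tuning congruence compares the fraction of edges whose
endpoints share a preference with the finite-sample same-preference pair
fraction `Σ n_k (n_k − 1) / (N (N − 1))` of the same unit set.

## Tuning

The evoked response is the baseline-subtracted spike count per stimulus,
with the baseline rate pooled from the 600 ms pre-stimulus windows and the
response window defaulting to the stimulus duration (the exact response
window used for the original polar plots is not constrained; the full
stimulus window is the least arbitrary choice). The preferred category is
the argmax of the per-category mean response; exact ties break
deterministically toward the lowest category and are flagged rather than
resolved by vector averaging, because the congruence analysis needs one
category per unit.

## Dynamics and recovery

The time-resolved connectivity index pools, for each latency relative to
onset, the 500 ms window at that latency across all trials (100 ms grid
step), recomputes the pairwise metrics from the pooled bins and rebuilds
the graph; the spike-count floors stay at session level since they are
unit properties. Pooling at matched latency rather than sliding over
continuous time keeps enough bins per estimate even for short windows.
The window/step defaults resolve a ~1 s recovery with ≥10 points on the
recovery limb. Recovery is fit by bounded Levenberg–Marquardt least
squares to `CI(t) = CI_∞ − (CI_∞ − CI_0) exp(−(t − t_offset)/τ)` on
post-offset points only, τ initialised at 1 s and bounded to (0.01, 30] s;
standard errors come from the Jacobian-based covariance. Non-convergence
returns a diagnosable failure object, never an exception. Note the index
is a thresholded readout of the underlying correlations, so the fitted τ
is a population-level effective constant; on synthetic sessions with
τ_gen = 1.2 s the end-to-end estimate lands within a few tenths of a
second of the truth, which is the resolution claimed.

## Numerical conventions

Bins are half-open `[start, start + bin)` with partial trailing bins
dropped; a spike exactly on a boundary joins the bin it starts. Jittered
coincidences leak across window boundaries, so windowed correlations are
attenuated by roughly the jitter spread over the window length — about
0.006 in r for 600 ms windows at the default jitter, proportionally less
for longer windows. This is an order of magnitude below the 0.2
connectivity threshold but is statistically detectable when comparing
states with different window lengths at high bin counts, which is why
equality claims between states are made as bounded-difference claims
rather than null-hypothesis tests.
Correlogram lags live on a symmetric 1 ms grid centred on zero, and the
optimized binary-search enumeration is tested for exact equality against
the brute-force double loop. Edge lists are canonical
(`unit_id_a < unit_id_b`, sorted), making graph artifacts diffable. All
randomness flows through explicit integer seeds (R's default Mersenne
Twister, restored after use), and identical `(config, seed)` pairs yield
byte-identical sessions.

## Problem sizes

The test suite and the acceptance script use: 600 s two-unit runs for the
correlation oracle; 16-unit sessions of 600 ramp trials (~20 min of
simulated recording) or 200 whisking trials (~20 min) for pipeline-level
checks, 10–20 seeds per claim; 100 seeds for graph-null calibrations;
500 seeds for the type-I-error calibration of the stability and
separation tests. These sizes put simulation error comfortably inside
each claim's tolerance (e.g. `SE(r) ≈ 1/sqrt(30000)` bins for the ±0.03
oracle check).

## Known limitations

* The pipeline starts at sorted spike times; no spike sorting is
  performed, and the validity indices evaluate *given* labels.
* Connectivity is undirected and unweighted; the symmetric metrics cannot
  support directionality claims, and no jitter-corrected or
  shift-predictor correlogram significance is computed.
* The ER-density null for the common-neighbor comparison ignores degree
  heterogeneity; the rewiring null is provided where that matters.
* Small populations (16 units) quantize the connectivity index in steps
  of 100/15 ≈ 6.7%, which makes weak-modulation recovery fits
  (γ close to 1) unstable — the recovery analysis is designed for the
  strong-desynchronization regime.
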