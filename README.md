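# synconn

State-dependent synchrony and functional connectivity analysis of
multi-unit cortical spike trains.

## The problem

Simultaneous extracellular recordings from a 16-contact linear probe
(50 µm pitch, layers 2/3–5) yield a population of sorted single units
whose correlated firing defines a *functional-connectivity* graph. The
scientific question this package serves: how does sensory stimulation
(passive whisker deflection, or artificial whisking against textured
surfaces) reorganise that graph — how much pairwise synchrony is lost
during stimulation, which connections (near/far, within/across layers,
tuning-congruent or not) survive, and how quickly connectivity recovers
after stimulus offset.

`synconn` implements the full analysis chain for electrophysiologists
working with such recordings, plus a seeded synthetic-session generator
with known ground truth so the chain is testable end to end without any
recorded data.

## The method

For each unordered pair of units *(i, j)* and each state *s* (spontaneous
= 600 ms pre-stimulus; evoked = the stimulus window, pooled across
trials):

* Pearson correlation of binned spike counts,
  *r_s(i, j)* (10 ms bins), with *p* from
  *t = r √((n−2)/(1−r²))*;
* cross-correlogram over ±50 ms (1 ms bins), summarised by
  *peak_z = (peak − mean)/SD* over the lag bins.

The pair is functionally connected in state *s* iff

1. *r_s ≥ 0.2*,
2. *peak_z > 2*, and
3. both units have > 3,000 spikes in the session and ≥ 1,000 spikes in
   each state.

Each unit's **connectivity index** is *100 · degree / (N − 1)*, the
percentage of other analysed units it is connected to. Downstream
statistics: relative desynchronization *(evoked − spont)/spont*; the
fraction of evoked edges also present spontaneously; common-neighbor
connection probability against the Erdős–Rényi expectation
*2|E|/(N(N−1))*; connection probability by depth distance and by layer;
tuning-congruence against the finite-sample expectation
*Σ n_k(n_k−1)/(N(N−1))*; and a bounded mono-exponential fit
*CI(t) = CI_∞ − (CI_∞ − CI_0) e^{−(t−t_off)/τ}* to the time-resolved
index after stimulus offset.

The generator produces correlated trains by thinning latent Poisson
"mother" processes (copy probability *p_u*, jitter σ_j, background
*b_u*), which gives the closed-form expected pairwise correlation
*ρ = p_i p_j λ_m / √((p_i λ_m + b_i)(p_j λ_m + b_j))* used as the
package's validation oracle. See
`vignettes/synchrony-pipeline.Rmd` for the complete model description.

## Worked example

```r
library(synconn)

cfg <- session_config(seed = 1)            # default study conditions
ses <- generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                        protocol = "artificial_whisking", n_trials = 200,
                        seed = 2, waveform_streams = TRUE)
ses$spikes
#> <spike_train_set> 16 units, 232201 spikes, 1206.818 s

w  <- make_state_windows(ses$events)
qc <- apply_qc(ses$spikes, ses$meta, w)
pm <- pair_metrics(ses$spikes, w, units = qc$accepted$units)
gs <- build_graph(pm, "spontaneous")
ge <- build_graph(pm, "evoked")
gs; ge
#> <connectivity_graph> state=spontaneous, 16 nodes, 24 edges, mean index 20.0%
#> <connectivity_graph> state=evoked, 16 nodes, 14 edges, mean index 11.7%

overlap_fraction(ge, gs)
#> [1] 1
tab <- connectivity_index_table(gs, ge)
mean(tab$relative_change[is.finite(tab$relative_change)])
#> [1] -0.4166667
common_neighbor_stats(gs)[c("p_common", "p_nocommon", "p_expected")]
#> $p_common    [1] 1
#> $p_nocommon  [1] 0
#> $p_expected  [1] 0.2
```

Reading: whisker activation dissolved 10 of the 24 spontaneously present
functional connections (a 42% mean drop in the connectivity index), every
evoked edge was already present spontaneously (overlap 1), and pairs
sharing a connected neighbor are far more likely to be connected than the
random-graph expectation — the assembly structure the generator planted
and the analysis recovered.

`run_pipeline(pipeline_config(out_dir, seed = 1))` runs the same chain as
one seeded, logged pipeline (simulate → qc → pairs → connect → topology →
tuning → dynamics) and writes the stage artifacts plus a `summary.json`.

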