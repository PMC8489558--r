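Package: synconn
Title: State-Dependent Synchrony and Functional Connectivity Analysis of
    Cortical Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-unit extracellular recordings from
    linear silicon probes: unit quality control (inter-spike-interval and
    firing-rate criteria, waveform stability, cluster-separation statistics
    and cluster-validity indices, duplicate-unit exclusion), state-resolved
    pairwise synchrony metrics (binned-count Pearson correlation and
    cross-correlogram peak score), a three-criterion functional-connectivity
    classification with per-neuron connectivity index, network-topology
    statistics (common-neighbor connection probability against a random
    null, distance and layer dependence, tuning-congruence probabilities),
    angular and texture-coarseness tuning estimation, time-resolved
    connectivity with mono-exponential recovery fitting, and a seeded
    synthetic-session generator based on thinned latent Poisson processes
    with known ground-truth correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
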