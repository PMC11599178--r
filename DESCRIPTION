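Package: normnet
Title: Social-Network Position and EEG Dynamics of Group-Norm Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: An end-to-end pipeline linking a person's position in a directed
  friend-nomination network to electrophysiological responses recorded while
  they process group norms delivered as peer feedback. The package computes
  directed social-network centralities (in-degree, out-degree, betweenness),
  simulates the adaptive peer-feedback rating task, extracts windowed ERP
  component amplitudes (N2, P3, LPP) over nine scalp regions with
  repeated-measures ANOVA and Greenhouse-Geisser correction, runs a
  spatiotemporal cluster-based permutation test on paired ERP contrasts,
  builds phase-locking-value (PLV) functional brain networks in four
  frequency bands, and sweeps sparsity-thresholded binary graphs for global
  efficiency, clustering, assortativity and local efficiency with AUC
  summaries. A synthetic-data generator produces nomination graphs,
  behavioral sessions and multi-channel EEG epochs with known ground truth
  so every stage can be validated against injected effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'behavior.R'
    'brain_graph.R'
    'cluster_perm.R'
    'connectivity.R'
    'erp.R'
    'filtering.R'
    'io.R'
    'montage.R'
    'normnet-package.R'
    'simulate_eeg.R'
    'simulate_network.R'
    'simulate_session.R'
    'social_network.R'
    'utils.R'
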