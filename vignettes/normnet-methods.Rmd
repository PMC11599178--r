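---
title: "Methods: linking social-network position to EEG group-norm processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking social-network position to EEG group-norm processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normnet)
```

# The scientific question and the pipeline

Does a person's position in their social network go together with how their
brain processes group norms? The analytic chain implemented here connects
three layers of data collected from one intact social group:

1. **Social network**: a directed friend-nomination graph over the group
   (each person names 1--5 particularly close friends), plus a
   questionnaire count of regularly contacted real-life friends and family.
   From the graph we compute in-degree (received nominations), out-degree
   (sent nominations) and betweenness centrality.
2. **Behavior**: an adaptive social-influence rating task. Each person
   first rates 60 exercise images on a 0--9 scale. In a second session the
   same images return, half with a fabricated "group rating" displayed
   (peer-feedback context) and half without (non-feedback context), and the
   person rates again.
3. **EEG**: 64-channel recordings epoched around image onset
   (-200 to +1000 ms, 500 Hz), analyzed as windowed ERP components, as a
   spatiotemporal cluster-based permutation contrast, and as
   phase-locking-value (PLV) functional networks summarized by binary-graph
   topology.

The statistical claims the pipeline targets are associations: between
centrality and the per-subject condition differences of ERP components,
and between centrality and the topology / synchrony of the functional
networks.

Because the human data underlying this design are not redistributable,
the package ships a first-class synthetic-data generator
(`simulateSocialNetwork()`, `simulateSession()`, `simulateEEG()`) that
emulates every statistical structure the analysis assumes, with
configurable ground truth. All validation in `tests/` runs against this
generator or against closed-form/brute-force oracles.

# The behavioral task and its statistics

The displayed group rating is the participant's initial rating shifted by
an offset drawn from $\{\pm1, \pm2, \pm3\}$, with a boundary-reflection
rule: if the shifted value leaves the 0--9 scale, the direction of the
shift is reversed (`makeGroupRating()`). An initial rating of 2 with an
intended offset of $-3$ therefore displays $5 = 2 + 3$. Reflection keeps
the result in range for the whole $10 \times 6$ input grid, which the
tests check exhaustively.

Three behavioral statistics are computed per subject
(`influenceScore()`, `conformingRate()`, `behaviorSummary()`):

* **influence score** -- the proportion of trials whose final rating
  differs from the initial rating, per condition;
* **conforming rate** -- among *changed* peer-feedback trials, the
  fraction whose change moved toward the displayed rating
  ($\mathrm{sign}(\text{final}-\text{initial}) =
  \mathrm{sign}(\text{shown}-\text{initial})$). Whether the published
  "tendency to conform" divides by changed trials or by all feedback
  trials is not stated; both denominators are implemented and
  changed-trials is the default, being the reading most consistent with a
  tendency *among adjustments*;
* **RT contrast** -- paired $t$ between condition means.

**Effect sizes.** The effect sizes printed alongside the paired tests in
this literature follow $d = 2t/\sqrt{df}$ (e.g. $t = 3.66$, $df = 26
\Rightarrow d = 1.44$), which is the two-sample conversion formula applied
to a paired design. `pairedContrast()` reports this convention as `d` for
fidelity, and the conventional paired $d_z = \bar{x}_{diff}/s_{diff}$ as
`dz`, so the unusual convention is never propagated silently.

# Social-network metrics

`betweennessCentrality()` implements Brandes' dependency accumulation on
the *directed* nomination graph and reports raw (unnormalized)
shortest-path membership sums:
$b(v) = \sum_{s \neq t \neq v} \sigma_{st}(v)/\sigma_{st}$, with
disconnected pairs contributing nothing. The source study does not state
whether its betweenness treated nominations as directed or symmetrized,
nor whether values were normalized; the reported scale (mean 3.33, SD 3.09
on 43 nodes) is compatible with several conventions. We default to
directed/unnormalized -- the nomination relation is genuinely asymmetric --
and expose `directed` and `normalized` flags for the alternatives. The
implementation is verified against exhaustive shortest-path enumeration on
random digraphs and cross-checked against igraph.

# ERP analysis

Preprocessing is deliberately minimal and linear: a zero-phase band-pass
(0.1--30 Hz), common-average reference, baseline correction over
$[-200, 0]$ ms, and rejection of any trial exceeding $\pm 75\,\mu V$ on
any channel.

**Filter realization.** Filters are realized in the frequency domain:
each trace is reflection-padded by 200 ms, transformed, multiplied by the
squared magnitude response of an order-2 Butterworth band-pass (the
response a forward--backward order-2 filter applies, i.e. 4th-order
effective roll-off), and transformed back. This is zero-phase by
construction, vectorizes across all trials and channels in one FFT pass,
and matches forward-backward IIR filtering away from the epoch edges. Only
corner frequencies, not a realization, are dictated by the source design.

**Windows and regions.** Component amplitudes are trial-averaged ERPs
averaged over closed windows N2 180--280 ms, P3 300--500 ms, LPP
600--800 ms (boundary samples included) and over nine scalp regions
(left/medial/right $\times$ frontal/central/parietal; 52 channels in
total). The 180--280 ms window is labeled FRN/N2/N2pc interchangeably in
the feedback literature; the neutral label N2 is used and the window is
the operational definition.

**ANOVA.** `rmAnova()` fits the within-subject 2 (feedback) $\times$ 3
(region) $\times$ 3 (hemisphere) design through the multivariate
linear-model route (`car::Anova`), reporting $F$, Greenhouse--Geisser
$\varepsilon$, GG-corrected $p$ for every effect, and partial
$\eta^2 = SS_{effect}/(SS_{effect}+SS_{error})$. For the 1-df feedback
effect sphericity holds by construction and $\varepsilon = 1$ exactly.
Simple effects after an interaction pool hemispheres within each lobe and
test the feedback contrast per lobe.

**Correlations and FDR.** `centralityCorrelations()` correlates each
centrality metric with the per-subject condition-difference amplitude in
every region. The published correction description is ambiguous about the
family; the default family is all region $\times$ metric tests of one
component (36 tests with the four standard metrics), with a per-metric
alternative. Benjamini--Hochberg adjustment is delegated to
`stats::p.adjust(method = "BH")` and verified in the tests against a
brute-force step-up oracle.

# Cluster-based permutation test

`clusterPermutation()` implements the standard nonparametric family-wise
test for a paired contrast: paired $t$ at every (channel, sample); points
with $|t|$ above the two-sided $\alpha = 0.05$ critical value grouped into
polarity-pure connected components under (spatial neighbor) $\vee$
(adjacent sample) adjacency; cluster mass = summed $t$; and a null of the
*maximum absolute* cluster mass over random within-subject sign flips.
Per-cluster Monte Carlo $p = (1 + \#\{null \ge |mass|\})/(1 + n_{perm})$,
the +1 convention avoiding zero $p$-values. The max-statistic reading is
the de-facto standard interpretation of per-cluster Monte Carlo testing.
With 12 or fewer subjects an exact variant enumerates all $2^n$ sign
patterns. No minimum cluster size is imposed.

**Channel adjacency.** The source analysis does not state its channel
neighborhood template. The package derives adjacency by thresholding
Euclidean distance between schematic 10--20 grid positions packaged with
the default montage; the threshold (1.45 grid units) gives a median of 6
neighbors per channel, typical of 64-channel template neighborhoods, and
is exposed in the layout configuration so other conventions can be swapped
in.

**Calibration.** The acceptance tests verify, at a reduced geometry chosen
for runtime (20 subjects, 16 channels, 100 samples spanning 0--990 ms,
1000 partitions), that the family-wise false-positive rate on pure-noise
data lies in $[0.02, 0.09]$ over 200 simulated datasets, and that a
352--430 ms centro-parietal effect with a raised-cosine profile peaking at
1 noise-SD per point is detected in at least 90% of 100 runs. The peak
amplitude of 1 SD is the documented SNR of this power fixture.

# PLV connectivity and brain-graph topology

Band-limited phases come from the analytic signal (negative frequencies
zeroed in the spectrum) of epochs filtered into delta 0.5--4, theta 4--8,
alpha 8--12 and beta 14--20 Hz; gamma is excluded because the 30 Hz
low-pass applied against muscle artifacts leaves no usable gamma signal.
The published verbal definition of PLV ("absolute value of the
instantaneous phase difference") is imprecise; the standard estimator
consistent with the stated [0, 1] range is implemented:
$\mathrm{PLV}_{ij} = \left| \overline{ e^{i(\phi_i - \phi_j)} } \right|$,
the modulus of the mean phasor over the 0--1000 ms window, pooled over
samples and trials (a per-trial-then-average variant is available via
`perTrial = TRUE`; the source is silent on this choice). Mastoid and
cerebellar channels (M1, M2, CB1, CB2) are excluded, leaving 60 network
nodes. Phase estimates near epoch edges inherit the usual filter/transform
edge transients despite 200 ms reflection padding; exact identities (e.g.
constant-lag sinusoids locking at 1) are therefore tested with analysis
windows interior to the epoch by at least the transient length.

`binarizeNetwork()` keeps the $K = \mathrm{round}(s \cdot N(N-1)/2)$
strongest edges at each sparsity $s \in \{0.05, 0.10, \ldots, 0.5\}$, with
deterministic lexicographic tie-breaking. Four metrics are computed per
binary graph:

* **GE**, global efficiency: mean over ordered pairs of $1/d_{ij}$, with
  $1/\infty = 0$ for disconnected pairs. The published phrasing ("inverse
  of the average shortest path length") is undefined on disconnected
  graphs, which sparsity 0.05 on 60 nodes routinely produces; the standard
  average-of-inverses efficiency is the default and the literal variant is
  available as `variant = "inverse_average"`.
* **CC**, clustering coefficient: mean over nodes of
  $2T_v / (k_v(k_v-1))$, nodes with $k_v < 2$ contributing 0.
* **AC**, degree assortativity: Pearson correlation of endpoint degrees
  over edges, both orientations per edge (Newman's estimator); undefined
  (NA with a warning) on regular graphs.
* **LE**, local efficiency: mean over nodes of the global efficiency of
  the neighbor-induced subgraph, nodes with fewer than 2 neighbors
  contributing 0.

All four are verified against brute-force enumeration oracles on random
graphs. Curves over the sparsity grid are summarized by the trapezoidal
AUC; a left-Riemann step variant is provided because toolbox conventions
differ. Condition contrasts of per-subject AUCs reuse
`pairedContrast()`.

`edgewiseCentralityAssociation()` is the descriptive network screen:
per-edge Pearson correlation of the across-subject $\Delta$PLV
(peer-feedback minus non-feedback) with centrality, edges retained at raw
$p < 0.01$ (uncorrected by design, mirroring the published screen), and
connected components of the retained-edge graph reported with region
annotation.

# The synthetic-data generator

`simulateEEG()` builds each trial as the sum of three components.

**Background noise** is spectrally shaped Gaussian noise with power
$\propto \max(f, f_{knee})^{-\gamma}$, default exponent $\gamma = 1$ with
a 2 Hz knee, scaled to 4 µV broadband RMS. Real EEG background spectra
flatten below a knee of roughly 1--2 Hz; without the knee, near-DC drift
dominates window-mean variance and no plausible number of trials
stabilizes the ERP estimates. The default RMS is at the clean end of the
realistic range -- chosen once so that effects of the published magnitude
(0.3--1 µV window-mean differences) are recoverable from 30 trials per
condition at the cohort sizes used in testing; real recordings are noisier
and would need more trials for the same precision.

**Band oscillations with controlled coupling.** Each coupling group
places a sinusoid at the geometric-mean frequency of its band on a set of
channels. The oscillator phase is uniform per trial; each channel adds an
independent von Mises jitter with concentration $\kappa$. Two channels
jittered with mean resultant length $\rho(\kappa) = I_1(\kappa)/I_0(\kappa)$
have expected pairwise locking $\rho^2$, so $\kappa$ solves
$\rho(\kappa) = \sqrt{\mathrm{PLV}_{target}}$, with a small correction for
the additive in-band noise: each channel's phasor is attenuated by
approximately $\exp(-c\,\sigma_b^2/(A^2/2) / 2)$, where $\sigma_b$ is the
in-band noise RMS, $A$ the oscillation amplitude (default $6\sigma_b$, so
the correction stays small in every band), and $c = 0.36$ a pooling
factor calibrated empirically once against the pooled-estimator output.
The generator's empirical PLV hits targets in $[0.2, 0.9]$ within
$\pm 0.05$, checked in the tests at 200 trials per condition. Von Mises
draws use the Best--Fisher rejection sampler (wrapped-normal
approximation for $\kappa > 100$).

**ERP components** are raised-cosine bumps over the component window,
normalized to unit *window mean* so that the `diff` parameter (in µV) is
exactly the expected window-mean condition difference. The default effect
geometry mirrors the reported pattern: parietal N2 made more negative by
feedback ($-1$ µV), broad centro-parietal P3 increase ($+0.3$ µV),
frontal LPP increase ($+0.5$ µV), and a beta-band coupling drop under
feedback. A subject's standardized centrality $z$ enters through
`centralityLink` slopes: the LPP condition difference is
$0.5 + 0.6z$ µV by default, the 0.6 µV-per-SD slope being the linkage the
end-to-end recovery tests target.

What the generator does *not* emulate: volume conduction and a realistic
leadfield (channels are conditionally independent given the injected
structure), ocular/muscle artifact morphology (threshold-exceeding square
pulses stand in for artifacts), latency jitter of components, and
between-subject variability beyond the centrality link. Passing tests
therefore demonstrate that the pipeline recovers the statistical
structures it assumes -- not that real recordings satisfy those
assumptions. A caveat inherited from the default geometry: a slow
coupled oscillation (the delta group) overlapping an analysis window acts
as potent trial noise for window means in its channels, because one delta
cycle spans the epoch; the default delta group therefore sits on
central/parietal channels away from the frontal LPP channels that carry
the centrality link.

# Simulation sizes used in validation

Validation problem sizes were chosen to make Monte Carlo error small
relative to the tested margins while keeping the default suite fast:
permutation-test calibration uses 200 null datasets and 100 power runs at
the reduced 16-channel geometry with 1000 partitions; end-to-end recovery
uses 10 replicate cohorts of 27 subjects with full 64-channel, 60-trial
sessions (the recovery statistics -- the sign of the LPP--betweenness
correlation and of the beta local-efficiency contrast -- are far from
their decision boundaries, so 10 replicates bound the pass rate tightly);
generator calibration sweeps use 6--8 seeds at 200 trials per condition.

# Numerical conventions and degenerate inputs

* Sample 1 of an epoch sits at `epochStart` ms; analysis windows are
  closed intervals including boundary samples.
* The epoch container stores float32 little-endian amplitudes with a JSON
  sidecar; values round-trip exactly at float32 precision.
* Zero-variance inputs are flagged, not silently dropped: constant
  signals have undefined phase (NA + warning), zero-variance correlations
  are excluded from FDR families, regular graphs have undefined
  assortativity, and zero-variance difference maps produce guarded
  $\pm\infty$ $t$-values that enter cluster masses as $\pm 10^{12}$.
* Binarization ties are broken by fixed lexicographic pair order, making
  every topology value reproducible bit-for-bit.
* All generators take explicit seeds and restore the caller's RNG state.

# Known limitations

The average reference redistributes focal ERP effects (a bump on 18 of 60
channels reappears, attenuated and sign-flipped, on the others), so
window-mean recovery tests assert the injected values on
baseline-corrected unreferenced data, while the end-to-end tests run the
full referenced pipeline and assert signs and orderings. The
frequency-domain filter realization differs from a time-domain
forward--backward IIR within the first/last ~100 ms of an epoch (edge
transients are handled by reflection padding rather than initial-condition
matching). Betweenness on the 43-node graphs is exact; the implementation
is quadratic in nodes and not intended for large networks.
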