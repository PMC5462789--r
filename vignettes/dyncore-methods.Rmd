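---
title: "Methods: dynamic functional core networks from phase-coupled signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic functional core networks from phase-coupled signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncore)
```

## What the package computes

`dyncore` characterizes how hub structure in functional brain networks
reconfigures over sub-second time scales. The analysis chain is:

1. **Source estimation (optional).** Scalp recordings `X = G S + N` are
   inverted with the weighted minimum-norm estimate (wMNE),
   `S_hat = (G' W G + lambda I)^-1 G' W X`, where `W` is diagonal with
   entries inversely proportional to the squared norms of the lead-field
   columns and `lambda` defaults to 0.2. Vertex series are averaged into
   atlas regions after sign alignment.
2. **Connectivity.** Signals are band-pass filtered (zero-phase FIR),
   segmented into non-overlapping epochs with amplitude-based artifact
   rejection, and converted to instantaneous phases via the analytic
   signal. The phase-locking value
   `PLV(x, y) = |mean_t exp(j(phi_y - phi_x))|` is computed over the whole
   epoch (static) and in sliding windows (dynamic). A window must span at
   least 6 cycles of the band's central frequency; in the beta band
   (14-25 Hz, centre 19.5 Hz) this gives 308 ms, i.e. 300 ms at the
   package's 100-ms reporting resolution.
3. **Graph metrics.** Each PLV matrix is proportionally thresholded
   (keeping the top fraction of edge weights; edges keep their weights)
   and summarized per node by betweenness centrality (shortest paths on
   lengths `1/w`), vulnerability (relative global-efficiency drop on node
   deletion), strength, and the Onnela weighted clustering coefficient.
   Metrics are normalized by their mean over surrogate networks obtained
   by reshuffling edge weights over the fixed topology (500 surrogates in
   the reference setting).
4. **Modularity and hub classes.** Partitions from three algorithms
   (Newman leading-eigenvector, Louvain, Infomap; 100 runs each in the
   reference setting) are combined through an association matrix, pruned
   against a permutation null (entries must exceed the null's 95th
   percentile) and re-clustered with Louvain. Nodes are classified by the
   within-module degree z-score `Z` and the participation coefficient
   `P`: `Z > 1.5` marks a hub; among hubs `P < 0.3` is provincial and
   `P >= 0.3` is connector.
5. **Dynamics and statistics.** Per window: the top node of each metric
   (transition matrices between consecutive windows), the dominant
   resting-state network by strict majority of the window's significant
   nodes (fractional occupancy), and per-node role labels
   (role timecourses). Wilcoxon rank-sum tests compare each node's metric
   distribution against the pooled others; exact binomial tests flag
   enriched transition columns against a uniform-destination null;
   chi-squared goodness-of-fit tests flag nodes whose role rates deviate
   from the pooled rate. All tests are Bonferroni corrected (level 0.01
   by default).

`run_pipeline()` executes stages 2-5 on region signals (or directly on a
generator configuration) and returns a classed object with `print`,
`summary` and `plot` methods; every stage is also exported on its own.

## The synthetic generator

No resting-state recordings ship with the package, so every claim is
exercised on synthetic signals with planted ground truth. Each region is
`x_i(t) = cos(theta_i(t)) + noise`, with

`theta_i = w_i1 * theta_d1 + ... + w_iM * theta_dM + w_ip * p_i + 2 pi f_c t`,

a convex mixture of module **driver** phases and a **private** phase, all
stationary band-limited jitter processes (Gaussian noise low-passed with a
4th-order Butterworth filter, rescaled to a fixed sd) around the carrier
`f_c`, the band's central frequency. Because all randomness is in
zero-mean stationary deviations, pairwise PLV is controlled by the mixture
weights: the residual phase-difference variance of a pair is the sum of
squared non-shared weights times the jitter variance.

* An ordinary node of module `m` has `w_im = kappa_within`; module
  drivers share a global driver with weight
  `kappa_between / kappa_within`, so cross-module pairs share weight
  `kappa_between`.
* A **provincial hub** has elevated own-driver weight
  `kappa_within + hub_delta` (remainder private): its within-module edges
  are strictly stronger than its peers', giving high `Z` and `P ~ 0`.
* A **connector hub** has own-driver weight `kappa_within + hub_delta/2`
  and spreads the remaining weight equally over the other modules'
  drivers, with no private component. A naive connector that splits its
  weight equally over all `M` drivers cannot work: with members at
  `kappa_within >= 0.5`, its within-module residual variance is at least
  its peers', so its within-module degree never stands out and it would
  always fail the `Z > 1.5` hub gate. The elevated-own + spread design
  keeps `Z ~ 2` while making the hub's cross-module edges strictly
  stronger than baseline cross-module pairs, which is what real connector
  hubs look like in thresholded graphs (`P ~ 0.5-0.67`).
* A `regime_schedule` swaps hub configurations instantaneously at block
  boundaries; ground-truth labels for analysis windows follow the
  majority-overlap regime.

### Frozen defaults and why

| parameter | default | rationale |
|---|---|---|
| band | 14-25 Hz | beta rhythm, the band of interest for resting hub dynamics |
| `kappa_within` / `kappa_between` | 0.55 / 0.05 | coupling contrast 0.5: strong planted modules with weak global coupling |
| `hub_delta` | 0.2 | near-optimal own-coupling elevation: edge strength to a member with weight `k` is maximized at own weight `(1 + k)/2` |
| phase jitter sd | 1.5 rad | separates within-module PLV (~0.64) from cross-module (~0.35) without saturating either end |
| jitter bandwidth | band width / 3 (~3.7 Hz in beta) | realistic decorrelation time (~0.3 s) for an 11-Hz-wide rhythm; keeps >98% of signal power inside the band (phase-modulation sidebands) and gives sliding windows enough independent phase samples |
| `noise_sd` | 0.1 | 10% additive noise relative to unit oscillation amplitude |

The generator emulates: band-limited oscillations, block phase coupling,
hubs of both types, piecewise-constant regimes, additive sensor noise, and
linear mixing through a toy lead field. It does **not** emulate volume
conduction beyond linear mixing, 1/f background spectra, amplitude
dynamics or nonstationary noise — so passing tests certify the estimator
chain on its own model class, not performance on real EEG.

## Numerical and design choices

* **Weight-to-length map** for shortest paths is `1/w`
  (`-log(w)` available). The thresholded graph keeps original weights;
  binarized variants are out of scope.
* **Threshold rounding** is round-half-up on `proportion * N(N-1)/2`;
  cutoff ties break by ascending (row, column) index so results are
  deterministic.
* **Clustering** is the Onnela geometric-mean form with weights
  normalized by the maximum; nodes of degree < 2 get 0.
* **Surrogates** permute the multiset of edge weights over the fixed
  topology, preserving the degree sequence; a node/metric with zero
  surrogate mean reports `NA` rather than infinity.
* **Consensus pruning** uses the per-entry 95th percentile of 100
  permutation-null association matrices (labels permuted within each
  partition, preserving module sizes); a fully pruned matrix returns
  singletons with a warning. Module ids are contiguous from 1.
* **`Z` conventions**: population standard deviation; modules with zero
  spread (including singletons) give `Z = 0`. Boundary cases classify as
  non-hub at `Z = 1.5` and connector at `P = 0.3`.
* **Windows** start at 0 and hop by `step` (default non-overlapping);
  the count is `floor((T/fs - window)/step) + 1` — 133 windows for a 40-s
  epoch at 300 ms. Windows are vetted against the rounded 6-cycle
  minimum.
* **Artifact rejection** is evaluated on raw epoch amplitudes before
  filtering (a filtered spike is smeared below threshold); returned
  epochs are filtered.
* **Rank-sum reading of "node significance"**: each node's metric samples
  (across windows/epochs) against the pooled samples of all other nodes,
  two-sided, exact for small untied samples. The transition-column null
  is uniform over destinations; chi-squared role tests fall back to exact
  binomial when an expected count is below 5.
* **Seeding**: a single seed fans out to per-stage streams keyed by stage
  name, so toggling one stage never shifts another's randomness; every
  generator and pipeline output is bit-reproducible given config + seed.

## Problem sizes used in the test-suite

Unit and end-to-end tests run at desk scale, chosen once:

* static hub recovery: 3 modules x 6 nodes, 40 s at 200 Hz,
  proportional threshold 0.35 — at 12-30 nodes the 68-region default of
  10% keeps fewer edges than the planted intra-module edge budget,
  so the desk-scale threshold is raised until the planted structure can
  be represented (the hub labels are stable across 0.3-0.5, which the
  sweep test asserts);
* dynamic role switching: 3 modules x 10 nodes, 12-s windows, 10-window
  regimes — per-window `Z` needs both a module size well above 4 (its
  ceiling is `sqrt(m - 1)`) and enough independent phase samples per
  window (~40 at this window length and jitter bandwidth);
* consensus recovery: binary 4 x 10-node planted-partition graphs at
  edge probabilities 0.9/0.05 (recovered exactly) and 0.6/0.2. At
  0.6/0.2 each node has more external than internal edges and the
  planted partition is usually not the modularity optimum; recovery is
  partial (median NMI ~0.5 with the three-algorithm consensus, ~0.7 for
  an idealized best-restart Louvain), a known limitation of
  modularity-based consensus near the detectability limit.

## Known limitations

* The wMNE omits noise-covariance whitening (a config hook is left for
  it) and uses a fixed scalar `lambda`; no per-dataset SNR estimation.
* Whether regional series should be mean- or PCA-aggregated is an open
  choice; the sign-aligned mean is implemented and recorded in metadata.
* PLV at the source level does not correct signal leakage;
  leakage-corrected estimators (orthogonalization, wPLI) are deliberately
  out of scope.
* Occupancy requires a per-window "significant node" rule; the package
  uses mean + 2 sd within the window (minimum: the argmax node), a
  declared stand-in exposed as a parameter.
* Markov modelling of the transition sequences and multilayer/temporal
  modularity are out of scope.
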