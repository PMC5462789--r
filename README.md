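# dyncore

Fast dynamic reconfiguration of resting-state functional brain networks:
who are the hubs, and how do their roles change over sub-second time
scales?

`dyncore` is an R package for network neuroscientists working with
region-level oscillatory signals (EEG/MEG source space). It implements the
full analysis chain from signals to dynamic hub statistics:

* **wMNE source estimation** — `S_hat = (GᵀWG + λI)⁻¹GᵀWX` with
  column-norm weighting (`W_pp ∝ 1/‖g_p‖²`, default `λ = 0.2`) and
  sign-aligned atlas aggregation, for users starting from scalp data and
  a lead field;
* **phase-locking connectivity** — `PLV(x,y) = |⟨e^{j(φ_y−φ_x)}⟩_t|` from
  analytic-signal phases, statically over whole epochs and in sliding
  windows, with the 6-cycle minimum-window rule (300 ms in the beta band,
  14–25 Hz);
* **weighted hub metrics** — betweenness centrality, vulnerability
  `V_i = (E − E_i)/E`, strength, Onnela clustering — on proportionally
  thresholded graphs, normalized against weight-reshuffled surrogate
  networks;
* **consensus modularity** — Newman leading-eigenvector + Louvain +
  Infomap ensembles combined through a permutation-null-pruned
  association matrix, then hub classification by within-module degree
  z-score `Z` and participation coefficient
  `P_i = 1 − Σ_m (K_i(m)/K_i)²`: hubs have `Z > 1.5`; `P < 0.3` marks a
  provincial hub, `P ≥ 0.3` a connector hub;
* **temporal dynamics** — per-window top-node transition matrices,
  resting-state-network fractional occupancy, hub-role timecourses, with
  Wilcoxon / exact-binomial / chi-squared testing under Bonferroni
  correction;
* **a seeded synthetic generator** — band-limited phase-coupled signals
  with planted modules, provincial/connector hubs and piecewise-constant
  coupling regimes, so the whole chain is testable end-to-end against
  known ground truth.

## Worked example

Plant three 4-node modules and one connector hub (node `R1`), then run the
whole pipeline:

```r
library(dyncore)

cfg <- synth_config(
  n_regions = 12, module_sizes = rep(4, 3), fs = 200, duration = 20,
  noise_sd = 0.1, seed = 1,
  hub_spec = list(list(node = 1, role = "connector", strength = 0.65)))

res <- run_pipeline(cfg, dyncore_config(
  window = 2, proportion = 0.35, n_surrogates = 100,
  n_runs_per_algo = 10, seed = 1))

print(res)
summary(res)
```

```
dyncore run: 12 nodes, 10 windows of 2 s
  consensus modules: 3
  hubs: 0 provincial, 1 connector
== static hub classification ==
  node        Z         P     label
1   R1 1.711226 0.6323541 connector

== occupancy (strength) ==
 M1  M2  M3 
0.6 0.2 0.2 

== transitions significant columns (strength) ==
R1
```

Reading the output: consensus clustering recovered the three planted
modules exactly (`partition_nmi(res$static$partition,
res$truth$partition)` is 1). The planted connector is the only node whose
within-module degree z-score exceeds 1.5, and its participation
coefficient 0.63 (edges spread over all three modules) classifies it as a
connector. Its module `M1` dominates the windowed analysis — it holds the
top-strength node in 60% of windows — and `R1` is the only significantly
enriched destination column of the strength transition matrix (exact
binomial against a uniform-destination null, Bonferroni-corrected).

Individual stages are exported too (`plv_static()`, `plv_dynamic()`,
`proportional_threshold()`, `normalize_metrics()`, `consensus_cluster()`,
`classify_hubs()`, `transition_matrix()`, `rsn_occupancy()`, ...), and
`sweep_pipeline()` re-runs the chain across window lengths, thresholds or
bands with a rank-correlation stability summary. See the methods vignette
(`vignettes/dyncore-methods.Rmd`) for the model, conventions and
limitations.

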