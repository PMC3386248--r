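# dynmod — dynamic modular architecture of functional brain networks

Resting (task-free) fMRI connectivity is usually reported as one
correlation matrix per subject, averaged over the scan. `dynmod` treats the
scan as a *sequence* of brain states instead: it slides a short window
through ROI-level BOLD time series, builds a fully connected, signed,
weighted Pearson graph per window, detects that window's community
structure, and quantifies how the modular organization reconfigures over
time — per-subject dwell times in modular configurations, consensus
"meta-modules" across all windows, and group contrasts in how long default
mode network (DMN) sub-networks contribute strongly to the ongoing state.
A synthetic generator of switching-state multivariate signals with planted
community structure provides ground truth for validating every stage.

## The statistic at the core

Each windowed graph is scored with the signed modularity Q\*. With positive
part w⁺ = max(w, 0), negative part w⁻ = max(−w, 0), node strengths s±ᵢ and
total weights v±:

    Q± = (1/v±) Σᵢⱼ ( w±ᵢⱼ − s±ᵢ s±ⱼ / v± ) δ(cᵢ, cⱼ)
    Q* = Q⁺ − ( v⁻ / (v⁺ + v⁻) ) · Q⁻

The weight diagonal is zero while the strength-product null term runs over
all pairs, so the all-in-one-module partition scores exactly 0. Communities
are found by seeded Louvain-style Q\* maximization (compiled in C++; ties
break deterministically), and chance levels come from a null model that
conserves the signed weight multiset exactly while matching node strength
sequences by discrepancy-reducing swaps.

Supporting machinery: data-driven window-length selection from the relative
standard deviation of Q\* against a half-scan reference; log-log power-law
extrapolation of the "instantaneous" 2-module proportion; within-module
degree Z-scores under the packaged 68-region atlas (`node_atlas()`) whose
five-module assignment and DMN sub-network definitions ship as metadata;
exact/approximate Wilcoxon rank-sum and chi-squared group comparisons.

## Worked example: the analysis workflow

The `analysis/` scripts run the study end to end on simulated cohorts
(68 regions, 100 volumes, TR 3 s, two switching modular states; run them in
order — later scripts read `results/data/` written by the first):

```sh
Rscript analysis/01_simulate_cohort.R 1   # cohorts + manifests
Rscript analysis/02_window_selection.R 1  # Q* variability vs window length
Rscript analysis/03_modular_analysis.R 1  # Q* vs null, dwell, meta-modules
Rscript analysis/04_group_comparison.R 1  # DMN sub-network dwell contrast
```

Output from a run with seed 1:

```
switching cohort: 12 subjects, 100 volumes x 68 regions
  2-modular state occupancy: mean 71.8% (range 21-100%)
selected window: 37 volumes (111 s at TR 3 s)
  at 11 volumes: 2 modules 65.6%, 3 modules 34.3%, 4 modules 0.1%
1080 windowed graphs, Q* median 0.458 (IQR 0.340-0.549)
null Q* median 0.119 over 108 randomized graphs (original 0.458)
2-module dwell: cohort mean 65.9% vs planted occupancy 71.8% (error 5.8 points)
meta-modules (k=3) adjusted Rand vs planted communities: 1.000
DMN sub-network dwell time, group medians and rank-sum p-values:
  pDMN: CN 60.0 (40.8-63.9) vs AD 13.3 (4.2-35.8), p = 0.00319
  aDMN: CN 25.0 (20.6-40.0) vs AD 76.7 (54.2-86.4), p = 0.00219
```

Reading: windowed graphs are strongly modular relative to chance (median
Q\* 0.458 vs 0.119 for strength-preserving nulls); per-subject dwell time
in the 2-modular configuration recovers the planted state occupancy to
within 6 points; consensus clustering of 1080 pooled partitions recovers
the planted communities perfectly; and the simulated "AD" group — whose
state occupancy was biased toward the anterior-strong configuration —
shows exactly the reciprocal pDMN-down / aDMN-up dwell-time contrast the
method is designed to expose. (The auto-selected window on this synthetic
cohort is 37 volumes; its Q\*-variability curve decays more slowly than
real data's, so the analyses above fix the window at 11 volumes, the
geometry the pipeline targets.)

Equivalent programmatic use:

```r
library(dynmod)
cohort <- generate_cohort(c(A = 20), default_switching_states(),
                          list(A = default_transition()), seed = 1)
dyn   <- dynamic_graphs(cohort[[1]]$ts, window_config(11))
parts <- lapply(dyn$graphs, detect_modules, n_restarts = 10, seed = 1)
modular_dwell_time(module_count_series(parts))
```

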