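---
title: "Dynamic modular architecture of functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic modular architecture of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynmod)
```

## The problem

Resting (task-free) fMRI connectivity is usually summarized by one
correlation matrix per subject, averaged over the whole scan. That average
hides the fact that the brain's community structure is non-stationary: over
tens of seconds, regions regroup into different modular configurations.
`dynmod` implements a complete pipeline for quantifying that
non-stationarity from ROI-level time series:

1. sliding-window construction of fully connected, signed, weighted
   correlation graphs (`dynamic_graphs()`);
2. community detection and modularity scoring on signed graphs, with
   strength-preserving null models (`detect_modules()`, `qstar()`,
   `null_model()`);
3. data-driven selection of the window length (`qstar_variance_curve()`,
   `select_window()`) and power-law extrapolation of the instantaneous
   modular configuration (`powerlaw_intercept()`);
4. per-subject dwell-time statistics over modular configurations
   (`modular_dwell_time()`) and meta-modular consensus clustering
   (`coassignment()`, `meta_modules()`);
5. sub-network dwell times under a fixed anatomical module assignment and
   two-group comparisons (`subnetwork_dwell_time()`, `compare_groups()`).

A synthetic generator of switching-state multivariate signals
(`generate_cohort()`) provides ground truth for every stage.

## Windowed signed graphs

For a scan of `T` volumes, windows of odd length `L` advance by a stride of
one volume, giving `floor((T - L) / 1) + 1` graphs, each centred on a
volume (start + (L-1)/2, 0-based half-open windows). With the default
geometry — 100 volumes at TR = 3 s and L = 11 — each subject yields 90
graphs. Edge weights are plain Pearson correlations of the windowed
signals. No thresholding or binarization is applied: the graphs stay fully
connected and signed, which is what the Q* statistic is designed for. The
diagonal is stored as 1 for convenience but excluded from every downstream
computation.

A region with zero variance inside a window has no defined correlation;
`strict` mode (the default) raises an error naming the region and window,
`lenient` mode zeroes its weights with a warning.

## The Q* statistic

For positive part \(w^+ = \max(w, 0)\) and negative part
\(w^- = \max(-w, 0)\),

\[
Q^\pm = \frac{1}{v^\pm} \sum_{ij}
  \left(w^\pm_{ij} - \frac{s^\pm_i s^\pm_j}{v^\pm}\right)
  \delta(c_i, c_j),
\qquad
Q^* = Q^+ - \frac{v^-}{v^+ + v^-}\, Q^-,
\]

with \(v^\pm\) the total positive/negative weight over ordered pairs and
\(s^\pm_i\) the node strengths. Two conventions matter and are fixed here
once:

* the weight diagonal is zero, but the strength-product (null) term runs
  over all pairs including \(i = j\); under this convention the
  all-in-one-module partition scores exactly 0. The alternative
  (excluding \(i = j\) from the null term too) shifts every partition's
  score by the same constant, so optimizer rankings are identical either
  way — only the reported value changes;
* if a graph has no negative weight, the negative term is dropped; an
  all-zero graph scores 0.

The implementation is verified in the test suite against an independent
direct-summation oracle to 1e-12.

## The optimizer

`detect_modules()` maximizes Q* by Louvain-style agglomeration: seeded
random node orders, repeated local moves (including the option for a node
to leave its community and stand alone), then aggregation of communities
into supernodes, iterated until no move improves the score. Ties in move
gain resolve to the lowest candidate community index, so a (graph, seed)
pair always yields the same partition. The default of 10 restarts keeps a
single detection under ~2 ms on 68-node graphs.

Because greedy modularity maximization has no optimality guarantee, the
primary correctness check is exhaustive: on random signed graphs with up to
8 nodes the detected Q* is compared against the maximum over *all* set
partitions (Bell(8) = 4140), and must reach it in at least 95% of
instances. Labels are canonicalized (first node's module is 1, the next
new module 2, ...) so partitions compare structurally.

## The null model

On a complete graph the degree distribution is trivially preserved, so
randomization acts on the weights. `null_model()` first permutes the
entire off-diagonal weight multiset uniformly at random across edge slots
(conserving the positive and negative weight multisets exactly), then runs
`n_passes` sweeps of pairwise weight swaps, accepting a swap only if it
reduces the summed L1 discrepancy between the null's and the original's
positive and negative strength sequences. Swaps exchange *signed* weights,
so the placement of positive versus negative edges is itself randomized
and then refined — this matters: refining the two sign parts separately
cannot recover node strengths whose sign placement the initial permutation
fixed badly. With the default 10 passes (10 candidate swaps per edge per
pass) the Spearman correlation between original and null strength
sequences exceeds 0.8 on realistic graphs of 20+ nodes, while planted
community structure is destroyed; a constant-weight graph passes through
unchanged.

## Window-length selection

Short windows estimate correlations noisily; long windows average away the
dynamics. Following the variability criterion, the standard deviation of
Q* over all cohort graphs is computed per candidate length and expressed
relative to the half-scan reference (`floor(T/2)` volumes):
`100 * (sd(L) / sd(reference) - 1)`. `select_window()` returns the
smallest odd length within `cutoff_pct` (default 10%) of the reference.
The reference length is even for even `T`; it participates in the curve
(lengths may be even internally for this purpose) but is never selectable,
since analysis windows must be centred. The curve uses the standard
deviation, not the variance, of Q*: the selection criterion is stated in
sd units and the package follows that convention throughout.

The "instantaneous" modular configuration is operationalized as the
y-intercept of an ordinary least-squares fit in log10-log10 space of the
proportion of 2-module windows against window length, i.e. the
extrapolated proportion at L = 1 volume (`100 * 10^intercept`). The fit
range defaults to odd lengths 11-49 for a 100-volume scan, the regime
where detection is reliable. Lengths with zero 2-module proportion make
the log undefined and raise an error rather than being silently dropped.

## Dwell times and meta-modules

`modular_dwell_time()` reports the percentage of a subject's windows spent
in each module-count configuration; over a complete partition of window
states these always total 100. Because module label numbers are arbitrary
from graph to graph, cohort-level structure is summarized by the
co-assignment matrix: the fraction of pooled graphs in which two nodes
share a label. This representation is invariant to per-graph relabelling,
which is the reason consensus clustering operates on it rather than on raw
label vectors (clustering label vectors directly would be
label-permutation-sensitive; this is the central interpretive decision in
the consensus step, and the only route implemented).
`meta_modules()` applies Ward agglomerative clustering to the
dissimilarity `1 - frequency`. The Lance-Williams Ward update is applied
to the dissimilarity as given (`hclust` method `ward.D`) — no squaring and
no embedding into coordinates — because the co-assignment dissimilarity is
already the quantity whose within-cluster heterogeneity we want to
minimize; Ward's coefficients make the merge heights monotone, and ties
resolve deterministically. The default cut at k = 5 mirrors the maximum
number of modules observed per windowed graph in the motivating analyses.

The packaged 68-node atlas (`node_atlas()`) records, for each region, the
consensus-clustering assignment and the final 5-module assignment in which
regions from the same intrinsic connectivity network were kept together
(five rows differ between the two columns). The final assignment is
shipped as metadata, not recomputed: the override is an anatomically
informed manual step, not an algorithm.

## Sub-network dwell time and group comparison

The within-module degree Z-score of node i standardizes its within-module
strength \(\kappa_i\) against the other members of its module, using the
population (divide-by-n) standard deviation; singleton modules and
zero-variance modules yield z = 0 rather than non-finite values. A DMN
sub-network's composite score is the mean z over its four nodes, computed
under the *fixed* final assignment (not each window's detected partition)
so that the quantity tracks reconfiguration of a stable anatomical module;
a config switch (`weight_mode`) chooses signed (default) or positive-only
weights, since either convention is defensible. A sub-network "strongly
contributes" to a window when its composite z is strictly positive (ties
at exactly 0 do not count); its dwell time is the percentage of such
windows.

Group contrasts use the two-sided Wilcoxon rank-sum test: exact
enumeration when the combined sample size is at most 20 with no ties, the
tie-corrected normal approximation otherwise; medians with
linear-interpolation quartiles are reported, and the quartile convention
is stated because interquartile ranges depend on it. Proportions compare
by 2x2 chi-squared without continuity correction (configurable). No
multiple-comparison correction is applied across the four sub-networks;
raw p-values are reported.

## The synthetic generator

The generator emulates the study geometry: 68 regions, 100 volumes,
TR = 3 s, band-limited signals. Each latent brain state is a
block-equicorrelated correlation matrix — `rho_in` within communities,
`rho_out` between, positive semi-definiteness checked at construction —
and the state sequence is a per-volume Markov chain, so dwell episodes
follow from self-transition probabilities. Abrupt switching is the only
regime modelled; whether real transitions are graded is unknown. Defaults,
chosen once as a realistic operating point for ROI-averaged BOLD:

* `rho_in = 0.7`, `rho_out = -0.2`: within-network ROI correlations of
  0.6-0.8 with modest anticorrelations are typical of clean resting-state
  data at this granularity;
* `noise_sd = 0.25`: measurement noise at a quarter of the signal scale;
* moving-average smoothing with halfwidth 1 volume stands in for bandpass
  filtering: it reproduces the temporal autocorrelation that matters for
  windowed correlation estimates without binding the generator to a
  filter design;
* two states — a 2-modular state (two of three node groups fused) and a
  3-modular state — sharing a 3-group refinement of sizes 23/23/22, so
  consensus clustering at k = 3 has a well-defined planted answer;
* transitions with mean dwell of roughly 83 and 36 volumes and stationary
  occupancy 70/30 (`default_transition()`): dwell episodes long relative
  to the 11-volume window, as expected for meta-stable brain states, so
  that windows straddling a transition (which genuinely exhibit mixed,
  often 3-modular structure) remain a minority. Straddling is the main
  source of bias in dwell recovery and the reason recovery is asserted to
  within 10 percentage points rather than exactly.

The DMN-contrast states (`dmn_switching_states()`) express the reciprocal
anterior/posterior configuration: in the anterior-strong state the
posterior DMN nodes are exiled from the community carrying the rest of the
task-negative module, so their within-module strength — and composite z —
drops, and vice versa. Group differences are planted purely as occupancy
differences of these shared states.

What the generator does *not* emulate: hemodynamic response functions,
spatial (voxel-level) structure, motion or physiological artifacts,
subject-level variation in the community maps themselves, graded state
transitions, and scanner drift. Tests passing on this generator therefore
validate the estimators' statistical behaviour under known switching
covariance, not robustness to acquisition artifacts.

## Numerical choices

* Pearson weights are clamped to [-1, 1] and symmetrized against rounding.
* State correlation matrices receive a 1e-9 diagonal ridge before Cholesky
  factorization, so exactly semi-definite structures remain factorizable.
* Optimizer move gains use a 1e-12 tolerance; equal-gain ties go to the
  lowest community index.
* Quartiles are type-7 (linear interpolation); z-score standard deviations
  are population-form; zero-variance guards return 0.
* All randomness flows through explicit integer seeds; per-subject and
  per-window seeds derive deterministically from a master seed, and seeded
  helpers restore the caller's RNG state.

## Problem sizes

The validation suite exercises the pipeline at sizes chosen to make every
property measurable in minutes on a single core: exhaustive optimizer
checks on 100 random graphs of up to 8 nodes; a 20-subject, 68-region,
100-volume cohort for dwell-time and meta-module recovery; 25 replicate
two-group cohorts (8 + 8 subjects) for the occupancy-shift contrast; and
400 replicate null cohorts (10 + 10 subjects, compared on planted-state
occupancy) for the type-I error of the rank-sum comparison. The analysis
scripts under `analysis/` default to a 12-subject cohort for the same
reason; all sizes are parameters, and nothing in the method depends on
them.

## Known limitations

* Greedy Q* maximization can return local optima on large graphs; the 95%
  exhaustive-agreement bound is established on small graphs and restarts
  mitigate, but do not eliminate, the risk at N = 68.
* The null model matches strength sequences approximately (rank
  correlation, not equality); exact strength preservation on complete
  signed graphs is a harder combinatorial problem than this pipeline
  needs.
* Windows straddling state transitions are genuinely ambiguous; dwell-time
  estimates inherit a bias toward configurations with more modules that
  grows with the switching rate.
* The two-group contrast consumes pre-labelled groups; matching,
  covariate adjustment and longitudinal structure are out of scope.
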