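---
title: "Methods: amplitude-envelope connectomes, group inference and graph-based classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplitude-envelope connectomes, group inference and graph-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aecnet)
```

# Overview

`aecnet` implements a complete resting-state oscillatory connectomics
pipeline for electrophysiological (MEG-style) atlas-node timecourses. Its
input is a per-subject time × node signal matrix; its outputs are
leakage-corrected amplitude-envelope connectivity matrices, group-level
dysconnectivity statistics with permutation and resampling control, and a
graph-theoretic classification of group membership. A synthetic cohort
generator with known ground truth makes every stage testable without access
to recordings.

The processing chain per subject and frequency band is fixed:

1. zero-phase band-pass filter into canonical bands,
2. symmetric multivariate orthogonalization (leakage correction),
3. Hilbert amplitude envelopes,
4. median-filter despiking, downsampling to 1 Hz, edge trimming,
5. pairwise Pearson correlation of envelopes, Fisher transform,
6. within-subject standardization of the edge distribution,
7. combination across bands by the per-edge Euclidean norm.

# The connectivity model

## Amplitude–amplitude coupling

Band-limited neural signals can co-fluctuate in their slow amplitude
envelopes even when their fast phases are unrelated. For nodes $i,j$ with
band-limited signals $x_i(t)$, the analytic signal
$a_i(t) = x_i(t) + \mathrm{i}\,\mathcal{H}[x_i](t)$ yields the envelope
$E_i(t) = |a_i(t)|$, and connectivity is the Pearson correlation
$r_{ij} = \mathrm{corr}(E_i, E_j)$ of the despiked, 1-Hz-downsampled
envelopes, variance-stabilized as $z_{ij} = \operatorname{atanh} r_{ij}$.
Envelope correlation is robust to small temporal misalignments and is the
standard stationary measure of large-scale coupling in source-projected
MEG.

Each subject's edge distribution is then standardized to mean 0, SD 1
across the $n(n-1)/2$ edges. This removes global offsets (data quality,
overall signal amplitude) so that group comparisons act on the *shape* of
the connectome, not its scale; a corollary, asserted in the tests, is that
the pipeline output is invariant to global rescaling of the input signals.

The six canonical bands are delta 2–4, theta 4–8, alpha 8–13, beta 13–30,
low gamma 40–60 and high gamma 60–90 Hz (`canonical_bands()`). A
frequency-agnostic map combines the six standardized maps per edge as
$\sqrt{\sum_b z_{ij,b}^2}$. The term "vector-sum" admits two readings —
Euclidean norm or plain sum; the norm is implemented as the default because
it treats increases and decreases in different bands as cumulative
evidence of band-specific structure, and a `method = "sum"` alternative is
provided in `combine_bands()`.

## Leakage and symmetric orthogonalization

Source reconstruction mixes signals linearly and instantaneously across
nodes ("leakage" or field spread), which inflates zero-lag correlations.
`symmetric_orthogonalize()` removes all shared zero-lag variance by
replacing the time × node matrix $X$ with the *closest* matrix $Y$ (in the
Frobenius sense) whose columns are mutually orthogonal — the
closest-orthogonal-matrix construction. Writing $Y = O\,\mathrm{diag}(d)$
with orthonormal $O$, the solution alternates

- $O \leftarrow$ polar factor of $X\,\mathrm{diag}(d)$ (via SVD), and
- $d \leftarrow \mathrm{diag}(O^\top X)$ (per-column projection),

initialized at the polar factor of $X$ itself, until the relative change
in the residual $\|X - Y\|_F$ falls below $10^{-9}$ (at most 100
iterations; non-convergence is an error reporting the residual). All nodes
are treated symmetrically — no node is privileged as a regression seed.
Rank-deficient input has no orthogonal counterpart of full rank and is
rejected with the offending columns named. The tests verify the fixed
point (already-orthogonal input is returned unchanged), the defining
property (normalized pairwise inner products below $10^{-6}$), and
optimality against an independent numerical minimizer: because the optimum
lies in the column space of $X$, the $200 \times 3$ problem reduces to
minimizing $\|R - W\,\mathrm{diag}(s)\|_F$ over $3\times3$ orthogonal $W$
(Euler angles, both determinant branches) and scales $s$, which a
quasi-Newton optimizer solves to $10^{-4}$ agreement.

Orthogonalization runs per band on the band-passed timecourses, before
envelope computation.

## Numerical details and degenerate inputs

- **Filter**: 4th-order Butterworth, applied forward–backward
  (`signal::filtfilt`) for zero phase. The band upper edge must lie below
  the Nyquist rate.
- **Hilbert transform**: FFT implementation of the analytic signal
  (positive frequencies doubled, negative zeroed, DC/Nyquist kept once).
- **Despiking**: running median of width 0.25 s (forced to an odd sample
  count, at least 3); **downsampling**: means over non-overlapping 1-s
  windows; **trimming**: 2 s per end at 1 Hz. A 250-s recording therefore
  yields 246 envelope samples. These widths are conventional choices; the
  procedure itself (median → 1 Hz → trim) is fixed.
- **Fisher transform**: correlations of exactly ±1 (possible only for
  degenerate inputs such as duplicated nodes) are clipped to
  ±(1 − 10⁻¹²) with a warning rather than propagating infinities;
  zero-variance nodes are an error naming the node.
- **Edge indexing**: upper triangle, 0-based, $i<j$, lexicographic — one
  convention across all modules, with lossless matrix↔vector round-trips.

# Group statistics

All group inference operates on a `cohort_data` object: a subject × edge
matrix, `case`/`control` labels, and optional covariates (age in years,
gender as 0/1, intracranial volume in 1-mm voxels).

**Rank-consensus edge selection.** Each subject's edges are ranked
(average ranks on ties — which also makes the mask invariant under any
strictly monotone per-subject transform), normalized by the edge count,
and averaged within each group. An edge is "valid" for a group when its
mean normalized rank exceeds $1 - f$ (default $f = 0.2$, i.e. a mean rank
above 0.8); the final mask is the union of the two group selections so
that signal confined to one cohort is not discarded.

**Welch tests.** At each valid edge, the unequal-variance $t$ statistic
with Welch–Satterthwaite degrees of freedom and a two-sided p-value
(sidedness is a documented choice; the implementation is two-sided
throughout). Positive $t$ means case > control. Edges with zero variance
in both groups are flagged rather than tested.

**Omnibus correction.** Family-wise error control uses the null
distribution of the *maximum* |t| over valid edges under random
reassignment of group labels (preserving group sizes; the standard
two-sample analog of sign-shuffling, which strictly applies to paired
designs). The threshold is the empirical 95th percentile of the max
distribution over 10,000 permutations by default. On a 3-vs-3 toy the
permutation distribution is verified against exhaustive enumeration of all
20 label assignments, and the family-wise error rate is verified on null
cohorts to lie in [0.02, 0.10] at $\alpha = 0.05$.

**Split-half sign consistency.** Per iteration, $\lfloor n_g/2 \rfloor$
subjects per group are drawn without replacement (odd group sizes drop one
subject per iteration), the case − control mean difference is computed per
valid edge, and its sign recorded; an edge is "robust" when one sign
occurs in ≥ 95% of 10,000 iterations (exact zeros count against both
signs). One property of this rule deserves emphasis: *it measures the
stability of the realized cohort difference, not population truth*. For a
null edge, the half-cohort difference varies around the observed cohort
difference with SD $\sqrt{2S^2/(n-1)}$ — essentially equal to the
across-cohort sampling SD of the cohort difference itself — so a null
edge passes the 95% bar whenever its cohort difference exceeds about
1.645 of those SDs, which happens with probability
$2\Phi(-1.645\sqrt{n/(n-1)}) \approx 0.10$ regardless of the number of
iterations. The acceptance script measures this background rate directly
(`splithalf_false_positive_pct`, ≈ 10% at 42 per group) alongside the
recovery rate at $d = 1$ effects (≈ 100%). Robust-edge counts should
therefore be read against a ≈ 10% base rate, not against zero.

**Covariate regression.** Each valid edge is regressed on an intercept,
the group indicator, age, gender and ICV (raw voxel units — slopes are
scale-dependent but the tabulated quantity, the sign, is not), the sign of
the group slope tabulated across 1000 split-half randomizations with the
same ≥ 95% rule. The regression reuses the same valid-edge mask as the
$t$-tests. A collinear full-cohort design is an error naming the offending
columns; a *randomly drawn half* whose design is rank-deficient (e.g. a
single-gender draw in a small cohort) is redrawn with a warning, since
aborting a 1000-iteration tabulation over one degenerate draw would make
the procedure unusable at pilot scale.

**Post-hoc power.** `ttest_power(d, n, alpha)` is the classical power of
the two-sided two-sample $t$ test: noncentrality $d\sqrt{n/2}$, pooled
df $2n-2$. With $n = 42$ per group it gives 95% power at $d = 0.8$ and
62% at $d = 0.5$ (to two decimals). Pooled df is used deliberately —
this is the standard power analysis, not a Welch-df variant.

# Individual networks and classification

**Graphs.** Each subject's standardized (or combined-frequency) map is
thresholded to its top 20% of edges (`ceiling(0.2 * E)`; ties broken by
edge index, deterministically). Retained weights are the connectivity
values; path computations use inverse weights as distances, so stronger
coupling = shorter paths. `fraction = 1` gives the unthresholded variant
used as a robustness check. Retained edges with nonpositive weight (only
possible near `fraction = 1`) stay in the graph for degree and clustering
but are excluded from path computations, with a warning.

**Six nodal metrics** (`node_metrics()`):

- *degree* — number of retained incident edges (unweighted, the one
  deliberately binary metric);
- *betweenness* — fraction of shortest paths through the node, endpoints
  excluded, normalized by $(n-1)(n-2)/2$ (the word "fraction" fixes the
  normalization; shortest-path multiplicity is handled by Brandes
  counting);
- *eccentricity* — maximal shortest-path distance to any *reachable* node;
  on disconnected graphs the maximum is over the node's component, and an
  isolated node gets 0 (a convention, flagged here because no universal
  one exists);
- *global efficiency* — mean inverse shortest-path distance to all other
  nodes, unreachable pairs contributing 0;
- *local efficiency* — mean inverse shortest-path distance between the
  node's neighbors within the neighbor-induced subgraph, with the same
  $1/w$ distances;
- *clustering* — Onnela's weighted coefficient
  $\frac{1}{k_v(k_v-1)} \sum_{u,w} (\hat w_{vu} \hat w_{vw} \hat w_{uw})^{1/3}$
  with weights rescaled by the graph maximum. Clustering uses the *raw*
  connectivity weights, not inverses: a triangle-density notion is about
  coupling strength, whereas inverse weights are meaningful only as path
  lengths. Nodes with fewer than two neighbors get clustering and local
  efficiency 0.

Shortest paths and Brandes betweenness are computed with igraph; every
metric is verified to $10^{-10}$ against an independent brute-force
enumerator (all simple paths, explicit triple loops) on random ≤ 8-node
graphs, and the expected transformation laws under node relabeling and
weight scaling are asserted as properties.

**Classification.** A linear SVM (cost 1 — no tuning, deliberately) is
trained on each single-metric feature block and on the pooled
$6n$-feature vector, under 100 repetitions of stratified 5-fold
cross-validation with a fresh fold assignment per repetition. Features are
z-scored *within training folds only*; the no-leakage property is asserted
by recomputing fold models by hand and by checking that shifting held-out
rows leaves the trained model untouched. Accuracy, sensitivity (case =
positive class) and specificity are computed per repetition from the
pooled test predictions and reported as mean ± SD; each subject's mean
predicted label is the fraction of repetitions in which it was predicted
"case". Significance comes from shuffling labels 5000 times and
recomputing mean CV accuracy, with the +1-corrected one-tailed p-value
$(1 + \#\{acc_{perm} \ge acc_{obs}\})/(n_{perm}+1)$. Permutation runs use
10 CV repetitions per shuffle instead of 100: the permutation distribution
of a *mean* accuracy is insensitive to the repetition count at this scale,
and the reduction is configurable and recorded in the report. Whether
sensitivity/specificity should be averaged per repetition or pooled over
all predictions is ambiguous; per-repetition averaging is implemented.

Subgroup contrasts (`run_contrasts()`) accept `"A_vs_B"` strings whose
sides are `case`, `control` or subgroup labels from the manifest; the
first side plays the positive class. Controls are not re-matched per
subgroup at desk scale — a subgroup is contrasted against all controls.

# The synthetic cohort generator

`generate_cohort()` emulates the data structure the pipeline is designed
for: two groups of 42 subjects, 90 cortical nodes, six bands, 250 s of
usable signal at 600 Hz, age 38.5 ± 12.5 y (cases) vs 33.3 ± 9.6 y
(controls), balanced gender, and an ICV deficit in cases (means
1.48 × 10⁶ vs 1.54 × 10⁶ voxels, SD 1.3 × 10⁵) so the covariate-regression
path is exercised. Smaller configurations are used in tests purely for
runtime; the defaults above *are* the emulated study conditions.

Per band and subject, each node's signal is a band-limited carrier (white
noise band-passed to the band) amplitude-modulated by a strictly positive
slow envelope. Envelopes are exponentiated correlated low-pass Gaussian
processes: coarse-rate Gaussian noise (8× the envelope bandwidth, default
0.5 Hz) is low-pass filtered, standardized, mixed by a Cholesky factor of
the target correlation matrix, exponentiated and linearly interpolated to
the carrier rate. The coarse-rate synthesis is a numerical choice: a
Butterworth low-pass at ~0.5 Hz applied directly at 600 Hz is severely
ill-conditioned. The latent (log-envelope) correlation equals the target
exactly; the *measured* envelope correlation attenuates (carrier noise,
exponentiation, filtering), so tests assert ordering and monotonicity
against the target, never equality. Target matrices are repaired to
positive semidefiniteness by eigenvalue clipping and rescaling to unit
diagonal, since user-specified edge patterns need not be jointly
consistent. Group effects reduce the target correlation at a designated
ground-truth edge set by a fractional `effect_delta` in cases; with
`effect_delta = 0` the groups are exchangeable, which the null-calibration
test exploits. Zero-lag leakage is emulated by mixing with
$I + \lambda R$ ($R$ random symmetric, zero diagonal), rescaled to
preserve per-column variance. Bands are generated independently — the
pipeline treats bands separately until the combination stage, so
cross-band coupling would add realism without adding test power.

`simulate_edge_cohort()` generates cohorts directly at the edge level
(standard-normal edges, affected edges shifted by exactly $-d$ SD in
cases). Calibration and recovery studies of the group-statistics
procedures use it: those procedures see only exchangeable subject × edge
data, edge-level nulls are *exactly* exchangeable, and the effect size is
controlled exactly rather than indirectly through the signal chain. The
signal-level generator is exercised end to end by the null-calibration,
leakage-correction and pipeline-determinism tests.

What the generator does *not* emulate: sensor-level physics, forward
models, head motion, non-Gaussian artifacts, 1/f spectra, cross-band
coupling, and spatially structured baseline connectivity (the baseline
target is flat across unaffected edges). Consequently, passing tests
demonstrate the correctness and calibration of the *procedures*, not that
real recordings would yield any particular effect pattern. One practical
corollary of the flat baseline: with all edges exchangeable, a 20%
rank-consensus mask on a small null cohort can legitimately come up empty;
small-scale smoke configurations therefore use a wider mask fraction.

# Problem sizes and reproducibility

Determinism is end to end: every stochastic routine takes an explicit
seed, uses a private RNG stream (the caller's RNG state is untouched), and
identical configuration + seed reproduces outputs byte for byte — asserted
by hashing a full pipeline run twice.

Test and acceptance runs use deliberately scaled problem sizes, chosen as
the smallest at which each property is cleanly measurable: ≤ 8-node graphs
for brute-force oracle equivalence (50 graphs), 10-node/20+20 cohorts ×
200 for omnibus FWER calibration (1000 permutations), 30-node cohorts with
42 per group × 5 seeds for split-half recovery (2000 iterations), 10-node
signals at 120–200 Hz for the signal-chain properties, and reduced
CV/permutation counts (documented in each call) for classifier
calibration. The statistical properties being checked are scale-free; the
defaults of the exported functions remain at the full study scale.

# Known limitations

- The split-half consistency rule's ≈ 10% null background rate (above) is
  intrinsic to the procedure, not tunable away; interpret robust-edge
  counts accordingly.
- The rank-consensus mask is undefined in spirit for cohorts whose edges
  are fully exchangeable (flat synthetic baselines) — real connectomes
  have structured strength distributions.
- Graph metrics on thresholded graphs depend on the retained-edge count;
  comparisons across subjects are meaningful because the count is fixed
  per subject, but absolute metric values should not be compared across
  different threshold fractions.
- The SVM is deliberately untuned (linear, cost 1); the goal is a
  reproducible discriminability measure, not maximal accuracy.
- HDF5 timecourse containers are not supported; CSV with JSON sidecars is
  the interchange format.
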