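---
title: "ROI-level network analysis of verbal-fluency task fMRI: methods and design"
author: "vfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI-level network analysis of verbal-fluency task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfnet)
```

## The scientific problem

Covert verbal-fluency tasks engage a left-lateralised fronto-temporal
language network: phonemic fluency leans on the left inferior frontal
gyrus (pars triangularis and opercularis) and the anterior middle and
inferior temporal gyri, while semantic fluency additionally recruits
the temporo-occipital middle and inferior temporal gyri. In temporal
lobe epilepsy (TLE) this network reorganises, and it does so
differently depending on whether hippocampal sclerosis (HS) is
present. `vfnet` implements a complete ROI-level analysis of such a
design with three groups — healthy controls (HC), TLE with HS, and TLE
without HS — covering:

1. per-subject functional connectivity (Pearson correlation between
   denoised region time series),
2. degree centrality (DC) summarised by its area under the curve (AUC)
   over a proportional-threshold density grid,
3. community structure of the left fronto-temporal subnetwork via
   repeated seeded Louvain optimisation, summarised by the consensus
   co-assignment probability and the region-to-cortex *affinity*
   statistic,
4. block-design GLM activation and a frontal laterality index (LI),
5. covariate-adjusted ANCOVA over edge/DC/affinity features with
   Benjamini–Hochberg FDR control, and
6. an HS classifier: forward-stepwise logistic feature selection
   feeding a single-hidden-layer neural network evaluated over
   repeated stratified 70/30 splits.

Because clinical BOLD data of this kind are not publicly deposited,
the package ships a first-class synthetic-cohort generator that
reproduces the statistical structure the analysis assumes, so every
stage is tested end-to-end without downloads.

## The synthetic cohort generator

`simulate_cohort()` draws one subject per configured slot (defaults 29
HC / 30 TLE-HS / 28 TLE-NHS, the three-group design under study).
Each subject's regions × timepoints matrix is built as

* latent innovations `e_t ~ N(0, C_g)` with a group-specific target
  correlation matrix `C_g`,
* AR(1) temporal smoothing with stationary unit variance (the
  cross-region correlation structure is preserved exactly),
* a task response: a 30 s rest / 30 s task boxcar over five blocks at
  TR = 1 s, convolved with the canonical double-gamma haemodynamic
  response (peak 6 s, undershoot 16 s, ratio 6 — the conventional
  parameterisation, since task-fMRI software rarely prints it), scaled
  by per-cortex amplitudes (left frontal positive, left temporal
  negative, mirroring task activation/deactivation),
* low-frequency cosine drift, white observation noise, white-matter /
  CSF-like nuisance channels leaking into every region, global spikes
  at outlier frames, and six random-walk motion parameters with jumps
  at those frames.

The target structure `C_g` is block-structured — within-cortex
correlation 0.4, between-cortex 0.1 — so community detection has a
planted ground truth, plus the group's *effect map*: an additive
offset on the edges between a seed region (the left aITG analogue)
and its cortex. Defaults are `-0.25` for the TLE-HS-like group and
`+0.15` for the TLE-NHS-like group with a per-subject jitter SD of
0.05. No published effect sizes exist for these contrasts, so these
values were fixed once as plausible for the reported group
separations and are exposed as free parameters rather than asserted
as estimates. When offsets push `C_g` outside the positive
semi-definite cone it is repaired by eigenvalue clipping at `1e-6`
(deterministic, with a warning).

Covariate distributions (age ~ 28 ± 8 years, education 12 ± 3 years,
MoCA ≈ 28.5 for controls vs 26 for patients, balanced sex) follow the
demographic profile typical of such cohorts. Behavioural scores
(VFC/VFP/VFS: Chinese-character, Pinyin/phonemic and semantic fluency)
are linear in the subject's generative seed-region connectivity plus
noise, with the strongest slope on the phonemic score — the
association the connectivity analysis is meant to recover.

Every subject's seed derives from the master seed by a Lehmer-style
mix (`derive_seed()`), so identical configurations reproduce
byte-identical cohorts while streams stay independent.

**What the generator does not emulate:** volumetric (voxel) data,
physiological (cardiac/respiratory) noise, spatial autocorrelation
within regions, non-Gaussian BOLD amplitude distributions, and
site/scanner effects. Passing tests therefore demonstrate the
*pipeline's* correctness and calibration under the assumed generative
model, not robustness to every artefact of real acquisitions.

## Denoising

`prep_series()` follows the regress-then-filter convention of
ROI-level connectivity software: ordinary least squares removal of
motion, one-hot outlier-frame indicators, the HRF-convolved task
regressor plus its temporal derivative (removing the block "module"
effect so task-locked covariance does not masquerade as
connectivity), and nuisance channels; then a zero-phase band-pass.
Outlier frames are regressed out rather than deleted to preserve
timepoint alignment for the filter.

Outlier detection flags frames whose global-signal z-score exceeds 5
or whose framewise motion differential exceeds 0.9 mm; these
thresholds are conventional artifact-detection defaults, chosen here
as implementation decisions.

The filter is an order-2 Butterworth band-pass (0.009–0.10 Hz by
default) applied forward–backward, with reflective padding and mean
removal to suppress edge transients. Confound regression is exactly
idempotent (residuals are orthogonal to the confounds to < 1e-8);
re-applying the *filter* necessarily re-applies its passband gain
(≈ 0.98 at 0.05 Hz), which is the irreducible sense in which the
pipeline is only idempotent "up to filter effects" — no realisable
IIR filter has a flat unit passband.

## Connectivity and edge features

`correlation_matrix()` computes Pearson correlations between all 132
region pairs of the denoised series (diagonal set to 0; constant
regions zeroed with a warning), and refuses raw series unless
explicitly overridden — a provenance flag set by `prep_series()`
guards against accidentally correlating unfiltered data.
`extract_edge_features()` Fisher-z-transforms the 6 ROI × 131
partner correlations, keeping each ROI–ROI pair once (canonical
ordering by region index), which yields `6 × 131 − C(6,2) = 771`
features per subject — the deduplication is our resolution of the
ambiguous "6 × 132" family count, chosen so no edge is counted twice
in one FDR family.

## Degree centrality and thresholding

`threshold_by_density()` binarizes a weighted matrix by keeping the
`k = round(d·M)` top-weight upper-triangle edges (half-up rounding;
the rounding rule is unstated in the originating analyses, so it is
fixed and documented here). Ranking is by signed weight — a strong
negative correlation is not a "connection" — with an `abs` option for
sensitivity. Ties break by lexicographic (i, j) order after a stable
sort, so results are fully deterministic. Degree curves over the
default 36-density grid (0.05–0.40, step 0.01) are non-decreasing by
the nestedness of proportional thresholds; `dc_auc()` integrates them
by the trapezoid rule (a step-sum mode is provided because the
original quadrature is unstated; on a constant-degree node the two
differ only by the endpoint convention).

Whether DC should be computed on the whole 132-node network or a
subnetwork is ambiguous; the default is the whole network.

## Community structure and affinity

Community detection runs on the left frontal + left temporal
subnetwork (the pipeline driver enforces this restriction), with
negative weights zeroed beforehand — a documented simplification;
signed-modularity variants are out of scope. The quality function is
Newman–Girvan weighted modularity

$$Q = \frac{1}{2m} \sum_{ij} \left(W_{ij} - \gamma\,\frac{k_i k_j}{2m}\right)\,\delta(c_i, c_j),$$

with resolution `gamma = 1` by default and exposed as a parameter,
since the original resolution is not recoverable. `louvain()` is the
classic greedy two-phase optimizer: local moves in seeded-random node
order until no gain (ties keep the current community), then
aggregation into super-nodes, repeated until a full level improves Q
by less than `1e-10`. Plain greedy descent from singletons stalls in
local optima on small dense graphs, so each call performs 5
deterministic restarts — the first from the canonical all-singletons
start, the rest from seeded random initial partitions — and returns
the best-Q partition; on 200 random weighted graphs of 4–8 nodes this
matches the exhaustively enumerated maximum in ≈ 98% of cases, which
plain single-start descent (like other off-the-shelf Louvain
implementations we compared) does not achieve.

Because the optimizer is stochastic, `consensus_coassignment()` runs
it 100 times (per-run seeds derived from a master seed) and records
`P_ij`, the fraction of runs assigning regions *i* and *j* to the same
community. The affinity of region *i* to cortex *X* is then

$$A_{iX} = \frac{1}{n_{Xi}} \sum_{j \in X,\, j \neq i} P_{ij},$$

where `n_Xi` counts the members of X other than *i* — a number in
[0, 1] measuring how consistently a region co-assorts with a cortex.

## Activation GLM and laterality

`fit_glm()` fits each region's time series on
[intercept | task | cosine drifts] by OLS and returns the task beta, t
and two-sided p. The frontal laterality index is
`LI = (L − R)/(L + R)` where L and R sum suprathreshold positive
t-mass (t > 2 by default) over left/right frontal regions; dominance
is left for LI > 0.2, right for LI < −0.2, bilateral otherwise. The
voxel-based LI toolboxes weight voxel counts with bootstrapping; at
ROI level that information does not exist, so the fixed-threshold
t-mass formula is a documented divergence. When no mass survives on
either side the LI is undefined and reported as bilateral with a
degenerate flag.

## Group statistics

`ancova()` fits `feature ~ covariates + group` (age, sex as 0/1,
education, MoCA by default) and tests the group block with a partial
F; with no covariates this reduces *exactly* to one-way ANOVA (tested
against `aov()` to 1e-8). Post hoc pairwise contrasts are adjusted
mean differences from the full model with t on residual degrees of
freedom. `group_compare()` applies this per feature with one
Benjamini–Hochberg family per analysis block (771 edges together;
DC-AUC and affinity corrected within their own families) — the
original correction families are unstated, so this grouping is a
documented, configurable choice. Post hoc tests are computed only for
FDR-surviving omnibus features by default, mirroring the usual
reporting style. Rejection uses `q < alpha`; SDs use the n−1
denominator throughout; a feature with no variation anywhere is
reported as F = 0, p = 1 by convention.

`standardize_scores()` z-scores behaviour against the HC reference;
`partial_correlation()` correlates OLS residuals with a t reference on
n − 2 − k degrees of freedom.

## Classification

Candidate features are the HC-standardized fluency scores plus the
FDR-significant functional statistics (capped at the top 20 by
omnibus F to keep the stepwise search tractable).
`forward_stepwise_logistic()` adds, at each step, the candidate with
the smallest likelihood-ratio p until none enters at p < 0.05; the
entry statistic is the LR test (SPSS's exact entry statistic is not
recoverable; a likelihood-ratio criterion is the standard reading of
"maximum-likelihood stepwise"). IRLS uses tolerance 1e-8 with an
iteration cap; perfect separation is detected and flagged, with
coefficients from the last stable iteration.

`train_nn()` is a single-hidden-layer feed-forward network (tanh
hidden units, two-class softmax, cross-entropy) trained by Møller's
scaled conjugate gradient with initial lambda 5e-7 and initial sigma
5e-5, weights initialised uniformly on [−0.5, 0.5] — a zero-width
interval is a degenerate symmetric initialisation and is warned
about. The hidden-unit count is 4 by default with an override, since
auto-selection heuristics of GUI tools are not reproducible.

`evaluate_repeated_split()` performs stratified 70/30 splits
(stratification avoids empty-class test sets at n ≈ 58), fits
selection and network strictly inside each training split, and
reports per-repetition test AUC with a percentile 95% interval over
100 repetitions. The pipeline also reports the full-sample in-sample
AUC because analyses of this design often quote it, but only the
split-based AUC is an unbiased estimate of discriminative ability —
the in-sample value is optimistically biased and should be read as an
upper bound. `roc_auc()` is the rank-based (Mann–Whitney) estimator
with ties counted 1/2.

## Numerical and design choices

* **Seeds.** All randomness flows from one master seed through
  `derive_seed()` (two Lehmer steps modulo 2³¹−1); no stage consults
  global RNG state, and every exported stochastic function
  saves/restores `.Random.seed`.
* **Louvain ties** keep the current community; aggregation stops at a
  Q gain below 1e-10; restarts make the returned optimum reliable
  (above).
* **Degenerate inputs**: constant regions (zeroed correlations, with
  warning), collinear confounds/covariates (dropped, with warning),
  |r| ≥ 1 (clipped to ±(1−1e-7) before atanh), all-zero community
  matrices (error), LI with no suprathreshold mass (degenerate
  bilateral).
* **I/O** is plain text (TSV/CSV/JSON) with `#` provenance headers
  and 17-significant-digit numerics, so write-then-read round-trips
  to full double precision and whole result bundles are byte-stable
  across runs; log lines carry configuration and content hashes but
  no wall-clock timestamps. A documented adapter point (the
  `vf_series` constructor) is where NIfTI-derived ROI series would
  enter; volumetric processing is out of scope.

## Problem sizes used in validation

The test-suite validates at sizes chosen to exercise the stated study
settings while remaining comfortable on a laptop: the optimizer
contract on 200 graphs of 4–8 nodes against exhaustive enumeration;
affinity recovery on a planted 20 + 20 two-block network over 100
consensus runs; FDR calibration on 2,000 null cohorts of a reduced
10-region parcellation (24-edge family, n = 29/30/28); power on 100
cohorts with a Fisher-z 0.3 seed deficit through the full
denoise→connectivity→ANCOVA chain; classifier behaviour on planted
separations and permuted labels over 100 × 70/30 splits; and
end-to-end determinism on two full default pipeline runs (87
subjects × 132 regions × 300 timepoints, 100 community runs, 100
split repetitions).

## Known limitations

* ROI-level only: no voxelwise contrasts, cluster-extent inference,
  bootstrap LI, or atlas handling of real NIfTI volumes.
* Negative connectivity is discarded for community detection; signed
  community models are not implemented.
* The affinity statistic depends on the stochastic optimizer's
  landscape; absolute Q values are not comparable to those of other
  quality functions or resolutions.
* The synthetic generator's Gaussian, stationary world is a lower
  bound on real-data difficulty; calibration results transfer to real
  cohorts only to the extent the model holds.
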