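---
title: "Methods: wavelet connectivity, MST-anchored sparsity sweeps and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet connectivity, MST-anchored sparsity sweeps and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`fcgraph` analyzes resting-state fMRI functional connectivity as a series of
binary graphs, in the style used to study regulatory (autonomic/respiratory)
brain subnetworks in epilepsy mortality risk. The pipeline starts from
parcellated ROI time series (a T × N matrix per subject; preprocessing,
parcellation and atlas registration are upstream and out of scope) and runs:

1. **Wavelet connectivity.** Each node series is decomposed with the
   maximal-overlap discrete wavelet transform (MODWT, pyramid algorithm);
   the connectivity weight between two nodes is the Pearson correlation of
   their scale-2 detail coefficients. At a sampling interval Δ the scale-2
   band is nominally [1/(8Δ), 1/(4Δ)] Hz — at TR = 3 s, 0.042–0.083 Hz, the
   low-frequency range where gray-matter network structure is most salient.
   The package reports this computed band rather than hard-coding any other
   figure; conventions in the literature for quoting MODWT bands vary, and
   we deliberately state only the arithmetic we implement.
2. **Graph construction.** Each weighted matrix is thresholded at sparsities
   0.50, 0.49, …, 0.05 (46 levels). At each level the maximum-weight
   spanning tree is included first — guaranteeing a connected graph at every
   sparsity — and the strongest remaining edges by descending signed
   correlation fill the quota `round(s·N(N−1)/2)`. All 46 graphs share one
   edge ranking, so the stack is nested.
3. **Metrics.** On each binary graph: Newman modularity Q (Louvain, 20
   seeded restarts, best Q kept), Guimerà–Amaral participation coefficient
   against that graph's own detected partition, and degree centrality. Per
   subject, degree averaged over all sparsities defines hubs (strictly more
   than one sample SD above the node mean) and hub prevalence; the hub
   distribution index (HDI) is the OLS slope of (subject − healthy-mean)
   regional degree on healthy-mean degree, where the healthy normative
   profile is the grand mean over healthy subjects and sparsities
   (leave-one-out when scoring a healthy subject itself).
4. **Aggregation and inference.** Curves are collapsed to trapezoidal AUC
   over the ascending sparsity axis. Mean connectivity (mean nodal strength
   of the weighted matrix) is regressed out of AUC measures by pooled OLS —
   group labels are deliberately excluded from the nuisance model. Group
   effects are tested with one-way ANOVA, pairwise pooled-t permutation
   tests (default 10,000 permutations, two-sided, `(1+k)/(B+1)` smoothing),
   Benjamini–Hochberg FDR across nodes within each contrast for nodal
   measures (global measures are uncorrected, having one value per
   subject), Cohen's d with pooled SD, and Spearman correlations (midranks,
   t-approximation p) for GTCS-frequency and IED-count associations.

The subnetwork scope restricts the *weighted* connectivity matrix to atlas
member nodes before thresholding, so sparsity is defined relative to the
subnetwork's own pair count; it is not an induced subgraph of whole-brain
thresholded graphs.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sparsity_max/min/step` | 0.50 / 0.05 / 0.01 | proportion of node pairs retained; 46 levels |
| `wavelet_family` | `d4` | Daubechies 4-tap extremal phase, the de-facto standard in wavelet connectivity; `haar` available |
| `boundary` | `periodic` | circular extension; `reflection` available |
| `restarts` | 20 | Louvain restarts per graph, best-Q kept |
| `n_permutations` | 10000 | permutations per two-sample test |
| `alpha`, `seed` | 0.05, 42 | nominal level; RNG seed threaded into every stochastic call |

## Numerical choices

- **Edge-count rounding.** The quota is `round(s·N(N−1)/2)` with base R's
  round-half-to-even. No floor/ceiling convention is canonical in the
  proportional-thresholding literature; half-to-even reproduces the
  reference behavior we targeted (e.g. N = 10, s = 0.50 → 22 edges).
- **Ties in edge weight** break by lexicographic (i, j) node order, making
  thresholding fully deterministic. On real (continuous) correlations ties
  are measure-zero. On *exactly tied* synthetic matrices (e.g. a noise-free
  block covariance) the rule is pathological: forced-in tied between-module
  edges concentrate on the lexicographically first module pairs, which at
  dense sparsities genuinely shifts the modularity optimum away from the
  planted partition (the optimizer is right; the planted labels score lower
  Q). Tests of planted-structure recovery therefore use either moderate
  sparsities, sampled (tie-free) realizations, or a uniform-tie
  idealization; this is a property of degenerate inputs, not of the
  pipeline.
- **Negative correlations** enter a graph only when positive weights are
  exhausted before the quota, and a message is logged when that happens.
- **Zero-degree nodes** (impossible after MST anchoring, possible on
  arbitrary adjacency input) take participation 0.
- **Hub threshold** uses the sample (n−1) SD and a strict `>`.
- **Permutation p** uses the `(1 + k)/(B + 1)` estimator, guaranteeing
  p > 0; `exact = TRUE` enumerates all splits and returns the exact tail
  probability.
- **Degenerate inference inputs** (constant mean connectivity, constant IED
  counts, zero pooled variance) are caught per stage with a logged message;
  the run continues.

## Design choices where the design was open

- **Community detection** is not pinned down by the lineage this pipeline
  follows; we use Louvain with a fixed seed and 20 restarts keeping the
  maximum-Q partition, which makes runs bit-reproducible and, on all ≤
  12-node graphs we enumerate in tests, matches exhaustive bipartition
  search.
- **MST variant.** A single maximum spanning tree plus strongest remaining
  edges (the standard reading of MST-anchored proportional thresholding);
  iterated-MST unions exist in the literature but change nothing about the
  contracts tested here (connectedness, exact counts, nestedness).
- **HDI for healthy controls** is computed leave-one-out, so a healthy
  subject is never compared against a normative mean containing itself; the
  HDI of the healthy mean profile against itself is identically 0. The
  normative profile is the simple grand mean over healthy subjects and
  sparsities. The HDI omnibus ANOVA runs over the patient groups only,
  since the measure is defined relative to the healthy group.
- **Nodal post-hoc family.** Permutation tests run on *every* node and BH
  correction is applied across the full node family within each contrast;
  the per-node omnibus ANOVA p is reported alongside rather than used as a
  gate. Gating shrinks the BH family to nodes already significant at α,
  which destroys null calibration of the FDR level (under the null ~40% of
  replicate runs would show a spurious FDR-significant node; with the full
  family the rate is at the nominal level, which our null-cohort tests
  verify).
- **Mean-connectivity regression** is applied to AUC-derived measures
  (modularity, participation, degree), pooled across groups; hub prevalence
  and HDI are not AUCs and are left unadjusted.

## The synthetic cohort generator

Real inputs for this design (risk-stratified epilepsy cohorts with
SUDEP outcomes) are not publicly deposited, so every downstream stage is
validated against a generator with known ground truth. A cohort is
specified by group sizes (default 8 SUDEP-like, 16 high-risk, 16 low-risk,
16 healthy — the emulated study design), node count (74), module count (4),
volumes (200) and TR (3 s). Signals are zero-mean Gaussian AR(1) processes
(φ = 0.3, a mild BOLD-like autocorrelation) whose stationary spatial
covariance is a planted block correlation matrix: within-module ρ = 0.40,
between-module ρ = 0.10 — values in the range typical of wavelet-band ROI
correlations. The first node of each module is a "hub": its correlations to
all other nodes are boosted by 0.15, giving a degree profile for hub
analyses to detect. Because a row/column boost is an indefinite low-rank
perturbation, the matrix is projected to the nearest PSD correlation matrix
(eigenvalue clipping + renormalization); the same projection backs the
participation effect.

Group effects are planted as covariance edits applied before sampling:

- `delta_rho_between` raises all between-module correlations (modularity
  degradation). A value that breaks positive semi-definiteness is rejected
  with the group named. The default SUDEP-like effect, +0.035, was
  calibrated once to yield a raw subnetwork Q-AUC Cohen's D ≈ 1.0 at
  16 vs 16 subjects and then frozen.
- `participation_nodes`/`participation_delta` add cross-module correlation
  only on designated rows/columns (participation elevation), with PSD
  projection.
- `hub_permute` relocates each hub to the next node in its module, so the
  degree profile decorrelates from the healthy normative profile and HDI
  slopes turn negative.

Clinical covariates: GTCS/month is 0 for low-risk and healthy subjects (the
risk-stratification definition) and `0.25 + lognormal(log 1, 0.9)` for
SUDEP-like and high-risk subjects, matching the observed case range
(~0.75–10/month) and guaranteeing > 3 GTCS/year; IED counts are Poisson
with a common mean (15) across patient groups — so the IED balance check
should pass — and missing for healthy controls.

**What a green test does and does not establish.** The generator produces
stationary Gaussian block-covariance signals. It has no hemodynamic forward
model, no physiological or motion artifact, no spatial autocorrelation
beyond the block structure, no inter-subject variability in module
membership, and its group effects are free parameters, not estimates of the
real pathology. Green parameter-recovery tests establish that the pipeline
detects the *kind* of effect the study reports at a plausible effect size —
not that the study's specific patient statistics are reproduced.

**Known limitation — mean-connectivity coupling.** Raising between-module
correlation mechanically raises mean connectivity (Cohen's D ≈ 1.2 on mean
connectivity itself at the default effect), so the nuisance regression
absorbs most of the planted modularity deficit (adjusted D ≈ 0.34 vs raw
D ≈ 1.04). The block generator cannot decouple the two the way real
pathology apparently does (where modularity differences persist despite
comparable mean connectivity); the parameter-recovery acceptance test is
therefore evaluated on the unadjusted Q-AUC contrast, whose effect size the
calibration statement refers to.

## Limitations

- Binary undirected graphs only; no weighted or directed variants, no
  small-worldness/efficiency measures.
- The frequency-band bookkeeping reports computed MODWT band edges;
  published figures quoted under other conventions will differ.
- ANOVA degrees of freedom are reported from the data actually analyzed;
  no attempt is made to reconcile externally printed dfs.
- The CLI consumes flat `key=value` config files; YAML is not required and
  not parsed.
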