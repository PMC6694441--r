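---
title: "Group-level tau-PET covariance networks: model, inference and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level tau-PET covariance networks: model, inference and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

Regional tau tracer uptake, measured once per subject on the 90-region AAL
parcellation, carries group-level structure: regions whose uptake co-varies
across the subjects of a group form a *structural covariance network*. This
package builds that network per biomarker-defined group (APOE ε4 carriership
crossed with CSF total-tau status, reference group `A4-T-`), compares the
groups' network topology with nonparametric permutation tests, compares
regional uptake levels with ANOVA and post-hoc contrasts under FDR control,
and correlates uptake with clinical scores (FAQ) and CSF total-tau. Because
subject-level imaging data cannot be redistributed, the package ships a
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes, so every stage is testable end to end.

## Network construction

For each group separately, the subject-by-region value matrix is
residualized: every region is regressed on intercept, age, sex (coded
0 = female, 1 = male; any fixed binary coding gives identical residuals) and
whole-brain mean uptake, and the residuals are kept. Fitting is per group so
that each group's network depends only on its own subjects, which is what
allows the permutation engine to rebuild pseudo-group networks from
relabeled subjects. A rank-deficient design (e.g. a constant sex column in a
small pseudo-group) drops the offending covariate with a warning rather than
failing, so permutation replicates behave gracefully.

The group network is the 90 × 90 Pearson correlation matrix `R` of the
residuals (unit diagonal, symmetric). It is thresholded by *sparsity*, the
fraction S of the N(N−1)/2 = 4005 possible edges that are kept:
`K = round(S × 4005)` (half away from zero — at S = 0.08, K = 320 and the
degrees sum to 640), and the K retained edges are the pairs with the largest
|R|. Defining the threshold through the edge count rather than a fixed
correlation cutoff equates network density across groups before topology is
compared; thresholding on |R| admits strong negative correlations as edges,
following the absolute-value convention. Ties at the K-th edge are broken
lexicographically on the (row, column) region indices, so binarization is
deterministic and edge sets are nested along increasing S.

The nodal analysis uses one fixed sparsity chosen by the standard criterion:
the smallest value at which every region is connected to the network, which
keeps all regions in play while admitting as few false-positive edges as
possible. `min_connected_sparsity()` implements this as a grid scan. The
conventional fixed value is S = 0.08; on the default synthetic cohort the
group networks connect fully only around S ≈ 0.10–0.13, so
`run_full_pipeline()` raises the nodal sparsity to the smallest connecting
value when needed (and records it in the manifest) instead of failing.

## Graph properties

All properties are computed on the binary undirected graph:

* **Clustering coefficient (Cp)** — mean over nodes of triangles through the
  node divided by `deg(deg−1)/2`. Nodes of degree < 2 contribute 0 and stay
  in the average; this is a documented convention because it changes Cp on
  sparse graphs.
* **Harmonic mean path length (Lp)** — the reciprocal of the mean inverse
  geodesic distance over ordered pairs. Disconnected pairs contribute zero
  inverse distance, so Lp stays finite on fragmented graphs, which is why it
  replaces the plain characteristic path length.
* **Modularity (Q)** — greedy agglomerative (CNM-style) merging from
  singleton communities, merging at each step the connected community pair
  with the largest gain ΔQ, ties broken by the smallest community-index
  pair; the partition with maximal Q along the merge path is returned. Q of
  a partition is `Σ_c [e_c/m − (d_c/2m)²]`. Greedy agglomeration is a
  heuristic: it can undershoot the true maximum (the tests bound it by an
  exhaustive search on small graphs) and its merge path, hence occasionally
  Q, depends on node order through the tie-break.
* **Betweenness centrality (BC)** — fractional shortest-path counting
  (Brandes accumulation) over unordered pairs. Reported raw by default;
  normalization by `(N−1)(N−2)/2` is an output option since the scale used
  in published tables is often unstated.
* **Degree** — row sums of the adjacency; a z-scored variant is available
  for cross-density comparisons.

## Inference

**Global permutation test.** For two groups and each sparsity on the 8–30%
grid, subjects are pooled and reshuffled into pseudo-groups of the original
sizes; the *entire* pipeline — residualization, correlation, binarization,
metric — is re-run on each pseudo-group. Recomputing the residualization
inside every permutation is the conservative choice that preserves the null
when the groups differ in covariate composition. The two-tailed p-value uses
the add-one estimator `(1 + #{|null| ≥ |observed|}) / (n_perm + 1)`, which
cannot return zero; at α = 0.05 this matches the 95%-confidence-interval
sorting description of the classical procedure up to that convention. The
study convention is 5000 permutations; inference is marginal per sparsity
(no correction across the grid), matching how per-density significance is
conventionally displayed. Permutations that produce a zero-variance residual
column are redrawn and counted.

**Nodal permutation test.** Same engine at the fixed nodal sparsity, one
observed difference per region, with Benjamini–Hochberg FDR across the 90
regions (`stats::p.adjust`). The exact tail convention (non-strict
inequality, add-one estimator) is stated rather than left implicit.

**Regional comparison.** One-way equal-variance ANOVA per region across the
four groups, BH-FDR across the 90 regions (the ROI-level analog of a
voxel-wise map; the FDR family is the 90 regions). By default in the
pipeline the ANOVA runs on covariate-adjusted values (age, sex, global
uptake residualized on the pooled cohort, group structure untouched),
mirroring the network residualization; the unadjusted variant is a flag.
This matters for power: the generator's confounds inflate raw regional
variance, so a planted shift of 1 SD of the stochastic component is only
about 0.77 SD of the raw values. Post-hoc contrasts are pooled-variance
two-sample t tests of each group against the reference, restricted to the
ANOVA-significant mask, FDR within each comparison. For two groups the
ANOVA F equals the squared contrast t, which the tests verify numerically.

**Clinical correlations.** Pearson r (two-tailed, `stats::cor.test`) between
regional uptake and FAQ within a group, over the ANOVA-significant mask, and
between CSF total-tau and regional plus whole-brain mean uptake. Raw Pearson
is the default; whether such correlations should partial out age and sex is
genuinely open, so an adjusted analysis can be built from `residualize()`
if wanted. Missing scores are dropped pairwise with a logged count.

**Demographics.** Categorical splits are compared with the uncorrected
Pearson chi-square (df = 1) and continuous variables with the pooled-variance
two-sample t from group summaries. These two conventions — no continuity
correction, pooled rather than Welch variance — are the ones under which the
published demographic table's p-values reproduce from its printed counts and
summaries, and they are fixed here for that reason.

## The synthetic cohort

`simulation_config()` defaults encode the study conditions: group sizes
103/34/44/44; per-group age, sex, FAQ, MMSE, CSF-Aβ and MCI/NC compositions
matching the demographic table (composition counts are realized exactly, not
in expectation); CSF total-tau consistent with each group's `T+`/`T−` suffix
around the 320 ng/L cut-off.

Regional uptake is `baseline + confounds + planted group effects +
stochastic part`. The stochastic part is built from shared latent factors —
one factor per lobar community of the atlas plus one global factor — scaled
so its within-module correlation is `within_module_r` (default 0.5) and its
between-module correlation `between_module_r` (default 0.15), values typical
of reported structural covariance blocks; the factor construction guarantees
a positive semi-definite covariance for any admissible configuration.
Confounds are linear in age, sex and a subject-level global factor. The
planted mean elevation (default 1.0 SD of the stochastic part, a
conventional moderate-to-large effect; published F/t statistics do not
identify the underlying effect size) is applied to ten temporal/limbic
regions — bilateral parahippocampal, fusiform, middle and inferior temporal,
right superior temporal, left amygdala — in the `A4+T+` group, making the
demonstration output qualitatively comparable to the published pattern. FAQ
in that group is `baseline + 30 × mean uptake over the effect regions +
noise`, integer-clipped to the instrument range 0–30; with the default noise
this yields planted-region FAQ correlations around r ≈ 0.4–0.6, the range
published for the real cohort. CSF total-tau in the same group tracks the
left olfactory and right parahippocampal regions (50 ng/L per SD), then is
clamped to the group's side of the cut-off.

What the generator does *not* emulate: spatial smoothness and
partial-volume structure of PET, scanner/site batch effects, non-Gaussian
uptake distributions, longitudinal structure, and any true coupling between
network topology and diagnosis. Passing tests therefore demonstrate that the
*pipeline* recovers what it assumes — planted covariance blocks, mean
shifts, score couplings — not that the biological findings replicate.

## Numerical choices and degenerate inputs

* K rounding is half-away-from-zero; documented because bit-exact tests
  depend on it.
* An empty binarized network: clustering is defined as 0 with a warning;
  path length and modularity error out.
* Zero-variance regions abort correlation with the region named; inside the
  permutation engine such draws are redrawn and counted instead.
* `residualize()` requires n ≥ 5 (more observations than the four
  regression parameters) and drops collinear covariates with a warning.
* Degenerate ANOVA regions (zero within-group variance everywhere) are
  reported as degenerate and excluded from the FDR family.
* All randomness flows through explicit seeds; the pipeline expands one run
  seed into fixed per-stage seeds so stages can be reproduced in isolation.

## Problem sizes used by the tests and scripts

The calibration of the permutation test uses exchangeable null pairs of
20 + 20 subjects over the full 90-region atlas, 400 Monte-Carlo repetitions
of the whole test at 200 permutations each, at sparsity 0.10; the rejection
band checked is [0.02, 0.09] at α = 0.05. Planted-effect recovery uses 20
full-size cohorts (225 subjects). The analysis scripts run at 200
permutations with a 2%-step sparsity grid as a desk-scale default; the
full-scale convention (5000 permutations, 1% grid) is a configuration
change, not a code change.

## Known limitations

* Greedy modularity is order-dependent under ΔQ ties and not guaranteed
  optimal; exact maximization is exponential and out of scope.
* The permutation engine re-estimates residuals per pseudo-group, which is
  conservative but roughly doubles cost; no shortcut estimator is offered
  by design (the observed and null statistics must share one code path).
* Published nodal tables whose scale is unidentifiable (betweenness units,
  negative "degrees") are matched in kind, not in value; the package makes
  no claim of reproducing them numerically.
* ROI-level ANOVA is a desk-scale substitution for voxel-wise mapping; the
  FDR family is 90 regions, not voxels, so significance is not directly
  comparable to voxel-level maps.
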