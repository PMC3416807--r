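---
title: "Coordinate-based meta-analysis with alemaps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based meta-analysis with alemaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alemaps)
```

# The problem

Functional neuroimaging studies report their findings as tables of peak
activation coordinates (foci) in a stereotactic millimetre space. A
coordinate-based meta-analysis asks where, across many independent
experiments, activation converges more than chance would allow. `alemaps`
implements the full analysis chain used to study whether several
task-related networks (pain, touch, attention, emotion, interoception,
memory, motor execution, reward) converge on a shared set of integrative
"hub" regions: activation likelihood estimation (ALE) per network,
permutation-null thresholding, probabilistic overlap and strict conjunction
across networks, meta-analytic connectivity modeling (MACM) of the
conjunction regions, representational similarity analysis of the network
maps, and literature term statistics (Jaccard co-occurrence and
forward/reverse Bayesian inference).

Because the underlying databases (BrainMap-style foci archives,
Neurosynth-style text-mined corpora) are not redistributable, the package
ships a synthetic-data generator that plants known structure — a hub shared
by all networks, private centers unique to each, calibrated activation
base rates — so that every stage can be validated against ground truth.

# The ALE model

Each focus is modeled as an isotropic 3-D Gaussian with full width at half
maximum (FWHM) of 10 mm, the conventional width for this family of
analyses; the corresponding standard deviation is
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2}) \approx 4.2466$ mm. The kernel is
evaluated at voxel centres, scaled by the voxel volume, and renormalised to
unit mass over the in-mask grid, so each focus contributes a per-voxel
activation probability.

An experiment's *modeled activation* (MA) map is the probabilistic union of
its foci kernels, $MA_i(v) = 1 - \prod_f (1 - k_f(v))$, and the ALE
statistic is the union across experiments,
$\mathrm{ALE}(v) = 1 - \prod_i (1 - MA_i(v))$. A useful algebraic fact: with
union-combined MA maps the grouped computation factorises into the plain
union over all foci, so the `by_experiment` switch in [ale_params()] cannot
change the result — the package computes the single-product form and the
test suite asserts the equivalence. (Grouping *would* matter for a
max-combined MA variant, which this package does not implement.)

## Null model and thresholding

Significance is assessed against a focus-randomisation null: every focus is
relocated independently and uniformly over the in-mask voxel centres,
preserving per-experiment focus counts; the ALE map is recomputed and all
in-mask voxel values pooled across permutations into one empirical null
sample. Voxelwise p-values use the add-one convention
$p = (1 + \#\{null \ge v\}) / (1 + n)$, so $p$ is never exactly zero and the
smallest attainable p-value is $1/(n+1)$.

Voxelwise p-values are corrected by Benjamini–Hochberg FDR at $q = 0.05$
(via `stats::p.adjust`; ties follow the standard largest-$k$ step-up rule,
so equal p-values share one decision). Surviving voxels are grouped into
connected components — 26-connectivity by default, the common neuroimaging
choice, switchable to 6 — and components with volume $\le 100$ mm³ are
removed (the strict $k > 100$ mm³ rule; at the default 2 mm isotropic
resolution 100 mm³ is 12.5 voxels, so 13-voxel clusters survive and
12-voxel clusters do not).

Parameters and defaults (`ale_params()`):

| parameter          | default | units | rationale                                   |
|--------------------|---------|-------|---------------------------------------------|
| `fwhm`             | 10      | mm    | conventional fixed kernel width             |
| `n_permutations`   | 1000    | —     | p-value floor ~1e-8 on a 32³ grid; desk-scale runs use 200 |
| `q_fdr`            | 0.05    | —     | standard FDR level                          |
| `min_cluster_mm3`  | 100     | mm³   | strict cluster-extent rule                  |
| `connectivity`     | 26      | —     | common neuroimaging adjacency               |
| `seed`             | NULL    | —     | permutation RNG; set for reproducibility    |

The permutation count and the connectivity rule are deliberately exposed as
parameters rather than fixed constants: neither is dictated by the method
itself, and sensitivity to them is worth checking in any real analysis.

# Overlap, conjunction and low-overlap extraction

The probabilistic overlap map is the voxelwise mean of the thresholded
binary network maps — summing each network's membership and dividing by the
number of networks. We read "summing the voxel value" as summing *binary*
membership because the conjunction is defined as the voxels where 100% of
the networks are represented; averaging raw ALE values instead is available
via `binary = FALSE`. The conjunction itself is an exact integer comparison
(count == N), never a floating-point test.

The low-overlap extraction selects, among voxels touched by at least one
network, the fraction (default 20%) with the lowest overlap. Overlap values
are discrete (multiples of 1/N), so selection works on whole value-strata:
strata are admitted from the lowest value upward while the cumulative count
stays within the quota `ceiling(fraction * n_nonzero)`; a stratum that
would overshoot is excluded entirely, so ties are never split arbitrarily.
Two degenerate cases are defined explicitly: a uniform map (single stratum)
returns all voxels with a warning, and a quota smaller than the lowest
stratum returns an empty map with a warning. With few networks (coarse
strata) the lowest stratum frequently exceeds a 20% quota; that is the
honest outcome of a stratum-respecting rule, not an error.

# MACM

Meta-analytic connectivity modeling selects the experiments reporting at
least one focus whose nearest voxel falls inside a seed region and runs the
full ALE chain on that subset. With several seed regions the default is the
*any-region* rule (an experiment qualifies by hitting one region);
`require_all = TRUE` switches to the stricter all-regions reading. Focus
membership is nearest-voxel with no padding by default; `dilate_mm` dilates
seeds by a spherical element for analyses that prefer padded seeds. The
selection report records, per experiment, which region(s) matched.

# Network similarity

The unthresholded ALE maps are vectorized over the mask (thresholding first
would make correlations degenerate for sparse maps; a thresholded variant
simply means passing the binary maps instead). Pairwise Pearson correlation
$r$ gives the dissimilarity $D = 1 - r \in [0, 2]$. Pearson (not Spearman)
is used because the dissimilarity is defined directly on the map values.

* **Reordering**: the similarity matrix is reordered by the Fiedler vector
  (second-smallest eigenvector of the graph Laplacian of $1 - D$), which
  concentrates large similarities near the diagonal. Exhaustive
  minimisation over permutations is factorial and is used only as a test
  oracle at small n; the spectral ordering is deterministic up to a global
  flip, resolved by fixing the sign of the first nonzero entry.
* **Clustering**: Ward's minimum-variance agglomeration on the $1 - r$
  distances, `hclust` method `"ward.D2"` by default (Ward's criterion on
  the distances, squaring internally); `"ward.D"` treats the supplied
  dissimilarities as already squared — the choice is exposed because either
  convention is defensible.
* **Embedding**: classical (Torgerson) MDS — double-centering of squared
  dissimilarities and top-$d$ spectral decomposition — with Kruskal
  stress-1 reported. Classical MDS is the default because the method is
  defined by its Euclidean-distance objective; iterative stress
  minimisation could be layered on top but is not needed for $n \le 10$
  networks.
* **Centrality**: `centrality_profile()` ranks networks by similarity
  $1 - D$ to a chosen reference, with shares normalized to percentages —
  the testable restatement of a network occupying a "central" position is
  that its mean distance to all others is minimal.

# Term statistics

A study corpus is a binary study-by-term and study-by-region incidence
table. The Jaccard index between two terms' study sets is
$J = |A \cap B| / |A \cup B|$, reported with its natural logarithm;
phenotype maps threshold edges at $\ln J > -10$ by default (disjoint sets
give $\ln J = -\infty$ and can never pass). Forward inference is the
counting estimate $P(\mathrm{act}\mid\mathrm{term})$; reverse inference
applies Bayes' rule with either the empirical term base rate (default) or a
user-supplied prior (0.5 mimics the uniform-prior convention of automated
meta-analytic frameworks). With the empirical prior, Bayes' rule collapses
to direct counting $P(\mathrm{term}\mid\mathrm{act}) =
n(\mathrm{term}\wedge\mathrm{act}) / n(\mathrm{act})$ — the test suite
asserts this consistency. A region with zero activation probability under
both likelihoods yields an `NA` posterior, never a silent 0.

# The synthetic generator

`generate_network()` scatters each experiment's foci around planted true
centers with isotropic Gaussian jitter plus a fraction of uniform noise
foci; `generate_hub_scenario()` builds the multi-network design — every
network shares one hub center and carries one private center, all centers
separated by more than 4 jitter standard deviations. Isotropic Gaussian
jitter mirrors the ALE kernel's own spatial-uncertainty model, which makes
parameter recovery interpretable. Defaults: 8 networks, 15 experiments of
10 foci each, 4 mm jitter, on a 64 mm cubic mask at 2 mm resolution — small
enough that the full pipeline runs in minutes on one core. The noise
fraction defaults to 0.15, a modest contamination level representative of
the unrelated foci that heterogeneous literature samples carry; it was
fixed once when the generator was designed.

What the generator does *not* emulate: brain anatomy (the mask is a cube, a
real mask is a convoluted volume whose border effects are stronger),
between-experiment sample-size differences (real ALE variants widen kernels
for small studies; this package fixes FWHM), spatially structured noise,
and any text content for the corpus. Passing recovery tests therefore shows
the chain is correct and well-calibrated, not that any particular real
dataset would yield the same maps.

`generate_corpus()` plants a designated target term that drives activation
in target regions at `p_act_given_term` vs `p_act_given_notterm`, giving
exact ground truth for the inference estimators.

# Numerical choices

* Volumes are axis-aligned only (diagonal NIfTI affine, positive voxel
  sizes); anything else is rejected on read rather than resampled.
* All public APIs speak millimetres; voxel indices are internal and
  1-based. Nearest-voxel assignment is within half a voxel per axis.
* Out-of-mask values are exactly 0 by construction; out-of-mask foci are
  flagged and excluded from kernels but never silently dropped.
* Kernel mass is renormalised over the mask to 1 (tolerance in tests:
  1e-9); the ALE union is computed in plain double precision and agrees
  with brute-force inclusion-exclusion to 1e-12.
* The empirical p-value convention adds one to numerator and denominator,
  avoiding zero p-values.
* `cmdscale` can return fewer than `d` columns when trailing eigenvalues
  are non-positive; missing columns are zero-padded so embeddings have a
  stable shape.

# Validation design

The test suite validates each stage against an independent oracle:
closed-form kernel identities; inclusion-exclusion expansion of the ALE
union; a hand-written BH step-up rule; exhaustive counting for Jaccard and
forward/reverse inference; exact re-embedding of Euclidean configurations;
and planted-structure recovery (hub conjunction, MACM co-activation group,
two-group Ward partition, central reference network) on the synthetic
scenarios at their default sizes (8 networks, 200 permutations per null,
32³-voxel grid — chosen so the whole suite completes in a few minutes).
A type-I calibration check confirms that with uniformly drawn foci about 5%
of voxels fall below uncorrected p = 0.05.

# Known limitations

* The recovered conjunction region is wider than the planted hub: the
  10 mm kernel convolved with 4 mm jitter gives the recovered blob an
  intrinsic FWHM of ~13.7 mm, so at FDR q = 0.05 the conjunction extends
  ~10–12 mm from the hub center. Containment diagnostics (the hub sphere
  recovered in full, no private center surviving) are the appropriate
  recovery checks; overlap coefficients against a sphere at the jitter
  scale are dominated by this kernel dilation and stay low even when
  recovery is perfect.
* The pooled-voxel null ignores spatial autocorrelation within a
  permutation; it matches the lineage of the method but is not a
  cluster-level inference.
* Fixed FWHM for all experiments; no subject-count-adaptive kernels.
* No Talairach/MNI conversion: all coordinates are assumed to live in one
  consistent millimetre space.
* Term statistics operate on binary incidence; no text mining.
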