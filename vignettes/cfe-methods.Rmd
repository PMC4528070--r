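---
title: "Connectivity-based fixel enhancement: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based fixel enhancement: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixelcfe)
```

## The problem

A *fixel* is a specific fibre population within a voxel. In crossing-fibre
white matter a single voxel commonly holds two or three fixels with
distinct orientations, each carrying its own scalar measure (apparent fibre
density, a test statistic, ...). Statistical machinery built for voxel
images — isotropic Gaussian smoothing, cluster-extent inference — mixes
these populations: a voxel neighbourhood straddles unrelated tracts, so
smoothing dilutes tract-specific effects and clusters conflate them.

`fixelcfe` replaces the spatial neighbourhood with a *structural* one. A
whole-tractogram of streamlines defines, for every fixel $f$, which other
fixels share its streamlines, and how consistently. Everything downstream —
smoothing, threshold-free enhancement, the permutation null — runs on that
graph instead of on the voxel lattice.

## Fixel–fixel connectivity

Streamlines are assigned to fixels via the local tangent: the path is
clipped exactly against the voxel lattice (half-open voxel extents, one
record per contiguous visit), the tangent is the unit vector from the entry
to the exit point of the visit, and the fixel in that voxel with the
smallest *axial* angle to the tangent (angles computed on $|\,\hat t \cdot
\hat v\,|$, since fixel orientations have no polarity) is assigned,
provided the angle is at most 45°. With $S_f$ the streamline set of fixel
$f$,

$$c_{fi} = \frac{|S_f \cap S_i|}{|S_f|},$$

an asymmetric proportion in $[0,1]$ with $c_{ff}=1$. Entries below the
prune threshold (default $0.01$) are deleted without renormalisation: they
correspond to probabilistically unlikely streamline pairings and their
removal keeps the matrix sparse.

Decisions worth stating, since the definition leaves them open:

* **Tangent per contiguous visit.** The tangent comes from the entry/exit
  pair of each visit, not from per-step finite differences; a streamline
  revisiting a voxel later contributes a separate visit, but each
  streamline counts each *fixel* at most once (the definition counts
  streamlines, not visits).
* **Assignment cutoff 45°.** Some cutoff is needed so that a streamline
  crossing a voxel obliquely is not forced onto a nearly orthogonal fixel;
  45° is the largest angle that still guarantees a unique nearest fixel
  among orientations separated by ≥ 90°, and it always permits assignment
  in single-fixel voxels. Ties at exactly the cutoff resolve to the lowest
  fixel id.
* **Unvisited fixels** keep an implicit self-connection $c_{ff}=1$ and
  nothing else, so smoothing and enhancement degrade to the identity there
  instead of failing; they are reported as diagnostics.
* **Geometry is axis-aligned** (voxel size + origin). Exact polyline/lattice
  clipping under arbitrary rotations would complicate the traversal for no
  benefit in template-space analysis, where data are resampled onto an
  axis-aligned grid anyway.

## Connectivity-based smoothing

Raw weights multiply a spatial Gaussian by connectivity,

$$w_{fi} \propto \exp\!\left(-\frac{d_{fi}^2}{2\sigma^2}\right) c_{fi},
\qquad \sigma = \frac{\mathrm{FWHM}}{2\sqrt{2\ln 2}},$$

with $d_{fi}$ the distance between voxel centers in mm (fixels carry no
sub-voxel position in this data model). Zero-connectivity pairs never
exchange signal regardless of distance; the Gaussian in turn stops remote
same-bundle fixels, whose values can differ systematically along the tract,
from dominating. Each row is normalised to sum to 1 — the definition shows
weights but no normalisation, and row-stochastic weights are the standard
kernel-smoothing choice because they preserve constants. The kernel is
truncated at $3\sigma$ (< 1.2 % of kernel mass) to keep the weight matrix
sparse. FWHM 0 mm returns identity weights; a row that loses all mass (an
isolated fixel) falls back to the identity with a diagnostic.

**Variance renormalisation.** Smoothing independent unit-variance noise
leaves fixel $f$ with variance $\sum_i w_{fi}^2$; dividing by its square
root restores sd 1 *exactly, per fixel*. A global empirical factor would
also be defensible — the renormalisation requirement admits both readings —
but the per-fixel factor is deterministic and exact for the simulation
design, so simulated statistic images remain calibrated after smoothing.

## The CFE statistic

$$\mathrm{CFE}(f) = \int_0^{h_f} e(f,h)^E\, h^H\, dh, \qquad
  e(f,h) = \sum_{i\,:\,h_i \ge h} c_{fi}^{\,C},$$

the threshold-free enhancement in which the "cluster extent" at height $h$
is the connectivity-weighted count of *structurally connected*
supra-threshold fixels — spatial contiguity is never required. $E$
(dimensionless, default 2) controls how strongly extent is rewarded, $H$
(default 3) how strongly height is rewarded, and $C \in [0,1]$ (default
0.5) how strongly the contribution of a connected fixel scales with its
measured connectivity ($C=0$: all connected fixels equal; $C=1$:
proportional). These defaults behave near-optimally across bundles of very
different length, curvature and crossing content, which is what makes a
single recommended set usable when the group effect is unknown.

Numerical choices:

* **Discretisation.** Left-Riemann sum at thresholds $dh, 2dh, \dots \le
  h_f$, the conventional TFCE discretisation; it converges as $dh \to 0$
  and the test suite checks the analytic cases at $dh = 10^{-4}$ to 0.1 %.
* **$dh = 0.1$** on the scale of the statistic, fixed in absolute terms and
  shared by the observed map and every permutation. A data-adaptive step
  would make enhanced values incomparable across permutations and the
  max-statistic null inconsistent. No canonical value exists for this step;
  0.1 follows common threshold-free-enhancement practice on t-statistics.
* **The fixel enhances itself**: the sum over connected supra-threshold
  fixels includes $f$ with $c_{ff}=1$ (whether the extent includes the
  fixel itself is not fixed by the formula; including it makes an isolated
  fixel reduce gracefully to pure height enhancement).
* **Negative statistics are never enhanced** ($h > 0$); a directional test
  of the opposite sign is a second pass on the negated map, and two-sided
  testing Bonferroni-doubles across the two passes (off by default).
* A literal triple-loop evaluator, `cfe_enhance_bruteforce()`, implements
  the same contract with no sparsity or vectorisation and serves as the
  independent oracle: the sparse path must match it to $10^{-9}$ relative.
* Classic voxel TFCE (`tfce_enhance()`, defaults $E=0.5$, $H=2$) is
  included for comparison tests only; on a fully connected chain with
  $C=0$ and a unimodal profile the two statistics coincide exactly, which
  the suite exploits as a cross-check.

## Inference

Per-fixel GLM t-statistics (shared design, OLS, $t = c^T\hat\beta /
\sqrt{\hat\sigma^2 c^T(X^TX)^{-1}c}$; zero-residual-variance fixels get
$t = 0$ with a diagnostic) feed a max-statistic permutation test in which
**CFE is part of the test statistic**: every permutation is re-enhanced
with identical parameters before its global maximum is recorded.
FWE-corrected p-values are $p(f) = \#\{\text{null maxima} \ge
\mathrm{CFE}(f)\}/n_\mathrm{perm}$, with ties counting against
significance and the identity labelling always included as permutation 1,
so $p \ge 1/n_\mathrm{perm}$.

The permutation scheme is Freedman–Lane under the reduced model: the design
is projected onto the null space of the contrast, reduced-model residual
rows are permuted, and the full-model statistic is recomputed on the
reconstructed data. This is the standard residual-permutation scheme for
GLMs with nuisance covariates; for a pure two-group design it reduces to
relabelling. Permutation schedules are seeded, duplicate-free, and switch
to exhaustive enumeration when the request approaches the number of
distinct orderings (with a warning when it exceeds it). The permutation
loop is a single sequential stream — results are therefore trivially
independent of any parallel layout — and p-values are bit-reproducible
given the seed.

## The synthetic phantom generator

The generator is the package's stand-in for an in vivo template: analytic
bundles (polyline centerline, radius, per-streamline Gaussian perpendicular
offsets carried along a local frame) produce a tractogram; fixels are then
derived *from the phantom's own streamline tangents* by greedy axial
clustering within each voxel, with a 30° minimum separation between
resulting fixels (bundles crossing more shallowly merge, mirroring what FOD
segmentation would do). Truth masks come from streamline→fixel visitation
per bundle, and a visitation-density map scaled to max 1 stands in for AFD
so that analysis-mask construction is exercisable. Statistic images are
i.i.d. $N(0,1)$ draws over the mask, with the paired signal image adding
`snr` on the truth fixels of the *same* draw — against unit noise the
planted amplitude is the SNR directly (an amplitude-1 signal in sd-0.5
noise being the SNR-2 reference construction). Per-realisation sub-seeds
make any subset of realisations regenerable in any order.

What this emulates: crossing geometry, tract-specific connectivity,
calibrated noise, paired noise/signal realisations. What it does not: FOD
estimation and segmentation, registration error, anatomically realistic
ROI shapes, spatially correlated physiological noise, streamline-count
biases of real tractography. Passing tests therefore validate the
*statistical machinery* under its stated model, not performance on real
data.

Five presets (`builtin_scenes()`) echo archetypal evaluation regions at toy
scale (≤ 32³ voxels, a few hundred fixels): a curved bundle crossing a
straight one ("arc"), a fanning trunk, a long thin bundle, a focal segment
of it, and three disjoint bundles jointly true.

## Fixel correspondence and the analysis mask

The two-step analysis mask first keeps fixels with template AFD > 0.33
(removing poorly corresponding fixels near the grey-matter interface),
takes the 3D voxel mask of voxels retaining at least one fixel, then
relaxes the threshold to AFD > 0.1 *within those voxels* so that
partial-volume crossing fixels survive. Both thresholds are strict, exactly
as specified. Subject fixels map to template fixels within the *same voxel*
by smallest axial angle under a 30° tolerance — whether "nearest" may cross
voxel boundaries is unspecified in the underlying construction, and
same-voxel matching is the simplest consistent reading; unmatched template
fixels extract the value 0, surplus subject fixels are ignored, and
matching is greedy with each subject fixel used at most once (ties to the
lowest id, deterministically).

## Evaluation: AFROC

For family-wise evaluation over many simulated inferences, a common
threshold sweeps from the maximum enhanced signal+noise value towards zero
(1000 evenly spaced thresholds by default; supra-threshold is strict `>`).
FPR is the fraction of noise-only realisations with *any* supra-threshold
fixel; TPR averages the detected fraction of truth fixels over signal
realisations (a rate rather than a raw count, so AUCs are comparable
across ROIs of different size). The AUC is the trapezoidal area restricted
to FPR ≤ 0.05 — family-wise error above that is of no practical interest —
linearly interpolated at the cut and divided by 0.05 to span $[0,1]$.
Curves whose FPR never reaches the cut extend their last TPR across the
band (perfect-specificity degenerate case). Sweeps share the noise
realisations across all parameter combinations (paired design), so
parameter comparisons are not confounded by noise sampling.

## Problem sizes

The package's own simulation studies run at deliberately modest scale: the
arc phantom (~330 fixels, 600 streamlines), 100–200 realisations per
condition, and 100–720 permutations per test. These sizes were chosen so
the entire validation suite executes in minutes on a laptop while leaving
all binomial acceptance bands meaningful; the implementation itself is
sparse throughout and scales to much larger fixel counts.

## Known limitations

* Connectivity quality is inherited from the tractogram; false streamline
  connections propagate into smoothing and enhancement neighbourhoods.
* The enhancement is stationary: no adjustment for spatially varying
  smoothness or connectivity density is applied, so sensitivity can vary
  across the mask.
* Distances use voxel centers; sub-voxel fixel positions are not modelled.
* Exchangeability of (reduced-model) residuals is assumed; variance groups
  and exchangeability blocks are not implemented.
* The generator's bundles are tubes with Gaussian cross-sections; highly
  fanning or sheet-like geometries are only coarsely approximated.
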