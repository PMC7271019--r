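---
title: "Methods: regional connectivity-based parcellation with rcbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional connectivity-based parcellation with rcbp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcbp)
```

## The model

Regional connectivity-based parcellation treats every voxel of a region
of interest (ROI) as an observation described by its *connectivity
fingerprint*: the vector of its connection strengths to a fixed set of
target voxels. The working assumption is that the ROI is composed of a
small number of subregions whose voxels share a common fingerprint up to
noise, so a hard clustering of the fingerprint rows recovers the
subdivision. This is a compression model: when connectivity changes
gradually across the region rather than in steps, the parcels are a
simplified description of the data, not neurobiological units.

Two connectivity markers are supported. Functional connectivity is the
Pearson correlation between a ROI voxel's and a target voxel's BOLD time
series, computed after optional spatial smoothing, nuisance regression
and band-pass filtering, and optionally variance-stabilized with
Fisher's Z (artanh). Structural connectivity starts from a sparse
streamline-count matrix produced by probabilistic tractography; the
counts are densified and cube-root transformed. Both paths assume the
inputs are already preprocessed and spatially normalized to a common
grid — the package validates grid conformity (shape, voxel size, origin,
within 10^-3^ mm) but performs no registration.

Individual clusterings are aggregated per k. Since cluster ids are
arbitrary within each subject, the group step is anchored on a quantity
that does not depend on them: the voxel-by-voxel Hamming distance,
`d(u, v)` = fraction of subjects placing `u` and `v` in different
clusters. A hierarchical tree on this matrix, cut at k, is the reference
labeling; each subject is relabeled by the id bijection maximizing
agreement with the reference; the per-voxel mode of the relabeled
subjects is the group parcellation (optionally the reference cut itself).
Relabel accuracy — the maximized agreement fraction — and the cophenetic
correlation of the reference tree are reported alongside.

## Parameters that matter

- `k_range` (unitless, default 2–5): the granularities probed. There is
  no attempt to pick "the" k automatically; the validity indices rank
  the solutions and the user decides.
- k-means: `n_init = 256` restarts with k-means++ seeding and
  `max_iter = 10000` Lloyd iterations per restart; the restart with the
  smallest within-cluster sum of squares wins. These defaults favour
  reproducibility of the optimum over speed; for well-separated data far
  fewer restarts reach the same optimum.
- Smoothing FWHM (mm, default 5): Gaussian kernel width,
  `sigma = FWHM / (2 sqrt(2 ln 2))`, converted to voxels through the
  affine.
- Band-pass edges (Hz, default 0.01–0.08): the conventional resting-state
  fluctuation band; must lie strictly inside (0, Nyquist).
- `roi_border_mm` (mm, default 0): a guard ring around the ROI removed
  from the target mask so that spatial smoothing cannot leak ROI signal
  into its own features.
- PCA reduction: either a component count or a variance fraction in
  (0, 1); fitted per subject on the column-centered matrix.
- Reference-tree linkage (default `"complete"`): used both for the group
  reference and, when agglomerative clustering is chosen at the
  individual level, reused there — the individual-level default is not
  independently specified anywhere, and sharing it keeps the two
  hierarchical steps consistent.
- Master seed: every unit of work (subject, k, stage) derives its own
  seed via a deterministic hash (`derive_seed`), so partial re-runs,
  interrupted runs and any worker count reproduce identical numbers.

## Numerical choices

- **Voxel indexing** is 0-based `(i, j, k)` grid coordinates everywhere;
  world coordinates in mm are obtained through the 4×4 affine. Rows of a
  connectivity matrix and entries of a label vector follow column-major
  grid order of the in-mask voxels.
- **Median filter** uses the 3×3×3 neighborhood (27 cells) with zero
  padding at the grid border; on binary data the median is 1 iff at
  least 14 cells are 1.
- **Parity subsampling** keeps voxels whose three 0-based indices are
  all even (phase 0). On the full 91×109×91 template grid this retains
  46×55×46 = 116,380 voxels.
- **Border removal** measures Euclidean distance in mm through the
  affine; a target voxel is removed when its distance to the nearest ROI
  voxel is ≤ the border. Computed in chunked closed form, verified
  against an exhaustive scan.
- **Upsampling** moves the voxel at `(i, j, k)` to `(fi, fj, fk)` on a
  grid with voxel size divided by `f`, preserving each source voxel's
  world position and the voxel count, and guaranteeing no two outputs are
  26-connected; the mapping is stored so results map back bijectively.
  **Downsampling** aggregates `f`³ blocks by majority (≥ half of the
  in-grid block cells set).
- **Smoothing** is separable discrete Gaussian convolution with kernel
  radius 4 sigma, unit-sum normalized, renormalized at truncated borders —
  so constant fields pass through exactly.
- **Band-pass** is a zero-phase (forward–backward) Butterworth of order
  3. The series mean is removed before filtering: DC lies outside the
  pass band by construction, and demeaning suppresses the start-up
  transient of the forward–backward pass.
- **Zero-variance series** yield correlation 0 with a warning, never NA,
  so clustering always sees finite values. Fisher's Z clips |r| at
  1 − 10^-15^ so r = ±1 maps to a large finite value.
- **"Cubic transform"** is implemented as the signed cube root
  `sign(x) |x|^(1/3)` — the variance-stabilizing reading for heavily
  skewed streamline counts; cubing the counts would do the opposite.
- **Sparse coordinate files** are read as 1-based `(row, col, value)`
  triples, the dialect the established tractography tooling emits; the
  choice is documented rather than derivable.
- **Empty k-means clusters** within a restart trigger re-initialization
  (up to 25 draws); a labeling missing one of its k ids is never
  returned.
- **Mode ties** are broken toward the smallest label id and counted in
  the log. **Relabeling** is exhaustive over k! permutations for k ≤ 8
  and maximum-weight bipartite matching on the contingency table above
  that; the two paths are property-tested to agree.
- **Relabel accuracy** is computed against the hierarchical reference
  (not against the post-hoc mode), matching its role of measuring how
  well a subject matches the reference.
- **Degenerate validity indices** (zero within-cluster dispersion for
  Calinski–Harabasz, coincident centroids for Davies–Bouldin) return the
  sentinel `.Machine$double.xmax` with a warning instead of erroring, so
  batch reports complete; constant distance matrices give a cophenetic
  correlation of NaN with a warning. Mismatch counts against a reference
  image are taken after optimal permutation alignment of ids — unaligned
  counting would depend on arbitrary ids.
- **Spectral clustering** uses a symmetrized k-nearest-neighbour
  affinity graph (default 10 neighbours), the normalized Laplacian, the
  k bottom eigenvectors row-normalized, and the package's own k-means on
  the embedding.

## What the synthetic generator emulates — and what it does not

`planted_design` plants axis-aligned contiguous parcels in a rectangular
ROI; each parcel has a prototype fingerprint (unit-norm random direction
scaled by `prototype_separation`, default 10) and each subject observes
prototype + i.i.d. Gaussian noise (`subject_noise_sd`, default 1). The
BOLD generator drives each parcel with a band-limited latent signal
(sinusoids inside 0.01–0.08 Hz) shared with a subset of target voxels,
optionally contaminated by a known confound (linear trend + slow
sinusoid) so nuisance regression can be tested for exact cancellation.
`make_noisy_labelings` emulates the consensus problem directly: planted
labels, per-subject id permutations, and a configurable flip rate.

This emulates the *statistical* structure the pipeline exploits —
distinct fingerprints, subject noise, arbitrary ids — but none of the
physiological structure of real data: no hemodynamics, head motion,
spatially correlated noise, partial-volume effects or gradual
connectivity transitions. Passing the planted-recovery tests therefore
shows the machinery is correct, not that real regions decompose cleanly;
on real data the indices routinely disagree and parcels are blurred.
Default cohort scale (30 subjects, 500 ROI voxels, 200 targets,
separation/noise = 10) was chosen as a desk-scale stand-in for a
well-organized region; the test and acceptance runs use this scale, with
smaller grids (tens of voxels, a handful of subjects) for the
per-operation oracle checks.

## Known limitations

- Native-space (per-subject grid) parcellation is out of scope; the
  group step requires a common voxel set.
- Surface (vertex-based) data, DICOM ingestion and tractography itself
  are not handled; the dMRI path begins at an existing sparse matrix.
- Group similarity scores are not independent of the individual
  clusterings they aggregate and can be optimistic; the report carries
  this caveat.
- The internal validity indices are computed per subject in that
  subject's own feature space; comparing their absolute values across
  data sets is meaningless.
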