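---
title: "Methods: thalamocortical connectivity gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thalamocortical connectivity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalagrad)
```

## The problem

Thalamocortical white-matter connectivity in the neonatal brain is
spatially organized: nearby thalamic locations connect to nearby cortical
targets, and this topography can be summarized by a small number of
*gradients* — smooth spatial patterns that jointly describe preferential
connectivity between thalamus and cortex. `thalagrad` implements the full
analysis chain for extracting such gradients from dense seed-by-vertex
structural connectomes and for testing how they vary with age and with
preterm birth, together with a synthetic-cohort generator that provides
ground truth for every stage.

The pipeline starts downstream of tractography. Its input is a table of
streamline endpoints (one row per streamline: seed id, endpoint
coordinates, mean fractional anisotropy sampled along the streamline).
Everything upstream — diffusion preprocessing, fibre-orientation
estimation, the tractography itself, and template-to-subject registration —
is the province of external tools and out of scope here.

## The connectome build

**Endpoint assignment** (`assign_endpoints`). Each endpoint is mapped to
the nearest non-medial-wall vertex by Euclidean distance on the
white-surface coordinates; if that vertex is within `radius` (default 5 mm)
the streamline's FA weight is accumulated into the (seed, vertex) cell,
otherwise the streamline is discarded. Connectivity is therefore a
non-negative sum of streamline weights. Distance ties break towards the
lowest vertex index so the build is deterministic.

**Surface smoothing** (`build_kernel`, `smooth_connectome`). Dense
connectomes are sensitive to accumulated integration error in streamline
propagation, so connectivity is smoothed across the cortical mesh with a
Gaussian kernel (default 3 mm FWHM, truncation `epsilon = 0.01`). Geodesic
distances are approximated by shortest paths on the mesh edge graph with
Euclidean edge lengths; at a 3 mm FWHM on meshes of this resolution the
error of the graph approximation is second order. Weights below `epsilon`
are zeroed *before* row normalization, and rows are renormalized to sum to
one, so smoothing conserves each seed's total connectivity exactly.
Smoothing methods for connectomes are usually described with one kernel
per connection endpoint; here the seed endpoint lives in thalamic volume,
not on a mesh, so the cortical kernel alone is the default and a
volumetric Euclidean Gaussian over seeds (`smooth_seeds`) is available but
off by default.

**Seed filtering** (`filter_seeds`). Deep, mostly medial, thalamic seeds
are difficult to track from; their near-empty rows would contribute mostly
noise. A seed is retained iff its row of the *across-subject mean* matrix
has at least `min_connected_vertices` (default 100) strictly positive
entries; the retained index set is then applied uniformly to every
subject. Filtering on the group mean rather than per subject keeps the
seed set — and hence the decomposition dimensions — identical across the
cohort.

**Sigmoid normalization** (`normalize_sigmoid`). Per vertex column,
\[
S(x) = \frac{1}{1 + \exp(-(x - \langle x\rangle)/\sigma_x)},
\]
with \(\langle x\rangle, \sigma_x\) the mean and standard deviation of that
connection across seeds, followed by a linear rescale of the column to
exactly \([0, 1]\). The transform is monotone within each column and damps
outliers. Two conventions had to be fixed where the procedure is
underdetermined: \(\sigma_x\) is the *population* (divide-by-n) standard
deviation, and the min–max rescale is per column (each vertex's profile
uses its own range). Columns with \(\sigma_x = 0\) are undefined under the
sigmoid and are set to its symmetric limit, the constant 0.5.

## Decomposition and alignment

The normalized matrix is centred per vertex column and decomposed by thin
SVD, \(M = USV^\mathsf{T}\) (`center_matrix`, `pca_svd`). Scores \(US\)
(one row per seed) and loadings \(V\) (one row per vertex) describe each
component's thalamic and cortical pattern; the variance explained by
component \(k\) is \(\lambda_k = s_k^2/(n-1)\), reported both absolutely
and as a fraction of the total. The SVD sign ambiguity is fixed by forcing
each loading column's largest-magnitude entry positive; any residual
reflection is absorbed by the alignment step.

A **term template** (`build_template`) is the decomposition of the
elementwise average matrix of the `n_template` (default 20) oldest
term-born subjects, centred identically to individual matrices. Each
individual decomposition is then aligned to it by an **orthogonal
Procrustes rotation** (`procrustes_align`) computed on the first
`k_align = 5` score columns and applied to both scores and loadings; no
scaling or translation is applied. Reflections are deliberately permitted:
independently computed SVDs differ by arbitrary sign flips that a pure
rotation could not undo. Per-subject similarity to the template
(`similarity_to_template`) is the Pearson correlation of one aligned
component column with the template's, over seeds or over vertices, and is
the summary used in the similarity-vs-age analyses. A leave-one-out
variant (`build_template(..., exclude = subject)`) supports templates that
exclude the subject under study.

## Spatial statistics

**Spin tests** (`make_spins`, `spin_test`). Cortical maps are spatially
autocorrelated, which inflates naive map-to-map correlations. The null
model rotates vertex positions on the spherical registration by
Haar-uniform random rotations and remaps each rotated vertex to its
nearest original vertex, preserving autocorrelation. The test is run in
both directions (spin map A against intact B, and vice versa) with
two-sided add-one p-values, and the reported `p_spin` is their average,
which removes the asymmetry of spinning only one map. Since a single
hemisphere is analysed, rotations are used as-is without mirrored pairs.

**Age maps** (`age_correlation_map`). Per seed (or vertex), the Pearson
correlation between the aligned component value and scan age across
subjects, with two-sided p-values from the t-distribution with \(n-2\)
degrees of freedom and Benjamini–Hochberg FDR control at 0.05 (`fdr_bh`,
delegating to `stats::p.adjust`). Seed and vertex families are corrected
separately, matching how the two domains are reported. Elements constant
across subjects have no defined correlation and are excluded from the FDR
family rather than silently assigned a p-value.

**Group inference** (`vertex_totals`, `glm_tmap`, `tfce_enhance`,
`permutation_fwer`). The preterm-vs-term outcome is each vertex's total
connectivity to the thalamus — column sums of the smoothed (pre-sigmoid)
matrix, whose values are still on the streamline-FA scale; a
proportion-of-connectivity option divides totals by their sum (off by
default). The per-vertex statistic is the two-tailed OLS t for the group
contrast controlling scan age and sex. Threshold-free cluster enhancement
integrates cluster support over heights
(\(\sum_h e(h,v)^E h^H\,dh\), surface defaults \(H = 2\), \(E = 0.5\),
\(dh = \max|t|/100\)), with cluster extent measured as surface area
(one-third of incident-triangle areas) and connectivity through shared
mesh edges; negative statistics are enhanced on the negated map and
re-negated. Family-wise error is controlled by Freedman–Lane permutation:
residuals of the covariates-only model are row-permuted, surrogate
outcomes refit, and the maximum (enhanced) absolute statistic over
vertices forms the null; add-one p-values are used throughout, so no
permutation p is ever exactly zero. `group_scalar_ancova` compares nested
linear models (covariates vs covariates + group) with a partial F-test for
scalar summaries such as variance-explained fractions.

## The synthetic cohort

The generator is the package's ground-truth surface, emulating a neonatal
cohort scanned across 29–45 weeks:

* `make_seed_grid` places seeds on a regular grid inside an ellipsoid.
  The defaults — 1.75 mm spacing in a 13 × 10 × 7.5 mm semi-axis
  ellipsoid — give 789 seeds, a dense left-thalamus-like seeding of
  roughly 800 seeds. Analyses in the test-suite and acceptance script use
  a 2.5 mm grid (241 seeds) with a level-3 icosphere cortex (642 vertices,
  585 outside the medial wall): large enough that gradients, alignment and
  spatial statistics behave as at full scale, small enough that the whole
  suite runs in minutes. These sizes are the package's documented working
  resolution for simulation studies.
* `make_sphere_mesh` builds an icosphere with unit-sphere registration
  coordinates and 60 mm "white" coordinates. The medial wall is a fixed
  geodesic cap (default angular radius 35°) around the inferior pole — a
  deliberately simple, testable stand-in for the real medial wall, flagged
  for exclusion everywhere.
* `plant_structure` constructs orthonormal ground-truth scores and
  loadings whose geometry mimics the observed gradients: component 1
  combines the medial-lateral and anterior-posterior seed axes and varies
  rostro-caudally on the cortex; component 2 spreads radially from a
  lateral thalamic anchor; higher components are low-order spatial
  harmonics. Score fields are centred before orthonormalization so that
  per-column mean removal cannot tilt the planted components — without
  this the noise-free round trip is not exact. Component weights are
  scaled so the component-1 signal has entry-level standard deviation ~1,
  letting noise be specified directly as a fraction of the leading
  signal.
* `simulate_cohort` draws each subject's matrix as baseline + planted
  signal + i.i.d. Gaussian noise, clipped at zero (connectivity is a
  non-negative sum of weights). The baseline is the smallest constant
  making the noise-free matrix non-negative, so with zero noise nothing is
  clipped. Noise standard deviation interpolates *linearly* between
  `noise_sd_at_min_age` (default 0.5, youngest) and `noise_sd_at_max_age`
  (default 0.1, oldest): the simplest monotone model that makes younger
  subjects noisier and hence drives the positive similarity-vs-age
  correlation the analyses are designed to detect. Preterm subjects
  receive fixed vertexwise connectivity offsets added to every seed's row.
  No generative model of inter-subject biological variability is claimed:
  age-scaled noise is a deliberate stand-in, so passing tests demonstrate
  parameter recovery and calibration of the machinery, not biological
  validity of any particular developmental model. Real connectomes also
  differ in ways the generator does not emulate — non-Gaussian weight
  distributions, distance-dependent sparsity, spatially correlated
  subject noise, registration error — so calibration results here should
  be read as necessary, not sufficient, evidence for real-data behaviour.
* `simulate_endpoints` inverts the build stage for round-trip testing:
  multinomial endpoint draws proportional to a target row, optional
  isotropic jitter, FA weights uniform in [0.1, 0.5]. The exact draw is
  recorded so tests can verify endpoint assignment recovers it.

## Numerical choices and degenerate inputs

* Decomposition applies to any common-scale matrix: `center_matrix` and
  `build_template` accept smoothed/filtered input as well as normalized.
  This is deliberate. The scaled sigmoid is a monotone but *nonlinear*
  per-column transform; passing an exactly low-rank matrix through it
  leaves the leading components recoverable only to |r| ≈ 0.94–0.97, so
  exact parameter-recovery contracts are stated for the decomposition
  pipeline operating on the generator's matrices directly, while the
  sigmoid's own contracts (midpoint, monotonicity, exact range) are
  tested separately. The end-to-end full workflow in
  `run_pipeline` still normalizes before decomposing.
* Ties in nearest-vertex matching (endpoint assignment, spins) break
  towards the lowest vertex index; grid and mesh constructions are fully
  deterministic; every stochastic stage consumes an explicit `rng_seed`.
* Degenerate fits (zero residual variance) yield infinite t / F with a
  warning rather than an error; constant maps are rejected by the spin
  test by name; constant columns are excluded from FDR families; an
  all-zero endpoint table produces an all-zero matrix with a warning.
* Permutation and spin p-values use the add-one convention,
  \((1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})\).

## Known limitations

* Graph-based geodesics slightly overestimate true surface distance on
  coarse meshes; kernels are correspondingly slightly wide.
* The spin null assumes a spherical registration and one hemisphere; no
  mirrored-pair machinery for bilateral maps is provided.
* Exact permutation options of external GLM toolboxes (exchangeability
  blocks, tail approximation) are not reproduced; the documented
  Freedman–Lane scheme with max-statistic FWER is the implemented
  behaviour.
* No volumetric (voxel) TFCE, no cluster-extent alternatives, and no
  nonlinear embeddings: the decomposition is PCA only.
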