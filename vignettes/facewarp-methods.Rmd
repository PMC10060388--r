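---
title: "Methods: landmark-based analysis of facial age morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based analysis of facial age morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`facewarp` quantifies how facial shape differs between adults and infants
across great-ape species from 2-D landmark data. This vignette documents
the statistical model behind each stage, every tunable parameter with its
default and rationale, the synthetic ground-truth generator used for
validation, and the numerical and design choices that were genuinely open.

## Shape model and superimposition

A specimen is an ordered configuration of $k$ landmarks
$X \in \mathbb{R}^{k \times 2}$; the landmark order is the homology order
and is never permuted. Shape is what remains after removing position,
scale and orientation. Generalized Procrustes analysis (GPA) centers each
configuration, scales it to unit centroid size
$\mathrm{CS}(X) = \sqrt{\sum_i \lVert x_i - \bar{x} \rVert^2}$, and
iterates two steps: rotate every specimen to the current consensus (the
2-D orthogonal-Procrustes solution via the SVD of the cross-covariance,
with determinant forced to $+1$ — faces have a left/right identity, so a
reflected "fit" would silently destroy asymmetry information), then
replace the consensus by the mean of the aligned specimens re-normalized
to unit centroid size, which is the least-squares consensus among
unit-size shapes. Both steps are descent steps on the total Procrustes sum
of squares, so the recorded objective trace is monotone non-increasing;
iteration stops when the consensus changes by less than `tol = 1e-8`
(root-sum-square) or after `max_iter = 100` iterations (flagged, not
fatal). A final rotation pass against the converged consensus makes the
rotation optimality conditions hold exactly, which keeps the trailing
eigenvalues of the shape covariance at numerical zero rather than at
$O(\text{tol}^2)$. For the study-scale problem ($n = 80$, $k = 97$) GPA
converges in ~4 iterations, far below landmark noise.

## Sliding semilandmarks

Of the 97 landmarks, 76 mark positions along outlines (brow, eye outlines,
nose edges, mouth, chin). Their position *along* the curve is an artefact
of digitization, so after GPA each semilandmark is allowed to move along
its tangent — the unit chord between its flanking landmarks in the current
specimen (the standard formulation; using the consensus chord instead is a
one-line change). Two displacement criteria are provided:

* **Procrustes distance** (default): the displacement is the orthogonal
  projection of the semilandmark's residual (consensus minus current
  position) onto the tangent — closed-form, independent per semilandmark,
  and bounded by the residual itself.
* **Bending energy** (the tpsRelw convention): displacements for all
  semilandmarks are solved jointly to minimize the thin-plate-spline
  bending energy of the specimen-to-consensus deformation,
  $h_x^\top B h_x + h_y^\top B h_y$ with $B$ the bending-energy matrix of
  the consensus.

After each sliding pass GPA is re-run; the cycle repeats up to
`outer_iter = 5` times or until the consensus stabilizes. Fixed landmarks
never move.

**Why the default is Procrustes distance.** The bending-energy solve
linearizes the outline along its chord, and smooth tangential flows along
an outline carry almost no bending energy, so the unconstrained minimizer
can slide points far beyond the chord's validity. In our validation
simulations (noise comparable to semilandmark spacing) the uncapped
bending-energy cycle *increases* the total Procrustes sum of squares from
cycle to cycle and degrades recovery of planted shape effects; we
therefore (a) limit each bending-energy slide to `cap_frac = 0.25` of the
chord length — a trust region for the linearization — and (b) default to
the exactly solvable, stable Procrustes-distance criterion. The original
analysis tool's sliding mode (or whether sliding was enabled at all) is
not documented, so both criteria are first-class, the fit records which
was used, and conclusions should be checked under both (`sliding_mode` in
`pipeline_config()`).

## Tangent projection and relative warps

Aligned shapes live near the unit sphere in $\mathbb{R}^{2k}$; Euclidean
multivariate methods apply after orthogonal projection into the tangent
space at the consensus, $v \mapsto v - (v \cdot c)\,c$ (rows are therefore
consensus-centered; the projection is idempotent; for near-consensus
shapes it differs from the raw residual only at second order in the
Procrustes distance — a property verified by test). Flattening order is
$(x_1, y_1, x_2, y_2, \dots)$ throughout.

Relative warps are the principal components of these rows. With the
default weighting exponent `alpha = 0` this is exactly PCA — implemented
as an eigendecomposition of the row covariance and cross-checked in the
tests against an independent SVD — which matches the source analysis's
description of the decomposition as a PCA. `alpha != 0` re-expresses the
non-affine part of each shape in the partial-warp basis of a
bending-energy model and scales the components by $\lambda^{-\alpha/2}$
before the PCA (affine component unweighted), for parity experiments with
bending-energy-weighted software.

Numerical conventions:

* eigen-pairs with eigenvalue below $10^{-12}$ of the largest are
  *trivial* and dropped; on generic data the non-trivial count is
  $\min(n-1,\ 2k-4)$ — the four missing dimensions are the two centering
  constraints, the scale gauge, and the rotation optimality constraint;
  for the 80-specimen study design this gives exactly 79 components;
* each eigenvector's sign is fixed so that the infant mean score exceeds
  the adult mean score on the fitted data (falling back to
  largest-loading-positive when no age labels are present), which makes
  "adult < infant" effect directions reproducible across platforms;
* scores are computed on tangent-projected coordinates; with shape
  variation this small the alternative (raw residuals) differs at second
  order, and an invariance test pins this down.

`shape_at_score()` reconstructs `consensus + score × eigenvector`; with
`score = ±1.5 × sqrt(eigenvalue)` this draws the conventional ±1.5 SD
extreme faces. `deformation_grid()` evaluates the exact thin-plate-spline
interpolant between two configurations on a regular grid. The
bending-energy quadratic form is built from the standard bordered TPS
system with kernel $U(r) = r^2 \log r^2$; it annihilates affine fields, is
invariant to rigid motion of the reference, scales as size$^{-2}$, and
equals the integrated bending of the interpolant up to the kernel's
constant ($1/16\pi$ for this normalization), which a quadrature oracle
verifies to 1%.

## Age classification

The discriminability of age classes from shape is measured with a
four-model battery on the scores of PC1–11: LDA, a linear SVM at cost 1,
and linear/RBF SVMs tuned by exhaustive grid search over
$\mathrm{cost}, \gamma \in \{2^{-10}, \dots, 2^{10}\}$ (integer exponents —
21 values per hyperparameter, 441 pairs for the RBF kernel — the
conventional reading of a $2^{-10}$–$2^{10}$ grid; the exponent range is
configurable). Tuning maximizes mean fourfold stratified cross-validated
accuracy with ties broken toward smaller cost, then smaller gamma.

Evaluation choices that the source description leaves open, and how they
were resolved:

* **Held-out, not training, metrics.** A tuned RBF SVM reaches training
  accuracy ≈ 1 trivially, which would make a reported accuracy of ~0.95
  uninformative; cross-validated metrics are the defensible reading. Both
  are computed and clearly labelled (`accuracy` vs `accuracy_train`).
* **Standardization.** PC scores have wildly different variances by
  construction, which breaks a shared gamma grid; features are therefore
  z-scored per column using training-fold statistics only. Toggleable
  (`standardize = FALSE`).
* **Non-nested by default.** The grid search and the reported evaluation
  share the fold structure; `nested = TRUE` re-tunes inside each training
  fold instead.
* **Fold assignment** is stratified by class, driven only by the seed, and
  built from a single shared permutation so that relabeling the classes
  leaves the folds unchanged (this makes label-swap invariance exact).
* **AUC** is computed by the rank-sum (Mann–Whitney) formulation on pooled
  out-of-fold decision scores — the signed margin for SVMs, the
  positive-class posterior for LDA — with ties given half credit.

`select_best()` picks the highest accuracy, breaking ties by AUC and then
by model simplicity (LDA before linear SVMs before RBF).

## Permutation inference and the age-class table

Each (group, PC) cell is tested by permutation: the observed statistic is
the cross-validated accuracy (AUC available via `statistic = "auc"`;
accuracy is the default, matching "classification performance"), the null
is built from `B = 1000` seeded label shuffles re-run through the
identical evaluation, and the p-value is the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, which is never zero and
has floor $1/(B+1)$. Directions come from the group means (adult < infant
or the reverse); significance bands at 0.005/0.01/0.05/0.10 mirror the
conventional reporting.

Two deliberate choices:

* **Frozen hyperparameters inside permutations.** Re-running a 441-point
  grid search inside each of 1000 permutations costs three orders of
  magnitude more CPU; in calibration simulations the frozen-parameter null
  is indistinguishable from uniform at the resolution of the test (the
  type-I error check in the acceptance suite), so `retune = FALSE` is the
  default and full re-tuning remains available.
* **No multiple-testing correction** across the (species × PC) grid — raw
  permutation p-values with bands, as in the source reporting; a
  Benjamini–Hochberg column is emitted alongside for transparency. Note
  what this implies: with ~10 null components each tested at
  $\alpha = 0.05$, some false positives per table are *expected* (about
  one in two tables), and the validation suite measures exactly that
  behaviour rather than pretending otherwise.

Per-species rows reuse the PC scores from the joint 80-specimen
decomposition (the natural reading of classifying each species "based on
each of PC 1–11"), not species-specific re-decompositions.

## Intra-annotator reliability

`icc_report()` compares two digitization sessions of the same specimens:
for every landmark and axis, a two-way random-effects, single-measure,
absolute-agreement ICC — ICC(A,1) — across sessions over specimens.
Absolute agreement is the right form for coordinate reproducibility
because a constant session offset *should* count against agreement; the
consistency form ICC(C,1) is available and the report records which was
used. Cells with zero between-specimen variance are undefined and reported
as `NA` with a warning. Under a one-session jitter model with error/signal
variance ratio $\rho$, the expected ICC(A,1) is
$1/(1 + \rho/2)$, which the acceptance suite verifies by simulation.

## The synthetic generator

`face_template()` builds a schematic, bilaterally symmetric 97-point
frontal face in the reference landmark economy — brow arc (17), eye
outlines (12 + 12), pupils (2), nose edges (7 + 7), subnasale (1), mouth
outline (16), chin arc (23) — with 76 semilandmarks whose slider triplets
always reference adjacent points of the same outline. `make_age_axes()`
constructs three unit displacement fields implementing the canonical
infantile features: eye enlargement + lowering, vertical compression with
compensatory widening, and top-heaviness. Each axis is projected exactly
orthogonal to (a) the similarity subspace at the template — planted
effects are pure shape — and (b) the semilandmark tangential directions:
moving a semilandmark along its own outline is, by the logic of sliding,
not an identifiable shape change, and an effect planted there would be
(correctly) removed again during superimposition. Planting effects in the
identifiable subspace is what makes the generator a fair ground truth for
a sliding pipeline.

`simulate_dataset()` draws, per species × age cell,
`template + species offset + (infant ? Σ magnitudeⱼ · axisⱼ : 0) +
isotropic N(0, σ²)` per coordinate, then a random similarity transform.
Defaults, fixed once:

| parameter | default | rationale |
|---|---|---|
| `n_per_cell` | 8 | the study design (5 species × 2 ages × 8 = 80) |
| `noise_sigma` | 0.01 | digitization noise in unit-centroid-size shape units |
| `age_magnitudes` | 0.05 / 0.03 / 0.025 | combined Procrustes distance ≈ 0.064 between age means — a strong but not trivial ontogenetic signal, and deliberately the dominant planted component so that recovery of the age axis by PC1 is a well-posed check |
| `species_offset_magnitude` | 0.02 | mild species structure; species realism is not needed to validate the inference machinery, and offsets are drawn once from a seeded isotropic Gaussian in shape space rather than hand-crafted |
| nuisance | rotation ±15°, scale 0.8–1.2, translation ±0.5 | the variation GPA must remove |

**What the generator does and does not emulate.** It reproduces the
study's design, landmark economy, semilandmark structure, nuisance
transforms, and a known low-rank signal; it does **not** reproduce real
faces' smooth, highly correlated individual variation — within-cell
variation here is isotropic noise by construction. One visible
consequence: real facial data concentrates >95% of shape variance in ~11
components because biological variation is low-rank, whereas isotropic
noise spreads variance over all ~186 shape dimensions, so the synthetic
11-PC cumulative variance sits near 40%, far below the real data's value.
Passing the validation suite therefore demonstrates correctness of the
algorithms and calibration of the inference, not that synthetic data are
statistically indistinguishable from photographs.

## Validation problem sizes

The simulation-based checks in the acceptance suite use: 50 replicate
datasets at the full study design for planted-axis recovery (per-PC
permutation tests at B = 49, whose p-value floor 0.02 is well below the
0.05 threshold); 200 null datasets at n = 40 with B = 199 for type-I-error
calibration; 100 repetitions for the null-AUC check; and 100 replicates
for the ICC expectation. These sizes were chosen so that Monte-Carlo error
is small relative to the tolerance being asserted while the whole suite
remains routinely runnable.

## Interfaces and limitations

The package's functions (with `run_pipeline()` as the one-call
orchestrator writing a CSV/TPS bundle plus a manifest of every setting and
seed) are the interface; there is no separate command-line binary. Known
limitations: 2-D landmarks only (no 3-D, no surface semilandmarks, no
missing-landmark estimation); no image handling — landmark configurations
are averaged and warped, never pixels; per-species inference at n = 16 has
the power one would expect of n = 16, and the per-PC tables inherit the
multiplicity behaviour discussed above; the slider-file dialect in the
wild varies, so both the plain three-column and the NTS-header dialects
are accepted and the detected index base is always reported.
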