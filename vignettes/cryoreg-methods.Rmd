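---
title: "cryoreg: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cryoreg: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cryoreg` implements the computational core of a whole-animal multimodal
imaging platform: registering ex-vivo blockface ("cryo") color volumes, MRI
volumes and 2D histology sections into one frame, quantifying how well that
worked, and analysing co-registered tumor and imaging-agent channels. This
vignette records the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic phantoms do and do not establish.

## The registration model

Registration is a two-stage chain from reference physical coordinates
$x$ (mm) to moving coordinates:

$$T(x) = A\,\bigl(x + u(x)\bigr),$$

where $A$ is an affine map estimated by block matching and $u$ is a cubic
B-spline free-form deformation (FFD) over a control-point lattice. All
resampling is *pull-back*: each output voxel is mapped through $T$ and the
moving volume is sampled once, trilinearly, so only a single interpolation
touches the data regardless of how many stages were estimated
(`compose_and_resample()`).

### Stage 1: block matching (rigid, then affine)

Local displacements are estimated by exhaustively searching integer voxel
shifts of small blocks, scoring each shift by the *absolute* normalized
cross-correlation. The absolute value matters: it matches edges regardless
of contrast polarity, which is what lets a correlation score work across
modalities when combined with selecting only high-variance (edge-rich)
blocks. A global transform is fitted to the surviving (center,
displacement) pairs by trimmed least squares: fit, discard the
`reject_fraction` of pairs with the largest residuals, refit, repeat until
the kept set stabilises. The rigid fit uses the SVD (Kabsch) solution with
a determinant correction; the affine fit uses ordinary least squares on
homogeneous coordinates.

Defaults (`BlockMatchConfig()`): 20-voxel blocks, 30-voxel search
neighbourhood, 3-voxel block overlap, 3 pyramid levels, up to 30
fit-transform-rematch cycles per level, the top 50% of blocks by variance
kept, 50% trimming. "Overlap of 3" is read as 3 voxels of overlap between
adjacent blocks (stride = block − 3). The rematch cycle stops early when
the incremental transform moves no bounding-box corner by more than 0.1
voxel. Subvoxel accuracy comes from the global fit averaging many
integer-shift matches, not from subvoxel search.

### Stage 2: free-form deformation

The FFD lattice has one displacement vector every `grid_spacing` voxels
(default 5), interpolated by the cubic B-spline basis. The optimizer
minimises

$$C = -(1 - w_1 - w_2)\,\mathrm{NMI} + w_1\,\mathrm{BE} + w_2\,\mathrm{JL},$$

with normalized mutual information
$\mathrm{NMI} = (H(I_1) + H(I_2)) / H(I_1, I_2)$ from a 256-bin hard-binned
joint histogram (inputs are expected on the 8-bit scale produced by
`window_to_byte()`), the bending energy BE (sum of squared second spatial
derivatives of the deformation, three pure plus twice the three mixed
terms), and the log-Jacobian penalty JL ($\sum |\log|\det J||$), which
penalises local compression and expansion symmetrically. The printed form
of this objective is typographically ambiguous about grouping; the reading
adopted here is the convex-style combination $(1-w_1-w_2)$ on the NMI term,
with NMI negated because the optimizer minimises.

Numerical conventions that the equations do not pin down:

* **Units.** BE and JL are computed in *voxel units of the evaluation
  grid* (displacements and derivatives per voxel index) and averaged over
  evaluation points (all voxel centers of the level grid). Averaging makes
  a single $(w_1, w_2)$ pair usable across pyramid levels; voxel units make
  the standalone operator oracles (`bending_energy()` of $u_1 = x_1^2$
  equals $4N$, JL of scale $s$ equals $3N|\log s|$) exact on an isotropic
  unit-spacing grid. With anisotropic spacing the voxel-unit BE weights
  axes unequally; this is documented rather than hidden.
* **Gradient.** The cost gradient with respect to each control-point
  component is a central finite difference (step `grad_eps = 0.4` voxels).
  Perturbing one control point only changes voxels in its 4-cell support,
  so the implementation updates the joint histogram, BE and JL sums locally
  instead of recomputing them; a test verifies this fast path agrees with
  naive full recomputation to machine precision. Hard-binned NMI is
  piecewise constant, so too small a step sees no bin crossings; 0.4 voxels
  reliably crosses bins on 8-bit data while staying well inside a lattice
  cell.
* **Line search and stopping.** Gradient descent uses the max-norm
  normalised direction with a backtracking (halving) line search. The
  initial trial step starts at 0.1 voxel and adapts: it doubles after an
  accepted step (capped at 2 voxels) and shrinks through backtracking. A
  fixed 0.1-voxel cap could not traverse multi-voxel displacements within
  the iteration budget. The stopping tolerance (default 0.001) is applied
  to the cost decrease over a 10-iteration window; per-iteration decreases
  are bounded by the step cap and would trigger far too early.
* **Multiscale.** Levels downsample volumes by 2 per axis after Gaussian
  smoothing ($\sigma = 1$ voxel). The lattice keeps `grid_spacing` *level*
  voxels between control points, so its physical resolution doubles on
  ascent; the coarse solution seeds the finer lattice by evaluating its
  displacement at the new control points (a quasi-interpolation — B-spline
  coefficients are not interpolating — which is adequate as an initial
  guess because optimization continues at the finer level).
* **Folding.** $|\det J| < 10^{-6}$ counts as folding. With $w_2 = 0$ and
  folding detected the optimizer aborts with a diagnostic; with an active
  JL weight (or `allow_folding = TRUE`, used by the weight grid search) the
  log is clamped and descent continues.

Defaults (`FFDConfig()`): $w_1 = 0.045$, $w_2 = 0.055$, grid 5 voxels, 3
levels, 500 iterations maximum, tolerance 0.001, 256 bins. Weights above
0.1 are accepted with a warning: they are known to degrade registrations
badly, and the pipeline validator flags them.

### 2D histology-to-blockface registration

Histology sections carry dense cellular texture with no counterpart in
blockface images, so similarity is computed on *edge* images after
iterative grayscale open/close filtering (disk radius 3 px, 2 rounds by
default) suppresses the cellular features. Edges are Sobel gradient
magnitudes (the operator is unspecified upstream; Sobel is chosen for
isotropy and ubiquity). A 4-parameter similarity (translation, rotation,
scale; rotation about the image center) is fitted by Nelder–Mead on the
edge NCC, with parameters scaled to pixels / degrees / scale×100 so simplex
steps are comparable; one restart from a perturbed initialisation guards
against a degenerate simplex. A 2D B-spline FFD then corrects residual
local distortion, maximising edge NCC with a bending-energy regulariser
(`w_be = 0.05` by default) over a 3-level pyramid (Gaussian smoothing
before each decimation). The NCC gradient uses the same local-update
finite-difference scheme as the 3D engine; the bending gradient is
analytic (the term is quadratic in the coefficients).

### CT-based freeze expansion

Hounsfield units are proportional to density for fixed composition, and
mass is conserved across freezing, so the local volume ratio is
$(1000 + \mathrm{CT}_{\text{before}}) / (1000 + \mathrm{CT}_{\text{after}})$.
`roi_volume_change()` evaluates this voxelwise over an ROI and reports
$100(\bar r - 1)$ with the population SD of the voxelwise ratios.
Nonphysical voxels (HU ≤ −1000) are excluded and counted rather than
failing the ROI. The HU-from-density relation is used only inside the CT
phantom generator; the analysis path consumes HU directly.

### Evaluation metrics

Volume difference $2\,| |A| - |B| | / (|A| + |B|)$ (a fraction; percent is
presentation), Dice, symmetric mean surface distance (boundary voxels =
foreground voxels with a six-connected background neighbour, distances
between voxel centers, directed means averaged both ways), and landmark
error (Euclidean distances of labeled pairs, mean and *population* SD).
The population-SD convention is used everywhere and recorded in report
metadata.

## The phantoms: what a green test establishes

No study data ships with the platform, so every fixture is generated by
seeded code with analytic ground truth (`make_phantom_pair()`,
`make_tumor_field()`, `make_histology_pair()`, `make_ct_freeze_pair()`).
The 3D pair places textured ellipsoidal organs and bright vessel-like
curves in an ellipsoidal body (block matching needs edge-rich content),
pushes the scene through a known affine + B-spline warp (the moving volume
is sampled through the numerically inverted truth transform, so pulling it
back through the truth reproduces the reference), remaps intensities
monotonically — optionally with contrast inversion inside one organ to
emulate modality differences — and adds Gaussian noise (sd 3 of 255 by
default). Truth warps are built from the same B-spline machinery the
registration uses, with peak amplitude kept below the truth-lattice spacing
so the map is invertible; this makes the recovery problem well-posed and
the truth representable, which is precisely what a recovery test needs —
and also its limitation: phantoms do not exercise deformations outside the
spline family, sliding organs, partial fields of view, or MR-specific
artifacts (bias fields, ghosting). A green recovery test shows the
machinery optimises its model correctly at the stated noise and contrast
conditions; it does not certify accuracy on real mouse data.

The 2D histology phantom adds sub-structure-scale speckle and a stain-like
gamma remap on top of a shared, edge-rich 2D anatomy. The lung-like option
of the 3D phantom adds a low-intensity organ whose local truth-warp
amplitude is doubled — the hardest region to register — used by the
weight-tuning harness. The CT phantom synthesises HU from per-organ volume
factors via mass conservation with HU noise sd 15.

The weight-tuning harness deserves a note on regime. Regularization
($w_1, w_2 > 0$) improves surface distance only when the data term is
genuinely ambiguous — low SNR, heavy deformation. On a benign phantom
(noise sd 6 of 255) whose truth warp is exactly spline-representable, the
*unregularized* fit wins: the penalties bias the solution away from a
large, recoverable warp. At noise sd 15 the documented ordering appears
(interior weights beat $(0,0)$; weights above 0.1 are clearly worse). The
weight-tuning phantom is therefore defined as that difficult regime
(lung-like organ, doubled local warp amplitude, noise sd 15). The effect is
not monotone in noise — at still higher noise the unregularized run can
again edge ahead on this generator — so the harness pins the regime and
seed, and this partial character is stated here rather than hidden.

Default phantom scale is 96×64×64 at 0.2 mm: seconds to generate, minutes
to register on one CPU. Tests run smaller instances of the same generators
(stated in each test) to keep the suite inside its time budget; sizes are
scaled down, thresholds are not.

## Known limitations

* Hard-binned NMI makes the cost piecewise constant; the finite-difference
  gradient relies on bin crossings and can stall on very low-contrast
  volumes. Parzen-windowed histograms would smooth this at some cost.
* The FFD optimizer is first-order gradient descent by design; it is
  robust but slow compared with quasi-Newton methods.
* Orientation metadata in NIfTI files is honoured only for axis-aligned
  geometries; oblique acquisition matrices are rejected rather than
  silently mangled.
* BE in voxel units weights axes unequally under anisotropic spacing (see
  above).
* Tumor "segmentation" is thresholded connected components — a stand-in
  for the platform's interactive segmentation, suitable for phantoms and
  for pre-thresholded fluorescence channels only.
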