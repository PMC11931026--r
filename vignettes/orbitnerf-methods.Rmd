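---
title: "Methods: ROI-constrained radiance fields for orbital plant capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI-constrained radiance fields for orbital plant capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`orbitnerf`, the assumptions behind them, the tunable parameters and their
defaults, the numerical choices made where the design was open, and what the
synthetic test scenes do and do not demonstrate about real captures.

## The acquisition model

The package assumes a "camera to plant" rig: the plant stands still at the
centre while one or two cameras orbit it on horizontal circular rails of
known radius `r_real` (meters). Two ring heights give top-down coverage; the
rig records `h1`, the lower camera's height above the ground, and `h2`, the
distance from the upper camera to the top of the bracket. These three
numbers form the `trajectory_prior()` and are the only calibration hardware
the pipeline needs beyond ordinary camera intrinsics (consumed from a
COLMAP-style text model or a config; intrinsic calibration itself is out of
scope, as is running structure-from-motion — poses are read from standard
model files or synthesized).

## Keyframe extraction

Videos are reduced to ~90 frames in three steps with the defaults fixed by
the acquisition design: equidistant downsampling to 50 frames per view
(indices `round(seq(0, n-1, length.out = 50)) + 1`, an endpoint-covering
maximal-gap progression), Laplacian-variance blur scoring, and seeded random
subselection to 45 per view. Sharpness is the variance of the response to
the 8-neighborhood Laplacian kernel `[[1,1,1],[1,-8,1],[1,1,1]]` on the
BT.601 grayscale image with replicate border padding; the grayscale weights
and border rule are our choices where the procedure only names the
neighborhood. A frame is rejected when its score falls below 20% of the mean
score of *all* frames (both views jointly, one pass — the threshold is not
re-estimated after removals); more than 10 rejections raise a quality
failure instructing re-acquisition, since that level of blur indicates a
failed capture rather than a few bad frames.

## Metric pose calibration

SfM poses live in an arbitrary similarity frame. Calibration proceeds in
three closed-form steps on the camera centres: (1) a total-least-squares
plane fit (smallest eigenvector of the centred covariance; the normal is
taken with non-negative z); the Rodrigues rotation `R_vtr` about
`n × (0,0,1)` maps the fitted normal onto z — the antiparallel case rotates
by π about x, any axis in the xy-plane being equally valid; (2) an algebraic
Kåsa circle fit in xy gives `r_virtual` and the scale `k = r_real /
r_virtual` (geometric refinement adds nothing at the noise levels of ring
captures — the suite verifies < 5 mm radius error at 1 mm isotropic noise);
(3) rings are split at the z-range midpoint, and recentering subtracts
`t_s = (x_c, y_c, (z_up + z_low)/2)`. One global rotation, scale and
translation are applied to every pose. The azimuth about z is unobservable
from the prior and left unfixed; since the plant is axially centred it
affects no measurement, and the tests compare azimuth-invariant quantities
(ring radii, heights, pairwise centre distances). Camera centres are
extracted as `−Rᵀt` for world-to-camera poses; a convention flag on every
pose removes the usual ambiguity.

The ROI box follows directly from the prior:
`[−r_real, r_real]` in x and y and `[z_low − h1, z_up + h2]` in z.

## The radiance field

The field maps position and view direction to density and color,
`F(x, d) → (σ, c)`, with:

* **Hash encoding** — L levels of feature grids, resolutions
  `N_l = floor(N_min · b^l)`, `b = exp((ln N_max − ln N_min)/(L−1))`;
  trilinear interpolation of F-dimensional entries, dense indexing when the
  corner grid fits the table and the spatial hash (coordinates times the
  primes 2654435761 and 805459861, xor, modulo T) otherwise. The full-scale
  default (`hash_grid_config()`) is L=16, T=2^19, F=2, 16→2048: the finest
  level divides the ROI into 2048 voxels per axis, which sharpens fine-scale
  geometry (2 mm branches at a 1.5 m box are ~3 voxels) without changing the
  encoding's output dimension L·F = 32.
* **Density net** — one hidden ReLU layer (64 units by default) producing a
  raw density (softplus for non-negativity) and a 15-dimensional geometric
  feature (ELU). The color net consumes a 16-dimensional geometric feature;
  we define the 16th component as the raw (pre-softplus) density value.
* **Color net** — two hidden ReLU layers (64 units) on the geometric
  feature concatenated with a frequency encoding of the view direction
  (`[d, sin(2^j π d), cos(2^j π d)]`, j = 0..3; 27 dims), terminal sigmoid.
* **Coarse stage** — a separate smaller field (own hash tables, L=8,
  N_max=512 at full scale; one hidden layer) whose weights
  `ω_i = T_i(1 − exp(−σ_i δ_i))` place the fine samples by
  inverse-transform sampling. We wrote the weight formula with the negative
  exponent of the standard emission-absorption model; without it the weights
  would be negative for positive optical depth. The coarse stage carries a
  small view-independent color head so it can be trained by the same
  photometric loss as the fine stage (the classic summed coarse + fine
  objective); distilling fine weights into it would be a proposal-network
  scheme, which is out of scope.

**Ray sampling.** Rays are intersected with the ROI box by the slab rule
(zero direction components handled as ±∞ slabs); on a hit, `t_min` is
clamped to 0 because the camera sits inside the box footprint during
capture. `round(roi_fraction · N_c)` stratified samples cover `(0, t_max]`
and the rest `(t_max, t_b]`; missing rays sample `(0, t_b]` entirely.
Defaults `N_c = 64`, `N_f = 128`, `roi_fraction = 0.75`, `t_b = 2×` the box
diagonal are ours (the procedure fixes none of them) and are config-exposed.
Background pixels keep their rays — no masks are used anywhere — and the
residual transmittance is composited onto a constant background color.

**Exposure and pose refinement.** Each training image owns an exposure rate
`E_i` (log2 units; the synthesized color is scaled by `S_i = 2^{E_i}` before
the loss, so renders at `E = 0` are canonical) and a pose offset
(`Δt`, axis-angle `Δθ`, applied as a left rotation). The objective is the
mean squared photometric error of the exposure-adjusted coarse and fine
renders plus `λ_E Σ E_i²` and `λ_p Σ(|Δt_i|² + |Δθ_i|²)`; λ = 1e-4, Adam
with learning rates 1e-2 (hash tables), 1e-3 (perceptrons and pose), 1e-2
(exposures) — all our choices, config-exposed.

**Gradients.** All gradients are analytic (hand-written reverse mode in the
compiled core), including through the trilinear interpolation to sample
positions and through the direction encoding, which is what pose offsets
need; the rotation Jacobian uses the Gallego–Yezzi closed form of
`∂exp([θ]ₓ)/∂θ`. Two stop-gradient conventions keep the estimator simple
and match what the finite-difference tests verify: sample t-values are
generated from the base (un-offset) poses and treated as constants, and the
coarse stage — a sampling guide — is evaluated at base poses, so pose
refinement flows only through the fine pass. The suite checks exposure and
pose gradients against central differences at 1e-4 relative tolerance on a
fixed ray batch chosen away from ReLU/interpolation kinks, where finite
differences are meaningful.

**Degenerate inputs.** All-zero coarse weights fall back to a uniform
sampling density (flagged); out-of-box positions clamp to the box faces with
zero positional gradient in the clamped component; a non-finite training
loss aborts with the iteration number.

## Mesh extraction and phenotypes

The trained density is sampled on a regular grid over the ROI box, zeroed
outside the box's inscribed cylinder (the region the orbit actually
observes; corners of the box are never seen from all sides), and
iso-contoured at `sigma_threshold`. The contouring is marching tetrahedra —
each voxel split into the six tetrahedra sharing its main diagonal, with
linear interpolation along edges and exact vertex sharing across cells. We
chose the tetrahedral variant of the marching-cubes family because it is
table-free and robust to the ambiguous cube cases; on the analytic-sphere
test it places the mean vertex radius well within one voxel of truth, and
the error shrinks monotonically with resolution. `sigma_threshold = 25` 1/m
is a default calibrated once on the synthetic scene (the boundary-demarcating
value is scene-dependent; users override per scene); grid resolution
defaults to 256 for production and 64–128 in tests. Plant height is the
mesh z-extent, `max(z) − min(z)`, in meters. Meshes export to OBJ and to
ASCII or binary little-endian PLY, with optional vertex colors queried from
the color net.

## Metrics

`PSNR = 10·log10(MAX²/MSE)` supports both peak conventions — `MAX = 1` for
float pipelines (the default everywhere internal) and 255 after 8-bit
export — reported explicitly, since the convention changes nothing at
matched quantization but must not be mixed. PSNR is computed over the full
frame; restricting it to a plant region would require a segmentation this
pipeline deliberately avoids. Phenotype accuracy uses MAE and
`R² = 1 − SS_res/SS_tot` (undefined, and an error, for zero-variance truth).

## The synthetic scene: what it shows and what it does not

`make_plant_field()` builds a piecewise-constant density field — a trunk
cylinder plus randomly placed and oriented leaf ellipsoids under a crown
whose apex sits exactly at `bound_height` — with distinct leaf colors, a
sinusoidal color modulation for leaf-scale texture, and density identically
zero outside a declared bounding cylinder. `render_ground_truth()` is a
fixed-step midpoint quadrature of the volume-rendering integral against
this field: an oracle renderer entirely independent of the trained model
(the suite checks it against the `1 − exp(−σL)` slab closed form and for
Cauchy convergence in the step count, and checks the package's own
compositing against it at matched sampling). `degrade()` fabricates uneven
exposure (multiplication by `2^e` with clipping) and Gaussian blur; the
Gaussian convolution is implemented in the compiled core with replicate
borders so the degradation exactly matches the border conventions of the
sharpness filter. Defaults for the study conditions are two rings of radius
0.75 m at heights 0.35/0.75 m, a 0.8 m plant, 64×64 frames, and a constant
background — chosen once as a desk-scale version of a sapling capture.

Passing on these scenes demonstrates the geometry, sampling, optimization
and measurement machinery end to end, under exactly known ground truth. It
does **not** demonstrate robustness to real-world nuisances the generator
omits: SfM pose noise and drift, rolling shutter, specular and translucent
leaves, wind motion between frames, textured backgrounds (a constant
background plus optional low-density clutter stands in), or real sensor
noise. The tolerances of the end-to-end tests (held-out PSNR ≥ 22 dB,
height within 2% at 40 views of 64×64 and 2000 iterations with an 8-level,
2^14-entry hash and 32-unit perceptrons) are scaled-down problem sizes
chosen for a single-core run, not claims about full-scale quality.

## Known limitations

* The Adam update touches every hash-table entry each step (dense moments);
  at the full 2^19-table configuration a sparse/lazy update would be the
  next optimization.
* Orientation of mesh faces is not globally consistent (the tetrahedral
  contouring emits triangles without a normal convention); height and
  radius measurements are unaffected.
* The background color is a config constant composited behind residual
  transmittance; scenes with strongly varying far background will push that
  appearance into peripheral density instead.
* Exposure rates are identifiable only up to a global offset (absorbed by
  the field's brightness); the recovery test therefore compares after
  centering. Beyond the offset there is a slower ambiguity: the
  view-conditioned color head can gradually absorb per-view brightness
  differences, and the L2 exposure prior biases `E` toward zero, pushing
  the explanation into the field. The exposure-recovery run therefore uses
  a weak exposure prior (`lambda_E = 1e-5`) and a faster exposure rate
  (3e-2) over a short schedule, so the exposure parameters win the
  explanation before the color head can; with the default prior and long
  schedules the correlation decays even though renders stay correct.
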