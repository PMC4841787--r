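---
title: "Methods: symmetric-template shape analysis of the third ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symmetric-template shape analysis of the third ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the model, the
parameters that matter, the numerical conventions, the design decisions
that were genuinely open, and what the synthetic validation does and does
not establish.

## Why a symmetric template with a midplane

The third ventricle is a thin (a few mm) midline cavity whose left and
right lateral walls face the thalami and hypothalami. Three properties of
the input data drive the design:

1. **Rough boundaries.** Segmentations from ~1 mm T1 images are noisy at
   the voxel scale; any analysis needs a smooth, consistent surface
   estimate rather than the raw mask boundary.
2. **Topological variation.** The inter-thalamic adhesion (IA), present in
   a subset of subjects, is a tissue bridge crossing the cavity: the mask
   acquires a through-hole. Meshes of different genus cannot be placed in
   vertex correspondence.
3. **Lateralised anatomy.** Atrophy of the surrounding structures is of
   interest per hemisphere, so left and right wall vertices must be
   distinguished consistently across subjects.

A genus-0 template with exact mirror symmetry about an explicit midplane
solves all three at once: every subject is a deformation of the same mesh
(dense correspondence), the IA region is represented as left and right
walls in contact at the plane (no topology change in the model), and the
vertex pairing across the plane makes left-right contrasts well defined.

## Template construction

`build_symmetric_shape()` aligns every subject's midsagittal plane (MSP)
to the standard plane x = 0, pools each aligned mask with its own mirror
image, averages signed distance fields (SDFs) on a common 0.7 mm isotropic
grid, and thresholds at zero. Averaging SDFs of plane-aligned binary masks
is a deliberate substitute for intensity-based diffeomorphic template
construction: with binary, thin-structure inputs the SDF mean preserves
the wall geometry well, requires no registration machinery, and is exactly
symmetric by construction (each subject enters together with its flip, and
the accumulated field is re-symmetrized against floating-point summation
order).

`build_template()` then shrink-wraps an **exactly mirror-symmetric sphere
scaffold** onto the mean mask using the package's own progressive Laplacian
deformation, re-imposing exact symmetry through the known vertex pairing
after every iteration. The scaffold is a UV sphere whose poles lie in the
midplane and whose meridian count is a multiple of four, so two whole
meridians lie exactly in the plane (midline vertices) and quad diagonals
can be mirrored strip-by-strip — the triangulated surface, not merely the
vertex set, is symmetric. This replaces the more conventional
marching-cubes + isotropic-remeshing + mirror-stitching route. The
trade-offs were weighed as follows: the shrink-wrap gives (i) an exact
vertex pairing and a machine-zero symmetry residual by construction, where
stitching two remeshed half-surfaces must reconcile boundary vertices;
(ii) guaranteed genus-0 topology, which is the model's assumption anyway;
and (iii) one code path — the same deformation machinery used for subjects
builds the template. Its cost is that vertex spacing is only approximately
uniform (latitude-uniform on the scaffold, redistributed by the Laplacian
during wrapping); for the statistics in this package, which are vertex-wise
and correspondence-based, that non-uniformity is benign.

Lateral walls are labelled by normal alignment: a vertex is "wall" when
its outward normal is within 45 degrees of the midplane normal (the
criterion is symmetric under the pairing). The threshold is a definition,
not an estimate; 45 degrees splits the surface into the two large
wall sheets and the rim, and the label only gates where the midplane
constraints may act.

Default template resolution is 2500 vertices (attained within ~1%,
e.g. 2522). At the third ventricle's ~1200 mm^2 surface this gives a mean
vertex spacing of ~0.7 mm, below the voxel size, so the mesh does not
limit the attainable accuracy.

## Subject fitting

**Rigid initialisation (3 DOF).** The template midplane is first mapped
onto the subject MSP exactly (minimal rotation, centre to centre). The
remaining freedom — rotation about the plane normal and in-plane
translation — is fixed in three sub-steps: a coarse deterministic scan of
the rotation angle (±15° in 2° steps, centroid-matched translation); an
iterative-closest-point refinement whose correspondences are projections
onto the *implicit* mask surface along the SDF gradient (sub-voxel, so the
angular optimum is not blurred by the voxel staircase); and a final
coordinate descent on the count of mismatching voxels between the
voxelized template and the mask (0.25° / 0.1 mm steps). The last step
exists because any distance-based objective flattens at the scale of the
boundary discretisation, while the voxel mismatch count remains sharp at
the true pose; on jittered-grid self-recovery trials the combination
recovers an injected (10°, 2 mm, −1 mm) pose to better than 0.5° and
0.1 mm. The restriction to 3 DOF keeps the model's centre of mass on the
MSP throughout.

**Progressive Laplacian deformation.** Each iteration recomputes vertex
normals, marches ±10 mm along them through the SDF to find the nearest
boundary crossing (linear interpolation between 0.25 mm samples gives the
sub-voxel target `b_i`; no crossing means no force), assembles the energy

E(V') = Σ ‖α_i (L(v_i') − L(v_i))‖² + Σ ‖b_i − v_i'‖²,

and solves its sparse normal equations (one Cholesky factorisation, three
right-hand sides; deterministic). `L` is the uniform-weight N-ring
Laplacian — uniform rather than cotangent weights because the operator is
defined via the neighbourhood centroid and the template mesh is
near-uniform. The reference Laplacians are those of the current iterate,
so the term penalises *incremental* distortion while the positional term
pulls the surface to the data. The stage schedule (N-ring 3 → 2 → 1, at
most 20/20/40 iterations, stopping when the mean displacement drops below
0.01 mm) realises the large-to-small-scale strategy: wide neighbourhoods
first move the surface coherently, narrow ones then capture local detail.

**Dynamic rigidity.** α_i falls linearly from `alpha_max` (1.0) at zero
force to `alpha_min` (0.15) at the search range, clamped to
[alpha_min, alpha_max]: vertices far from the boundary keep their local
geometry; vertices pulled hard are released so the force spreads to their
neighbours rather than spiking.

**Midplane constraints.** The *active* constraint fires for wall vertices
whose perpendicular gap to the plane contains no mask foreground (sampled
at 0.25 mm steps) and is narrower than twice the voxel diagonal
(2 × √(1² + 1² + 1.3²) ≈ 3.84 mm at the default voxel size): the target
becomes the foot point on the plane, and the rigidity is set to
`alpha_min` so the contact force dominates local shape preservation — with
the magnitude-based α the near-plane vertices would be maximally rigid and
never close the last fraction of a millimetre. The *passive* constraint,
applied after every solve and once at the end, projects any wall vertex
that crossed to the wrong side back onto the plane; it applies to wall
vertices only, since midline vertices live on the plane by definition and
rim vertices legitimately straddle it. On IA phantoms the active vertices
end within 0.1 mm of the plane and no wall vertex penetrates beyond
machine precision.

## Shape measures

Fitted meshes are normalised to the template by an isotropic rescale about
the midplane-projected centroid — the factor is
(ICV_subject / ICV_reference)^(1/3) when intracranial volumes are supplied,
else a user scalar — followed by the same 3-DOF Procrustes alignment
(closed form). The vertex-wise deformity is the displacement projected on
the template normal, **outward positive** (enlargement), matching the
convention that ventricular contraction carries a negative coefficient in
atrophy analyses.

Width maps sample the midplane on a 0.5 mm grid; the first in-plane axis
follows world y (anteroposterior). A line through each sample point along
the plane normal is intersected with the mesh (watertight ray-triangle
tests; coincident hits on shared edges deduplicated at 1e-9); the left and
right half-widths take the *farthest* crossing on each side, bounding the
lumen, and points missing a side are flagged invalid rather than erroring.
TVW and TVA follow their defining formulas; TVA is normalised by the
map-wide maximum width and therefore lies in [0, 1]. Because the
anterior/posterior measurement points are defined anatomically (thalamus
vs hypothalamus contact) rather than numerically, the regional widths
take the maximum TVW on each side of a configurable anteroposterior split
(default: the midpoint of the valid in-plane extent); both the maximum and
the mean TVA are exposed since either may serve as the scalar asymmetry
summary.

On the validation side, the relative volume difference is implemented as a
signed percentage (|A|−|B|)/|B|·100 and the volume overlap error as
(1 − |A∩B|/|A∪B|)·100; because "volume difference" is sometimes reported
in mm³, the absolute difference in mm³ is emitted alongside. Surface
distances against a mask are computed to its **voxel boundary mesh** (the
exposed voxel faces), point-to-triangle in both directions: boundary-voxel
*centres* sit half a voxel inside the surface and would floor the mean
distance at ~0.5 mm for purely conventional reasons.

## Statistics

`robust_fit()` wraps bisquare IRLS (tuning constant 4.685, MAD scale) —
the standard robust configuration for these analyses — with standard
errors from the robust covariance and two-sided t p-values on n − p
degrees of freedom; exact fits short-circuit to least squares where robust
weights are undefined. `vertexwise_regression()` maps a predictor's
coefficient over all template vertices and controls the false discovery
rate across vertices with Benjamini-Hochberg (a specific correction had to
be chosen; BH is the field default for vertex-wise maps). Gender/group is
coded 0/1 and age is centred when used as a covariate. Under a permuted
predictor the raw p-values are calibrated (fraction below 0.05 within
0.05 ± 0.02) and essentially no vertex survives FDR.

## The synthetic phantom generator

`make_phantom()` builds an analytic, thin, near-midline slab: left and
right walls at half-widths that taper to zero on an elliptical rim
(plateau profile 1 − ρ⁴), default footprint 25 × 20 mm and half-widths
~2.5 mm per side — third-ventricle scale — voxelized at 1.0 × 1.0 × 1.3 mm
by the voxel-centre rule. Boundary roughness is a band-limited Gaussian
field (white noise on a 3 mm lattice, bilinearly interpolated, amplitude
in mm as its standard deviation) added to each wall independently; 3 mm is
the shortest wavelength so that "smoothing out the roughness" is a
meaningful, testable behaviour distinct from sub-voxel noise. An IA is a
cylinder of given radius removed through the slab, producing a genuine
genus change (Euler characteristic 2 → 0). The generator returns the true
plane, analytic half-width maps on a 0.5 mm grid and the true volume, so
every downstream quantity has a ground truth.

`make_cohort()` draws phantom parameters from stated ranges (defaults:
per-side half-width 1.6-3.2 mm, left-right asymmetry ±0.8 mm, length
22-28 mm, height 16-20 mm, roughness 0.5 mm, the last half of the cohort
carrying a 2 mm IA), and generates covariates with known injected effects.

What the phantoms do **not** emulate: image intensities or segmentation
error structure beyond boundary roughness, the curved course and recesses
of the real ventricle, partial-volume behaviour at the IA, or
population-level covariance between shape and covariates. Passing the
synthetic suites therefore demonstrates that the machinery recovers known
geometry and effects under realistic scale, voxel anisotropy, roughness
and topology change — not that real-cohort effect sizes would be
reproduced.

### Study conditions used by the automated experiments

- **Reconstruction accuracy:** 20 phantoms (10 with IA), default ranges,
  roughness 0.5 mm, template at 2500 vertices; cohort means of Dice,
  symmetric mean distance and symmetric Hausdorff distance. Typical
  values ~0.98 / 0.21 mm / 1.3 mm.
- **Pose recovery:** 10 trials of an injected (10°, 2 mm, −1 mm) in-plane
  pose with sub-voxel grid offsets re-randomised per trial.
- **Effect recovery:** 24 phantoms, +1 mm total width injected into group
  1. The base width is dithered uniformly across one voxel and entered as
  a known design covariate: a fixed base width aliases the voxel-rounding
  bias (periodic in the wall position with a one-voxel period) directly
  into the group contrast, while free default ranges leave the contrast
  estimate dominated by between-subject width variance rather than by
  measurement error. Dithering plus adjustment isolates what the
  experiment is meant to test — the measurement pipeline's fidelity.
- Unit and property suites run on smaller objects (4-phantom cohort,
  1500-vertex template, 50-vertex solver oracles).

## Numerical conventions and edge cases

- World coordinates are RAS millimetres; voxel indices 0-based; affines
  NIfTI-convention. Masks resample nearest-neighbour, SDFs linearly.
- The SDF is the exact Euclidean distance transform (voxel centre to voxel
  centre), negative inside; under trilinear interpolation its zero level
  falls on the faces between inside and outside centres, which is the
  surface the fitter and the voxelizer agree on.
- Voxelization uses parity ray casting along +x with a fixed off-lattice
  jitter of the ray origins, so hits on shared triangle edges cannot
  double-count; the result matches the analytic centre-inside rule
  exactly on spheres.
- The MSP symmetry estimator scores a candidate plane by the mean squared
  SDF at the reflected surface points (voxel-face corners). Reflection
  Dice — reported as the QC score — plateaus over ~half a voxel of plane
  perturbation and cannot resolve tilt to a degree.
- Flip-invariance of the mean-shape builder holds up to nearest-neighbour
  rounding ties at resampling boundaries (a few voxels per mask), and the
  full fit of an exactly symmetric input is symmetric to ~0.05 mm (ICP
  tie-breaking, sparse-solve ordering); exactly symmetric *meshes* yield
  exactly mirror-consistent deformities.
- Degenerate inputs error early with a specific message: empty masks,
  planar/linear masks (MSP estimation), open meshes (voxelization, with
  the boundary edges named), rank-deficient designs (with the collinear
  columns named), zero-variance predictors.

## Known limitations

- The template is genus 0 by design; a cavity with multiple adhesions is
  still modelled as walls in contact, and the fitted surface inside a
  large adhesion is an extrapolation of the contact constraint.
- MSP estimation assumes approximate reflective symmetry of the mask; a
  strongly asymmetric ventricle biases the symmetry plane, which is why an
  externally supplied transform or an explicit per-subject override takes
  precedence, and the symmetry Dice is reported as QC without a pass
  threshold.
- Vertex spacing is approximately, not exactly, uniform (see template
  construction), so vertex-wise statistics weight the surface slightly
  unevenly; area weighting is used where an area fraction is the target.
- No self-intersection repair is performed during deformation; the
  progressive schedule and rigidity bounds make folds unlikely at the
  default settings but do not preclude them for extreme inputs.
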