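---
title: "Voxel-based finite element prediction of vertebral strength: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based finite element prediction of vertebral strength: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vertfe)
```

This vignette explains the models behind `vertfe`, the parameters that
matter, and the design decisions taken where the underlying methodology is
genuinely open. It states no empirical result beyond what the package's own
tests and `scripts/acceptance.R` compute.

## The pipeline

A labelled CT-like volume (label 1 = vertebral body, 2 = posterior
elements) passes through four stages: structured tetrahedral meshing,
HU-to-material mapping, displacement-controlled compression with
progressive element failure, and agreement statistics. Units form a
consistent mm–MPa–N system.

## Material mapping

The mapping chain is

ρ_app = 47 + 1.122·HU (mg/cm³), ρ_ash = 0.6·ρ_app (g/cm³),
E_z = −349 + 5.82·ρ_app (MPa), E_x = E_y = 0.333·E_z,
G_xy = 0.121·E_z, G_xz = G_yz = 0.157·E_z,
σ_max = 137·ρ_ash^1.88 below ρ_ash = 0.317, 114·ρ_ash^1.72 at and above,
σ_min = 65.1·ρ_ash^1.93, ε_AB = −0.00315 + 0.0728·ρ_ash.

Three bridging decisions were needed:

* **Units.** The relations are only dimensionally coherent with ρ_app in
  mg/cm³ (driving E_z) and ρ_ash in g/cm³ (driving the strength limits and
  ε_AB); the 0.317 branch point sits in g/cm³. The package fixes these
  units and converts internally.
* **Poisson ratios.** None are published alongside the moduli ratios. The
  defaults ν_xy = 0.381 and ν_xz = ν_yz = 0.104 are in the range used for
  transversely isotropic trabecular bone, and the resulting 6×6 tensor is
  verified symmetric positive definite for HU in [−200, 2000] (a sweep in
  the test suite). Were a non-positive-definite combination configured, the
  code falls back to isotropic ν = 0.3 with a warning.
* **Clamps.** The affine relations go negative for fat/marrow HU; apparent
  density is clamped at 1 mg/cm³, E_z at 0.01 MPa and ε_AB at 0, keeping
  every element solvable. The two σ_max branches differ by under 2% at the
  branch point; the boundary value is assigned to the upper branch.

Element HU is the mean over voxel centres inside the tetrahedron (falling
back to the centroid voxel for sub-voxel elements). By default `map_mesh()`
restricts the average to foreground voxels: a body-fitted mesher samples
bone only, and without the restriction the stair-step boundary cells of
the structured mesh blend in 0-HU background, which both weakens the
boundary artificially and couples the material field to the mesh
resolution.

## Meshing

The mask is block-coarsened to cubic cells of roughly the requested edge
length (cells are integer voxel blocks, so requested edges snap — 2.5 mm at
1 mm voxels becomes 2 mm). A cell is kept when at least half its voxels are
foreground (volume-unbiased on average), and each kept cell splits into the
six Kuhn tetrahedra sharing the cell's main diagonal, which makes faces
conforming across cells without any parity bookkeeping. Element labels
follow the majority of the cell's foreground voxels. No surface smoothing
is applied: comparisons within the package are relative, and determinism is
worth more than cosmetic geometry. Boundary node sets take the body-surface
nodes within a 2% band of the body's z-extremes; posterior-element nodes
are excluded so load is introduced through the body only.

## Compression and failure

The inferior body surface is fixed in all components; the superior surface
nodes are driven in z and held in x/y, mimicking platen loading (the
alternative — laterally free driven nodes — is not what a stiff platen
does). The prescribed compression defaults to 0.4% of body height over 20
equal increments. The strength relations imply compressive failure strains
around σ_min/E_z ≈ 0.15%, so 0.4% places the force peak mid-ramp where the
increments resolve it well; a much larger ramp would compress the entire
failure event into the first increment.

The published pipeline ran its failure analysis in a commercial solver
whose post-yield constitutive law is not described. `vertfe` uses an
explicit, deterministic brittle-damage rule: after each linear solve,
elements whose maximum principal stress exceeds σ_max or whose minimum
principal stress drops below −σ_min (strict inequalities, so ties never
fail) have all moduli multiplied by a knockdown factor (default 0.01), and
the increment is re-solved until no new failures occur or a damage
iteration cap (default 8) is reached; cap hits are recorded as warnings on
the result and simply defer the remaining failures to the next increment.
ε_AB is computed and exported, and can optionally act as an axial-strain
failure cap (`use_strain_cap`), but is off by default — with the brittle
rule the stress limits dominate. The failure load is the curve's peak; the
run stops once the force falls below a fraction (default 0.6) of the
running peak.

Implementation notes: between damage events the response is linear in the
prescribed displacement, so the solver factorises the constrained stiffness
(supernodal sparse Cholesky) only when damage actually occurs and rescales
solutions otherwise; congruent cells share one element stiffness per local
tetrahedron, assembled by vectorised scatter-add. Equilibrium (driven and
fixed reactions summing to zero within 1e−8 relative) is recorded at every
increment.

## Phantoms

The generator emulates what the analysis needs, not anatomy: an elliptical
cylinder (default half-axes 18 × 14 mm, height 28 mm — adult lumbar scale)
with a 1.5 mm cortical shell at 600 HU and a trabecular interior of
180 ± 50 HU, spatially correlated over 3 mm (white noise smoothed with a
Gaussian kernel and rescaled — the simplest stationary correlated field).
Posterior elements are two cylindrical pedicles, a lamina bar and a
rectangular spinous process attached to the posterior face: the load-path
topology matters for the posterior-element comparison, anatomical fidelity
does not. Contrast enhancement adds a smooth random HU offset
(default +30 ± 10 HU over 5 mm; the clinical literature does not pin the
bone-HU increase, so the mean is a free parameter) to labelled voxels.
Thick-slice reconstruction averages groups of slices (partial-volume
model), with masks resampled by majority vote, ties toward foreground, to
preserve the thin shell.

Cohorts are matched pairs: each subject draws anatomy and HU jitter around
the base spec, and the weakened member's trabecular and shell HU are scaled
so the apparent density falls by (1−d)^(1/1.88) — the reciprocal of the
strength–density exponent — targeting a failure-load decrement of
approximately d.

What the phantoms do *not* model: realistic vertebral shape (endplate
concavity, process geometry), scanner physics (beam hardening, noise
spectra), or fracture deformation. Passing tests therefore demonstrate the
pipeline's internal correctness and the directions of condition effects,
not patient-level accuracy; absolute failure loads depend on the phantom's
HU scale and are lower than typical patient values.

## Statistics

Bland–Altman differences are oriented condition-of-interest minus
reference, so a positive bias means the condition of interest reads higher.
The unpaired cohort test uses Welch's form (unequal variances are
plausible and pooling buys nothing); the paired test is also reported since
the cohort design is matched pairs. All p-values are two-tailed. RMSCV uses
per-subject sample standard deviations over repeated runs; because the
solver is deterministic, repeats differ only when the phantom noise is
reseeded, and with identical seeds the RMSCV is exactly zero.

## Problem sizes and numerical tolerances

The test suite and acceptance script run the default phantom at 2 mm cells
(~17k elements) for equilibrium, scaling and direction checks; the
mesh-refinement comparison descends to 1 mm (~133k elements); condition
grids and the 20-replicate cohort power study run at 3 mm cells with 10
increments — at a 15% strength decrement the paired signal is large, and
the coarse mesh keeps 360 simulations tractable on one CPU. Equilibrium and
patch-test residuals are held to 1e−8 relative; the strength-scaling
homogeneity check (doubling all stress limits and the displacement ramp
doubles the whole curve) holds to 1e−12 because it is an exact property of
the piecewise-linear algorithm.

## Known limitations

* Brittle element knockdown is a simplification of post-yield bone
  behaviour; softening plasticity would change absolute failure loads.
* Failure localisation makes the brittle model inherently somewhat
  mesh-sensitive; the refinement check quantifies this on the default
  phantom.
* The structured mesh cannot place elements smaller than a voxel, so
  thick-slice conditions are meshed at the coarser of the requested edge
  and the slice thickness.
* Stress averaging is per element with no partial-volume weighting at the
  bone boundary.
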