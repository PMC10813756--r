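---
title: "Simulating vertebral wedge compression fractures from CT-like volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating vertebral wedge compression fractures from CT-like volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertfem)
```

## The model

`vertfem` implements a quantitative-CT-based finite-element (QCT-FE)
pipeline for isolated vertebral bodies under axial compression.  The
target phenomenon is the anterior wedge compression fracture: the
anterior column of the vertebral body collapses while the posterior
column stays comparatively intact.  The pipeline runs from a
Hounsfield-unit (HU) voxel volume to a load--displacement curve,
stiffness/strength estimates, and a sector-resolved map of plastic
failure, with every stage testable against synthetic phantoms.

### Density calibration

Apparent density is a linear function of CT attenuation,

$$\rho = a + b \cdot \mathrm{HU}, \qquad \rho \ge \rho_{\min},$$

with defaults $a = 0.48$ g/cm$^3$, $b = 4.6\times 10^{-4}$ g/cm$^3$ per
HU and a floor $\rho_{\min} = 0.01$ g/cm$^3$ that prevents nonphysical
non-positive densities.  A note on the slope: the published constant
is printed as $4.6\times 10^{4}$, which would put cancellous bone at
$\sim 10^{7}$ g/cm$^3$; we read this as a sign-of-exponent typo and use
$10^{-4}$ scale, keeping both constants overridable
(`calibration_line()`) and announcing the assumption in
`default_calibration()` rather than hiding it.  The floor is applied
*after* the linear map, which is the only ordering that guarantees the
stated minimum.  `fit_calibration()` recovers $(a, b)$ from
core-sample $(\mathrm{HU}, \rho)$ pairs by unweighted ordinary least
squares; nothing in the model justifies a weighted fit.

### Material laws

Each element receives isotropic elastic--perfectly-plastic properties
from power laws of apparent density ($\rho$ in g/cm$^3$, $E$ in MPa):

$$E = 3050\,\rho^{1.81}, \qquad
  \varepsilon_y = s \cdot 0.0065\,\rho^{-1.42}, \qquad \nu = 0.3,$$

with yield stress $\sigma_y = E\,\varepsilon_y$ and no hardening
(`material_law()`).  The factor $s$ (`yield_scale`, default 1) is a
dimensionless calibration knob on the yield strain; calibrating
predicted strengths against the compression experiments of porcine
thoracolumbar bodies that this package emulates yields $s = 3.1$, and
`calibrate_yield_scale()` reproduces that calibration procedure on
synthetic data.  Because
$p_E + p_y = 0.39 > 0$, $\sigma_y$ increases with density even though
the yield strain decreases.

Two unit conventions are deliberate choices.  The laws are applied to
apparent density directly (`ash_ratio = 1`), which keeps the printed
anchor value $E(1.0) = 3050$ MPa reproducible; the apparent/ash
conversion factor 0.6 is exposed as an option because the source
mentions the ratio without stating where it enters, and its printed
direction ($\rho_{app}/\rho_{ash} = 0.6$, implying ash *denser* than
apparent) inverts the usual convention -- we take no side and activate
neither direction by default.  Densities are g/cm$^3$ and moduli MPa,
the conventional units for such power laws; with mm-scale meshes this
makes forces come out in N.

`assign_materials()` supports both continuous per-element cards and the
conventional binned assignment (uniform-width density bins, card
evaluated at the bin-mean density).

### Meshing and anatomical frame

Masked voxels are subdivided into six tetrahedra each by the
uniform-orientation Kuhn (Freudenthal) decomposition
(`voxels_to_tets()`).  Every voxel is cut identically, so shared quad
faces are split along the same diagonal on both sides and the mesh is
conforming by construction; the test suite checks that every interior
face is shared by exactly two tetrahedra and that the tetrahedra
partition the masked volume exactly.  Edge lengths track the voxel
size, so $\sim$1 mm voxels reproduce the $\sim$1 mm T4 edges typical of
QCT-FE vertebral models.  The cost is a stair-stepped surface; no
smoothing is applied, and the refinement tests quantify the effect
instead of hiding it.  Each tetrahedron inherits its parent voxel's
calibrated density -- the degenerate (and exact) case of averaging the
voxel centres inside the element, since every tetrahedron lies within
one voxel.

The anatomical frame (`build_frame()`) mirrors the usual construction:
the transverse-plane normal averages the best-fit plane normals of the
cranial and caudal surfaces; the centre of mass is density-weighted;
the anterior direction is the anteroposterior axis projected into the
transverse plane; the sagittal plane contains the axial and anterior
directions through the centre of mass.  "Body width" is read as the
anteroposterior extent of the node cloud: the control point is
displaced *anteriorly* to provoke the anterior wedge pattern, so the
natural length scale for that offset is the anteroposterior dimension.
The mediolateral alternative can be obtained by passing a modified
frame, but it is not the default.

### Boundary conditions and solver

Loading is displacement-controlled through a control point placed on
the cranial (upper-plate) plane, offset anteriorly by 10% of the body
width from the projected centre of mass (`place_control_point()`) --
the follower-load construction.  The control point is rigidly coupled
to every cranial surface node (the multi-point-constraint equivalent),
its transverse translations are locked, its three rotations are free,
and the caudal surface is fully fixed.  The coupling is implemented by
master--slave elimination with linearised rotations: cranial node
displacements are expressed as control-point translation plus rotation
crossed with the lever arm, and the reduced system contains only free
nodal DOFs plus the three rotations.  No rotation cap is imposed.

The uniaxial stress law generalises to associative J2 (von Mises)
perfect plasticity with radial return -- the standard realisation of
"perfectly plastic" in production FE codes; uniaxial stress states
reproduce the uniaxial law identically, which the bar oracles exploit.
Kinematics are small-strain and geometrically linear: "nonlinear
analysis" is read as material nonlinearity only, a documented
limitation (no buckling, no large rotations beyond the linearised
coupling).

Each increment applies an equal share of the total prescribed
compression (default: one third of the axial height, the conventional
failure displacement for these tests, over 40 increments) and is
equilibrated by Newton iteration with consistent tangents:

* a displacement-control *predictor* computes the first correction from
  the tangent at the last committed state, avoiding the spurious
  plastification that evaluating the tangent at the naively-displaced
  state would cause in the element layer adjacent to the loaded
  surface;
* subsequent corrections use the consistent tangent at the current
  iterate with a backtracking line search on the residual norm;
* convergence requires the reduced residual to fall below $10^{-6}$
  of the incremental force scale (absolute fallback $10^{-8}$ N), with
  at most 25 iterations per increment;
* a non-converged increment is bisected (up to four levels) before the
  solve is abandoned with an explicit failure flag and the partial
  record retained.

The linearised systems are solved by sparse Cholesky factorisation.
At the plastic limit load the consistent tangent of a
perfectly-plastic model is only positive *semi*-definite; when the
factorisation fails, a small diagonal shift ($10^{-8}$ to $10^{-2}$ of
the mean diagonal) restores definiteness.  The shifted matrix serves
purely as the iteration operator -- equilibrium is judged on the
residual -- so converged results are unaffected.

### Post-processing and comparison statistics

Stiffness is the OLS slope over ascending-branch points whose load lies
in 20--80% of the peak (`extract_stiffness()`); stiffness is defined
only as the slope of the curve's linear trajectory, so the window
is a design choice, recorded with every result and configurable.
Strength is the curve maximum (`extract_strength()`); for a perfectly
plastic model the global maximum and the "highest point of elastic
response" coincide at the plateau onset, so the distinction is moot
here and the global maximum is used.  Experimental CSV curves pass
through the same extractors -- one code path for both sources.

`fracture_map()` flags elements with final equivalent plastic strain
(PEEQ) above a threshold (default $10^{-8}$, absorbing round-off;
threshold 0 reproduces the literal nonzero-plastic-strain rule) and
bins element centroids into anterior / posterior / lateral-left /
lateral-right sectors with a 45-degree half-angle about the anterior
axis.  The sector half-angle is a design choice; the
anterior/posterolateral failure pattern it resolves is described only
qualitatively in the experiments this package emulates.

Model-versus-experiment statistics use absolute percent errors and the
squared Pearson correlation as the coefficient of determination (for a
simple linear fit this equals regression $R^2$).
`calibrate_yield_scale()` minimises the mean absolute *strength*
percent error by bounded scalar minimisation, warm-started at
`mean(experimental / predicted-at-scale-1)`: for a perfectly plastic
model the limit load is (near-)exactly linear in the scale, so the warm
start lands next to the optimum and the refinement bracket can be
narrow.  Stiffness is reported but never optimised -- in the original
calibration of this kind the stiffness error *worsened* when the
strength was calibrated, and the package mirrors that asymmetry.

## The synthetic phantoms

No CT volumes or test-machine curves are distributed with the problem
this package addresses, so the `phantom` module generates everything
the pipeline consumes:

* `make_vertebra_phantom()` -- an elliptical cylinder with a
  cosine-modulated concave waist, a bright cortical shell
  (`hu_cortical`, default 1200 HU) of configurable thickness, and a
  smoothed, seeded Gaussian trabecular HU field (default
  $350 \pm 60$ HU) standardised to its requested mean and SD.  The
  defaults (height 22 mm, anteroposterior semi-axis 14 mm, mediolateral
  18 mm) are in the range of adolescent porcine lower-thoracic bodies.
  No quantitative HU statistics exist for the source specimens, so the
  HU defaults are plausible-but-invented and labelled synthetic; the
  trabecular field is smoothed over a 3-voxel kernel so per-element
  densities are well-posed under mesh refinement.  Air is $-1000$ HU
  and excluded by the mask before calibration, so the density floor is
  exercised in tests by deliberately low in-mask HU, not by air.
* `make_bar_phantom()` -- a uniform rectangular prism whose stiffness
  ($EA/L$) and plastic limit load ($\sigma_y A$) are closed-form; the
  solver is verified against both to $10^{-8}$ relative and 0.5%.
* `make_synthetic_experiment()` -- per-specimen bilinear
  load--displacement curves with stiffness and strength drawn from
  normals truncated at zero.  The default means and SDs
  ($9.54 \pm 1.1$ kN/mm, $10.2 \pm 0.86$ kN) reproduce the dispersion
  of the physical compression experiments this package emulates; they
  are distributional targets, not per-specimen reproductions.

What the phantoms deliberately do *not* emulate: posterior elements and
pedicles (the emulated protocol removes them), endplate curvature
(flat-ended phantoms stand in for the polished, plate-cut specimens),
scanner physics (no beam hardening, no acquisition noise), and the
cortical/trabecular microarchitecture.  Tests passing on phantoms
therefore validate the *pipeline mechanics* -- calibration, meshing,
constitutive update, equilibrium, extraction -- not the biofidelity of
any particular vertebra.

The phantom coordinate convention, used everywhere: axis 1
mediolateral, axis 2 anteroposterior (anterior positive), axis 3 axial
(cranial positive); voxel centres at `origin + (index - 0.5) * spacing`.

## Numerical choices

* Node identity comes from the global voxel-corner grid, so no
  tolerance-based deduplication is needed; coordinates are exact.
* Tetrahedron orientation is fixed positive; an inverted element aborts
  assembly with the element index in the message.
* Voigt storage is engineering-shear ($\gamma = 2\varepsilon$) for
  strain-like quantities, including the stored plastic strain, so
  $\sigma = D(\varepsilon - \varepsilon_p)$ holds componentwise.
* The radial-return consistent tangent is
  $\kappa\,\mathbf{1}\otimes\mathbf{1}
   + 2\mu\beta\,(I_{dev} - \hat n \otimes \hat n)$ with
  $\beta = \sigma_y / q_{trial}$ -- symmetric, verified against finite
  differences in development and against an independent dense assembly
  in the tests.
* Determinism: every random draw is governed by an explicit seed
  through an RNG-state-preserving wrapper; identical configuration plus
  seed gives bit-identical phantom volumes and hash-identical pipeline
  manifests.
* Degenerate inputs error early: voxel size exceeding a phantom
  semi-axis, empty masks, all-identical calibration HU, non-positive
  densities, fewer than three stiffness-window points, zero body width.

## Problem sizes used by the shipped tests

The test and verification suites run on deliberately coarse problems
chosen to exercise every code path at desk scale: verification bars of
160--1280 voxels at 1 and 0.5 mm; vertebra phantoms at 2--2.5 mm voxels
($\sim$1000 voxels, $\sim$6400 tetrahedra); 12--40 displacement
increments.  The yield-scale recovery study uses three phantoms at 2 mm
voxels with 2% multiplicative strength noise and recovers the
generating factor 3.1 to well within 5%.  Production-scale runs
($\sim$1 mm voxels, $\sim$200k elements) use the same code path --
assembly is compiled and the factorisation sparse -- but are not part
of the routine test run.

## Known limitations

* Small-strain kinematics; no geometric nonlinearity, contact, or
  element erosion.  Failure is read from the PEEQ field, not from crack
  geometry.
* Isotropic materials; no anisotropy, strain-rate dependence, damage or
  softening.
* Stair-stepped phantom surfaces bias surface stresses locally; the
  refinement tests bound, but do not remove, the effect.
* The synthetic-experiment generator emulates summary dispersion only;
  per-specimen agreement with any physical dataset is out of scope, and
  the package makes no claim about reproducing specimen-level results
  without the original volumes and curves.
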