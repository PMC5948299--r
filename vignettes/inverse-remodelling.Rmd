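---
title: "Inverse-remodelling joint load prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse-remodelling joint load prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(femload)
```

## The model

Bone adapts its architecture to its mechanical environment: tissue is
added where the local mechanical stimulus exceeds a remodelling
equilibrium level and resorbed where it falls short.  Run backwards,
this gives a way to estimate the loading history of a bone from its
architecture alone: the most probable loading is the one that brings the
observed structure closest to remodelling equilibrium everywhere.

`femload` implements this inverse problem for hip joint loading.  The
loading history is represented by $n$ unit load cases — distributed
contact loads on the femoral head with resultants of 1000 N inclined at
fixed angles in the frontal plane — each assumed to act with magnitude
$\alpha_i$ for a share $m_i/m_\mathrm{tot}$ of the load cycles.  With
per-element strain energy density (SED) fields $U_i(\mathbf{x})$ from
linear elastic voxel finite-element solves, the combined tissue stimulus
is

$$U(\mathbf{x}) = \sum_{i=1}^{n} \frac{m_i}{m_\mathrm{tot}}
  \,\alpha_i^2\, U_i(\mathbf{x})
  = \sum_{i=1}^{n} s_i\, U_i(\mathbf{x}),$$

where $s_i = \alpha_i^2\, m_i/m_\mathrm{tot}$ absorbs magnitude and
cycle share (SED is quadratic in load).  The optimal combination
minimizes the squared distance to the equilibrium stimulus
$\tilde U$ over all bone elements $\mathbf{x} \in \mathcal{X}$:

$$\min_{s \ge 0}\; \sum_{\mathbf{x} \in \mathcal{X}}
  \Bigl[\tilde U - \sum_i s_i U_i(\mathbf{x})\Bigr]^2,$$

a non-negative least-squares (NNLS) problem.  Assuming equal cycle
counts for all cases ($m_i/m_\mathrm{tot} = 1/n$), magnitudes follow as
$\alpha_i = \sqrt{n\, s_i}$, and joint load vectors as
$\alpha_i \mathbf{F}_i$.  The quality of the fit is summarized by the
coefficient of variation (CoV) of $U(\mathbf{x})$ before (uniform
$s_i$) and after optimization.

Two consequences of this structure are used for validation throughout
the package: the objective is linear in $\tilde U$, so magnitudes scale
as $\sqrt{\tilde U}$ with directions unchanged; and scaling all elastic
moduli by $k$ scales every SED by $1/k$ and hence all magnitudes by
$\sqrt{k}$, again leaving directions unchanged.

## Pipeline parameters

| parameter | default | units | role |
|---|---|---|---|
| Gaussian filter | support 2 voxels, $\sigma$ 1.6 voxels | – | noise suppression before segmentation |
| segmentation threshold | 3000 | grey value | fixed global bone threshold, *inclusive* (value $\ge$ threshold is bone) |
| resampling | factor 2, block mean | – | grey-level downsampling before thresholding |
| crop box | 1.5 $\times$ head radius | – | lateral/distal extent below the head centre |
| cartilage layer | 2.2 mm | mm | soft spherical cap transmitting the contact load |
| unit loads | 4 at $-20°, 20°, 60°, 100°$ | degrees | frontal-plane inclinations from the vertical axis |
| load patch | cone opening 40° (full apex angle) | degrees | sphere $\cap$ cone contact patch |
| nodal distribution | uniform pressure, surface normal | – | alternatives: uniform parallel, Hertz-type ellipsoidal |
| resultant | 1000 N | N | per unit load case |
| bone / cartilage modulus | 10 000 / 10 MPa | MPa | linear elastic, isotropic, $\nu = 0.3$ |
| equilibrium stimulus $\tilde U$ | 0.02 | MPa | remodelling set point |
| ROI reduction | 0 | mm | pull-back from lateral/distal boundaries |

Units are mm–N–MPa throughout.  The inclination sign convention is
positive from the vertical axis towards medial within the frontal
plane; reported joint load vectors use the outward (+d) convention
while nodal forces push into the head.  The "opening angle 40°" is read
as the full apex angle (half-angle 20°): on a femoral head of radius
24.3 mm this yields the 224 mm² patch area consistent with full-scale
models, via the closed form $2\pi R^2(1-\cos 20°)$.

## The voxel FE solver

One trilinear hexahedral element per labelled voxel; all elements share
a cached unit-modulus reference stiffness matrix scaled per element by
its modulus.  The solver is a matrix-free Jacobi-preconditioned
conjugate gradient (default relative residual $10^{-6}$); the operator
product gathers element displacements into a $24 \times n_e$ matrix and
applies the reference stiffness with one BLAS multiply.  Per-element
SED is recovered in the energy-consistent form
$U_e = \tfrac12 u_e^\top K_e u_e / V_e$, which makes the global work
balance $\tfrac12 f^\top u = \sum_e U_e V_e$ hold to solver tolerance —
a centroid strain recovery would not satisfy it on non-uniform fields.
Elements couple through shared nodes, so floating-component removal
uses 26-connectivity; background flood fills (outer-surface detection,
cartilage capping) use 6-connectivity, against which a voxelized
surface is watertight.

Constraint handling is by projection (homogeneous Dirichlet on the
lateral and distal crop faces).  Nodal loads on the cartilage surface
carry *projected* tributary face areas — raw staircase areas
over-weight oblique surface bands by up to $\sqrt 3$ and bias the
resultant of a symmetric cap by about 1°; projected areas keep it
within 0.15°.

## The synthetic specimen generator

No raw scan or telemetry data ship with the package; every input is
generated.  The mini joint is a desk-scale femur stand-in: a spherical
head (radius $0.2 L$ for domain extent $L$), an inclined cylindrical
neck narrower than the head (radius $0.1 L$, direction
$(-0.6, 0, -0.8)$, giving the interior cross-section minimum the frame
construction needs), and a distal support block whose bottom is fully
constrained.  Geometry is evaluated analytically at voxel centres, so
rotated specimens are exact, not resampled.  The default domain is
$48^3$ voxels at 0.5 mm.

Structures adapted to a known load history are grown by forward
remodelling with an intermediate-density rule: element modulus
$E = E_0 \rho^p$ (default $p = 3$), stimulus $S = U/\rho$, update
$\rho \leftarrow \mathrm{clip}(\rho + \lambda (S - S^\ast)/S^\ast,
\rho_\mathrm{min}, 1)$ with gain $\lambda = 0.1$, floor
$\rho_\mathrm{min} = 0.1$ and target $S^\ast = 0.02$ MPa, from a seeded
noisy mid-density start.  Three design elements beyond the bare rule
proved necessary for the generator to reach its goal (a *binary*
structure near remodelling equilibrium):

1. **Sensor-influence smoothing.**  The stimulus is smoothed with a
   Gaussian kernel (SD 1 voxel) before the update.  With purely local
   sensing, struts saturate far above the target: a floor-density
   neighbour senses only $(\rho_\mathrm{min}/1)^2 \approx 1\%$ of the
   strut stimulus and is never recruited, so overloaded struts cannot
   shed load sideways.
2. **Cortical shell.**  The one-voxel surface of the envelope is held
   at full density, standing in for the subchondral and cortical shell
   of a real bone.  Sphere fitting, cartilage capping and the neck
   cross-section search are ill-posed on strut-only structures.
3. **Binary surface polish.**  After thresholding the converged density
   field at $\rho \ge 0.5$, a surface-remodelling phase runs on the
   full-modulus binary structure: vacant envelope neighbours sensing
   more than $1.3\,S^\ast$ are deposited, surface elements sensing less
   than $0.7\,S^\ast$ are resorbed.  The intermediate-density
   equilibrium does not survive binarization unchanged; the polish
   restores equilibrium in the state the inverse algorithm actually
   sees.

The generating magnitude is calibrated, not fixed in newtons: the mini
joint is roughly an order of magnitude smaller than a femur, so
physiologic forces would saturate the density field.
`calibrate_load_magnitude()` performs one probe solve at uniform
mid-density and returns the magnitude that pins the *upper-decile* core
stimulus to the target — the upper decile because the neck bottleneck
and the contact zone, not the median tissue, limit what the structure
can carry at equilibrium.

Grayscale rendering uses two grey levels (6000 bone, 1000 background),
optional Gaussian blur as a partial-volume surrogate and seeded
Gaussian noise.  At the coarse synthetic voxel size the forward/inverse
harness renders with a mild blur (SD 0.35 voxels) and segments without
additional smoothing: the default filter scale (σ 1.6 voxels) is
appropriate for fine CT voxels but erases one-voxel struts here, and at
a grey-level contrast of 5000 with noise SD 150 the threshold sits 13
noise SDs from both levels.

Load traces emulate instrumented-prosthesis recordings: half-sine force
magnitude profiles per activity cycle with a fixed per-activity
direction in the implant frame, optional Gaussian jitter on the peak
magnitude only.  The default activity set peaks at 2700 N near 18° for
level walking and spans frontal-plane inclinations 3.7°–66.6°, the
published in vivo range, which is the emulation target rather than a
measured output.

## What the synthetic data do and do not show

The generator produces structures for which the inverse problem is
well-posed by construction and at a scale far below real micro-FE
models (thousands, not hundreds of millions, of degrees of freedom).
Passing the forward/inverse tests therefore demonstrates the internal
consistency of the implementation — segmentation, frame construction,
load application, FE solve and NNLS inversion composed correctly — not
the biological validity of load predictions on real femora.  Real
trabecular architecture carries non-mechanical influences (genetics,
calcium homeostasis, hormones), partial-volume and beam-hardening
effects, and much finer struts relative to the voxel size; none of
these are emulated beyond Gaussian blur and noise.

Known desk-scale limitations: on a head of ~9 voxel radius all load
paths funnel through the same neck, so only the dominant direction
(near 20°) is reliably recoverable — single-case histories at extreme
inclinations ($-20°$, $100°$) drift towards the neck-aligned cases.
The forward/inverse consistency experiments therefore use the dominant
20° case, matching the direction the method actually reports on real
data.

## Numerical choices

* PCG tolerances: $10^{-5}$ for unit-load solves feeding the inversion,
  $3\times10^{-4}$ with warm starts inside remodelling iterations
  (density changes dominate residual error there).
* Threshold rule is inclusive ($\ge$), fixing the block-mean
  checkerboard edge case deterministically.
* Gaussian "support 2" is the truncation radius in voxels at the given
  σ; boundary handling is replicate by default, periodic available
  (and mean-conserving).
* Peak-vector ties break to the lowest load-case index; zero-alpha
  solutions flag the peak as undefined.
* The NNLS solver is the Lawson–Hanson active set
  (`pracma::lsqnonneg`), deterministic; tiny negative round-off in the
  returned coefficients is clamped at zero.
* CoV uses the population SD (divisor $n$); group summaries in the
  comparison reports use the sample SD (divisor $n-1$), which
  reproduces the published summary rows of the packaged per-specimen
  table.
* The Wilcoxon signed-rank test reports the exact two-sided p by
  default ($n \le 25$, no ties), with the normal approximation behind a
  flag; on the packaged CoV pairs the exact p is $2/2^{10} \approx
  0.00195$.
* Sensitivity load-area variations are specified as areas of the
  full-scale reference (215.1 / 121.5 / 54.2 mm²) and realized as area
  *ratios* converted to the cone half-angle that yields the target area
  on the fitted head sphere, so the same design applies to any head
  radius.  Length-type parameters (ROI reductions, shaft section) scale
  with `length_scale` for desk-scale domains.

## Problem sizes used by the shipped experiments

The test-suite experiments run at $48^3$ voxels (forward/inverse
consistency, 20 seeds), $36^3$ (sensitivity design, full 19-run
layout at `length_scale = 0.15`), and $32^3$ or below for solver
verification — sizes chosen so the whole suite completes on a single
CPU in minutes while every stage of the pipeline still has several
voxels of resolution across its smallest feature.

## Known limitations

Beyond the desk-scale items above: overlapping load patches make the
NNLS design rank-deficient (the solution is flagged, not repaired);
spatially varying equilibrium stimuli and per-case cycle counts are out
of scope; the cartilage layer is a numerical load-transmission device,
not a contact model — bone-to-bone or horseshoe-shaped pressure
distributions are not represented.
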