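---
title: "EF-based TMS motor mapping on synthetic heads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EF-based TMS motor mapping on synthetic heads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tmsmap` implements EF-informed motor mapping: it computes the electric
field (EF) that a figure-8 TMS coil induces in a volume-conductor head
model, and localizes the cortical representation of a muscle by combining
the EF maps of the stimuli that evoked the largest motor-evoked potentials
(MEPs). Because the package ships its own synthetic-data generator, every
stage can be validated against planted ground truth. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic setting does and does not demonstrate.

## The volume-conductor model

At TMS frequencies (~kHz) displacement currents are negligible and the
external magnetic field is not perturbed by tissue currents
(magneto-quasi-static approximation). The induced scalar potential solves

$$\nabla\cdot\sigma\nabla\varphi \;=\; -\nabla\cdot\sigma\,
\partial_t\mathbf{A}_0,$$

with insulating boundary ($\sigma = 0$ outside the head; the voxel grid
always contains an air shell), and the field is
$\mathbf{E} = -\nabla\varphi - \partial_t\mathbf{A}$.

**Discretization.** One unknown per conducting voxel; fluxes on voxel faces
with harmonic averaging of the two adjacent conductivities — the
flux-conserving choice for piecewise-constant $\sigma$, equivalent to a
7-point stencil. Faces toward background carry zero flux, so the insulating
boundary is exact and the right-hand side (the discrete divergence of
$\sigma\,\partial_t\mathbf{A}_0$) sums to zero: the singular pure-Neumann
system is compatible by construction. The tests compare this operator
against a dense direct solve on small grids (agreement at machine
precision) and against analytic null cases (a uniform $\partial_t\mathbf A$
in a homogeneous conductor induces no field; the discrete solution
reproduces this to ~1e-11 because the exact potential is affine).

**Solver.** Jacobi-preconditioned conjugate gradient, relative residual
tolerance 1e-6 (configurable). The potential is reported in the zero-mean
gauge over conducting nodes. On the default phantom (~270k unknowns) a
solve takes a few seconds; typical iteration counts are 300–500 with the
skull/CSF contrast of ~165.

**Gradient reconstruction.** Central differences where both axis neighbors
conduct, one-sided at boundaries. $\partial_t\mathbf{A}_0$ is evaluated at
voxel centers and averaged onto faces for the right-hand side.

**Conductivities** (S/m, configurable): skin 0.465, skull 0.010, CSF 1.654,
gray 0.275, white 0.126 — standard literature values. Relative EF maps are
insensitive to the exact assignment; the layered-sphere test quantifies
this (field change <5% between a homogeneous and a 3-layer sphere of equal
outer radius).

## The coil model

The figure-8 coil is a thin-wire idealization: two coplanar wings of nine
concentric circular loops each (diameters 55–92 mm), wings tangent at the
coil center with opposite winding sense so the currents run in the same
direction under the center. $\partial_t\mathbf{A}_0$ follows from the
Biot–Savart integral with midpoint quadrature over 72 straight segments per
loop (changing to 144 segments moves the field by <0.1%; the numerically
curled potential matches the closed-form on-axis loop field to <0.1% at 128
segments). The coil current derivative is 174 A/µs at 100% stimulator
output and scales linearly with %MSO, so each placement is solved once at
100% and rescaled exactly.

Geometry not fixed by the coil's published dimensions was decided once: the
wing centers sit at ± the outer loop radius along the handle axis (tangent
wings), all loops of a wing are coplanar and concentric, and the coil plane
is tangent to the scalp at the placement point (configurable standoff,
default 0).

## The synthetic head and its protocol

The phantom is a compact spherical head (skin radius 40 mm, scalp-to-cortex
≈ 12.5 mm — the adult scalp–cortex distance on a desk-scale budget) with
five nested layers and a single sulcus-like fold: both cortical boundaries
are depressed by a half-period cosine groove (default amplitude 7 mm,
wavelength 12 mm, length 32 mm) running along y across the vertex, with the
groove filled by CSF. This is the minimal geometry that distinguishes gyral
crown, lip, sulcal wall and fundus — the regions the two EF metrics are
known to weight differently — and the generator paints those region labels
onto the surface for use in tests.

Two ground-truth "muscle" sites are planted on the fold lip, separated by
~3 mm along the fold (FDI-analog lateral, ADM-analog medial), mirroring the
neighboring hand-muscle representations the method is meant to resolve. A
per-subject seed jitters the fold amplitude (±5%) and the site separation
(±0.3 mm) so cohorts are not degenerate; the same spec + seed is bit-for-bit
reproducible.

The stimulation protocol generator reproduces the sulcus-aligned grid:
8 anchors at 5 mm arc spacing along the scalp projection of the fold, each
shifted −5/0/+5 mm along the induced-current direction → 24 unique
placements (4 stimuli/cm²), with the current direction perpendicular to the
sulcus and the coil normal along the scalp normal; intensities 35/45/55
%MSO with 5 trials each (120 stimulations per intensity).

**Surface extraction** casts a ray per icosphere vertex (subdivision 5,
~0.9 mm edges) from outside the head toward the center and places the
vertex 0.8 mm inside the outermost gray voxel along the ray — exact for
these star-shaped phantoms and cheaper than marching cubes, while giving
all subjects a shared mesh topology (group-level maps are vertex-wise sums;
no nonlinear registration is needed or attempted). Two corrections matter
at voxel resolution: the sampling depth is divided by the cosine between
ray and surface normal (capped at 0.3) so that "0.8 mm inside gray" is
measured perpendicular to the cortical sheet on sulcal walls, and the ray
radii get two Laplacian smoothing passes to remove the sub-voxel staircase
of the label volume (without this, surface normals on a voxelized sphere
deviate by a few degrees). After both, >99% of vertices fall inside
gray-matter voxels at 1 mm resolution.

## EF metrics and hotspot mapping

Each stimulus yields two per-vertex metrics: strength $|\mathbf{E}|$ and
the **unsigned** normal component $|\mathbf{E}\cdot\mathbf{n}|$. The
product rule requires nonnegative factors and no sign convention for the
normal is established, so the absolute value is used; the signed component
is retained for inspection. Sampling is trilinear (nearest-voxel sampling
leaves visible staircase artifacts at 1 mm).

The hotspot of a muscle multiplies the unit-max-normalized maps of the k
placements with the largest MEPs (trials reduced to the per-placement
median by default; max and single-trial ranking are options; ties broken by
placement id). The product is computed as a sum of logs with a 1e-12 floor
and renormalized to maximum 1 — the multiplication itself is the model, the
log-domain evaluation is only a numerical scheme. The mask keeps vertices
above 0.1 of the maximum; a triangle contributes its full area when its
mean vertex value is suprathreshold (the discrete area estimator is not
otherwise pinned down); the CoG weights suprathreshold vertex positions by
map value × vertex area (a binary-mask CoG is available). These choices
make mask, area and CoG invariant under positive rescaling of any input
map, which the tests assert exactly.

On the synthetic subject this machinery reproduces the expected qualitative
behavior: the strength map peaks on the gyral crown while the normal
component peaks at the lip/wall; hotspot area decreases monotonically with
k for noise-free MEPs; and the normal-component hotspot is much smaller
than the strength hotspot at every k. At 1 mm and k = 3 the
normal-component area is ~170 mm², well under the ~400 mm² scale of a
cortical finger representation. The strength-metric area stays larger
(~730 mm² at k = 5, crossing 400 mm² only at k ≈ 8): with a single fold,
the rest of the cap is smooth and the coil's |EF| footprint varies little
across it, so the relative 10% threshold retains a large area. Resolving
muscle-scale areas with the strength metric would need a fully gyrified
cortex, which is outside this generator's scope. The contrast between the
two metrics — the normal component concentrating far faster — is the
robust, reproduced finding.

## MEP simulation and dose–response

Each muscle responds through a ground-truth sigmoid of the EF metric at its
truth vertex: $\mathrm{MEP} = a/(1+e^{-b(\mathrm{EF}-c)})$, multiplied by
lognormal trial noise (default $\sigma_{\log} = 0.3$) plus a uniform
baseline floor (default 0.01 mV). Trial noise uses an isolated RNG stream
seeded from the config, so simulations never disturb the caller's RNG and
are reproducible.

Because the absolute field scale depends on the phantom, the generator
anchors the truth sigmoids to the achieved fields:
the tangent-line threshold $c - 2/b$ is placed at the field the best
placement delivers at 42 %MSO, and $c$ at 1.18× that value — the ratio
between recruitment turning point and threshold field implied by reported
motor-mapping recruitment parameters. Saturation amplitudes default to
2 mV (FDI) and 1.6 mV (ADM).

Fitting uses Levenberg–Marquardt least squares from a deterministic
multi-start grid (b ∈ {0.01, 0.05, 0.1, 0.5}, c at the EF quartiles,
a = max MEP); the best converged start by residual sum of squares wins.
A fit is flagged *divergent* — excluded rather than thrown — when the slope
is non-positive, the turning point lies more than 50% of the EF range
outside the data, or a relative parameter standard error exceeds 100%.
Threshold and saturation are the closed forms $c \mp 2/b$; the tests verify
the threshold against a numeric tangent construction to 1e-6 and parameter
recovery to 1% on noise-free data (median error <15% per parameter at
$\sigma_{\log}=0.3$ over 20 seeds with 72 pairs). `EF_max` for each
stimulus is the metric value at the argmax vertex of the hotspot map; both
metrics are computed and reported separately since they need not share an
argmax. Defining saturation as $c + 2/b$ (the symmetric tangent intercept
with the plateau) is interpretive; it is stated in the fit object rather
than hidden.

The resting motor threshold is estimated as the smallest tested intensity
at which ≥50% of trials at the best placement exceed 50 µV peak-to-peak
(the conventional criterion; none is mandated by the protocol itself). On
the 35/45/55 grid the estimate is grid-limited; simulated 1 %MSO sweeps
(fields scale exactly linearly) recover an anchored threshold to ±2 %MSO.

## Evaluation studies

* **Sample-count sweep**: hotspot area vs k = 1…8 per muscle and metric.
* **Random-sampling localization**: for MEP-amplitude categories 75/50/25/0
  (% of the maximum MEP; "0" means any response above the 50 µV detection
  floor), k records are drawn uniformly without replacement from the
  eligible set, mapped, and the CoG error is measured against the reference
  hotspot built from the k highest-MEP records. 100 repetitions by default,
  with a dedicated RNG stream per category so adding categories does not
  perturb existing ones; categories with fewer than k eligible records are
  skipped with a warning and the eligible counts are reported for audit.
  On the default subject the median error increases monotonically from the
  75% to the 0% category.
* Evaluation uses the 55 %MSO records by default (the suprathreshold
  condition); pooled-intensity selection is possible by passing the full
  record table.

## Problem sizes and reproducibility

Defaults were chosen once for desk-scale work: 1 mm voxels (~270k
conducting unknowns, ~5 s per placement solve; the full 24-placement
pipeline runs in ~2 minutes), icosphere subdivision 5 (~3.8k cap vertices).
The test suite exercises the qualitative pipeline at 2 mm and verifies
grid convergence of the cortical field about the default resolution
(1 → 0.5 mm changes the maximum cortical |EF| by <2%; 2 mm is adequate for
rank-based mapping but not for extreme field statistics, which is why the
convergence check is anchored at 1 mm). The entire pipeline is a pure
function of (config, seed); all randomness flows from the master seed
through isolated streams.

## Known limitations

* One sinusoidal fold on a sphere is not a gyrified cortex: absolute
  strength-metric hotspot areas are inflated (see above), EF magnitudes and
  recruitment parameters are phantom-specific, and anatomical variability
  across "subjects" is limited to seeded jitter.
* The phantom is compact (40 mm skin radius) with adult-like scalp–cortex
  distance but child-like curvature under a full-size 92 mm coil.
* Isotropic conductivities; no anisotropy, no capacitive effects, no coil
  casing or waveform model.
* Group-level analysis relies on shared mesh topology, standing in for
  template registration of real anatomies.
* MEPs are generated directly from the EF at a point; there is no neural
  cable model, EMG waveform synthesis, or trial-to-trial facilitation.
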