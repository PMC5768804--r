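---
title: "Models and numerical methods behind rfasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind rfasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rfasim is a desk-scale, CPU-only simulator of percutaneous radiofrequency
ablation (RFA) of hepatic tumors. It predicts the coagulation zone produced
by a heating protocol delivered through a simple or umbrella-shaped probe
inside a patient model, and quantifies how sensitive that prediction is to
uncertain tissue parameters and needle placement. Clinical deployments of
this kind of pipeline build the patient model from segmented CT images; in
this package the model is a *synthetic phantom*, so that every downstream
component can be exercised and verified without imaging data.

## The patient model

A phantom is a regular, axis-aligned voxel grid (mm world coordinates,
0-based indices, axis order x, y, z, identity orientation) carrying

* a liver region of interest (ROI) — the simulation domain,
* a tumor mask (sphere, by construction),
* a large-vessel mask (capped cylinders),
* per-voxel tissue property fields realized from per-class scalars.

Voxel membership uses the voxel-center-in-shape rule, with no
partial-volume weighting. This makes every mask constructor exactly
reproducible by a brute-force scan over voxel centers, which is how the
test suite verifies them. Where shapes overlap, precedence is
vessel > tumor > healthy: vessels are heat sinks and must never be
overwritten, and the stored tumor mask consequently never intersects the
vessel mask.

Because deposited heat decays quickly with distance from the probe, the
domain is restricted to a sphere of radius 60 mm around the tumor centroid
(`crop_domain()`); tissue beyond that border has no appreciable influence
on the temperature field at ablation time scales, and the solver and all
metrics operate inside the restricted ROI only.

Default tissue properties (all configurable through
`tissue_properties()`): density 1060 kg/m^3, specific heat 3600 J/(kg K)
and conductivity 0.512 W/(m K) for healthy liver, slightly adjusted for
tumor tissue; blood heat capacity 3600 J/(kg K) and arterial temperature
37 °C. These magnitudes are standard hepatic bioheat values. The blood
mass perfusion rate defaults to 2.0 kg/(m^3 s) in healthy liver and
0.6 kg/(m^3 s) in tumor; perfusion is both the least well known parameter
in practice and the one the ensemble machinery is most often pointed at.

## Bioheat model

Temperature follows the Pennes bioheat equation

$$\rho c \,\partial_t T \;=\; \nabla\cdot(k \nabla T)
\;-\; \omega_b c_b\,(T - T_b) \;+\; q,$$

with the distributed perfusion sink $\omega_b c_b (T - T_b)$ acting in all
perfused tissue and a volumetric source $q$. Two heat-sink mechanisms are
distinguished: porous tissue perfusion enters through the $\omega_b$ term,
while *large* vessels are modeled as Dirichlet regions pinned at blood
temperature — the strongest possible local sink, appropriate for vessels
large enough to be segmented. Voxels outside the ROI are likewise held at
body temperature; the outer grid box itself is insulated, but at the
default geometry the spherical ROI boundary lies well inside it.

Power deposition is an isotropic 3D Gaussian around the needle's source
points: the tip for a simple electrode, and the tip plus the deployed
prong tips for an umbrella probe, with equal weights by default (the
per-prong power split of real generators is not published; equal split is
the symmetric choice and can be overridden). The raw kernel sum is
renormalized over the ROI so the voxel integral of $q$ equals the
commanded power exactly, independent of kernel truncation. The default
kernel width is $\sigma = 4$ mm: at desk-scale grid resolution a narrower
kernel concentrates nearly all power in single voxels per prong, which
both fragments the heated zone and makes the probe thermometer saturate
the controller long before the inter-prong tissue is hot.

Protocols are ordered phases with a duration, a control mode
(`constant_power`, `temperature_controlled`, `cooldown`), a power level, a
target temperature and an umbrella extension fraction. The controller is
proportional: $P = \mathrm{clamp}\!\left(P_{max}\,(1 - (T_{probe} -
T_{target})/\mathrm{band}),\, 0,\, P_{max}\right)$ with a 5 °C band; the
probe temperature is the maximum over the needle source voxels (the
sensing location of real probes is vendor-specific; the maximum is the
conservative reading). The default demonstration protocol heats for 600 s
towards 105 °C at up to 40 W and then cools for 60 s — a shortened
umbrella-probe sequence; vendor sequences target similar temperatures but
run 2–3 times longer.

## Cell death and lesion extraction

Each voxel carries a three-state kinetic model, Alive ⇄ Vulnerable → Dead:

$$k_f(T, A) = \bar{k}_f\, e^{T/T_k}\,(1 - A), \qquad
\dot A = -k_f A + k_b V, \quad
\dot V = k_f A - k_b V - k_f V, \quad
\dot D = k_f V,$$

with defaults $\bar{k}_f = 3.33\times10^{-3}\,\mathrm{s}^{-1}$,
$k_b = 7.77\times10^{-3}\,\mathrm{s}^{-1}$, $T_k = 40.5$ °C from the
published parameterization of this model. Dead is absorbing, so the
predicted lesion can only grow during a simulation — the property behind
on-line lesion tracking, and one the tests assert directly. Note that the
pristine state $A = 1$ is a fixed point of these equations (the forward
rate carries the $1 - A$ feedback factor); simulations therefore start
from $A_0 = 0.99$, $V_0 = 0.01$, as in the model's published setup.

The lesion is the set of ROI voxels with $D \ge 0.8$. The extraction rule
of the original workflow is not published in detail; the threshold is a
documented, configurable choice. The lesion *surface* is the iso-surface
of the $D$ field at the threshold, triangulated by marching tetrahedra
(every grid cell is split into six tetrahedra, each contributing up to two
triangles with vertices interpolated linearly along crossed edges). Linear
interpolation gives sub-voxel surface placement for smooth fields, which
the radial-field tests quantify.

## Numerics

* **Spatial discretization.** 7-point finite differences on the voxel
  grid, with harmonic-mean face conductivities so that flux is continuous
  across tissue interfaces. This replaces the adaptive tetrahedral FEM of
  image-based clinical pipelines; on smooth synthetic phantoms a regular
  grid converges cleanly (the suite checks that halving the spacing moves
  the final peak temperature by under 2 %) and keeps every operator
  exactly reproducible.
* **Time integration.** Operator splitting at the step `dt` (default 2 s):
  one temperature step, then one cell-death step. The temperature step is
  forward Euler whenever `dt` satisfies the explicit stability bound
  $dt \le \min \rho c / (\sum_f k_f/h^2 + \omega_b c_b)$ — at 2 mm voxels
  the bound is ≈ 4.8 s, so desk-scale runs take the cheap path — and
  backward Euler (supernodal sparse Cholesky, factored once per run)
  otherwise; `method = "implicit"`/`"explicit"` forces either scheme, and
  the explicit path refuses unstable steps with the bound in the error
  message. The kinetics are advanced per voxel by one classical RK4 step
  at the *mid-step* temperature $(T^n + T^{n+1})/2$, which removes the
  first-order coupling error of naive splitting; states are clamped to
  $[0,1]$ and renormalized to $A + V + D = 1$ each step.
* **Verification against closed forms.** The solver is checked against
  the linear steady conduction profile between fixed-temperature plates
  and against the Pennes point-source far field
  $(P/4\pi k r)\,e^{-r/\delta}$, $\delta = \sqrt{k/\omega_b c_b}$, on a
  configuration chosen to be in that formula's regime: kernel width small
  against the measurement radii, $\delta$ (≈ 6.6 mm) well resolved by the
  1.5 mm grid, and the Dirichlet ROI boundary several $\delta$ beyond the
  probe shells. Energy balance in an insulated, unperfused medium holds to
  1e-6 relative per step for both schemes.
* **Degenerate inputs.** Zero-radius tumors keep exactly the voxel under
  the center; zero-power protocols leave the field at body temperature
  and the lesion empty; an empty lesion is a valid result everywhere
  except surface-distance metrics, which require non-empty surfaces and
  say so.

## Registration

Needle images are mapped into the model frame by least-squares rigid
registration of ≥ 3 paired landmarks (Kabsch/Procrustes via SVD of the
cross-covariance, with the smallest-singular-vector sign flip so the
result is always a proper rotation, never a reflection). Collinear or
under-sized landmark sets raise an error rather than returning an
ill-determined fit. The tests recover randomly drawn transforms to
1e-9 mm RMS and cross-check residuals against an independent closed-form
quaternion solution.

## Ensemble uncertainty quantification

Up to two parameters vary simultaneously: tissue perfusion, tumor
perfusion, heat capacity, thermal conductivity, or the needle geometry.
Scalar parameters take either a linear grid including both endpoints (a
single iteration takes the midpoint) or seeded uniform draws; needle
variation displaces the tip, trocar point and prong tips independently by
vectors drawn uniformly from a ball of radius `r` (rejection sampling from
the bounding cube, seeded, hence bit-reproducible). The ensemble simulates
the full Cartesian product — `it_p1 * it_p2` runs.

The lesion ensemble is summarized by a contour-boxplot variant on voxel
masks: the depth of a member is the fraction of *pairs of other members*
whose intersection and union sandwich it (2-subset contour band depth).
The deepest member is the median (ties broken by lowest index, for
deterministic reporting); members with depth below 0.1 are outliers; the
50 % band is the intersection/union of the deeper half of the non-outlying
members and the envelope that of all of them. The published description
names only "a variation of contour boxplots", so the subset size, the
outlier threshold and the two-band split are documented package choices.

## Validation metrics

With voxel counts $a = |test|$, $b = |reference|$, $i = |test \cap
reference|$: DSC $= 200\,i/(a+b)$, SN $= 100\,i/b$, PPV $= 100\,i/a$,
RVD $= 100\,|a-b|/b$ (a signed variant is available; reported RVD is
non-negative). Surface distances are symmetric vertex-to-nearest-triangle
distances pooled over both directions — AAE is their mean, min/max their
extremes; a one-sided option exists because the published tables do not
state sidedness. An intervention counts as successful iff RVD < 20 %,
SN > 80 % and AAE < 3 mm, all strict.

The safety-margin classifier labels each lesion-surface point by its
distance to the tumor surface: `failed` below 4.5 mm, `critical` in
[4.5, 5.5] mm, `safe` above 5.5 mm. The published bands use strict
inequalities on both sides, leaving the boundary values unassigned; the
closed critical band is the conservative completion, and the labels
partition every point set.

## What the phantom does and does not show

The generator emulates the *structure* of a registered patient model —
masks, property fields, domain restriction, landmarks — under exactly
known geometry, which is what makes brute-force oracles and closed-form
solutions available. It does not emulate segmentation error, deformable
registration residue, tissue inhomogeneity beyond the three classes,
temperature-dependent properties, vaporization/impedance roll-off, or
track ablation. Passing tests therefore demonstrate correctness of the
numerical pipeline under its stated model, not clinical accuracy; the
published multi-center accuracy of this class of simulators cannot be
reproduced without the clinical images.

## Problem sizes

The shipped configurations are sized for a single CPU: the default
phantom is 64³ voxels at 2 mm (ROI ≈ 113k voxels) with a 600 s + 60 s
protocol at `dt = 2`; ensembles run 25 members at 32³ with shortened
protocols; the verification grids are ≤ 53³. All are package choices made
once and recorded here.

```{r example}
library(rfasim)
ph <- default_phantom()
res <- run_protocol(ph, default_needle(ph), default_protocol())
metrics_report(res$lesion, ph$tumor)
```
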