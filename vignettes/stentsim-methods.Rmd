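---
title: "Methods: a desk-scale surrogate for coronary bifurcation stenting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale surrogate for coronary bifurcation stenting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentsim)
```

# What this package models

`stentsim` is a desk-scale re-implementation of an image-based platform for
patient-specific simulation of coronary *bifurcation* stenting. The clinical
workflow it mirrors is: (i) reconstruct the 3D bifurcation lumen and wall by
fusing biplane angiography (centerline) with an intravascular OCT pullback
(cross-sectional contours); (ii) grade the plaque from OCT tissue composition
and assign hyperelastic material laws accordingly; (iii) crimp, position and
bend virtual stents and balloons along the centerline; (iv) replay the actual
procedure step by step (stenting, proximal optimization, side-branch strut
opening, kissing balloon inflation), each step starting from the stressed
state left by the previous one; (v) reconstruct the deployed stent from OCT
strut detections; (vi) assess hemodynamics (time-averaged wall shear stress,
TAWSS) before and after stenting; and (vii) quantify agreement between
simulated and reference mean lumen/stent diameter profiles with Bland-Altman
statistics, co-registered at the carina.

The reference platform performs steps (iii)-(iv) with explicit 3D
finite-element contact mechanics and step (vi) with transient 3D CFD. Both
are deliberately out of scope here: this package replaces them with reduced
surrogates (below) that preserve the procedure grammar, the constitutive
laws, and the qualitative mechanical contracts, while running in seconds on
one CPU. Wherever the surrogate departs from the full-physics pipeline, that
is stated here and in the function documentation; the package never claims
equivalence with 3D FEA/CFD.

# Geometry and reconstruction

All coordinates are millimetres in a right-handed frame. Arclength is
measured from the proximal main-vessel (MV) inlet; the side branch (SB)
measures arclength from the carina, which is the fixed landmark for every
co-registration in the package.

**Biplane centerline.** Views are *parallel* projections whose planes all
contain the table (x) axis, so each projected curve retains the true axial
coordinate of the 3D centerline. Two views at least 30 degrees apart then
determine the in-plane coordinates per axial sample by a 2x2 linear solve.
This is an idealization of clinical cone-beam biplane systems chosen so that
the synthetic round trip is exactly solvable; foreshortening and epipolar
calibration problems of real angiography are intentionally absent, and the
30-degree limit mirrors the practical lower bound for usable view
separation.

**Outer-border rule.** OCT often loses the outer wall behind attenuating
tissue. The rule implemented is purely a function of the total missing arc:
below 180 degrees of circumference the missing spans are filled by periodic
cubic-spline interpolation through the visible border; above 180 degrees the
frame is discarded (a value, not an error — discarded frames are logged and
the loft simply spans the gap). Exactly 180 degrees is treated as
interpolable; the reference description uses strict inequalities in both
directions, so the boundary case is a documented package choice.

**Frame placement and rotation.** Frames are spaced by the pullback pitch
with the carina frame pinned exactly to the carina arclength. Rotational
registration of OCT frames about the catheter axis is not observable in the
data this package consumes; the convention is rotation-minimizing (parallel
transport) frames along the centerline, with angle zero at the SB-ostium
direction. Synthetic data are generated with the same convention, so
round-trip tests are exact; on real data this would be an unresolved degree
of freedom.

**Branch merging.** No mesh-boolean library is available in the target
environment, so the union of the two branch tubes is computed implicitly:
each branch becomes a capsule-like signed distance field around its
centerline with the per-slice area-equivalent radius, the union is the
pointwise minimum, and the surface is extracted with a hand-written marching
tetrahedra on the Kuhn (6-tet) subdivision, which splits shared cube faces
consistently and therefore yields watertight meshes by construction. Volumes
are voxel counts on the same grid — chosen over surface integrals because it
makes the containment property (union volume at least each branch volume)
exact rather than approximate. The SB ostium curve is traced where SB
surface lines cross the MV lumen field, and its area is measured on the
best-fit plane.

# Materials

The constitutive table (shipped as versioned JSON in `inst/extdata`) holds:
bench silicone (incompressible Neo-Hookean, C10 = 0.154 MPa, fitted from
compression tests of the cast phantom material); a sixth-order reduced
polynomial law for normal arterial wall; and five plaque classes from very
soft to very stiff mapped to integer plaque scores -2..+2, each with a yield
stress. Uniaxial Cauchy stress for W = sum Ci0 (I1-3)^i under incompressible
uniaxial stretch is

  sigma(lambda) = 2 (lambda^2 - 1/lambda) sum_i i Ci0 (I1 - 3)^(i-1),
  I1 = lambda^2 + 2/lambda,

and the test suite verifies it against central-difference differentiation of
the energy density. The plaque yield stresses are implemented as a
perfect-plasticity *cap* on the stress magnitude: the post-yield law is not
specified in the source material, and a cap is the simplest conservative
choice (it never overestimates wall resistance and leaves the elastic curve
untouched below yield). Two non-obvious facts the tests pin down: the class
stresses are strictly ordered only at finite stretch (asserted at
lambda = 1.2) — in the infinitesimal limit the "soft" class is *below*
"very soft" because of its smaller C10 — and the stress families are
continuous in the quarter score by construction.

**Plaque scoring.** Tissue composition (lipid / fibrous / calcified area
fractions) maps to a quarter-step score in [-2, +2], with +2 = calcium only
and -2 = lipid only. The exact weighting used by the reference workflow is
published elsewhere and not restated in the source; the stand-in implemented
here is the area-fraction contrast 2 (f_Ca - f_lipid) / (f_Ca + f_fib +
f_lipid), rounded to the nearest quarter with ties toward zero. It honors
both stated endpoints, is symmetric (equal calcium and lipid cancel), and is
isolated behind `score_composition()` so a different rule can be swapped in
without touching anything else. Fractional scores interpolate the stress
curves of the two adjacent classes pointwise in stress at each stretch.
Zones are contiguous runs of frames whose scores round to the same quarter.

**Alloys and balloons.** Stent alloys follow a bilinear Von Mises law:
elastic to the 0.2% proof stress, then linear isotropic hardening to
(elongation, tensile strength) — or a flat plateau for the Pt-Ir wire core,
which is specified with perfect plasticity. Shell-core wire struts use an
area-weighted effective modulus (default core fraction 0.25, configurable).
Balloon membranes are linear elastic with class moduli 300 / 900 / 1500 MPa
(compliant / semi-compliant / non-compliant).

# The deployment surrogate

The centerpiece simplification: instead of 3D explicit FEA with contact, the
vessel is discretized into independent cross-sectional slices (default
spacing 0.25 mm, matching the reference element size), and each procedure
step solves a per-slice quasi-static radial equilibrium

  P_balloon = p_wall(r) + sum_layers p_ring(r),

by bisection to 1e-6 mm, clamped above by the balloon's pressure-diameter
curve. The wall term is the thin-walled relation p = (t/r) sigma(r/r0) with
the slice's constitutive law; the stent term is a thin-ring hoop surrogate
p = k sigma_alloy(eps) A_strut / (r w_ring) with eps the strain from the
ring's plastic-set radius, w_ring the ring pitch and k a dimensionless ring
constant (default 0.25, calibrated once so that a crimped ring yields under
a few atmospheres — the order of real deployment pressures — and not
revisited). Deflation updates each layer's plastic set by elastic unloading
at slope E from the loading peak, then settles the slice where the wall
balances the rings; unstented slices recoil exactly to the reference radius.
Layers whose unloaded set radius is below the local reference radius are
malapposed: the wall rests at r0, the stent floats at its set radius, and
the gap is reported by `malapposition_map()`.

What this surrogate keeps from the full model: state carryover between
steps (bitwise-reproducible chaining), pressure monotonicity, bounded
recoil with plastic retention, POT locality to the proximal MV, two-layer
overlap (culotte) by summing ring pressures, KBI overlap as the
area-equivalent combined balloon cross-section, and the plaque-stiffness
effect (an identical procedure expands a +1-scored lesion less than a
-1-scored one). What it cannot represent: strut-level contact and
interlocking, longitudinal coupling between slices, dog-boning at balloon
edges, wall pre-stress, and stress/strain fields in the wall. The frictional
contact coefficient (0.2) and explicit-solver settings of the reference
setup are carried as provenance metadata in every procedure log, tagged
"recorded-not-simulated".

**Ostium bookkeeping.** The effective SB ostium area is pi r^2 averaged over
the ostium-adjacent slices, reduced by a configurable strut-coverage
fraction (default 0.25) while the ostium is jailed by an MV stent crossing
the carina. Side-branch strut opening recrosses through the distal cell (the
stated assumption when the true recross cell is unknown), clears the jailed
marker and therefore strictly increases the effective area. This is overt
bookkeeping, not cell mechanics, and is documented as such.

# Stent reconstruction from strut detections

Strut "detection" is simulated by sampling the deployed stent into frames at
0.2 mm pitch (image-based segmentation is out of scope). Points are
flattened to (axial, circumferential-arc) coordinates, renormalized to a
common reference circumference so tapered lumens do not distort the
pattern, then registered to the 2D design pattern by grid-searched periodic
rotation plus Nelder-Mead refinement, a bounded (plus/minus 20% of ring
pitch) per-ring axial adjustment for foreshortening, and one-to-one
point-node assignment under a 0.3 mm gate. The assignment is greedy by
increasing distance rather than an optimal bipartite matching — no
assignment solver is available in the target environment — which is
equivalent for well-separated strut detections and is isolated so it can be
replaced. Because the zig-zag pattern repeats every two angular bins,
rotation is recoverable only modulo that symmetry (45 degrees for 8 crowns);
the equivariance test accounts for it. Matched nodes are wrapped back onto
the lumen surface offset inward by half a strut thickness, so the full round
trip is exact (node RMSE below one strut width) when the stent is apposed;
a malapposed stent cannot be recovered from lumen geometry alone and the
fixtures use apposed deployments.

# Reduced-order hemodynamics

Blood is Carreau: mu(gdot) = mu_inf + (mu0 - mu_inf) [1 + (lambda gdot)^2]
^((n-1)/2) with mu_inf = 0.0035 Pa s, mu0 = 0.25 Pa s, lambda = 25 s,
n = 0.25, density 1060 kg/m^3. The inlet waveform is a packaged generic
diastolic-dominant coronary shape (period 0.8 s, mean 50 mL/min at the
3.0 mm reference diameter — a typical proximal coronary flow; the shape is
replaceable through `flow_conditions()`). Mean inlet flow scales with
inlet diameter as D^(7/3); the exact adjustment rule of the reference
workflow is not printed, so the same exponent as the branch-flow split is
reused for self-consistency and left configurable. Daughter-branch flows
follow the Huo-Kassab relation Q_mv/Q_sb = (d_mv/d_sb)^(7/3), which
conserves flow exactly at every time sample. Wall shear stress per slice is
Poiseuille with the Carreau viscosity evaluated at the wall shear rate
4Q/(pi r^3); TAWSS is the cycle mean. Inlet/outlet extensions and the
three-cycle transient washout of the 3D solver are no-ops in a quasi-steady
1D model and are retained as metadata only. The pre/post contract the tests
enforce is qualitative: enlarging a stenosed lumen lowers TAWSS at the
former stenosis.

# Synthetic data: the stated world

The generator emulates the *inputs* of the clinical pipeline, not images:
tapered bifurcations (defaults: proximal MV 3.5 mm tapering to 3.0 mm over
30 mm, SB 2.5 mm at 60 degrees, carina at 18 mm) with cosine-shaped diameter
stenoses (the reference case is a 60% diameter stenosis, 8 mm long, centered
10 mm from the inlet — a severe but common target lesion); OCT-like
pullbacks with circular contours, composition arcs proportional to the local
tissue-fraction map, and injectable dropout arcs; parallel biplane
projections; bench variants with uniform silicone walls; and procedure
tables for provisional, TAP and culotte techniques. Real plaque-arc geometry
has no published distribution to sample from; the default composition map (a
fibrous background with a lipid shoulder and calcific core at each stenosis)
is an arbitrary but fixed choice, documented here and not tuned against any
test. A green round-trip test therefore establishes internal consistency of
the pipeline under its own conventions — not fidelity to clinical OCT, which
would require the non-public imaging data.

# Numerical choices and degenerate inputs

- Equilibrium bisection: 80 iterations or interval below 1e-6 mm;
  deterministic; zero pressure is an identity by definition.
- Marching tetrahedra: field values exactly zero are nudged by 1e-12 to
  avoid degenerate crossings; meshes welded at 1e-9 mm for extraction and
  1e-6 mm for edge accounting.
- Monotonicity assertions in tests allow slack at the bisection tolerance
  (1e-5 mm), not at machine precision: re-solving an equilibrium can move a
  radius by a few 1e-7 mm in either direction.
- Periodic spline interpolation is used for both missing-arc completion and
  strut-ring area upsampling; a ring polygon through only 8 crown points
  would otherwise underestimate enclosed area by ~10%.
- Degenerate centerline samples (duplicate points) inherit the previous
  tangent in the parallel-transport frames; arclength grids are deduplicated
  at 1e-9 mm.
- Procedure JSON uses the step/action/device/placement record schema;
  steps must be numbered consecutively and placement references must point
  backward. (YAML was the natural format for the step tables but no YAML
  parser is available in the target R environment, so JSON is used with an
  identical schema.)

# Agreement analysis

MLD is the per-slice area-equivalent diameter 2 sqrt(A/pi); the per-slice
definition is not fixed by the source material, so a chord-averaged
alternative is implemented behind `method = "chord"` and the area definition
documented as the default. MSD is the area-equivalent diameter of the
periodic-spline ring through strut centroids. Profiles are co-registered by
shifting both to carina-relative arclength and interpolating the reference
at the simulated samples. Bland-Altman uses the sample (n-1) standard
deviation and fixed 1.96 multipliers, so bias is exactly the midpoint of the
limits; "overall" rows pool all paired differences across cases rather than
averaging per-case biases. Reproducing the reference platform's printed
agreement tables would require its non-public bench and clinical images;
this package checks instead that its implementation satisfies the
Bland-Altman conventions those tables obey (bias = midpoint of limits, to
printed rounding).

# Known limitations

Beyond the surrogate boundaries already stated: no cardiac-phase vessel
motion; no cone-beam projection geometry; no image-intensity processing
anywhere; no wall pre-stress; no drug elution or biology; stent presets are
representative ring-and-link patterns, not manufacturer CAD (crown/link
counts per commercial device are not public); and the silicone density
carried in the material table (2.32 g/cm3, as printed in the source
material) is unusually high for PDMS but is unused by the quasi-static
mechanics.
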