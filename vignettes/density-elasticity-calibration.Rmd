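---
title: "Calibrating a density-elasticity law from voxel models and bending tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a density-elasticity law from voxel models and bending tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cortical bone is strongly heterogeneous: its local stiffness tracks its
local mineral density, which computed tomography measures voxel by voxel
on the Hounsfield scale (HU, defined as `1000*(mu - mu_water)/mu_water`
from linear attenuation coefficients). A common way to turn a CT scan into
a patient- or specimen-specific finite-element model is the power law

> E = a (c HU + b)^d, with apparent density rho_app = c HU + b,

where E is the Young modulus in MPa, rho_app is in kg/m^3 and a, b, c, d
are coefficients that must be identified empirically for the bone at hand.
`bonecal` implements that identification end to end for cuboidal
cortical-bone samples tested in three-point bending:

1. **Density binning.** Each voxel of the HU grid is assigned to one of 11
   density ranges with edges 600, 800, ..., 2400 HU and representative
   middles 500, 700, ..., 2500 HU. Intervals are half-open `[lo, hi)`; the
   source imaging convention does not state how boundary values were
   assigned between touching ranges, so the standard histogram rule was
   adopted as a deterministic choice, without claiming fidelity on exact
   boundary values. Values outside 600-2400 HU fall in the open-ended
   extreme bins.
2. **Midpoint remeshing.** Scanner grids are generally rotated relative to
   the sample faces. One point is generated at the centroid of each voxel,
   carrying its bin label; a rigid transform into the sample frame is
   estimated from the principal axes of that cloud; and a fresh grid of
   cubic elements spanning the *measured* sample dimensions inherits, per
   element, the bin of the nearest transformed midpoint. Elements farther
   than one element diagonal from every midpoint fall back to the lowest
   bin, the conventional sink for out-of-range material.
3. **Bending simulation.** The binned model becomes a structured mesh of
   eight-node (HEX8) trilinear bricks with full 2x2x2 Gauss integration,
   per-bin Young moduli and a common Poisson ratio. A prescribed downward
   deflection of the mid-span load line yields the reaction force, and the
   bending stiffness is `k = (F(0.8 mm) - F(0.2 mm)) / 0.6 mm`.
4. **Inverse identification.** A population-based genetic search minimises
   `err = sum_i (k_i_FEA - k_i_Exp)^2` over the box a in [0.2, 0.8],
   b in [1200, 5000], c in [2, 8], d in [0.1, 2], subject to
   E(2500 HU) <= E_limit.

## What the measurements contribute

Each sample enters as (i) a voxel grid of HU values, (ii) measured outer
dimensions (height A, thickness B, length L) and the 46 mm support span,
and (iii) a measured force-deflection curve. The experimental stiffness is
the least-squares slope of force against deflection restricted to the
0.2-0.8 mm window, where the response is linear (coefficient of
determination typically 0.994-0.998 on real machines). Window endpoints
are inclusive and interpolated linearly when the sampling grid skips them.

## Numerical choices in the bending model

**Supports and load as contact strips.** The physical test presses
R = 5 mm steel half-rounds into the sample. Modelling those contacts
explicitly needs a nonlinear contact solver; the calibrated quantity,
however, is a slope in a window where the response is linear, so the
package replaces contact by kinematic constraints: vertical rollers along
the two support lines, a prescribed vertical displacement along the load
line, one support line additionally pinned axially and one corner node
laterally (a minimal statically determinate set). A literal zero-width
line constraint would be a two-dimensional point load, whose local
compliance grows without bound as the mesh refines; the constraints are
therefore applied over strips of fixed physical width (default 1.5 mm,
the order of the Hertzian contact patch of the roller at the forces
reached here). On meshes coarser than the strip width this degenerates to
a single node line; `contact_width = 0` requests literal lines, which the
convergence tests use on node-aligned geometry.

**Stiffness extraction.** The solver is linear, so `F(d) = k d` exactly
and the 0.2/0.8 mm window formula returns k identically; it is retained
because measured curves are noisy and nonlinear outside the window.

**Accuracy.** Against the shear-corrected (Timoshenko, kappa = 5/6)
closed-form stiffness of a homogeneous rectangular beam - evaluated at the
realized mesh cross-section and realized support span, since the meshed
box pads the measured dimensions up to one element - the FE result agrees
within 10% at 0.75 mm elements, converging monotonically with shrinking
increments under refinement. The residual contract of the sparse solve is
1e-8 (observed ~1e-14 with the supernodal Cholesky factorisation used);
load-line and support reactions balance to 1e-6 relative.

**Solver engineering.** For the inverse problem thousands of bending
solves differ only in the per-bin moduli. The assembly is therefore
factored once per sample into a sparsity template plus a matrix `S` with
one column per bin such that the stiffness values are `S %*% E_bins`; the
symbolic Cholesky analysis is likewise reused, so every candidate costs
one numeric refactorisation (~60 ms at desk scale).

## The search and its degeneracies

The four coefficients are **jointly under-determined**: scaling b and c by
any s > 0 while scaling a by s^-d leaves E(HU) unchanged everywhere, so an
exactly flat one-parameter family passes through every solution, and a
further direction is nearly flat (singular values of the stiffness
Jacobian at the reference coefficients span five orders of magnitude).
Fits must therefore be judged by the recovered E(HU) curve and the error
norm, never by raw parameter values.

This geometry also dictated the evolutionary operators. Blend crossover
with isotropic Gaussian mutation - a common real-coded default - stalls
two to four orders of magnitude above the attainable error on noiseless
synthetic problems, because isotropic steps almost surely leave the narrow
curved valley. The package instead builds each trial individual from the
current best plus a weighted difference of two random population members
(weight 0.7), recombines it gene-wise with its parent (crossover
probability 0.9), clips to the bounds, and keeps it only if it is at least
as good as the parent. Difference vectors sampled from a population that
has begun to align with the valley automatically point along it, and the
greedy replacement makes the search elitist by construction. Infeasible
candidates - modulus cap exceeded or non-positive density at any bin
middle - receive an infinite error (death penalty). Evaluations are cached
on the candidate rounded to six significant digits, so repeated solutions
cost nothing; the run terminates early when the best error has not
improved by a relative 1e-6 for a configurable number of consecutive
generations (default 4; the desk-scale tests use 8 because the
difference-vector dynamics routinely pause for a few generations before
improving again).

Population 200 and at most 30 generations are the full-scale defaults;
the package's own tests run a desk-scale preset of 3 synthetic samples,
1.5 mm elements, population 40 and at most 40 generations, which
reproduces the ground-truth E(HU) curve within 2% at all 11 bin middles.

## The synthetic-data generator

`generate_phantom()` emulates what a CT of a cuboidal cortical sample
delivers, without any scan:

- a **target per-bin occupancy** (defaults mid-range-heavy, as cortical
  bone is); voxels are ranked by a spatial pattern value and assigned to
  bins by quantile, so realised fractions match the target exactly up to
  integer rounding;
- a **spatial pattern**: `layered-gradient` (denser towards the outer
  height/thickness faces), `radial`, or `uniform`;
- a **misalignment rotation** between the sample and the scanner lattice
  (default 10 degrees of yaw, a sample laid flat but skewed on the table);
  background voxels outside the sample are `NA` and take no part in
  binning or remeshing;
- within-bin HU noise (default sd 40 HU), clamped so bin membership is
  unchanged.

`forward_experiment()` closes the loop: bin, remesh, solve, then sample
the force-deflection line on a 0-1 mm grid and add Gaussian force noise.
The default noise sd of 65 N is about 1% of the peak force of the
desk-scale phantoms and puts the fitted R^2 of their stiffness
regressions inside the experimentally observed 0.994-0.998 band;
deflection is treated as exact because the test machine is displacement
controlled.

What the phantoms deliberately do **not** model: CT physics (beam
hardening, scatter, reconstruction artifacts), partial-volume averaging at
the sample surface, spatially correlated density noise, and any post-yield
behaviour. Passing closed-loop tests therefore demonstrates that the
pipeline and the identification are self-consistent, not that the law
fitted to any particular real scan is accurate.

## Known limitations

- **Remeshing bias.** Nearest-midpoint resampling between two lattices of
  similar pitch under rotation systematically under-samples the outermost
  voxel shell (no target centre lies closer than half an element to a
  face). On strongly layered phantoms this biases one boundary bin by up
  to ~2 percentage points at matched 1 mm resolution, and more when the
  target elements are coarser than the source voxels. The identity remesh
  (aligned, matched pitch) is exact.
- **Idealised constraints.** Which degrees of freedom real roller contact
  transmits is not modelled; the strip idealisation is validated only
  through the beam oracle and closed-loop recovery.
- **Linear elasticity only.** No contact, damage, rate effects or
  geometric nonlinearity; curves outside the 0.2-0.8 mm window are out of
  calibrated scope.
- **Stiffness units.** Force per deflection is N/mm throughout; published
  comparisons of this kind sometimes print N/mm^2 for the same quantity.
- **Poisson ratio** is fixed (default 0.3, the dominant literature value)
  and not calibrated; the modulus cap default of 21,000 MPa sits just
  above the stiffest calibrated range and is configurable.

## Desk-scale problem sizes

The test suite and examples run: phantoms at 1.0-1.5 mm voxels, remeshed
elements of 1.0-1.5 mm (~1,800 elements, ~7,600 degrees of freedom per
sample), and the beam-theory oracle at 0.75 mm (~14,600 elements). These
sizes were chosen so a full closed loop runs in minutes on a laptop while
staying in the asymptotic regime the coarser checks already exhibit;
production use at 0.3 mm voxels only changes run time.

## A minimal session

```{r, eval = FALSE}
library(bonecal)

geo <- sample_geometry(height = 11.58, thickness = 7.39, length = 68.14)
truth <- ground_truth(material_law(0.388524, 4419.3, 2.20939, 1.17823))

ph <- generate_phantom(phantom_spec(geo, spacing = 1.0, seed = 1))
fw <- forward_experiment(ph, truth, bending_setup(geo), element_size = 1.0)

stiffness_from_curve(fw$curve)     # slope and R^2 in the linear window
build_bin_table(hu_binning(), truth$law)  # per-range density and modulus
```
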