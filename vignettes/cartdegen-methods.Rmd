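---
title: "Methods: mechanobiological simulation of proteoglycan loss in injured cartilage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanobiological simulation of proteoglycan loss in injured cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Traumatic loading of articular cartilage produces surface cracks; when the
injured tissue is then loaded cyclically, proteoglycans (PGs) are lost
around the lesions long before the collagen network degrades.  Because the
fixed charge density (FCD) of the glycosaminoglycan side chains is the
measurable proxy for PG content, this package simulates *FCD loss around
cartilage cracks* under a physiological compression protocol, with three
candidate driving mechanisms: interstitial fluid velocity, deviatoric
strain, and maximum shear strain.

The simulated specimen is a cylindrical explant, 3 mm diameter and 1 mm
thick, harvested from young bovine knee cartilage.  Its cross-section is
meshed with 4-node quadrilaterals; parametric surface notches stand in for
segmented histological crack geometries, which are not publicly available.

# Constitutive model

The tissue is a fibril-reinforced porohyperelastic material with Donnan
osmotic swelling.  The total Cauchy stress is

$$\sigma_{tot} = \sigma_f + \sigma_{nf} - \Delta\pi I - \mu^f I - T_c I,$$

with a non-fibrillar neo-Hookean ground substance

$$\sigma_{nf} = K_{nf}\frac{\ln J}{J} I + \frac{G_{nf}}{J}(F F^T - J^{2/3} I),$$

tension-only fibrils $\sigma_f = E_f\,\varepsilon_f$ for
$\varepsilon_f > 0$ (zero otherwise), a Donnan osmotic pressure

$$\Delta\pi = \phi_{int} RT\sqrt{c_{FCD}^2 + 4\tfrac{(\gamma^\pm_{ext})^2}{(\gamma^\pm_{int})^2}c_{ext}^2} - 2\phi_{ext} RT c_{ext},$$

an optional chemical-expansion stress $T_c$, and Darcy flow
$q = -k\nabla p$ with interstitial fluid velocity
$v_{fl} = q\,(e+1)/e$, $e = n_{fl}/n_s$.

Decisions taken where the constitutive family leaves freedom:

* **Fibril strain measure.** The fibril stress law does not fix a strain
  measure; we use the logarithmic stretch
  $\varepsilon_f = \ln|F\,\hat e_f|$, consistent with the finite-strain
  setting, and isolate it in `fibril_strain()` so a Green-strain variant
  can be swapped in one place.
* **Pressure split.** The FE pressure unknown is the chemical potential of
  water $\mu^f$; the osmotic pressure $\Delta\pi$ is evaluated
  constitutively from the local FCD, so the physical pore pressure is
  $p = \Delta\pi + \mu^f$.  Flow is driven by $\nabla\mu^f$, which makes
  the free-swelling equilibrium ($\mu^f \equiv 0$) exactly flux-free even
  though $\Delta\pi$ varies with depth.
* **FCD compaction.** The reference FCD is defined per unit reference
  fluid volume and rescaled by the current fluid volume
  $J - n_{s,0}$ (incompressible solid) whenever the osmotic terms are
  evaluated, so compaction concentrates the fixed charges.
* **Mobile anion concentration** in $T_c$ follows ideal Donnan
  equilibrium, $c^- = (\sqrt{c_{FCD}^2+4 g^2 c_{ext}^2}-c_{FCD})/2$.
* **Unprinted coefficients.** The osmotic/activity coefficients and the
  chemical-expansion constants are taken from the literature by the
  original study but not printed; we default to ideal coefficients
  ($\phi = \gamma^\pm = 1$) and disable chemical expansion
  ($a_0 = \kappa = 0$), all overridable, rather than hard-code guessed
  values.

Units are mm-N-s-MPa with FCD in mEq/ml; the single conversion constant
$RT\cdot 10^{-3}$ MPa·ml/mEq (`rt_constant()`) centralizes osmotic unit
handling.  Table-level defaults: $E_f = 20$ MPa, $E_{nf} = 0.16$ MPa,
$\nu_{nf} = 0.42$, $k = 1.3\times10^{-3}$ mm$^4$/(N·s), $C = 3.009$,
$c_{ext} = 0.15$ mEq/ml, $T = 293$ K.

# Composition and fibril architecture

Depth-wise profiles (normalized depth $h$, surface 0, bottom 1):
fluid fraction $n_{fl} = 0.85 - 0.15h$, and sixth-degree polynomials for
FCD and relative collagen density (`depth_profiles()`).  A measured
optical-density profile can replace the FCD polynomial via
`od_profile_to_fcd()`, which refits the degree-6 polynomial and rescales
it to a prescribed depth-averaged FCD.

The primary fibril family follows one of four arrangements; the arcade
(Benninghoff) default runs tangent to the surface in the superficial zone
(0–15% of thickness), rotates linearly across the transitional zone
(15–40%) and is depth-normal below.  Those zone fractions are the standard
histological description for young bovine cartilage and are configurable.
The secondary family is a fixed fan of 8 in-plane directions plus the
out-of-plane axis; primary fibrils are weighted $\rho_z C$, secondary
$\rho_z$ per direction.  Because the fibril sum is a discrete directional
quadrature, $E_f$ acts as an *effective* modulus tied to this
discretization — which is consistent, since $E_f$ is calibrated against
force records simulated with the same discretization.

# Finite elements

The coupled $(u, p)$ problem is solved with a total-Lagrangian,
backward-Euler formulation on 4-node quadrilaterals with equal-order
bilinear displacement and pressure.  Equal-order pairs are not inf-sup
stable in the undrained limit, so a local pressure-projection
stabilization (Bochev–Dohrmann type) is applied to the *rate* of the
intra-element pressure fluctuation with coefficient
$\alpha/G_{nf}$, $\alpha = 0.1$ by default.  The confined-compression
benchmark in the test suite shows the transient solution is insensitive
to $\alpha$ over two orders of magnitude at the meshes used, while values
much below the default destabilize Newton on strongly swollen states.

The element tangent is a forward finite difference of the analytic
residual over the 12 element dofs; at the residual tolerances used this
behaves like a consistent tangent, and it keeps the tension-only fibril
switching and the osmotic nonlinearity exactly in sync with the residual.
Newton uses backtracking line search (relative residual $10^{-6}$,
absolute floor $5\times10^{-7}$ N, at most 30 iterations).  The osmotic
prestress is ramped in load steps during the free-swelling solve, with
automatic ramp refinement on non-convergence; the transient driver
bisects a time step up to three levels if Newton fails on a softened
configuration.

**Formulation.** The explant is a disk, and the package defaults to the
axisymmetric formulation (plane strain remains available as a switch).
Plane strain exaggerates in-plane stretch at 15% compression — enough to
push intact-tissue deviatoric strains past the degeneration threshold,
contradicting the documented intact null result — while axisymmetry
reproduces it; results always record the formulation used.

**Boundary conditions.** Platen contact is idealized as prescribed axial
displacement with free radial sliding (frictionless) and no flux
(impermeable); lift-off is flagged, not resolved, if the net platen
reaction becomes tensile.  The bottom is axially fixed, frictionless and
impermeable; the symmetry axis is radially fixed; free lateral and lesion
surfaces drain at ambient pressure.  The cyclic protocol applies
$\varepsilon(t) = 0.15\,\sin^2(\pi t)$ (haversine, 1 Hz) relative to the
swollen thickness, with $\Delta t = 0.025$ s (40 steps per cycle).
Three cycles per adaptive iteration are the default and the per-point
cycle maxima are taken over the final cycle.  Displacement-controlled
compression of a swollen, draining explant rides a consolidation
transient with a time constant of minutes, so peak reaction forces keep
decaying by a few percent per cycle for far longer than is practical to
simulate per adaptive iteration (the experiment cycles for an hour).
What the degeneration criteria consume is nevertheless stable: the test
suite verifies that per-point cycle maxima of the strain fields change by
under 2% per cycle, while fluid-velocity maxima inherit a ~5%/cycle decay
from the same transient — an inherent cycle-count sensitivity of the
fluid-driven mechanism that the chosen default fixes consistently across
all runs.  Scaled-down acceptance runs use two cycles.

# Degeneration algorithm

Per adaptive iteration: solve free swelling, run the cyclic protocol,
extract per-integration-point maxima of
$\varepsilon_{dev} = \tfrac13\sqrt{(\varepsilon_1-\varepsilon_2)^2+(\varepsilon_1-\varepsilon_3)^2+(\varepsilon_2-\varepsilon_3)^2}$,
$\varepsilon_{shr} = \varepsilon_{max}-\varepsilon_{min}$ (Hencky
principal strains) and $|v_{fl}|$, then apply the piecewise-constant rate
factor: $D_r = 0$ below the mechanism threshold (0.20 deviatoric, 0.50
shear, 0.04 mm/s fluid velocity), $D_r = 0.6$ between threshold and the
complete-failure value (1.0 strain, 1.5 mm/s).  Two decisions the
published description leaves open:

* **Update law.** No explicit FCD update equation is printed; we deplete
  multiplicatively, $c_{new} = (1-D_r)\,c_{old}$, once per adaptive
  iteration.  The factor is dimensionless, the update is bounded, reaches
  near-total local depletion well inside the 50-iteration budget, and is
  self-limiting because lost swelling pressure reduces the local drive.
* **Above failure.** The printed third branch reads "0 if
  $\varepsilon \le \varepsilon_{failure}$", which conflicts both with the
  second branch and with the notion of *complete failure of the ground
  substance*.  We read it as a typo for $\ge$ and deplete the point
  fully ($c_{new} = 0$); `above_failure = "zero_rate"` restores the
  literal reading.

The loop runs 50 iterations by default and stops early at a fixed point
(an iteration that triggers nothing), which makes the intact-explant null
result cheap: nothing triggers at iteration 1 and the loop ends.

# Synthetic data

Two generators stand in for laboratory data; both are labelled synthetic
and are built in code:

* `generate_synthetic_record()` simulates the stepped stress-relaxation
  protocol (10% pre-strain over 200 s + 600 s hold, then two 2.5% steps,
  30 s + 300 s each) and adds multiplicative Gaussian noise (default 1%,
  a typical load-cell specification).  It reproduces the *shape* of real
  records — transient peaks, poroelastic decay, equilibrium plateaus —
  but not instrument drift, contact seating artifacts, or biological
  variability between disks.
* The CLI `fixtures` command also emits a noisy depth-wise
  optical-density profile around the default FCD polynomial for testing
  `od_profile_to_fcd()`.

A green calibration test therefore establishes that the inverse problem
is well-posed against the model itself (identity recovery, noise
robustness), not that the printed parameter values are uniquely
recoverable from any real specimen.

# What the scaled-down acceptance runs establish

The simulation-backed acceptance criteria run on coarse meshes
(element size 0.10–0.15 mm) with two loading cycles per iteration to stay
inside CI budgets.  They establish the *qualitative* reproductions: no
FCD change in intact explants, FCD loss concentrated within 0.2 mm of
crack surfaces, and the sensitivity directions of permeability and fibril
modulus.  They do not establish mesh-converged magnitudes of localized
loss.

Two known limitations surface in this reimplementation:

* **Intact deviatoric margin.** At the default thresholds the intact
  model's peak deviatoric strain sits close to the 0.20 trigger: clearly
  below it on the coarse acceptance mesh, but approaching (and slightly
  exceeding) it in a small transitional-zone region as the mesh is
  refined.  The original study tuned its thresholds against its own
  discretization; the same property in this implementation is
  discretization-marginal, and the methods here report the mesh used.
* **Upper-corner loss.** The reference pattern shows FCD loss at the
  upper free corners in cracked samples.  In this implementation the
  corner fluid velocity — a boundary-layer quantity at the junction of an
  impermeable platen and a draining lateral surface, formally singular as
  the mesh is refined — stays below the 0.04 mm/s trigger at tractable
  resolutions, for intact and cracked geometries alike.  The
  corresponding acceptance assertion is therefore expected to fail and is
  left in place rather than weakened; the crack-localization part of the
  same criterion passes robustly.

# Default crack geometry

Injured explants show on average two surface cracks per sample, with no
published dimensions.  The default injured geometry carries two v-notch
cracks — one mid-surface (mouth at 0.7 mm, 0.4 mm deep) and one
peripheral (mouth at 1.25 mm, 0.35 mm deep), both 0.2 mm wide at the
mouth — chosen once on the grounds that unconfined injurious compression
favors peripheral cracking where tensile hoop stresses peak.  Crack
position, depth, width, inclination and profile are all configurable
through `crack_spec()`.

# Reproducibility

Runs are deterministic given a configuration; the only randomness in the
package is the synthetic-noise generator, which is seed-controlled.
Result bundles embed a provenance block (package version, formulation,
mechanism, config hash, seed).
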