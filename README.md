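# cartdegen

Mechanobiological finite-element simulation of proteoglycan loss around
cartilage lesions.

## The scientific problem

A traumatic impact cracks the articular surface; subsequent *normal*
cyclic loading then depletes proteoglycans (PGs) around the cracks,
setting the stage for post-traumatic osteoarthritis.  The measurable
proxy for PG content is the fixed charge density (FCD, mEq/ml) of the
glycosaminoglycan chains.  `cartdegen` asks: which mechanical signal —
interstitial fluid velocity, deviatoric strain, or maximum shear strain —
best explains the localized FCD loss observed around cracks in loaded
cartilage explants?

The package is for tissue biomechanicists and mechanobiology modellers
who want a self-contained, scriptable version of this class of adaptive
degeneration model without a commercial FE stack.

## The model

Cartilage is a fibril-reinforced porohyperelastic material with Donnan
swelling; the total Cauchy stress is

    sigma_tot = sigma_f + sigma_nf − Δπ I − μ_f I − T_c I

with a neo-Hookean ground substance `sigma_nf = K ln(J)/J I + G/J (F Fᵀ −
J^{2/3} I)`, tension-only collagen fibrils `sigma_f = E_f ε_f (ε_f > 0)`
arranged in a depth-dependent arcade, the Donnan osmotic pressure
`Δπ = φ_int RT √(c_FCD² + 4c_ext²) − 2φ_ext RT c_ext`, and Darcy flow
`q = −k ∇μ_f`, `v_fl = q (e+1)/e`.  A small biphasic (u–p) solver —
4-node quads, equal-order displacement/pressure with pressure-projection
stabilization, total-Lagrangian Newton, backward Euler — applies a free
swelling step followed by haversine unconfined compression (15%
amplitude, 1 Hz).

The degeneration loop then depletes FCD wherever a cycle-maximum field
exceeds its threshold (`ε_dev` > 0.20, `ε_shr` > 0.50, or `v_fl` > 0.04
mm/s), with a piecewise-constant rate factor `D_r = 0.6` between
threshold and complete failure (`ε` = 1.0, `v_fl` = 1.5 mm/s), applied
multiplicatively (`c_new = (1 − D_r) c_old`) for 50 iterations or until a
fixed point.  Intact explants trigger nothing; cracked explants lose FCD
around the lesions.

Also included: a parametric crack mesher, depth-wise composition
profiles, inverse calibration of `(E_f, E_nf, k)` from stress-relaxation
force records by Nelder–Mead on the normalized MSE, a parametric sweep
runner, and VTK/CSV/JSON output.

## Worked example

```r
library(cartdegen)
params <- material_params()
mesh <- build_explant_mesh(cracks = list(crack_spec(0.7, 0.4, 0.2)),
                           target_h = 0.12)
comp <- composition_field(mesh, params)
hist <- run_degeneration_loop(mesh, comp, params,
                              loading_protocol(n_cycles = 2),
                              degeneration_config("fluid_velocity",
                                                  n_iterations = 10))
print(hist)
summ <- degeneration_summary(hist, mesh)
cat(sprintf("near-lesion loss %.3f vs far-field %.3f\n",
            summ$near_loss, summ$far_loss))
```

prints

```
degeneration_history: 10 iteration(s), mechanism fluid_velocity
  total relative FCD loss 0.0227, max local loss 1.000
near-lesion loss 0.131 vs far-field 0.000
```

i.e. after ten adaptive iterations the explant has lost 2.3% of its total
FCD; points within 0.2 mm of the crack faces have lost 13% on average
(some fully depleted), while tissue farther than 0.6 mm away is
untouched — the localized PG-loss pattern seen experimentally around
cracks.  An intact mesh run reports exactly zero loss.

The same run is scriptable from the shell:

```sh
inst/cli/cartdegen run --outdir results --mechanism fluid_velocity
inst/cli/cartdegen sweep --parameter k --values 1.3e-3,6.5e-3
inst/cli/cartdegen calibrate --record forces.csv
```

## Layout

- `R/`, `src/` — solver, materials, geometry, degeneration, calibration
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/cartdegen-methods.Rmd` — model assumptions, numerical
  choices, design decisions, limitations
- `inst/cli/cartdegen` — command-line driver
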