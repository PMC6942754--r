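# porefield

Finite-element simulation of **carbon-nanotube-enhanced cell electroporation
under nanosecond pulsed electric fields**, in R.

High-intensity nanosecond pulses (nsPEF) permeabilize tumour-cell membranes,
but the field strengths required raise electrical-safety problems. Conductive
carbon nanotubes (CNTs) concentrate the field at their tips (the
lightning-rod effect), so adding them near cells promises the same
electroporation at lower applied fields. `porefield` is for bioelectromagnetics
modellers who want a scriptable, fully open reimplementation of that
simulation chain — field distortion → transmembrane voltage → pore dynamics →
electroporated area — without a commercial FEM product.

## The model

A five-layer dielectric cell (medium / plasma membrane / cytoplasm / nuclear
envelope / nucleoplasm; r_c = 10 µm, r_n = 5 µm) sits centred in a 200 µm
square domain between plate electrodes driven by a trapezoidal pulse
(6 kV/cm, 300 ns, 2 ns rise). The bulk obeys the quasi-static
conduction–displacement equation

    −∇·(σ∇ψ) − ∇·(ε₀εᵣ ∂ₜ∇ψ) = 0,

solved with P1 triangles and backward Euler. Each membrane is a
zero-thickness distributed-impedance interface carrying

    J = (σ_m0/d)(V_m − U_rest) + (ε₀ε_m/d) ∂V_m/∂t + J_EP ,

with duplicated contour DOFs so the potential can jump. Per interface node
the pore density N follows the asymptotic Smoluchowski-derived rate equation

    dN/dt = α e^{(V/U_ep)²} (1 − N/N₀ e^{−q(V/U_ep)²}),

and a representative pore radius evolves down the pore-energy gradient
(electric force, steric repulsion, line tension, effective surface tension);
J_EP closes the loop through a per-pore series-resistance law. CNTs are
capsule (stadium) cross-sections placed by seeded Monte Carlo rejection
sampling around the cell. Post-processing provides field-strength area
histograms, the electroporated area S(t) = ∮ πr²N dl, its time integral (the
permeabilized flux), and analytic diagnostics (Schwan transmembrane voltage,
tip-enhancement scaling).

## Worked example

```r
library(porefield)

p     <- default_params()                 # published geometry + constants
cnts  <- sample_cnts(p, seed = 42)        # 5 random CNT capsules near the cell
scene <- build_scene(p, cnts, seed = 42L)
mesh  <- build_mesh(scene)
sim   <- run_simulation(p, scene, mesh)   # coupled field + electroporation, 400 ns
print(sim)
sim_summary(sim)
```

which prints

```
<ep_sim> 553 steps to 400 ns, 81 snapshots, electroporation on
  outer membrane: max |u| 1.013 V, max N 7.44e+15 m^-2, final S 0.953 um^2/um
  inner membrane: max |u| 1.049 V, max N 4.95e+16 m^-2, final S 1.92 um^2/um
```

with the summary row (plateau snapshot at 150 ns): `maxE_domain = 3.67e6 V/m`
(36.7 kV/cm, at a CNT tip — a 6× enhancement of the applied 6 kV/cm),
`maxE_cell = 1.54e6 V/m` inside the cell, peak outer-membrane pore density
7.4e15 m⁻², transmembrane voltage clamped near 1 V by the pore conductance,
and end-of-pulse electroporated areas of 0.98 (outer) and 2.16 (inner)
µm²/µm that decay after the pulse as pores reseal. Re-running with
`n_cnts = 0` (or `cmd_compare()`) shows every poration measure is smaller
without the tubes.

Command-style front ends write a complete reproducible output bundle
(manifest with checksums, scene JSON, VTK mesh + field, membrane and
poration CSVs, histograms):

```r
cmd_run(seed = 1, out_dir = "run1")            # one scene end to end
cmd_compare(seed = 1, out_dir = "cmp")         # with vs without CNTs, matched meshes
cmd_show_ledger()                              # corrections to the published table
```

or from a shell: `Rscript inst/cli/porefield.R run --seed 1 --out run1`.

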