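---
title: "Methods: planar finite-element simulation of nanotube-enhanced cell electroporation"
author: "porefield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar finite-element simulation of nanotube-enhanced cell electroporation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porefield)
```

## The physical problem

A single spherical cell is modelled as five nested dielectrics — extracellular
medium, plasma membrane, cytoplasm, nuclear envelope, nucleoplasm — centred in
a 200 µm square domain between two plate electrodes. A trapezoidal
nanosecond pulsed electric field (nsPEF; default 6 kV/cm plateau, 300 ns
width, 2 ns rise and fall) is applied across the electrodes. Conductive
carbon-nanotube (CNT) capsules with large aspect ratios may be scattered near
the cell; their tips concentrate the field (the lightning-rod effect), which
in turn intensifies membrane electroporation. The package quantifies that
chain: field distortion → transmembrane voltage → pore creation and growth →
electroporated area and permeabilized flux, with and without CNTs.

## Governing equations

**Bulk.** The quasi-static conduction–displacement equation
$$-\nabla\!\cdot\!(\sigma\nabla\psi)\;-\;\nabla\!\cdot\!\Big(\varepsilon_0\varepsilon_r\,\partial_t\nabla\psi\Big)=0$$
holds in every bulk region with the region's conductivity and relative
permittivity. The electrodes are Dirichlet boundaries (left edge driven at
the pulse voltage, right edge grounded); the top and bottom edges carry no
normal current.

**Membranes.** Both membranes are *zero-thickness distributed-impedance
interfaces*, not meshed layers: meshing a 5 nm film inside a 200 µm domain is
intractable, and the membrane current law is exactly an interface condition.
The potential is allowed to jump across each membrane contour (duplicated
trace degrees of freedom), and the normal current between the traces is
$$J = \frac{\sigma_{m0}}{d}\,(V_m - U_\mathrm{rest}) + \frac{\varepsilon_0\varepsilon_m}{d}\,\frac{\partial V_m}{\partial t} + J_\mathrm{EP},$$
with $d$ the (geometric) membrane thickness, which enters only here. The
same law with the nuclear-envelope constants applies on the envelope.

A bookkeeping note on the resting potential: the solver evolves
$u = V_m - U_\mathrm{rest}$, the transmembrane voltage relative to rest, and
drives the pore equations with $u$. This is the only reading under which the
rest state is exactly stationary, as the model intends; since $|u|$ reaches
~1 V during the pulse while $|U_\mathrm{rest}| = 80$ mV, the distinction is
numerically minor. $U_\mathrm{rest}$ is retained in the registry.

**Pore density.** Per interface node, the asymptotic Smoluchowski-derived
rate equation
$$\frac{dN}{dt} = \alpha\, e^{(u/U_{ep})^2}\Big(1 - \frac{N}{N_0}e^{-q (u/U_{ep})^2}\Big)$$
with creation coefficient $\alpha = 10^9\,\mathrm{m^{-2}s^{-1}}$,
characteristic voltage $U_{ep} = 170$ mV, rest density
$N_0 = 1.5\times10^9\,\mathrm{m^{-2}}$ and exponent $q = 2.46$. At constant
voltage this is linear in $N$ with the closed-form fixed point
$N_\infty = N_0 e^{q(u/U_{ep})^2}$ — used both inside the integrator (exact
exponential update) and as a test oracle.

**Pore radius.** A representative pore radius per node follows the
energy-gradient flow $dr/dt = -(D/kT)\,dW/dr$ with
$$W(r) = -u^2 F_\mathrm{max}\big(r - r_h\ln(r + r_h + r_t)\big) + C_s\Big(\frac{r_*}{r}\Big)^4 + 2\pi\gamma r - \pi\delta_\mathrm{eff}r^2,$$
i.e.
$$\frac{dr}{dt} = \frac{D}{kT}\left[\frac{u^2F_\mathrm{max}}{1+r_h/(r+r_t)} + \frac{4C_s r_*^4}{r^5} - 2\pi\gamma + 2\pi\delta_\mathrm{eff}\,r\right].$$
The printed source of this energy is typographically garbled; the radius
equation is printable and self-consistent, so it is normative here and the
energy is reconstructed as its antiderivative (the two are verified against
each other by central differences in the tests). The steric coefficient
$C_s = 1.4\times10^{-19}$ J and the constant $r_t = 0.31$ nm are taken from
the asymptotic-electroporation literature because the published table omits
them; both are configurable and ledgered in `corrections_ledger()`.

With these constants the $u=0$ stationary radius is ≈ 1.15 nm (slightly above
$r_* = 0.8$ nm), so a resting membrane relaxes its representative radius
there; the configurable floor at $0.65\,r_*$ is a numerical guard only.

**Effective tension.** $\delta_\mathrm{eff}(A) = 2\sigma' - (2\sigma' -
\sigma_0)/(1-A)^2$ with $A = \pi r^2 N$ the local fractional electroporated
area (capped at 0.99); $\sigma' = 2\times10^{-2}$ J/m², $\sigma_0 =
10^{-6}$ J/m².

**Electroporation current.** $J_\mathrm{EP} = N\,u/(R_\mathrm{int} +
R_\mathrm{acc})$ per membrane area, with pore-interior resistance
$R_\mathrm{int} = d/(\sigma_p \pi r^2)$ and, in the default `"access"`
model, the electrolyte access resistance $R_\mathrm{acc} = 1/(2\bar\sigma r)$
($\bar\sigma$ = mean of the two adjacent bulk conductivities). The published
model names $J_\mathrm{EP}$ without a per-pore law; `pore_current_model:
ohmic` drops the access term.

## Discretisation

* **Mesh.** Graded point cloud (exact nodes on both membrane circles and
  every capsule boundary, structured collar rings, staggered background
  grid), Delaunay triangulation (via *deldir*; faces rebuilt from its edge
  list by 3-clique enumeration), three Laplacian smoothing rounds of the
  free points, region tagging by exact point location, and verification that
  every membrane contour is a conforming closed edge chain. Defaults:
  `h_far` 10 µm, `h_membrane` 0.35 µm, capsule caps at D/12, growth rate
  0.5, quality bound 8° minimum angle. The membrane spacing was fixed by a
  self-convergence study (plateau max field changes < 2% under h → h/2) and
  the cap spacing by tip-field convergence (D/12 within ~5% of D/24);
  both were chosen on that evidence alone.
* **Time stepping.** Backward Euler on the coupled bulk + membrane-charging
  system (unconditionally stable, first-order; verified by Richardson
  extrapolation), with the pore state frozen during the field solve and the
  field frozen during the pore update (operator splitting). Step sizes: 0.1
  ns through the pulse edges, 1 ns on the plateau and afterwards. The sparse
  symmetric system is refactorised each step by CHOLMOD factor update.
* **Pore sub-stepping.** Within each field step the density uses its exact
  exponential update (written with `expm1` — the naive form loses the whole
  increment to cancellation once $b\,h < 10^{-16}$), newly created pores
  enter at $r_*$ by area-weighted merging, and the radius takes a
  semi-implicit (derivative-damped) Euler step. Sub-steps are sized so no
  state variable changes by more than 5%, with the *net* radius rate (drift
  plus merge pull) as the controlling quantity; near stable stationary radii
  the damped update self-limits to the Newton correction, so long
  equilibration windows cost few sub-steps.

## The synthetic scene generator

`sample_cnts()` draws capsule (2D stadium) cross-sections of CNTs: centres
area-uniform in an annular band 1–15 µm outside the membrane (the published
setup places the tubes "near the cells"), orientations uniform, tip-to-tip
lengths uniform in 0.5–2 µm and diameters in 20–100 nm (aspect ratios
10–100, bracketing the cited 10 nm × 1 µm tube), five capsules per cell
(the published count). Rejection sampling enforces a 100 nm clearance
between every capsule and the cell, other capsules, the electrodes and the
walls, with a budget of 10 000 attempts per capsule; the same seed always
reproduces the same configuration, and a named substream per module keeps
CNT sampling from perturbing any other randomness.

What the generator does *not* emulate: CNT agglomeration, membrane adhesion
or uptake, three-dimensional orientation, and any distribution information
beyond "about five tubes near the cell" — the paper's own derivation of the
count is not reproducible from its stated quantities, so `n_cnts` is an
ordinary config parameter.

## Dimensionality: what the planar model can and cannot reproduce

The solved geometry is a 2D plane (a square domain with side electrodes and
a disk cross-section of the cell), the committed reading of the published
figures. Three consequences, all visible in the acceptance checks:

1. The passive steady transmembrane voltage is $2\,r_c E\cos\theta$ (cylinder
   factor 2), not the spherical $1.5\,r_c E\cos\theta$; `schwan_tmv()`
   exposes both factors.
2. Tip enhancement of a conducting capsule scales like
   $\sqrt{L/\rho_\mathrm{tip}}$ in-plane, not like the 3D field-emission
   scaling $\beta L/D$. For the cited 100:1 tube the solver finds 13×
   (and $\sqrt{L/\rho} = 14$), versus the three-dimensional 1000× figure.
3. With the published conductivities the porated cell is nearly transparent
   in-plane (interior field $1.54\,E_0$) and the conductive nucleoplasm
   funnels current through its leaky, porated envelope, so the resolved
   domain maximum sits at the nucleus poles at ≈ 15.4 kV/cm — above the
   published 7.5/7 kV/cm maxima, which match spherical factors on a mesh far
   too coarse (1354 elements) to resolve nucleus-pole peaks.

Within-model comparisons — the with/without-CNT enhancement of max field,
pore density, electroporated area and permeabilized flux — are dimensionally
robust and all reproduce: adding capsules never decreases any of them on
matched meshes.

## Degenerate inputs and numerical guards

* $|u|$ is capped at 2 V inside the pore-rate exponent (with a warning);
  in practice pore conductance clamps $|u|$ near 1 V.
* `A_frac` is capped at 0.99 before the tension closure's
  $(1-A)^{-2}$ singularity.
* Zero-amplitude pulses, zero-CNT scenes and partial simulation windows
  (`t_stop`) are all first-class.
* Exactly axis-aligned capsules can produce degenerate cocircular point
  quadruples; boundary points carry a small deterministic tangential wobble
  and the triangulator retries under a tiny global rotation if its adjacency
  check still fails.
* An infeasible packing request fails after the rejection budget with the
  achieved count in the message.

## Problem sizes

Default runs use ~1.8k mesh nodes (CNT-free) to ~4k (five capsules), 550
implicit steps to 400 ns, a few seconds per run; the 20-seed ensemble runs
in under two minutes. The convergence studies above justify these sizes.

## Known limitations

Planar geometry (above); one representative pore radius per interface node
rather than a per-pore population (the electroporated-area integrand
$\pi r^2 N$ is exactly representable, but radius *distributions* are not);
no Joule heating, electrode electrochemistry or molecular transport beyond
the flux proxy; the published rows "relative density of pores 0.15" and
"energy barrier coefficient 2.65" map to no implemented equation and are
stored unused.
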