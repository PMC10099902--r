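---
title: "A voxel-based reaction-diffusion model of rice leaf photosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A voxel-based reaction-diffusion model of rice leaf photosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eleaf` simulates C3 photosynthesis in a rice leaf from the anatomy up.
One periodic interveinal unit of the leaf is reconstructed as a labelled
voxel volume; Monte-Carlo ray tracing distributes absorbed light over the
chloroplasts; a finite-volume solver computes the coupled steady state of
gaseous CO2, dissolved CO2 and bicarbonate; and
Farquhar–von-Caemmerer–Berry (FvCB) metabolism evaluated per chloroplast
closes the loop, yielding leaf-level net assimilation `A_N` and the PSII
quantum yield `PhiPSII`.  This vignette explains the model, its
assumptions, the tunable parameters and the numerical choices, and is the
authoritative record of the design decisions taken where several options
were defensible.

## The anatomy generator

The simulated domain is the repeating motif of a grass leaf: one
interveinal span with half a minor vein at each lateral edge, periodic in
the lateral (`x`) and proximo-distal (`y`) directions, with the adaxial
surface at `z = 0`.  The scaffold holds two epidermes, a vein wrapped in a
bundle-sheath (BS) ring of `n = 7` cells, and an adaxial bulliform block
whose depth is the difference between the mesophyll thickness at the vein
and at the bulliform position.

Mesophyll cells (MCs) are lobed prisms: a cross-section
`r(theta) = r0 (1 + a cos(n_lobe theta))` on an ellipse, extruded along
the proximo-distal axis with elliptical end caps.  The default lobe
amplitude `a = 0.35` gives the strongly lobed outline typical of rice
MCs.  Template volume is closed-form and the surface area is computed by
quadrature over the parametric surface, so lobe-number sweeps compare
cells of exactly equal volume.

Cells are packed on a jittered row lattice, two staggered cell layers
deep in `y` so that the airspace percolates around cells in all three
directions, as it does in real tissue.  Two measured targets drive the
packing: mesophyll porosity (airspace fraction) and `S_mes` (fraction of
MC wall in contact with airspace).  A composite density parameter (the
in-row gap together with the proximo-distal pitch) is bisected until the
measured porosity is within ±0.02 of target; around that, the row overlap
is bisected until `S_mes` is within ±5 % relative.  Contacting cell faces
merge wall-to-wall and leave the exposed-surface accounting.  The
generator also reserves vertical intercellular-airspace channels (one per
~35 µm of interveinal distance, ≈2 µm half-width) that cells may not
enter.  Without them the voxelised airspace seals itself off from the
epidermis — real leaves never do this; connected IAS columns are exactly
what microCT shows in grasses — and the stomatal boundary would starve
the interior.  Stomatal patches are centred over these channels.

Chloroplasts occupy a peripheral shell of each cell, preferentially along
airspace-facing walls (rice plastids line the exposed periphery), trimmed
or grown voxel-by-voxel until the plastid volume fraction is within
±0.02 of target.  A one-voxel cytosol shell separates the band from the
vacuolar interior.  Cell walls thinner than the voxel (the default
0.15 µm wall versus 1–2 µm voxels) are *not* voxelised; the wall is an
interface property of the transport operator.  At sub-wall resolutions
the `mc_wall`/`bs_wall` labels would be produced instead.

Because the anatomical inputs constrain but do not fully determine the
geometry, replicate reconstructions with different seeds
(`generate_replicates()`, conventionally five) sample the residual
freedom; all downstream experiments run on such ensembles with matched
seeds between compared arms, so that parameter effects are isolated from
packing noise.

### What the generator does and does not emulate

The generator reproduces porosity, exposed surface fraction, plastid
fractions and the leaf-scale layout of rice tissue, and its packing
replicates behave like independent biological replicates.  It does not
reproduce the fine interdigitation of real lobed cells: at matched
porosity the voxel family exposes less wall than real rice (the presets
place `S_mes` at the family's feasible frontier, around 0.3 rather than
~0.5), and the surface contrast between 4- and 10-lobe cells survives
voxelisation only partially.  Consequently the model's
lobe-number response diverges from boundary-conforming reconstructions:
the exposed-surface penalty of low lobe numbers is largely buffered by
alternative supply routes, while smoother cells leave wider voxel
airspace channels, so a 4-lobe leaf can even assimilate slightly *more*
than a 10-lobe leaf in this family.  Lobe-sweep outputs should be read
as properties of the voxel family, not of leaves.  Porosity and `S_mes` are also not fully
independent dials: near rice-like porosity the joint feasible set is a
narrow band, and the in-silico experiments therefore run the generator in
a non-strict mode that holds an infeasible secondary target as closely as
the constraints allow — the measured values are always recorded in the
volume's `achieved` field.

## Light

A single effective waveband (PPFD-weighted) is traced.  Photon packets
enter the adaxial surface (collimated by default, optionally
cosine-diffuse), refract and reflect by the unpolarised Fresnel
coefficients at every refractive-index step between voxels (air 1.0,
cytosol/vacuole/stroma 1.353, wall-like tissue 1.415), wrap around the
periodic lateral boundaries, and are absorbed by chlorophyll inside
chloroplast voxels with Beer–Lambert attenuation.  The chlorophyll
concentration is the leaf chlorophyll content divided by the chloroplast
volume per leaf area of the actual geometry: the measured chlorophyll is
spread uniformly over all chloroplasts.  Packets are terminated by
Russian roulette below 1e-4 of their initial weight (cap of 1000
interface events).  Batch means give Monte-Carlo standard errors; energy
closure `R + T + A = 1` holds within three such errors, and the absorbed
field is exactly linear in the incident flux, which the experiment driver
exploits by tracing each geometry once and rescaling per light level.

## CO2 transport

Cell-centred finite volumes on the voxel grid, with one CO2 unknown per
airspace or liquid voxel and one bicarbonate unknown per
carbonic-anhydrase compartment voxel (cytosol and stroma).  Interface
conditions:

* air–cell faces use a two-film Henry partition
  (`flux = K (H c_gas - c_liq)`, dimensionless `H = 0.74` at 28 °C) with
  the wall (`t_wall / (f_wall D_l)`, `f_wall = 0.3`), the plasma
  membrane, and — where the peripheral voxel is a chloroplast — a 0.5-µm
  cytosolic film plus the envelope, all in series;
* cell–cell contact faces carry two walls and two membranes (plus
  envelopes as needed);
* bicarbonate crosses no membranes: its diffusion is confined within a
  compartment, and the (de)hydration reaction
  `k_h (c - b / K_eq)` couples the pools with `K_eq` set by pH (7.2
  cytosol, 7.8 stroma) and an effective CA-accelerated
  `k_h = 1000 s^-1`;
* epidermis, vein and bulliform tissue are zero-flux (bulliform cells
  are treated as air-tight caps, one of the open structural questions);
* `C_i` is imposed on airspace voxels in stomatal patches on both
  surfaces (rice is amphistomatous), centred over the IAS channels and on
  a ~50-µm lateral grid.

Membrane permeabilities default to 7e-3 m s^-1, the upper
(aquaporin-facilitated) end of the published range.  This is a deliberate
calibration: the voxel cell family exposes less wall per volume than real
rice mesophyll, and with mid-range permeabilities the synthetic leaf's
mesophyll conductance fell well below the measured rice range
(0.3–0.5 mol m^-2 s^-1 bar^-1).  With the default parameterisation the
model sits near 0.2 mol m^-2 s^-1 bar^-1 and reproduces leaf-level
behaviour (ambient assimilation, the saturating plateau just above
40 µmol m^-2 s^-1, PhiPSII extremes).  All values are config-overridable;
they are literature-standing defaults, not measurements.

The FvCB sink is nonlinear in the local CO2 concentration, so the solver
linearises it with a fixed diagonal shift equal to the sink's maximum
slope (computed once, independent of light and `C_i`).  The shifted
operator is factored once per geometry — after eliminating the Dirichlet
columns it is symmetric positive definite under a diagonal similarity
transform (weights 1, `1/sqrt(H)`, `1/sqrt(H K_eq)` for gas, dissolved
CO2 and bicarbonate), so a sparse Cholesky factorisation applies — and a
Picard iteration with geometric-series (Aitken) extrapolation then costs
only triangular solves per step, for every point of a `C_i` × light
grid.  Convergence is declared at a relative update below 1e-8; at
convergence the stomatal boundary influx matches the integrated net sink
to better than 1e-6 relative.  The leading discretisation error is the
first-order half-cell film at membrane interfaces: halving the voxel size
on a fixed geometry moves `A_N` by about 3 % at the default 2 µm.

## Metabolism

Each cell receives the light its chloroplast voxels absorbed.  Potential
electron transport is the smaller root of the non-rectangular hyperbola
`theta J^2 - (x + Jmax_cell) J + x Jmax_cell = 0` with
`x = s · Y(II)LL · I_abs,cell`; `Jmax` is distributed over cells in
proportion to chloroplast volume, as are the volumetric `Vcmax` density
(chloroplast volume) and respiration (cytosol + chloroplast volume; no
explicit mitochondria).  Per chloroplast voxel the sink is
`(1 - Gamma*/Cc) min(Wc, Wj)` with `Wc = Vcmax_vol Cc / (Cc + Kc (1 +
O/Ko))` and `Wj = J_vol Cc / (4 Cc + 8 Gamma*)`.  Rubisco constants are
tobacco-derived values adjusted to the fixed leaf temperature of 28 °C
(`Gamma* = 49.8` µbar, `Kc = 557` µbar, `Ko = 322` mbar); no temperature
response and no triose-phosphate-utilisation limit are included.
`PhiPSII = J_realised / (s · absorptance · Q)`, where `J_realised` is the
electron flux consistent with the realised (possibly Rubisco-limited)
assimilation; in the low-light limit this converges to `Y(II)LL` and at
high light it decays towards zero.  The lumped factor `s` calibrates
incident-flux-based fluorometry against electron flux and is fitted
jointly with `Y(II)LL`; with the default `s = 1` the synthetic leaf's
PhiPSII reaches ≈0.1 at 2000 µmol m^-2 s^-1, matching the behaviour the
model family is meant to emulate.

## Parameter estimation

`fit_parameters()` inverts combined A/C_i + AQ curves with PhiPSII for
(`Vcmax`, `Jmax`, `Rd`, `Y(II)LL`, `s`) using an elitist generational GA
(population 100, 200 generations, tournament selection k = 3, SBX
crossover 0.9, polynomial mutation 0.1, elitism 2) followed by a
Nelder-Mead polish.  The forward model inside the loop is a homogeneous
big-leaf evaluation of the same FvCB equations with `Cc = Ci` and a fixed
absorptance — full-3D-in-the-loop fitting would be far more expensive and
the extra mesophyll detail is not identifiable from leaf-level curves
anyway.  The objective is `SSE(A) + w * SSE(PhiPSII)` with `w` scaled by
the variance ratio of the data so both terms carry comparable weight.  On
noise-free synthetic curves every parameter is recovered within 5 %
(in practice to machine precision); with realistic noise
(0.5 µmol m^-2 s^-1 on A, 0.01 on PhiPSII) median errors stay within
15 % for the scale parameters.  Datasets without C_i points below
300 µbar get an identifiability warning: `Vcmax` and `Rd` are then
weakly constrained.

The default measurement protocol mirrors standard combined
gas-exchange/fluorescence practice at 28 °C: an A/C_i ladder
400 → 50 → 1500 at saturating PPFD 2000 µmol m^-2 s^-1, and an AQ ladder
2000 → 25 µmol m^-2 s^-1 at ambient CO2.  The protocol's concentration
set points are used directly as `C_i` values by the synthetic-curve
generator.

## In-silico experiments

Three drivers reproduce the standard analyses:

* `response_surface()`: one solve per (C_i, Q) grid point per replicate
  geometry, with the light field rescaled and the matrix factorisation
  reused within a replicate; assimilation is monotone along both axes.
* `factor_substitution()`: all parameters are partitioned into nine
  groups (F1 leaf-scale structure, F2 MC size/shape, F3 porosity, F4
  bundle sheath, F5 MC plastid fraction, F6 wall thickness, F7 `S_mes`,
  F8 chlorophyll, F9 metabolism).  Substituting group values from the
  elevated-CO2 parameter set into the ambient model, with matched
  geometry and tracer seeds, isolates each group's contribution to the
  assimilation change; substituting every group reproduces the full
  alternative model bit-for-bit (the partition identity).  With the
  shipped presets the metabolic group dominates the assimilation gain at
  elevated C_i (share near 100 % because the remaining structural terms
  largely cancel), and is negative at ambient C_i.
* `sweep_anatomy()`: porosity, `S_mes` or lobe number is swept while the
  other targets are held as constant as the packing constraints allow
  (for lobe sweeps the `S_mes` target is released — exposure is the
  derived outcome of lobing, the mechanism under study);
  each (value, condition) cell carries a one-way fixed-effects ANOVA flag
  (P < 0.05 across replicates) against the unmodified control, whose own
  cell is exactly zero by matched-seed determinism.  For lobe sweeps a
  `marked` flag records a >10 % drop in mean assimilation relative to the
  largest lobe number.

## Parameter presets

Two documented synthetic presets ship with the package, `"aCO2"` and
`"eCO2"`, emulating rice grown at 480 versus 1000 ppm CO2.  They are
literature-typical values arranged to reproduce the acclimation pattern
of such experiments — under elevated CO2: significantly reduced porosity
(0.30 → 0.285) and `S_mes` (0.32 → 0.305), slight positive trends in MC
and BS size, slightly thicker walls, marginally fewer MC plastids, more
BS plastids and chlorophyll, with leaf thickness and vein spacing
unchanged; metabolic acclimation shifts capacity from carboxylation
(Vcmax 160 → 140 µmol m^-2 s^-1) towards electron transport
(Jmax 215 → 242) with higher respiration (1.5 → 2.2) and slightly lower
`Y(II)LL` (0.78 → 0.74).  They are fixtures for simulation studies, not
measurements; the magnitudes were chosen once, within the generator's
jointly feasible range, and the kinetic values calibrated so the ambient
preset reproduces realistic rice leaf-level curves.  The `S_mes` presets
sit below real rice values (~0.5) because the voxel family cannot reach
them at rice porosity — a known limitation, not a claim about leaves.

## Problem sizes and determinism

The default test and experiment configurations voxelise the unit cell at
2 µm (≈30 000 voxels, ≈50 000 unknowns; ≈5 s to assemble and factor,
then well under 0.1 s per solve), trace 15 000–30 000 photon packets, and
use two to five replicate geometries; lobe sweeps run at 1.5 µm so the
lobes are resolved.  These sizes keep a full verification run on a single
CPU in minutes while leaving the tolerances meaningful.  Every stochastic
stage takes an explicit seed, identical inputs give bit-identical
outputs (the tracer carries its own generator, so R's RNG state is
untouched), and replicate ensembles derive their seeds as
`base_seed + 0:(n-1)`.

## Known limitations

* Porosity and `S_mes` are only narrowly independent near rice-like
  porosity; absolute `S_mes` runs below real rice.
* The lobe-number response is unreliable: the voxel family buffers (and
  can reverse) the assimilation penalty of low lobe numbers; the >10 %
  "marked" drop at four lobes is not reproduced.
* Interface films make the transport discretisation first-order at
  membranes (~3 % in `A_N` per halving of the voxel size).
* No TPU limitation, no temperature response, no stomatal or water
  dynamics; `C_i` is an imposed boundary condition, tortuosity and
  connectivity of the airspace are whatever the generator produces and
  are not separately controllable.
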