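---
title: "Minimum-distance solvation analysis: model, estimators and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-distance solvation analysis: model, estimators and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvkit)
```

## The model

solvkit measures how solvent species organize around a molecular solute
in a periodic (orthorhombic) box. The central observable is the
*minimum-distance distribution function* (MDDF). For each solvent
molecule in each configuration we record

- `rmin`: the minimum, over all (solute atom, solvent atom) pairs, of the
  minimum-image distance, and
- the realizing atom pair.

Hydrogens are included on both sides: hydrogen-bond contacts appear near
1.9 Å and would be invisible to heavy-atom-only or center-of-mass
distances. For a monatomic solvent the molecular minimum reduces to a
single-site distance and the MDDF becomes the classical proximal
distribution function.

Counts are accumulated into half-open bins `[lo, hi)` of width 0.1 Å out
to 30 Å and averaged over frames. The MDDF is

    g(r) = n(r) / n*(r),

where `n*(r)` comes from a *reference state*: `nRandomFactor` rigid
replicas of each solvent molecule (shape taken from the frame, orientation
uniform over rotations) placed uniformly at random in the same box, their
minimum distances to the solute histogrammed identically, and the counts
rescaled to the bulk density. Around an irregular solute the
minimum-distance "shells" have no closed-form volume; the reference count
divided by the placement density is the Monte-Carlo estimate of the shell
volume V(r), and this estimate — not an analytic 4πr²Δr — normalizes
every density in the package. For a point solute the two agree, which is
one of the test oracles.

On the same grid the Kirkwood–Buff integral is evaluated as

    G(R) = (N(R) - N*(R)) / rho_c,

with `N(R)` the cumulative minimum-distance count, `N*(R)` the cumulative
reference count rescaled to the bulk density `rho_c`, and `rho_c`
measured in the 20–30 Å minimum-distance shell — an open subvolume far
from the solute, which corrects the finite-size depletion of the bulk
when the solute domain holds a non-negligible share of the solvent.
`G(R)` converges once R exceeds the range over which the solute perturbs
the solution (the *solute domain*, default 20 Å); convergence is flagged
from `|G(20) - G(30)|`.

The preferential-solvation parameter compares a cosolvent with water:

    Gamma(R) = rho_c * (G_pc(R) - G_pw(R)),

positive when the cosolvent accumulates at the solute surface at water's
expense. When several ionic species form the cosolvent, bulk
electroneutrality makes their merged ("pseudo-component") treatment the
default: `mergePseudoComponents()` concatenates record sets and the
merged bulk density is the sum of the components'. The charged-solute
correction to Gamma is intentionally out of scope; the package targets
net-neutral solutes.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `binWidth` | 0.1 | Å | resolves hydrogen-bond peaks (~1.9 Å) with ~20 bins |
| `rMax` | 30 | Å | outer edge of the bulk shell; must be ≤ min(box side)/2 |
| `Rdomain` | 20 | Å | solute-domain radius where G is read off; large ionic cosolvents perturb the solution unusually far |
| `bulkShell` | [20, 30] | Å | bulk-density estimate outside the solute domain |
| `nRandomFactor` | 10 | — | reference sampling noise is ~1/10 of the counts' noise |
| `cutoff` (coordination) | 5 | Å | first-shell contact count |
| hydration radii | 5, 10 | Å | first shell and first-plus-second shell of an ion |
| replicas | caller's choice | — | SEMs are computed across frames of one run and across replicas in the pipeline; real trajectories have correlated frames, so replica-level SEMs are the honest ones there |

All distance cutoffs are validated against the minimum-image bound
min(side)/2; violating requests error rather than silently wrapping.

## The synthetic generator

`buildIdealGasSystem()`, `buildExcludedShellSystem()` and
`buildProfileSystem()` draw *independent* frames (no dynamics): the
analysis is purely configurational averaging, and independent frames
maximize statistical power per frame. Each species follows a
piecewise-constant radial enrichment λ(r) around the box center —
`rho_bulk * lambda(r)` with λ = 0 below an exclusion radius, user values
on given intervals, and λ = 1 beyond — sampled exactly by inverse-CDF in
r inside the profiled sphere plus uniform placement outside it
(exclusion-only systems use plain rejection). Multi-atom species are
rigid templates (3-site bent water, 2-site ion) with orientations uniform
over rotations; the optional pairing flag places each cation within a
fixed radius of an anion for local electroneutrality (the cation's own
profile is then ignored). Reproducibility: one integer seed, with frame
`k` drawing from stream `seed + k`, so identical recipes serialize
byte-identically and frames could be generated in parallel.

What this emulates — and what it does not. The generator reproduces the
*statistical structure* the estimators consume: exclusion volumes,
enrichment shells, species mixtures, local ion pairing. It has no forces,
no Boltzmann sampling, no frame-to-frame correlation, no conformational
flexibility, and its profiles are exact only around a point-like solute.
Passing tests therefore validate the estimators (binning, reference
construction, normalization, integrals, decompositions) — not any claim
about real solvent physics, force fields or sampling quality of real
trajectories.

Closed-form oracles used in the tests:

- ideal gas: g ≡ 1, G(R) → 0, Γ → 0;
- exclusion radius d: G(R→∞) = −(4/3)πd³ (−268.1 Å³ at d = 4);
- λ = 2 on [4, 6] Å over an exclusion at 4: G(20) = 4π/3(6³−4³) −
  4π/3·4³ = 368.6 Å³, and Γ(20) = ρ_c · 368.6;
- uniform bath: coordination and hydration counts ρ·(4/3)πc³.

The hydration closed form is exact for *point* solvent sites; a
multi-atom molecule is counted when any atom lies within the radius, so
its capture region is a dilated sphere and the count exceeds
ρ·(4/3)πr³ — a property of the any-atom definition, not an estimator
error.

## Numerical choices

- **Bins** are half-open, left-closed; a distance exactly at `rMax` is
  excluded. Bin assignment adds 1e-9 to r/Δr before flooring so a
  distance sitting on a bin edge lands deterministically in the upper
  bin despite floating-point division.
- **Ties** in the minimum distance break to the lower solute atom index,
  then the lower solvent atom index, making records fully deterministic.
- **Oracle equality.** The cell-list kernel (C++) and the exhaustive
  pure-R scan compute displacement components as
  `dx - box * round(dx/box)` with round-half-to-even in both languages
  and identical summation order, with floating-point contraction
  disabled in the compiled code; the two paths agree *bitwise*,
  realizing atom pairs included, which the tests assert with
  `identical()` rather than a tolerance.
- **Censoring.** Molecules with no solute atom within `rMax` yield a
  record with `rmin = NA` (one record per molecule per frame, always);
  downstream statistics only query r ≤ `rMax`, so censoring is lossless.
- **Zero-reference bins** (innermost bins around a point solute have
  vanishing shell volume) are flagged undefined and reported as NA,
  never divided.
- **Degenerate inputs.** Zero-count species histogram to zeros with a
  warning; a zero bulk-shell count gives density 0 with a warning; a
  zero shell volume is an error. Exclusion radii with rejection
  acceptance below 1% error out with advice.
- **Attribution** of each count to the single realizing pair (no
  fractional sharing) makes every decomposition an exact partition:
  contribution curves sum to the total MDDF to 1e-12, residue maps
  marginalize back to the species histogram exactly, and difference maps
  are exactly antisymmetric.

## Design decisions that were genuinely open

- *Reference construction.* Random rigid re-insertion of the frame's own
  molecules (shapes from the trajectory) rather than fixed idealized
  geometries; for rigid synthetic solvents the two coincide, and for
  real data re-insertion preserves the conformer population.
- *Solute molecule grouping.* One molecule per chain for the solute
  (solvents: one per residue block). Solute molecule identity never
  enters the statistics — all solute atoms join the distance search — so
  the coarser grouping was chosen to keep species-template validation
  meaningful.
- *Internal indexing* is 1-based throughout (R idiom), 1-based in PDB
  serialization too.
- *Trajectory formats.* XYZ (with the box on the comment line) and DCD
  with an orthorhombic unit cell; XTC is rejected with a clear error, as
  no R-level reader exists. Coordinates are Å everywhere.
- *Hydration distance definition.* "Within a radius of an ion" uses the
  any-atom molecular minimum distance, consistent with the MDDF's
  geometry.
- *Maps.* Residue × distance matrices are the quantitative core behind
  3D surface-painted density figures; the painting/smoothing step is
  presentation, not measurement, and is out of scope.

## Problem sizes in the shipped tests

Unit tests run systems of 50–2 500 molecules over 2–60 frames (seconds);
the statistical validation suite uses up to 3 000 molecules × 400 frames
(~10⁶ minimum-distance samples per system) so that Monte-Carlo 3σ bounds
on G(20 Å) are a few tens of Å³. All bounds are derived from the data
(per-frame spread plus propagated bulk-density uncertainty), never fitted
constants.

## Known limitations

- Orthorhombic boxes only; triclinic cells are rejected.
- No charged-solute Γ correction: results assume a net-neutral solute.
- Frames are treated as independent when SEMs are computed within a run;
  for correlated real trajectories, use replicas (the pipeline's
  replica-level SEM) instead.
- The reference state samples positions and orientations, not solvent
  conformers beyond those present in the frame.
- Minimum-distance KB integrals inherit the estimator's slow Monte-Carlo
  convergence with R³; the bulk-shell density correction mitigates but
  does not remove finite-size effects.
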