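# solvkit

Solvation-structure analysis for molecular solutes from simulation
configurations: **minimum-distance distribution functions (MDDFs)**,
**Kirkwood–Buff (KB) integrals**, **preferential-solvation parameters**,
coordination numbers and ion hydration numbers — with a
synthetic-configuration generator whose statistics are known in closed
form, so every estimator ships with an analytic or brute-force oracle.

## Who this is for

Researchers studying how cosolvents (ionic-liquid ions, osmolytes, salts)
organize around proteins or other irregular solutes in aqueous mixtures.
Center-of-mass radial distribution functions blur short-range structure
around large molecules; the MDDF instead bins, for each solvent molecule,
the *minimum* distance between any of its atoms and any solute atom, so
the distribution follows the molecular surface and hydrogen-bonding peaks
near 2 Å stay visible.

## The quantities

For solvent species *c* around solute *p*, with half-open 0.1 Å bins of
the minimum distance *r*:

- **MDDF**: g(r) = n(r) / n\*(r), where n(r) is the mean per-frame count of
  solvent molecules at minimum distance r and n\*(r) the same count in a
  reference state — solvent placed uniformly at random at the bulk density
  with no solute–solvent interactions. The reference simultaneously
  provides a Monte-Carlo estimate of the minimum-distance shell volumes
  V(r), which have no closed form around an irregular solute.
- **KB integral**: G\_cp(R) = (N\_cp(R) − N\*\_cp(R)) / ρ\_c, with N\_cp(R)
  the number of minimum distances below R, N\*\_cp(R) the reference count
  rescaled to the bulk density ρ\_c, measured in the 20–30 Å shell (a
  finite-size correction). G converges once R exceeds the solute's
  perturbation range (the "protein domain", 20 Å by default):
  net accumulation gives G > 0, depletion G < 0.
- **Preferential solvation**: Γ\_pc(R) = ρ\_c (G\_pc(R) − G\_pw(R)).
  Positive Γ means the cosolvent displaces water at the solute surface.
- **Coordination number**: mean count of molecules with minimum distance
  below a cutoff (5 Å default). **Hydration number**: mean count of water
  molecules within a fixed radius of each ion, binned by that ion's
  distance to the solute.

Every count is attributed to the realizing (solute atom, solvent atom)
pair, so the MDDF decomposes exactly by solvent atom name, solute residue
or residue class, and residue × distance maps (and species difference
maps) come for free.

## Worked example

A rigid 4-residue toy solute in a 64 Å periodic box, with a DCA-like
cosolvent enriched twofold in the 4–6 Å shell (excluded below 4 Å) plus
uniform water:

```r
library(solvkit)

recipe <- systemRecipe(
  box     = c(64, 64, 64),
  species = list(
    profileSpec("DCA",   500, exclusion = 4, breaks = 6, lambda = 2),
    profileSpec("water", 1500)),
  solute  = buildToySolute(4, c("acidic", "basic", "polar", "nonpolar")),
  nFrames = 100, seed = 42)
sys <- buildProfileSystem(recipe)

recs <- minimumDistances(sys$frames, sys$topology, "DCA", rMax = 30)
hist <- accumulateHistogram(recs, sys$topology)
ref  <- referenceCounts(sys$frames, sys$topology, "DCA", seed = 43)
bd   <- bulkDensity(hist, ref)

computeMddf(hist, ref, bd$rho)
#> MDDF [DCA]: 300 bins, bulk density 0.001882 Å^-3
#>   max g(r) = 1.98 at r = 4.65 Å
kbIntegral(hist, ref, bd$rho)
#> KBI [DCA]: G(20 Å) = 958.8 Å^3 (0.5774 L/mol), converged
```

The MDDF plateaus at the generator's enrichment factor (g ≈ 2 inside the
4–6 Å shell) and the positive converged KB integral quantifies the net
accumulation of the cosolvent in the solute domain; with the water KBI
and `preferentialSolvation()` this yields Γ(20 Å) > 0, i.e. the
cosolvent preferentially solvates the toy solute. `coordinationNumber()`
reports 2.68 ± 0.16 DCA molecules within 5 Å of this solute.

For a one-shot run (generation → records → MDDF → KBI/Γ → coordination →
hydration → maps, with per-replica SEMs and TSV/JSON outputs) use
`runPipeline("config.yaml")` or the wrapper
`Rscript inst/scripts/solvkit.R run config.yaml`.

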