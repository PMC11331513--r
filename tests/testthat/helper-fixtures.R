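# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# point solute + one point solvent species, uniform (ideal gas)
idealPointSystem <- function(n = 1500, frames = 40, box = 64, seed = 101) {
  rec <- systemRecipe(box = rep(box, 3),
                      species = profileSpec("S", n),
                      nFrames = frames, seed = seed)
  buildIdealGasSystem(rec)
}

# full analysis of a one-species point system: records, hist, ref
analyzePointSystem <- function(sys, tag = "S", rMax = 30, factor = 10,
                               refSeed = 999) {
  recs <- minimumDistances(sys$frames, sys$topology, tag, rMax = rMax)
  hist <- accumulateHistogram(recs, sys$topology, rMax = rMax)
  ref <- referenceCounts(sys$frames, sys$topology, tag,
                         nRandomFactor = factor, seed = refSeed,
                         rMax = rMax)
  list(records = recs, hist = hist, ref = ref)
}

# minimal hand-built topology: one-atom solute + n point solvent molecules
pointTopology <- function(nSolvent, tag = "S") {
  buildTopology(atom_name = c("CA", rep("X", nSolvent)),
                residue_name = c("GLY", rep(tag, nSolvent)),
                residue_number = c(1, seq_len(nSolvent)),
                chain = c("A", rep("S", nSolvent)))
}

# Monte-Carlo sigma for a KB integral estimate at R: the per-frame spread
# of G(R) plus, when the bulk density was measured from the shell, its
# uncertainty propagated through N(R)/rho ~ Vcum(R).
kbiSigma <- function(kbiRes, ref, bd = NULL, R = 20) {
  i <- which.min(abs(kbiRes@R - R))
  semG <- kbiRes@sem[i]
  if (is.null(bd) || !is.finite(bd$sem)) return(semG)
  vcum <- sum(siteVolumes(ref)[seq_len(i)])
  sqrt(semG^2 + (vcum * bd$sem / bd$rho)^2)
}
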