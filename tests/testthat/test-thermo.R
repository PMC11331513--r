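test_that("bulk density recovers the generator density from the shell", {
  sys <- fixture("ideal_kbi", function()
    idealPointSystem(n = 2000, frames = 40, box = 64, seed = 601))
  an <- fixture("ideal_kbi_an", function()
    analyzePointSystem(fixture("ideal_kbi", function()
      idealPointSystem(n = 2000, frames = 40, box = 64, seed = 601))))
  bd <- bulkDensity(an$hist, an$ref)
  rho0 <- 2000 / 64^3
  expect_lt(abs(bd$rho - rho0), 3 * bd$sem)
  expect_equal(bd$molar, bd$rho / (6.02214076e23 * 1e-27))
  expect_error(bulkDensity(an$hist, an$ref, shell = c(20, 60)), "rMax")
})

test_that("shells outside the minimum-image region are rejected upstream", {
  sys <- fixture("ideal_kbi", function()
    idealPointSystem(n = 2000, frames = 40, box = 64, seed = 601))
  # a [20, 60] shell on a 95 A box would need rMax = 60 > min(side)/2
  expect_error(minimumDistances(sys$frames[[1]], sys$topology, "S",
                                rMax = 60), "minimum-image")
})

test_that("a species absent from the shell gives zero density, warned", {
  topo <- pointTopology(2)
  recs <- data.frame(frame = 1L, species = "S", molecule = 2:3,
                     rmin = c(3, 5), solute_atom = 1L, solvent_atom = 2:3)
  attr(recs, "rMax") <- 30; attr(recs, "nFrames") <- 1L
  attr(recs, "boxVolume") <- 64^3
  h <- accumulateHistogram(recs, topo)
  sysR <- fixture("ideal_kbi", function()
    idealPointSystem(n = 2000, frames = 40, box = 64, seed = 601))
  ref <- fixture("ideal_kbi_an", function()
    analyzePointSystem(fixture("ideal_kbi", function()
      idealPointSystem(n = 2000, frames = 40, box = 64, seed = 601))))$ref
  expect_warning(bd <- bulkDensity(h, ref), "zero")
  expect_equal(bd$rho, 0)
})

test_that("the ideal gas has a statistically zero KB integral at 20 A", {
  an <- fixture("ideal_kbi_an", function()
    analyzePointSystem(fixture("ideal_kbi", function()
      idealPointSystem(n = 2000, frames = 40, box = 64, seed = 601))))
  bd <- bulkDensity(an$hist, an$ref)
  k <- kbIntegral(an$hist, an$ref, bd$rho)
  expect_lt(abs(kbiAt(k, 20)), 3 * kbiSigma(k, an$ref, bd))
  # G(0) = 0 by construction
  expect_equal(k@G[1], siteCounts(an$hist)[1] / bd$rho -
                 siteVolumes(an$ref)[1])
})

test_that("KB integrals match the quadrature of (lambda - 1) r^2", {
  # random piecewise-constant enrichment around a point solute
  set.seed(4)
  breaks <- sort(round(runif(2, 4, 12), 1))
  lam <- round(runif(2, 0.3, 2), 2)
  sys <- buildProfileSystem(systemRecipe(
    box = c(64, 64, 64),
    species = profileSpec("S", 2500, exclusion = 3, breaks = breaks,
                          lambda = lam),
    nFrames = 60, seed = 602))
  an <- analyzePointSystem(sys, factor = 10, refSeed = 603)
  bd <- bulkDensity(an$hist, an$ref)
  k <- kbIntegral(an$hist, an$ref, bd$rho)
  quad <- function(R) {
    iv <- data.frame(lo = c(0, 3, breaks[1]),
                     hi = c(3, breaks[1], breaks[2]),
                     lambda = c(0, lam))
    iv$hi <- pmin(iv$hi, R)
    iv <- iv[iv$lo < iv$hi, ]
    sum((iv$lambda - 1) * 4 * pi / 3 * (iv$hi^3 - iv$lo^3))
  }
  sig <- kbiSigma(k, an$ref, bd)
  for (R in c(10, 15, 20))
    expect_lt(abs(kbiAt(k, R) - quad(R)), 3 * sig)
})

test_that("merging pseudo-components is a count identity", {
  sys <- fixture("two_species", function() buildProfileSystem(systemRecipe(
    box = c(64, 64, 64),
    species = list(profileSpec("AN1", 700, exclusion = 3, breaks = 6,
                               lambda = 2),
                   profileSpec("AN2", 500),
                   profileSpec("water", 1200, template = "water")),
    nFrames = 25, seed = 604)))
  r1 <- minimumDistances(sys$frames, sys$topology, "AN1")
  r2 <- minimumDistances(sys$frames, sys$topology, "AN2")
  merged <- mergePseudoComponents(r1, r2, tag = "cosolvent")
  expect_equal(nrow(merged), nrow(r1) + nrow(r2))
  expect_true(all(merged$species == "cosolvent"))
  expect_error(mergePseudoComponents(r1, r1), "overlap")

  # with a shared reference, the merged KBI is the density-weighted mean
  ref <- referenceCounts(sys$frames, sys$topology, "AN1",
                         nRandomFactor = 6, seed = 605)
  h1 <- accumulateHistogram(r1, sys$topology)
  h2 <- accumulateHistogram(r2, sys$topology)
  hm <- accumulateHistogram(merged, sys$topology)
  rho1 <- expectedBulkDensity(sys$recipe, "AN1")
  rho2 <- expectedBulkDensity(sys$recipe, "AN2")
  k1 <- kbIntegral(h1, ref, rho1)
  k2 <- kbIntegral(h2, ref, rho2)
  km <- kbIntegral(hm, ref, rho1 + rho2)
  expect_lt(max(abs(km@G - (rho1 * k1@G + rho2 * k2@G) / (rho1 + rho2))),
            1e-8)
})

test_that("electroneutral pairing equalizes cation and anion integrals", {
  sys <- buildProfileSystem(systemRecipe(
    box = c(64, 64, 64),
    species = list(profileSpec("CAT", 1200, role = "cation"),
                   profileSpec("AN1", 800, role = "anion", exclusion = 3,
                               breaks = 6, lambda = 3),
                   profileSpec("AN2", 400, role = "anion")),
    nFrames = 60, seed = 606, pairing = TRUE, pairRadius = 3))
  rc <- minimumDistances(sys$frames, sys$topology, "CAT")
  ra <- mergePseudoComponents(
    minimumDistances(sys$frames, sys$topology, "AN1"),
    minimumDistances(sys$frames, sys$topology, "AN2"), tag = "anions")
  ref <- referenceCounts(sys$frames, sys$topology, "CAT",
                         nRandomFactor = 8, seed = 607)
  hc <- accumulateHistogram(rc, sys$topology)
  ha <- accumulateHistogram(ra, sys$topology)
  bdc <- bulkDensity(hc, ref)
  bda <- bulkDensity(ha, ref)
  kc <- kbIntegral(hc, ref, bdc$rho)
  ka <- kbIntegral(ha, ref, bda$rho)
  tol <- 3 * sqrt(kbiSigma(kc, ref, bdc)^2 + kbiSigma(ka, ref, bda)^2)
  expect_lt(abs(kbiAt(kc, 20) - kbiAt(ka, 20)), tol)
})

test_that("Gamma is zero for equal integrals and positive for enrichment", {
  an <- fixture("ideal_kbi_an", function()
    analyzePointSystem(fixture("ideal_kbi", function()
      idealPointSystem(n = 2000, frames = 40, box = 64, seed = 601))))
  k <- kbIntegral(an$hist, an$ref)
  g0 <- preferentialSolvation(k, k)
  expect_true(all(g0@gamma == 0))

  sys <- fixture("two_species", function() buildProfileSystem(systemRecipe(
    box = c(64, 64, 64),
    species = list(profileSpec("AN1", 700, exclusion = 3, breaks = 6,
                               lambda = 2),
                   profileSpec("AN2", 500),
                   profileSpec("water", 1200, template = "water")),
    nFrames = 25, seed = 604)))
  rAn <- minimumDistances(sys$frames, sys$topology, "AN1")
  rW <- minimumDistances(sys$frames, sys$topology, "water")
  hA <- accumulateHistogram(rAn, sys$topology)
  hW <- accumulateHistogram(rW, sys$topology)
  refA <- referenceCounts(sys$frames, sys$topology, "AN1",
                          nRandomFactor = 6, seed = 608)
  refW <- referenceCounts(sys$frames, sys$topology, "water",
                          nRandomFactor = 6, seed = 609)
  kA <- kbIntegral(hA, refA)
  kW <- kbIntegral(hW, refW)
  gam <- preferentialSolvation(kA, kW)
  expect_gt(gammaAt(gam, 20), 0)

  kShort <- kbIntegral(accumulateHistogram(rAn, sys$topology, rMax = 20),
                       referenceCounts(sys$frames, sys$topology, "AN1",
                                       nRandomFactor = 4, seed = 610,
                                       rMax = 20),
                       bulkShell = c(12, 20))
  expect_error(preferentialSolvation(kShort, kW), "grids")
})

test_that("coordination numbers follow closed forms and are monotone", {
  # excluded shell beyond the cutoff: zero coordination
  sysE <- buildExcludedShellSystem(systemRecipe(
    box = c(44, 44, 44), species = profileSpec("S", 400, exclusion = 6),
    nFrames = 10, seed = 611))
  rE <- minimumDistances(sysE$frames, sysE$topology, "S", rMax = 20)
  expect_equal(coordinationNumber(rE, cutoff = 5)$mean, 0)
  expect_error(coordinationNumber(rE, cutoff = 25), "censoring")

  # ideal gas: rho * (4/3) pi c^3, and monotone in the cutoff
  an <- fixture("ideal_kbi_an", function()
    analyzePointSystem(fixture("ideal_kbi", function()
      idealPointSystem(n = 2000, frames = 40, box = 64, seed = 601))))
  rho0 <- 2000 / 64^3
  prev <- 0
  for (cutoff in c(3, 5, 8)) {
    cn <- coordinationNumber(an$records, cutoff)
    expected <- rho0 * 4 * pi * cutoff^3 / 3
    expect_lt(abs(cn$mean - expected), 3 * max(cn$sem, 1e-3))
    expect_gte(cn$mean, prev)
    prev <- cn$mean
  }

  # 2:1 enrichment within the cutoff gives a ~2:1 coordination ratio
  sys2 <- buildProfileSystem(systemRecipe(
    box = c(44, 44, 44),
    species = list(profileSpec("A", 900, breaks = 5, lambda = 2),
                   profileSpec("B", 900)),
    nFrames = 50, seed = 612))
  r2 <- minimumDistances(sys2$frames, sys2$topology, c("A", "B"),
                         rMax = 20)
  cn2 <- coordinationNumber(r2, cutoff = 5)
  ratio <- cn2$mean[cn2$species == "A"] / cn2$mean[cn2$species == "B"]
  expect_lt(abs(ratio - 2), 0.45)
})

test_that("hydration numbers match the uniform-bath closed form", {
  # point water sites: the capture region of a multi-atom molecule is a
  # dilated sphere, so the (4/3) pi r^3 closed form is exact for points
  sys <- fixture("hydration_sys", function() buildIdealGasSystem(
    systemRecipe(box = c(44, 44, 44),
                 species = list(profileSpec("ION", 15),
                                profileSpec("water", 1200)),
                 nFrames = 12, seed = 613)))
  hyd <- bulkCoordination(sys$frames, sys$topology, "ION",
                          radii = c(5, 10), rMax = 20)
  rho_w <- 1200 / 44^3
  for (rad in c(5, 10)) {
    sub <- hyd[hyd$radius == rad, ]
    est <- sum(sub$waters * sub$n_ions) / sum(sub$n_ions)
    expected <- rho_w * 4 * pi * rad^3 / 3
    sigma <- sqrt(expected / sum(sub$n_ions))
    expect_lt(abs(est - expected), 3 * sigma + 0.05)
  }
  # radius-10 counts dominate radius-5 counts in every distance bin
  m5 <- hyd[hyd$radius == 5, c("bin_lo", "waters")]
  m10 <- hyd[hyd$radius == 10, c("bin_lo", "waters")]
  shared <- intersect(m5$bin_lo, m10$bin_lo)
  expect_true(all(m10$waters[match(shared, m10$bin_lo)] >=
                    m5$waters[match(shared, m5$bin_lo)]))

  # a lone ion with no waters nearby counts zero at both radii
  topo <- buildTopology(c("CA", "I", "O", "O"),
                        c("GLY", "ION", "HOH", "HOH"),
                        c(1, 2, 3, 4), c("A", "S", "S", "S"))
  fr <- new("Frame",
            coords = rbind(c(22, 22, 22), c(10, 22, 22), c(22, 38, 22),
                           c(38, 22, 22)),
            box = c(44, 44, 44), frameIndex = 1L)
  h0 <- bulkCoordination(list(fr), topo, "ION", radii = c(5, 10),
                         rMax = 21)
  expect_equal(nrow(h0), 2L)
  expect_true(all(h0$waters == 0))
})
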