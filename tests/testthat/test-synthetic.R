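test_that("nominal concentrations reproduce the printed bookkeeping", {
  # closed form n / (N_A V): 252 and 502 cations in the 95 A cube
  expect_equal(nominalConcentration(0, c(95, 95, 95)), 0)
  c252 <- nominalConcentration(252, c(95, 95, 95))
  c502 <- nominalConcentration(502, c(95, 95, 95))
  expect_equal(c252, 252 / (6.02214076e23 * 95^3 * 1e-27))
  expect_lt(abs(c252 - 0.48), 0.02)
  expect_lt(abs(c502 - 0.97), 0.03)
})

test_that("identical recipe and seed give byte-identical trajectories", {
  build <- function() buildProfileSystem(systemRecipe(
    box = c(30, 30, 30),
    species = list(profileSpec("A", 40, exclusion = 3, breaks = 5,
                               lambda = 2),
                   profileSpec("W", 60, template = "water")),
    nFrames = 3, seed = 77))
  s1 <- build(); s2 <- build()
  f1 <- withr::local_tempfile(fileext = ".xyz")
  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeTrajectoryXYZ(s1$frames, s1$topology, f1)
  writeTrajectoryXYZ(s2$frames, s2$topology, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- buildProfileSystem(systemRecipe(
    box = c(30, 30, 30),
    species = list(profileSpec("A", 40, exclusion = 3, breaks = 5,
                               lambda = 2),
                   profileSpec("W", 60, template = "water")),
    nFrames = 3, seed = 78))
  expect_false(identical(coords(s1$frames[[1]]), coords(s3$frames[[1]])))
})

test_that("placed molecule counts match the recipe exactly, every frame", {
  rec <- systemRecipe(box = c(30, 30, 30),
                      species = list(profileSpec("A", 17),
                                     profileSpec("W", 23,
                                                 template = "water")),
                      nFrames = 4, seed = 5)
  sys <- buildIdealGasSystem(rec)
  a <- atoms(sys$topology)
  expect_equal(length(unique(a$molecule_index[a$species_tag == "A"])), 17L)
  expect_equal(length(unique(a$molecule_index[a$species_tag == "W"])), 23L)
  for (fr in sys$frames)
    expect_equal(nrow(coords(fr)), nAtoms(sys$topology))
})

test_that("profile sampling recovers the target radial density", {
  # lambda = 0 below 4, 2 on [4,6], 1 beyond: empirical histogram of
  # distances to the center within 3-sigma Poisson bands of
  # rho_bulk * lambda * shell volume
  n <- 2000; frames <- 30; box <- 40
  rec <- systemRecipe(box = rep(box, 3),
                      species = profileSpec("S", n, exclusion = 4,
                                            breaks = 6, lambda = 2),
                      nFrames = frames, seed = 13)
  sys <- buildProfileSystem(rec)
  rho <- expectedBulkDensity(rec, "S")
  center <- rep(box / 2, 3)
  r <- unlist(lapply(sys$frames, function(fr) {
    d <- sweep(coords(fr)[-1, , drop = FALSE], 2, center)
    d <- d - box * round(d / box)
    sqrt(rowSums(d^2))
  }))
  expect_gte(min(r), 4)
  edges <- seq(0, 10, by = 1)
  lambda <- c(0, 0, 0, 0, 2, 2, 1, 1, 1, 1)
  expected <- frames * rho * lambda *
    (4 * pi / 3) * (edges[-1]^3 - edges[-11]^3)
  got <- as.numeric(table(cut(r, edges)))
  for (b in which(expected > 0))
    expect_lt(abs(got[b] - expected[b]), 3 * sqrt(expected[b]) + 1)
})

test_that("zero exclusion reduces to the ideal gas exactly", {
  recIdeal <- systemRecipe(box = c(25, 25, 25),
                           species = profileSpec("S", 100),
                           nFrames = 2, seed = 31)
  recExcl <- systemRecipe(box = c(25, 25, 25),
                          species = profileSpec("S", 100),
                          nFrames = 2, seed = 31)
  s1 <- buildIdealGasSystem(recIdeal)
  s2 <- buildExcludedShellSystem(recExcl)
  expect_identical(coords(s1$frames[[1]]), coords(s2$frames[[1]]))
})

test_that("a trivial profile is statistically an ideal gas", {
  box <- 40
  sysP <- buildProfileSystem(systemRecipe(
    box = rep(box, 3), species = profileSpec("S", 1000, breaks = 8,
                                             lambda = 1),
    nFrames = 5, seed = 71))
  sysI <- buildIdealGasSystem(systemRecipe(
    box = rep(box, 3), species = profileSpec("S", 1000),
    nFrames = 5, seed = 72))
  rOf <- function(sys) unlist(lapply(sys$frames, function(fr) {
    d <- sweep(coords(fr)[-1, , drop = FALSE], 2, rep(box / 2, 3))
    d <- d - box * round(d / box)
    sqrt(rowSums(d^2))
  }))
  ks <- suppressWarnings(stats::ks.test(rOf(sysP), rOf(sysI)))
  expect_gt(ks$p.value, 0.001)
})

test_that("pairing enforces per-frame cation/anion count and proximity", {
  rec <- systemRecipe(box = c(40, 40, 40),
                      species = list(
                        profileSpec("CAT", 60, role = "cation"),
                        profileSpec("AN1", 40, role = "anion",
                                    exclusion = 3, breaks = 5, lambda = 2),
                        profileSpec("AN2", 20, role = "anion")),
                      nFrames = 2, seed = 9, pairing = TRUE,
                      pairRadius = 3)
  sys <- buildProfileSystem(rec)
  a <- atoms(sys$topology)
  nc <- length(unique(a$molecule_index[a$species_tag == "CAT"]))
  na <- length(unique(a$molecule_index[a$species_tag %in%
                                         c("AN1", "AN2")]))
  expect_identical(nc, na)
  # every cation within pairRadius of some anion (minimum image)
  fr <- sys$frames[[1]]
  x <- coords(fr)
  cat_xyz <- x[a$species_tag == "CAT", , drop = FALSE]
  an_xyz <- x[a$species_tag %in% c("AN1", "AN2"), , drop = FALSE]
  box <- boxSides(fr)
  for (i in seq_len(nrow(cat_xyz))) {
    d <- sweep(an_xyz, 2, cat_xyz[i, ])
    d <- sweep(d, 2, box, function(v, b) v - b * round(v / b))
    expect_lte(min(sqrt(rowSums(d^2))), 3 + 1e-9)
  }
  expect_error(systemRecipe(box = c(40, 40, 40),
                            species = list(
                              profileSpec("CAT", 10, role = "cation"),
                              profileSpec("AN1", 5, role = "anion")),
                            pairing = TRUE),
               "cation count")
})

test_that("the toy solute is labeled, classified and rigid", {
  sol <- buildToySolute(4, c("acidic", "basic", "polar", "nonpolar"))
  rec <- systemRecipe(box = c(30, 30, 30), solute = sol,
                      species = profileSpec("S", 10), nFrames = 3,
                      seed = 2)
  sys <- buildIdealGasSystem(rec)
  cls <- classifyResidues(sys$topology)
  expect_setequal(cls$class, c("acidic", "basic", "polar", "nonpolar"))
  idx <- atoms(sys$topology)$species_tag == "protein"
  expect_identical(coords(sys$frames[[1]])[idx, ],
                   coords(sys$frames[[3]])[idx, ])
  pt <- buildToySolute(1)
  expect_equal(unname(pt$coords), matrix(0, 1, 3))
})

test_that("over-dense ideal gas warns and infeasible exclusion errors", {
  expect_warning(buildIdealGasSystem(systemRecipe(
    box = c(5, 5, 5), species = profileSpec("S", 500), nFrames = 1,
    seed = 1)), "packing")
  expect_error(systemRecipe(box = c(10, 10, 10),
                            species = profileSpec("S", 5, exclusion = 6)),
               "min\\(side\\)/2")
})
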