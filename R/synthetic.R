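## Synthetic periodic configurations with known radial structure. Frames are
## independent draws (configurational averaging only), so every downstream
## statistic has a closed-form or Monte-Carlo oracle.

.SOLVENT_TEMPLATES <- list(
  # rigid bent 3-site water, OH 0.9572 A, HOH 104.52 deg
  water = {
    ang <- 104.52 * pi / 180
    m <- rbind(O = c(0, 0, 0),
               H1 = c(0.9572, 0, 0),
               H2 = 0.9572 * c(cos(ang), sin(ang), 0))
    m
  },
  # 2-site rigid ion, 1.2 A bond
  diatomic = rbind(X1 = c(0, 0, 0), X2 = c(1.2, 0, 0)),
  point = rbind(X = c(0, 0, 0)))

#' Radial enrichment profile for one solvent species
#'
#' Defines the target number density of a species as
#' \code{rho_bulk * lambda(r)} where \code{r} is the distance to the solute
#' and \code{lambda} is piecewise constant: \code{lambda = 0} below
#' \code{exclusion}, the given values on the intervals between consecutive
#' \code{breaks}, and 1 beyond the last break.
#'
#' @param tag species tag (also used as the residue name).
#' @param count molecules to place per frame.
#' @param template \code{"point"}, \code{"water"}, \code{"diatomic"}, or an
#'   n x 3 matrix of rigid-body atom offsets (rownames = atom names).
#' @param exclusion exclusion radius d in Angstrom (lambda = 0 for r < d).
#' @param breaks increasing boundaries (Angstrom) of the lambda intervals,
#'   starting after \code{exclusion}.
#' @param lambda one nonnegative value per interval; lambda = 1 past the
#'   last break.
#' @param role \code{"neutral"}, \code{"cation"} or \code{"anion"} (used by
#'   the pairing option of \code{\link{systemRecipe}}).
#' @return a \code{ProfileSpec} (list).
#' @export
profileSpec <- function(tag, count, template = "point", exclusion = 0,
                        breaks = numeric(0), lambda = numeric(0),
                        role = c("neutral", "cation", "anion")) {
  role <- match.arg(role)
  stopifnot(count >= 0, exclusion >= 0,
            length(breaks) == length(lambda), all(lambda >= 0),
            !is.unsorted(breaks, strictly = TRUE))
  if (length(breaks) && breaks[1] <= exclusion)
    stop("breaks must start above the exclusion radius", call. = FALSE)
  if (is.character(template)) {
    template <- .SOLVENT_TEMPLATES[[match.arg(template,
                                              names(.SOLVENT_TEMPLATES))]]
  }
  stopifnot(is.matrix(template), ncol(template) == 3)
  lo <- c(if (exclusion > 0) 0, if (length(breaks)) c(exclusion, breaks[-length(breaks)]))
  hi <- c(if (exclusion > 0) exclusion, breaks)
  lam <- c(if (exclusion > 0) 0, lambda)
  structure(list(tag = tag, count = as.integer(count), template = template,
                 intervals = data.frame(lo = lo, hi = hi, lambda = lam),
                 role = role),
            class = "ProfileSpec")
}

.profileRmax <- function(spec) {
  iv <- spec$intervals
  if (nrow(iv)) max(iv$hi) else 0
}

# effective volume seen by the species: V_box + 4pi int (lambda-1) r^2 dr
.effectiveVolume <- function(spec, box) {
  iv <- spec$intervals
  v <- prod(box)
  if (nrow(iv))
    v <- v + sum((iv$lambda - 1) * (4 * pi / 3) * (iv$hi^3 - iv$lo^3))
  v
}

#' Expected bulk number density of a species in a recipe
#'
#' \code{count / V_eff}, where the effective volume corrects the box volume
#' for the enrichment/depletion integral of the species' profile. For a
#' uniform species this is simply count/volume.
#'
#' @param recipe a \code{SystemRecipe}.
#' @param tag species tag.
#' @return molecules per Angstrom^3.
#' @export
expectedBulkDensity <- function(recipe, tag) {
  spec <- recipe$species[[tag]]
  if (is.null(spec)) stop("no species '", tag, "' in recipe", call. = FALSE)
  spec$count / .effectiveVolume(spec, recipe$box)
}

#' Build a rigid toy solute
#'
#' A linear rigid cluster of one pseudo-atom per residue (CA only, spaced
#' like consecutive alpha carbons), with residue names chosen to realize the
#' requested classes (acidic -> ASP, basic -> LYS, polar -> GLN,
#' nonpolar -> GLY, other -> UNK).
#'
#' @param nResidues number of residues (>= 1).
#' @param classes character vector of classes, recycled to
#'   \code{nResidues}; default all nonpolar.
#' @param spacing inter-residue spacing in Angstrom.
#' @return list(coords, atom_name, residue_name, residue_number) describing
#'   the solute geometry, centered at the origin.
#' @export
buildToySolute <- function(nResidues, classes = "nonpolar", spacing = 3.8) {
  stopifnot(nResidues >= 1)
  classes <- rep_len(classes, nResidues)
  name_of <- c(acidic = "ASP", basic = "LYS", polar = "GLN",
               nonpolar = "GLY")
  resn <- ifelse(classes %in% names(name_of), name_of[classes], "UNK")
  x <- (seq_len(nResidues) - (nResidues + 1) / 2) * spacing
  list(coords = cbind(x, 0, 0),
       atom_name = rep("CA", nResidues),
       residue_name = unname(resn),
       residue_number = seq_len(nResidues))
}

#' Recipe for a synthetic periodic system
#'
#' @param box numeric(3) orthorhombic side lengths, Angstrom.
#' @param species list of \code{\link{profileSpec}} objects.
#' @param solute solute geometry from \code{\link{buildToySolute}}, or NULL
#'   for a single-point solute; placed rigidly at the box center in every
#'   frame.
#' @param nFrames number of independent frames to draw.
#' @param seed integer RNG seed; frame k uses stream \code{seed + k}.
#' @param pairing if TRUE, cation-species molecules are placed within
#'   \code{pairRadius} of anion positions (local electroneutrality); the
#'   cation count must equal the total anion count and the cation's own
#'   profile is ignored.
#' @param pairRadius pairing displacement radius, Angstrom.
#' @return a \code{SystemRecipe} (list).
#' @export
systemRecipe <- function(box, species, solute = NULL, nFrames = 1,
                         seed = 1, pairing = FALSE, pairRadius = 3) {
  box <- .validateBox(box)
  if (is.null(solute)) solute <- buildToySolute(1)
  if (inherits(species, "ProfileSpec")) species <- list(species)
  names(species) <- vapply(species, `[[`, "", "tag")
  for (sp in species) {
    rmx <- .profileRmax(sp)
    if (rmx > min(box) / 2)
      stop(sprintf("species '%s': profile extends to %g Å, past min(side)/2",
                   sp$tag, rmx), call. = FALSE)
  }
  if (pairing) {
    ncat <- sum(vapply(species, function(s)
      if (s$role == "cation") s$count else 0L, 0L))
    nani <- sum(vapply(species, function(s)
      if (s$role == "anion") s$count else 0L, 0L))
    if (ncat != nani)
      stop("pairing requires cation count == total anion count",
           call. = FALSE)
  }
  structure(list(box = box, solute = solute, species = species,
                 nFrames = as.integer(nFrames), seed = as.integer(seed),
                 pairing = isTRUE(pairing), pairRadius = pairRadius),
            class = "SystemRecipe")
}

#' Nominal molar concentration of a molecule count in a box
#'
#' \code{n / (N_A * V)} with V the box volume in liters.
#'
#' @param n molecule count.
#' @param box numeric(3) side lengths in Angstrom.
#' @return concentration in mol/L.
#' @export
nominalConcentration <- function(n, box) {
  box <- .validateBox(box)
  n / (.NA_CONST * prod(box) * .A3_TO_L)
}

## ---- sampling ----------------------------------------------------------

# n positions with density rho * lambda(r) around `center` in `box`;
# inverse-CDF in r within the profiled sphere, uniform in the complement.
.sampleProfilePositions <- function(n, box, intervals, center) {
  rmax <- if (nrow(intervals)) max(intervals$hi) else 0
  vbox <- prod(box)
  if (rmax == 0) {  # pure ideal gas
    return(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                 runif(n, 0, box[3])))
  }
  mInt <- intervals$lambda * (4 * pi / 3) * (intervals$hi^3 - intervals$lo^3)
  mOut <- vbox - (4 * pi / 3) * rmax^3
  mass <- c(mInt, mOut)
  comp <- sample.int(length(mass), n, replace = TRUE, prob = mass)
  out <- matrix(0, n, 3)
  inSphere <- comp <= nrow(intervals)
  k <- sum(inSphere)
  if (k) {
    lo3 <- intervals$lo[comp[inSphere]]^3
    hi3 <- intervals$hi[comp[inSphere]]^3
    r <- (lo3 + runif(k) * (hi3 - lo3))^(1 / 3)
    dir <- matrix(rnorm(3 * k), k, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    out[inSphere, ] <- sweep(dir * r, 2, center, `+`)
  }
  m <- sum(!inSphere)
  if (m) {
    # uniform on box minus the profiled sphere, by rejection
    got <- 0L
    buf <- matrix(0, m, 3)
    while (got < m) {
      need <- m - got
      cand <- cbind(runif(2 * need, 0, box[1]), runif(2 * need, 0, box[2]),
                    runif(2 * need, 0, box[3]))
      d <- sweep(cand, 2, center)
      d <- sweep(d, 2, box, function(x, b) x - b * round(x / b))
      keep <- which(rowSums(d^2) >= rmax^2)
      keep <- head(keep, need)
      if (length(keep)) {
        buf[(got + 1):(got + length(keep)), ] <- cand[keep, , drop = FALSE]
        got <- got + length(keep)
      }
    }
    out[!inSphere, ] <- buf
  }
  .wrapBox(out, box)
}

# expand reference positions into rigid multi-atom molecules with uniform
# random orientations
.placeMolecules <- function(positions, template) {
  n <- nrow(positions)
  nat <- nrow(template)
  if (n == 0L) return(matrix(0, 0, 3))
  if (nat == 1L) return(positions)
  off <- .randomRotatedOffsets(template, n)
  off + positions[rep(seq_len(n), each = nat), , drop = FALSE]
}

.buildSystemTopology <- function(recipe) {
  sol <- recipe$solute
  an <- sol$atom_name; rn <- sol$residue_name; rno <- sol$residue_number
  ch <- rep("A", length(an))
  for (sp in recipe$species) {
    nat <- nrow(sp$template)
    tnames <- rownames(sp$template)
    if (is.null(tnames)) tnames <- paste0("X", seq_len(nat))
    resname <- if (identical(sp$tag, "water")) "HOH" else sp$tag
    an <- c(an, rep(tnames, sp$count))
    rn <- c(rn, rep(resname, sp$count * nat))
    rno <- c(rno, rep(seq_len(sp$count), each = nat))
    ch <- c(ch, rep("S", sp$count * nat))
  }
  buildTopology(an, rn, rno, ch)
}

# one frame of solvent coordinates; mode: "ideal" | "excluded" | "profile"
.drawFrame <- function(recipe, frameIdx, mode) {
  set.seed(.frameSeed(recipe$seed, frameIdx))
  box <- recipe$box
  center <- box / 2
  soluteXYZ <- sweep(recipe$solute$coords, 2, center, `+`)

  # pass 1: one reference position per molecule, species in recipe order
  posList <- list()
  anionPos <- NULL
  for (sp in recipe$species) {
    if (sp$count == 0L) {
      posList[[sp$tag]] <- matrix(0, 0, 3)
      next
    }
    if (recipe$pairing && sp$role == "cation") next  # placed after anions
    pos <- if (mode == "excluded") {
      d <- if (nrow(sp$intervals)) sp$intervals$hi[1] else 0
      .rejectionExcluded(sp$count, box, d, center)
    } else {
      .sampleProfilePositions(sp$count, box, sp$intervals, center)
    }
    if (recipe$pairing && sp$role == "anion") anionPos <- rbind(anionPos, pos)
    posList[[sp$tag]] <- pos
  }
  if (recipe$pairing) {
    # each cation sits within pairRadius of one anion (local neutrality)
    k0 <- 0L
    for (sp in recipe$species) {
      if (sp$role != "cation" || sp$count == 0L) next
      u <- runif(sp$count)^(1 / 3) * recipe$pairRadius
      dir <- matrix(rnorm(3 * sp$count), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      posList[[sp$tag]] <-
        .wrapBox(anionPos[(k0 + 1):(k0 + sp$count), , drop = FALSE] +
                   dir * u, box)
      k0 <- k0 + sp$count
    }
  }

  # pass 2: expand reference positions into rigid molecules, recipe order
  xyz <- soluteXYZ
  for (sp in recipe$species)
    xyz <- rbind(xyz, .placeMolecules(posList[[sp$tag]], sp$template))
  new("Frame", coords = xyz, box = box, frameIndex = as.integer(frameIdx))
}

.rejectionExcluded <- function(n, box, d, center) {
  if (d <= 0) {
    return(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                 runif(n, 0, box[3])))
  }
  if (1 - (4 * pi / 3) * d^3 / prod(box) < 0.01)
    stop("rejection acceptance below 1%: reduce the exclusion radius",
         call. = FALSE)
  got <- 0L
  out <- matrix(0, n, 3)
  while (got < n) {
    need <- n - got
    cand <- cbind(runif(2 * need, 0, box[1]), runif(2 * need, 0, box[2]),
                  runif(2 * need, 0, box[3]))
    dd <- sweep(cand, 2, center)
    dd <- sweep(dd, 2, box, function(x, b) x - b * round(x / b))
    keep <- head(which(rowSums(dd^2) >= d^2), need)
    if (length(keep)) {
      out[(got + 1):(got + length(keep)), ] <- cand[keep, , drop = FALSE]
      got <- got + length(keep)
    }
  }
  out
}

.buildSystem <- function(recipe, mode) {
  topo <- .buildSystemTopology(recipe)
  frames <- lapply(seq_len(recipe$nFrames), function(k)
    .drawFrame(recipe, k, mode))
  list(topology = topo, frames = frames, recipe = recipe)
}

#' Ideal-gas system: solvent uniform in the box
#'
#' Every species is placed uniformly at random (positions and rigid-body
#' orientations), independent across frames: the no-interaction null for
#' which the MDDF is 1 everywhere and all KB integrals vanish. Requested
#' profiles must be trivial (no exclusion, lambda = 1).
#'
#' @param recipe a \code{\link{systemRecipe}}.
#' @return list(topology, frames, recipe).
#' @export
buildIdealGasSystem <- function(recipe) {
  for (sp in recipe$species)
    if (nrow(sp$intervals) && any(sp$intervals$lambda != 1))
      stop("ideal-gas system requires lambda = 1 and no exclusion; ",
           "species '", sp$tag, "' has a nontrivial profile", call. = FALSE)
  dens <- vapply(recipe$species, function(s) s$count, 0L) / prod(recipe$box)
  if (any(dens > 0.05))
    warning("requested density exceeds a liquid-like packing bound; ",
            "ideal-gas molecules may overlap", call. = FALSE)
  .buildSystem(recipe, "ideal")
}

#' Hard-exclusion system: solvent uniform outside radius d
#'
#' A single-point solute with solvent uniform on \code{r >= d} (rejection
#' sampled). The exclusion radius is the species' \code{exclusion};
#' the converged KB integral is \code{-(4/3) pi d^3} in closed form.
#'
#' @param recipe a \code{\link{systemRecipe}} whose species carry only an
#'   exclusion (no enrichment intervals) and whose solute is a single point.
#' @return list(topology, frames, recipe).
#' @export
buildExcludedShellSystem <- function(recipe) {
  if (nrow(recipe$solute$coords) != 1L)
    stop("excluded-shell system requires a single-point solute",
         call. = FALSE)
  for (sp in recipe$species) {
    iv <- sp$intervals
    if (nrow(iv) > 1L || (nrow(iv) == 1L && iv$lambda[1] != 0))
      stop("excluded-shell species must have only an exclusion radius",
           call. = FALSE)
    if (nrow(iv) && iv$hi[1] >= min(recipe$box) / 2)
      stop("exclusion radius must be below min(side)/2", call. = FALSE)
  }
  .buildSystem(recipe, "excluded")
}

#' Profile system: solvent with prescribed radial enrichment
#'
#' Positions are drawn with radial density \code{rho_bulk * lambda(r)}
#' around a point (or small) solute: inverse-CDF sampling of r within the
#' profiled sphere, uniform placement outside it, uniform random rigid-body
#' orientations for multi-atom species.
#'
#' @param recipe a \code{\link{systemRecipe}}.
#' @return list(topology, frames, recipe).
#' @export
buildProfileSystem <- function(recipe) {
  .buildSystem(recipe, "profile")
}
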