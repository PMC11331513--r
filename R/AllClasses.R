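#' @import methods
NULL

#' Topology: atoms grouped into molecules and species
#'
#' A \code{Topology} holds one row per atom with its name, element, residue
#' name and index, molecule index and species tag. Atoms of one molecule are
#' contiguous; all molecules of a species share the same atom-name template.
#'
#' @slot atoms data.frame with columns \code{atom_index} (1-based, unique),
#'   \code{atom_name}, \code{element}, \code{residue_name},
#'   \code{residue_index}, \code{molecule_index}, \code{species_tag},
#'   \code{chain}.
#' @name Topology-class
#' @aliases Topology-class
#' @exportClass Topology
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("atom_index", "atom_name", "element", "residue_name",
            "residue_index", "molecule_index", "species_tag", "chain")
  miss <- setdiff(need, names(a))
  if (length(miss)) return(paste("missing atom columns:",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(a$atom_index)) return("atom_index not unique")
  if (!identical(a$atom_index, seq_len(nrow(a))))
    return("atom_index must be 1..nAtoms in order")
  ## molecules must be contiguous atom ranges
  m <- a$molecule_index
  if (any(m != cummax(m)) || any(diff(unique(m)) != 1L))
    return("molecule_index must be nondecreasing contiguous blocks")
  ## one species per molecule
  sp <- tapply(a$species_tag, a$molecule_index,
               function(x) length(unique(x)))
  if (any(sp != 1L)) return("a molecule spans more than one species")
  ## homogeneous templates within species
  for (tag in unique(a$species_tag)) {
    rows <- a[a$species_tag == tag, ]
    tmpl <- split(rows$atom_name, rows$molecule_index)
    if (length(unique(vapply(tmpl, paste, "", collapse = "\r"))) > 1L) {
      bad <- names(tmpl)[which(vapply(tmpl, paste, "", collapse = "\r") !=
                                 paste(tmpl[[1]], collapse = "\r"))[1]]
      return(sprintf(
        "species '%s': molecule %s does not match the species template",
        tag, bad))
    }
  }
  TRUE
})

#' Frame: one configuration with its periodic box
#'
#' @slot coords numeric matrix, nAtoms x 3, Angstrom.
#' @slot box numeric(3), orthorhombic side lengths in Angstrom.
#' @slot frameIndex integer frame number (1-based).
#' @name Frame-class
#' @aliases Frame-class
#' @exportClass Frame
setClass("Frame", representation(coords = "matrix", box = "numeric",
                                 frameIndex = "integer"))

setValidity("Frame", function(object) {
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (any(!is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@box) != 3L || any(object@box <= 0))
    return("box must be three positive side lengths")
  TRUE
})

#' Binned minimum-distance site counts with decompositions
#'
#' Per-bin mean (over frames) count of solvent molecules whose minimum
#' distance to the solute falls in each half-open bin \code{[lo, hi)},
#' together with the decomposition of those counts by the solvent atom and
#' the solute residue realizing each minimum distance.
#'
#' @slot species character, solvent species tag(s) accumulated.
#' @slot binWidth,rMax binning, Angstrom.
#' @slot nFrames number of frames averaged.
#' @slot counts numeric, mean site count per frame per bin.
#' @slot countsPerFrame matrix bins x frames of raw per-frame counts.
#' @slot solventAtomCounts matrix bins x solvent-atom-name, mean per frame.
#' @slot residueCounts matrix bins x solute residue, mean per frame.
#' @slot residueInfo data.frame(residue_index, residue_name, class).
#' @slot nMolecules mean number of solvent molecules per frame.
#' @slot boxVolume mean box volume, Angstrom^3.
#' @name MinDistHistogram-class
#' @exportClass MinDistHistogram
setClass("MinDistHistogram", representation(
  species = "character", binWidth = "numeric", rMax = "numeric",
  nFrames = "integer", counts = "numeric", countsPerFrame = "matrix",
  solventAtomCounts = "matrix", residueCounts = "matrix",
  residueInfo = "data.frame", nMolecules = "numeric",
  boxVolume = "numeric"))

setValidity("MinDistHistogram", function(object) {
  nb <- length(object@counts)
  if (nb != round(object@rMax / object@binWidth))
    return("counts length inconsistent with binWidth and rMax")
  if (any(object@counts < 0)) return("negative counts")
  if (nrow(object@solventAtomCounts) &&
      max(abs(rowSums(object@solventAtomCounts) - object@counts)) > 1e-9)
    return("solvent-atom decomposition does not sum to total counts")
  if (nrow(object@residueCounts) &&
      max(abs(rowSums(object@residueCounts) - object@counts)) > 1e-9)
    return("residue decomposition does not sum to total counts")
  TRUE
})

#' Reference-state (noninteracting) minimum-distance counts
#'
#' Counts from random rigid placements of the frame's solvent molecules at
#' uniform density, used to normalize the MDDF and as the Monte-Carlo
#' estimate of minimum-distance shell volumes around the solute.
#'
#' @slot binWidth,rMax binning, Angstrom.
#' @slot nFrames frames used.
#' @slot refCounts mean reference count per frame per bin (at placement
#'   density).
#' @slot siteVolumes Monte-Carlo estimate of each minimum-distance shell
#'   volume, Angstrom^3: \code{refCounts / placementDensity}.
#' @slot placementDensity molecules/Angstrom^3 used for random placement.
#' @slot nRandomFactor replicas per real solvent molecule.
#' @slot seed RNG seed used.
#' @name ReferenceCounts-class
#' @exportClass ReferenceCounts
setClass("ReferenceCounts", representation(
  binWidth = "numeric", rMax = "numeric", nFrames = "integer",
  refCounts = "numeric", siteVolumes = "numeric",
  placementDensity = "numeric", nRandomFactor = "numeric",
  seed = "integer"))

#' Minimum-distance distribution function
#'
#' @slot r bin centers, Angstrom.
#' @slot gmd the MDDF: site counts over reference counts at bulk density.
#' @slot undefined logical, bins where the reference count is zero (gmd is
#'   NA there, never divided).
#' @slot contributions matrix bins x label of contribution curves whose
#'   pointwise sum equals \code{gmd}; empty until \code{decomposeMddf}.
#' @slot bulkDensity molecules/Angstrom^3 used in the normalization.
#' @slot histogram,reference the inputs, retained for KB integration.
#' @name MDDFResult-class
#' @exportClass MDDFResult
setClass("MDDFResult", representation(
  r = "numeric", gmd = "numeric", undefined = "logical",
  contributions = "matrix", bulkDensity = "numeric",
  histogram = "MinDistHistogram", reference = "ReferenceCounts"))

#' Kirkwood-Buff integral on the minimum-distance grid
#'
#' @slot R grid of bin upper edges, Angstrom.
#' @slot G KB integral G(R), Angstrom^3.
#' @slot GLmol same in L/mol.
#' @slot perFrame matrix bins x frames of per-frame G(R) curves.
#' @slot sem standard error of G(R) across frames (or replicas).
#' @slot rhoC bulk density used, molecules/Angstrom^3.
#' @slot converged logical flag from |G(Rdomain) - G(rMax)| against tol.
#' @slot Rdomain the solute-domain radius used for the convergence check.
#' @slot species species tag(s).
#' @name KBIResult-class
#' @exportClass KBIResult
setClass("KBIResult", representation(
  R = "numeric", G = "numeric", GLmol = "numeric", perFrame = "matrix",
  sem = "numeric", rhoC = "numeric", converged = "logical",
  Rdomain = "numeric", species = "character"))

#' Preferential-solvation parameter
#'
#' @slot R grid, Angstrom.
#' @slot gamma dimensionless preferential-solvation parameter.
#' @slot sem standard error across frames where available.
#' @slot rhoC cosolvent bulk density, molecules/Angstrom^3.
#' @slot cosolvent,water species tags of the two components.
#' @name GammaResult-class
#' @exportClass GammaResult
setClass("GammaResult", representation(
  R = "numeric", gamma = "numeric", sem = "numeric", rhoC = "numeric",
  cosolvent = "character", water = "character"))

#' Residue x distance contribution map
#'
#' @slot counts matrix (solute residue x distance bin) of mean per-frame
#'   minimum-distance counts attributed to each residue.
#' @slot density same normalized by shell volume and bulk density (an MDDF
#'   contribution per residue); NA where shell volume is zero.
#' @slot r bin centers.
#' @slot residueInfo data.frame(residue_index, residue_name, class).
#' @slot species solvent species tag.
#' @name ResidueDistanceMap-class
#' @exportClass ResidueDistanceMap
setClass("ResidueDistanceMap", representation(
  counts = "matrix", density = "matrix", r = "numeric",
  residueInfo = "data.frame", species = "character"))

#' Difference of two residue x distance maps (A - B)
#'
#' @slot delta elementwise difference of the density matrices, A - B.
#' @slot deltaCounts elementwise difference of the raw count matrices.
#' @slot r bin centers.
#' @slot residueInfo residue labels shared by both maps.
#' @slot speciesA,speciesB the two species tags.
#' @name DifferenceMap-class
#' @exportClass DifferenceMap
setClass("DifferenceMap", representation(
  delta = "matrix", deltaCounts = "matrix", r = "numeric",
  residueInfo = "data.frame", speciesA = "character",
  speciesB = "character"))

## ---- show methods ----------------------------------------------------

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  sp <- table(a$species_tag[!duplicated(a$molecule_index)])
  cat(sprintf("Topology: %d atoms, %d molecules, %d species\n",
              nrow(a), length(unique(a$molecule_index)), length(sp)))
  for (tag in names(sp)) {
    nat <- sum(a$species_tag == tag) / sp[[tag]]
    cat(sprintf("  %-10s %6d molecules x %d atoms\n", tag, sp[[tag]], nat))
  }
})

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame %d: %d atoms, box %.2f x %.2f x %.2f Å\n",
              object@frameIndex, nrow(object@coords),
              object@box[1], object@box[2], object@box[3]))
})

setMethod("show", "MinDistHistogram", function(object) {
  cat(sprintf(
    "MinDistHistogram [%s]: %d bins of %.2f Å to %.1f Å, %d frames\n",
    paste(object@species, collapse = "+"), length(object@counts),
    object@binWidth, object@rMax, object@nFrames))
  cat(sprintf("  mean molecules/frame: %.1f; counted sites/frame: %.1f\n",
              object@nMolecules, sum(object@counts)))
})

setMethod("show", "MDDFResult", function(object) {
  # peak reported over bins with enough reference samples to be meaningful
  ok <- !object@undefined &
    object@reference@refCounts * object@reference@nFrames >= 10
  cat(sprintf("MDDF [%s]: %d bins, bulk density %.4g Å^-3\n",
              paste(object@histogram@species, collapse = "+"),
              length(object@r), object@bulkDensity))
  if (any(ok))
    cat(sprintf("  max g(r) = %.2f at r = %.2f Å\n",
                max(object@gmd[ok]), object@r[ok][which.max(object@gmd[ok])]))
})

setMethod("show", "KBIResult", function(object) {
  iR <- which.min(abs(object@R - object@Rdomain))
  cat(sprintf("KBI [%s]: G(%.0f Å) = %.1f Å^3 (%.4f L/mol), %s\n",
              paste(object@species, collapse = "+"), object@Rdomain,
              object@G[iR], object@GLmol[iR],
              if (isTRUE(object@converged)) "converged" else "not converged"))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("Gamma [%s vs %s]: Gamma(max R) = %.3f\n",
              object@cosolvent, object@water,
              object@gamma[length(object@gamma)]))
})

setMethod("show", "ResidueDistanceMap", function(object) {
  cat(sprintf("ResidueDistanceMap [%s]: %d residues x %d bins\n",
              object@species, nrow(object@counts), ncol(object@counts)))
})

setMethod("show", "DifferenceMap", function(object) {
  cat(sprintf("DifferenceMap [%s - %s]: %d residues x %d bins\n",
              object@speciesA, object@speciesB, nrow(object@delta),
              ncol(object@delta)))
})
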