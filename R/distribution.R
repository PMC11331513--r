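## Minimum-distance histograms, the noninteracting reference state, the
## MDDF g(r) = counts / reference counts, and its decompositions by solvent
## atom and solute residue. Bins are half-open [lo, hi), 0.1 A wide by
## default, spanning 0-30 A.

# half-open [lo, hi) bins; the epsilon makes a distance at a bin edge land
# deterministically in the upper bin despite floating-point division
.binOf <- function(r, binWidth, nb) {
  pmin(nb, as.integer(floor(r / binWidth + 1e-9)) + 1L)
}

.nBins <- function(binWidth, rMax) {
  nb <- round(rMax / binWidth)
  if (abs(nb * binWidth - rMax) > 1e-9)
    stop("rMax must be an integer multiple of binWidth", call. = FALSE)
  as.integer(nb)
}

#' Accumulate the minimum-distance histogram
#'
#' Bins the per-molecule minimum distances into half-open \code{[lo, hi)}
#' bins and averages the per-bin site counts over frames, retaining the
#' decomposition of every count by the solvent atom and the solute residue
#' that realize the minimum distance. Censored records (no solute atom
#' within the search radius) never enter any bin.
#'
#' @param records output of \code{\link{minimumDistances}}.
#' @param topology the \code{Topology} the records were computed from.
#' @param binWidth bin width in Angstrom (default 0.1).
#' @param rMax histogram extent in Angstrom (default 30); a distance exactly
#'   at \code{rMax} is excluded.
#' @param soluteSpecies tag of the solute species (for the residue
#'   decomposition).
#' @param classMap residue-class map, see \code{\link{defaultResidueClasses}}.
#' @return a \code{\linkS4class{MinDistHistogram}}.
#' @export
accumulateHistogram <- function(records, topology, binWidth = 0.1,
                                rMax = 30, soluteSpecies = "protein",
                                classMap = defaultResidueClasses()) {
  a <- atoms(topology)
  ok <- !is.na(records$rmin)
  if (any(records$solute_atom[ok] > nrow(a)) ||
      any(records$solvent_atom[ok] > nrow(a)))
    stop("records reference atoms beyond this topology: mismatched inputs",
         call. = FALSE)
  recRmax <- attr(records, "rMax")
  if (!is.null(recRmax) && recRmax < rMax)
    stop(sprintf(
      "records were censored at %g Å; cannot histogram out to %g Å",
      recRmax, rMax), call. = FALSE)
  nb <- .nBins(binWidth, rMax)
  nFrames <- attr(records, "nFrames")
  if (is.null(nFrames)) nFrames <- length(unique(records$frame))
  nFrames <- as.integer(nFrames)

  keep <- ok & records$rmin < rMax
  r <- records$rmin[keep]
  bin <- .binOf(r, binWidth, nb)
  fbin <- factor(bin, levels = seq_len(nb))

  counts <- tabulate(bin, nb) / nFrames
  frameLevels <- sort(unique(records$frame))
  countsPerFrame <- unclass(table(fbin,
                                  factor(records$frame[keep],
                                         levels = frameLevels)))
  dimnames(countsPerFrame) <- NULL
  countsPerFrame <- matrix(as.numeric(countsPerFrame), nb,
                           length(frameLevels))

  atomLevels <- sort(unique(
    a$atom_name[a$species_tag %in% unique(records$species)]))
  if (!length(atomLevels))
    atomLevels <- sort(unique(a$atom_name[records$solvent_atom[keep]]))
  atomName <- factor(a$atom_name[records$solvent_atom[keep]],
                     levels = atomLevels)
  solventAtomCounts <- unclass(table(fbin, atomName)) / nFrames
  class(solventAtomCounts) <- "matrix"

  residue <- a$residue_index[records$solute_atom[keep]]
  resInfo <- suppressWarnings(
    classifyResidues(topology, classMap, soluteSpecies))
  residueCounts <- unclass(table(
    fbin, factor(residue, levels = resInfo$residue_index))) / nFrames
  class(residueCounts) <- "matrix"
  colnames(residueCounts) <- as.character(resInfo$residue_index)

  boxVolume <- attr(records, "boxVolume")
  if (is.null(boxVolume)) boxVolume <- NA_real_
  new("MinDistHistogram",
      species = unique(records$species),
      binWidth = binWidth, rMax = rMax, nFrames = nFrames,
      counts = as.numeric(counts),
      countsPerFrame = countsPerFrame,
      solventAtomCounts = solventAtomCounts,
      residueCounts = residueCounts,
      residueInfo = resInfo,
      nMolecules = nrow(records) / nFrames,
      boxVolume = boxVolume)
}

#' Reference-state counts and minimum-distance shell volumes
#'
#' Builds the noninteracting reference: for every frame,
#' \code{nRandomFactor} rigid replicas of each solvent molecule (shape taken
#' from the frame, orientation uniform on rotations) are placed uniformly at
#' random in the box, and their minimum distances to the solute are
#' histogrammed. Dividing the mean reference count by the placement density
#' gives a Monte-Carlo estimate of each minimum-distance shell volume
#' around the solute, which has no closed form for irregular solutes.
#'
#' @param frames list of \code{Frame}.
#' @param topology the matching \code{Topology}.
#' @param solventSpecies solvent species tag(s).
#' @param soluteSpecies solute species tag.
#' @param nRandomFactor replicas per real solvent molecule (default 10).
#' @param seed RNG seed for the random placements.
#' @param binWidth,rMax binning as in \code{\link{accumulateHistogram}}.
#' @return a \code{\linkS4class{ReferenceCounts}}.
#' @export
referenceCounts <- function(frames, topology, solventSpecies,
                            soluteSpecies = "protein", nRandomFactor = 10,
                            seed = 1, binWidth = 0.1, rMax = 30) {
  if (is(frames, "Frame")) frames <- list(frames)
  nb <- .nBins(binWidth, rMax)
  a <- atoms(topology)
  solIdx <- .soluteAtomIdx(topology, soluteSpecies)
  total <- numeric(nb)
  dens <- numeric(length(frames))
  anyMol <- FALSE
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    box <- boxSides(fr)
    .checkCutoff(rMax, box, "rMax")
    set.seed(.frameSeed(seed, frameIndex(fr)))
    x <- coords(fr)
    allXYZ <- NULL
    allMol <- integer(0)
    nRep <- 0L
    for (tag in solventSpecies) {
      sel <- a$species_tag == tag
      if (!any(sel)) next
      mols <- unique(a$molecule_index[sel])
      nmol <- length(mols)
      if (!nmol) next
      anyMol <- TRUE
      # rigid template from the first molecule of the species in this frame
      atomsOfFirst <- a$atom_index[a$molecule_index == mols[1]]
      tmpl <- x[atomsOfFirst, , drop = FALSE]
      tmpl <- sweep(tmpl, 2, tmpl[1, ])
      nRepSp <- nRandomFactor * nmol
      pos <- cbind(runif(nRepSp, 0, box[1]), runif(nRepSp, 0, box[2]),
                   runif(nRepSp, 0, box[3]))
      xyz <- .placeMolecules(pos, tmpl)
      allXYZ <- rbind(allXYZ, xyz)
      allMol <- c(allMol, nRep + rep(seq_len(nRepSp), each = nrow(tmpl)))
      nRep <- nRep + nRepSp
    }
    if (nRep == 0L) next
    res <- cpp_min_distances(x[solIdx, , drop = FALSE], allXYZ, allMol,
                             nRep, box, rMax)
    r <- res$rmin[!is.na(res$rmin)]
    r <- r[r < rMax]
    total <- total + tabulate(.binOf(r, binWidth, nb), nb)
    dens[k] <- nRep / prod(box)
  }
  if (!anyMol) {
    warning("no solvent molecules: reference counts are all zero",
            call. = FALSE)
    dens <- 1
  }
  refCounts <- total / length(frames)
  placementDensity <- mean(dens)
  new("ReferenceCounts",
      binWidth = binWidth, rMax = rMax, nFrames = length(frames),
      refCounts = as.numeric(refCounts),
      siteVolumes = as.numeric(refCounts / placementDensity),
      placementDensity = placementDensity,
      nRandomFactor = as.numeric(nRandomFactor),
      seed = as.integer(seed))
}

.checkBinning <- function(hist, ref) {
  if (abs(hist@binWidth - ref@binWidth) > 1e-12 ||
      abs(hist@rMax - ref@rMax) > 1e-12)
    stop("histogram and reference binning do not match", call. = FALSE)
}

.shellBins <- function(binWidth, nb, shell) {
  lo <- (seq_len(nb) - 1) * binWidth
  hi <- seq_len(nb) * binWidth
  which(lo >= shell[1] - 1e-9 & hi <= shell[2] + 1e-9)
}

#' Compute the minimum-distance distribution function
#'
#' \code{g(r) = counts(r) / (rho_c * V(r))}: mean site counts over the
#' reference counts rescaled to the bulk density. Bins with zero reference
#' volume are flagged undefined (NA), never divided.
#'
#' @param hist a \code{\linkS4class{MinDistHistogram}}.
#' @param ref the matching \code{\linkS4class{ReferenceCounts}}.
#' @param bulkDensity bulk number density in molecules/Angstrom^3; when
#'   NULL it is estimated from the bulk shell (finite-size correction).
#' @param bulkShell numeric(2), the bulk-shell bounds in Angstrom.
#' @return a \code{\linkS4class{MDDFResult}}.
#' @export
computeMddf <- function(hist, ref, bulkDensity = NULL,
                        bulkShell = c(20, 30)) {
  .checkBinning(hist, ref)
  nb <- length(hist@counts)
  if (is.null(bulkDensity)) {
    sb <- .shellBins(hist@binWidth, nb, bulkShell)
    vol <- sum(ref@siteVolumes[sb])
    if (vol <= 0)
      stop("zero bulk-shell volume: cannot estimate the bulk density",
           call. = FALSE)
    bulkDensity <- sum(hist@counts[sb]) / vol
  }
  refAtBulk <- bulkDensity * ref@siteVolumes
  undef <- refAtBulk <= 0
  g <- rep(NA_real_, nb)
  g[!undef] <- hist@counts[!undef] / refAtBulk[!undef]
  new("MDDFResult",
      r = binCenters(hist), gmd = g, undefined = undef,
      contributions = matrix(0, 0, 0), bulkDensity = bulkDensity,
      histogram = hist, reference = ref)
}

#' Decompose an MDDF into labeled contributions
#'
#' Attributes each minimum-distance count to the single realizing pair and
#' returns contribution curves whose pointwise sum equals the total MDDF.
#'
#' @param result a \code{\linkS4class{MDDFResult}}.
#' @param by \code{"solvent_atom"} (solvent atom name),
#'   \code{"residue_class"} or \code{"residue_index"} (solute side).
#' @return the result with its \code{contributions} slot filled
#'   (bins x label matrix).
#' @export
decomposeMddf <- function(result,
                          by = c("solvent_atom", "residue_class",
                                 "residue_index")) {
  if (length(by) != 1L || !by %in% c("solvent_atom", "residue_class",
                                     "residue_index"))
    stop("unknown grouping key; valid keys: solvent_atom, residue_class, ",
         "residue_index", call. = FALSE)
  hist <- result@histogram
  m <- switch(by,
    solvent_atom = hist@solventAtomCounts,
    residue_index = hist@residueCounts,
    residue_class = {
      cls <- hist@residueInfo$class
      t(rowsum(t(hist@residueCounts), group = cls))
    })
  refAtBulk <- result@bulkDensity * result@reference@siteVolumes
  contrib <- m
  contrib[refAtBulk <= 0, ] <- NA_real_
  pos <- refAtBulk > 0
  contrib[pos, ] <- m[pos, , drop = FALSE] / refAtBulk[pos]
  result@contributions <- contrib
  result
}

#' Write an MDDF (with contributions) as TSV
#'
#' @param result a \code{\linkS4class{MDDFResult}}.
#' @param path output file.
#' @export
writeMddf <- function(result, path) {
  df <- data.frame(r = result@r, gmd = result@gmd)
  if (ncol(result@contributions))
    df <- cbind(df, as.data.frame(result@contributions))
  write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
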