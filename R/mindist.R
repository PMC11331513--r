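## Per-solvent-molecule minimum distances to the solute under periodic
## boundaries (minimum-image, orthorhombic). The production path is a
## cell-list kernel in C++; a pure-R exhaustive scan with the identical
## arithmetic serves as the testing oracle. Ties are broken to the lower
## solute atom index, then the lower solvent atom index.

.soluteAtomIdx <- function(topology, soluteSpecies) {
  a <- atoms(topology)
  idx <- a$atom_index[a$species_tag %in% soluteSpecies]
  if (!length(idx))
    stop("no atoms for solute species ",
         paste(soluteSpecies, collapse = ", "), call. = FALSE)
  idx
}

.solventAtomIdx <- function(topology, solventSpecies) {
  a <- atoms(topology)
  sel <- a$species_tag %in% solventSpecies
  if (!any(sel))
    stop("no atoms for solvent species ",
         paste(solventSpecies, collapse = ", "), call. = FALSE)
  idx <- a$atom_index[sel]
  mol <- a$molecule_index[sel]
  list(idx = idx, mol = mol,
       molIds = unique(mol),
       species = a$species_tag[sel][!duplicated(mol)])
}

.recordsFromKernel <- function(res, frame, topology, sv, solIdx) {
  molIds <- sv$molIds
  data.frame(
    frame = frameIndex(frame),
    species = sv$species,
    molecule = molIds,
    rmin = res$rmin,
    solute_atom = solIdx[res$solute_atom],
    solvent_atom = sv$idx[res$solvent_atom],
    stringsAsFactors = FALSE)
}

#' Minimum distances of solvent molecules to the solute (cell list)
#'
#' For every molecule of the requested solvent species, the minimum over
#' all (solute atom, solvent atom) pairs of the minimum-image distance,
#' with the realizing atom pair annotated. Exactly one record per solvent
#' molecule per frame; molecules with no solute atom within \code{rMax}
#' are censored (\code{rmin = NA}), which is valid because downstream
#' statistics only ever query distances up to \code{rMax}.
#'
#' @param frame a \code{Frame} (or list of frames).
#' @param topology the matching \code{Topology}.
#' @param solventSpecies character vector of solvent species tags.
#' @param soluteSpecies solute species tag (default \code{"protein"}).
#' @param rMax censoring distance, Angstrom; must not exceed min(side)/2.
#' @return data.frame(frame, species, molecule, rmin, solute_atom,
#'   solvent_atom) with attribute \code{"rMax"}.
#' @export
minimumDistances <- function(frame, topology, solventSpecies,
                             soluteSpecies = "protein", rMax = 30) {
  if (is.list(frame)) {
    recs <- lapply(frame, minimumDistances, topology = topology,
                   solventSpecies = solventSpecies,
                   soluteSpecies = soluteSpecies, rMax = rMax)
    out <- do.call(rbind, recs)
    attr(out, "rMax") <- rMax
    attr(out, "nFrames") <- length(frame)
    attr(out, "boxVolume") <- mean(vapply(frame,
                                          function(f) prod(boxSides(f)), 0))
    return(out)
  }
  box <- boxSides(frame)
  .checkCutoff(rMax, box, "rMax")
  solIdx <- .soluteAtomIdx(topology, soluteSpecies)
  sv <- .solventAtomIdx(topology, solventSpecies)
  if (length(intersect(solIdx, sv$idx)))
    stop("solute and solvent atom sets overlap", call. = FALSE)
  x <- coords(frame)
  molLocal <- match(sv$mol, sv$molIds)
  res <- cpp_min_distances(x[solIdx, , drop = FALSE],
                           x[sv$idx, , drop = FALSE],
                           molLocal, length(sv$molIds),
                           box, rMax)
  out <- .recordsFromKernel(res, frame, topology, sv, solIdx)
  attr(out, "rMax") <- rMax
  attr(out, "nFrames") <- 1L
  attr(out, "boxVolume") <- prod(box)
  out
}

#' Minimum distances by exhaustive pairwise scan (oracle)
#'
#' Same contract as \code{\link{minimumDistances}} but O(solute atoms x
#' solvent atoms) in plain R, intended as an independent oracle on small
#' systems. Distances use the same minimum-image arithmetic (round-half-to-
#' even image counts), so agreement with the cell-list kernel is exact,
#' realizing atom pairs included.
#'
#' @inheritParams minimumDistances
#' @return data.frame as in \code{\link{minimumDistances}}.
#' @export
bruteForceMinimumDistances <- function(frame, topology, solventSpecies,
                                       soluteSpecies = "protein",
                                       rMax = 30) {
  box <- boxSides(frame)
  .checkCutoff(rMax, box, "rMax")
  solIdx <- .soluteAtomIdx(topology, soluteSpecies)
  sv <- .solventAtomIdx(topology, solventSpecies)
  if (length(intersect(solIdx, sv$idx)))
    stop("solute and solvent atom sets overlap", call. = FALSE)
  x <- coords(frame)
  P <- x[solIdx, , drop = FALSE]
  S <- x[sv$idx, , drop = FALSE]
  ns <- nrow(P); m <- nrow(S)
  # d2[i, j]: solute atom i vs solvent atom j, built column-major so each
  # squared term is computed exactly as in the C++ kernel
  d2 <- matrix(0, ns, m)
  for (j in seq_len(m)) {
    dx <- P[, 1] - S[j, 1]; dx <- dx - box[1] * round(dx / box[1])
    dy <- P[, 2] - S[j, 2]; dy <- dy - box[2] * round(dy / box[2])
    dz <- P[, 3] - S[j, 3]; dz <- dz - box[3] * round(dz / box[3])
    s <- dx * dx
    s <- s + dy * dy
    s <- s + dz * dz
    d2[, j] <- s
  }
  molLocal <- match(sv$mol, sv$molIds)
  nmol <- length(sv$molIds)
  rmin <- rep(NA_real_, nmol)
  isol <- rep(NA_integer_, nmol)
  jsolv <- rep(NA_integer_, nmol)
  cut2 <- rMax * rMax
  for (k in seq_len(nmol)) {
    cols <- which(molLocal == k)
    sub <- d2[, cols, drop = FALSE]
    best <- Inf; bi <- NA_integer_; bj <- NA_integer_
    for (ci in seq_len(ns)) {            # ascending solute atom index first
      for (cj in seq_along(cols)) {      # then ascending solvent atom index
        v <- sub[ci, cj]
        if (v <= cut2 && v < best) {     # strict <: first (i, j) wins ties
          best <- v; bi <- ci; bj <- cols[cj]
        }
      }
    }
    if (is.finite(best)) {
      rmin[k] <- sqrt(best)
      isol[k] <- bi
      jsolv[k] <- bj
    }
  }
  out <- .recordsFromKernel(list(rmin = rmin, solute_atom = isol,
                                 solvent_atom = jsolv),
                            frame, topology, sv, solIdx)
  attr(out, "rMax") <- rMax
  attr(out, "nFrames") <- 1L
  attr(out, "boxVolume") <- prod(box)
  out
}

#' Dump minimum-distance records as TSV
#'
#' @param records output of \code{\link{minimumDistances}}.
#' @param topology the matching \code{Topology} (adds atom names).
#' @param path output file.
#' @export
writeMinDistRecords <- function(records, topology, path) {
  a <- atoms(topology)
  out <- records
  out$solute_atom_name <- a$atom_name[records$solute_atom]
  out$solvent_atom_name <- a$atom_name[records$solvent_atom]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
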