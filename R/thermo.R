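## Kirkwood-Buff integrals on the minimum-distance grid, bulk densities
## from the 20-30 A shell (finite-size correction), preferential-solvation
## parameters, coordination numbers and ion hydration numbers.
##
## G(R) = (N(R) - N*(R)) / rho_c, where N(R) counts solute-solvent minimum
## distances below R, N*(R) is the reference-state count rescaled to the
## bulk density rho_c, and rho_c is measured in the bulk shell.

#' Bulk density of a solvent species from the bulk shell
#'
#' The mean number of molecules whose minimum distance to the solute lies
#' in the shell, divided by the shell's minimum-distance volume estimated
#' from the reference state. Estimating the density in an open subvolume far
#' from the solute provides the finite-size correction for KB integrals.
#'
#' @param hist a \code{\linkS4class{MinDistHistogram}}.
#' @param ref the matching \code{\linkS4class{ReferenceCounts}}.
#' @param shell numeric(2) shell bounds in Angstrom, default \code{c(20, 30)}.
#' @return list with \code{rho} (molecules/Angstrom^3), \code{molar}
#'   (mol/L), \code{sem} (SEM of rho across frames), \code{shell} and
#'   \code{species}.
#' @export
bulkDensity <- function(hist, ref, shell = c(20, 30)) {
  .checkBinning(hist, ref)
  stopifnot(length(shell) == 2L, shell[1] >= 0, shell[2] > shell[1])
  if (shell[2] > hist@rMax + 1e-9)
    stop(sprintf("bulk shell [%g, %g] extends past rMax = %g Å",
                 shell[1], shell[2], hist@rMax), call. = FALSE)
  nb <- length(hist@counts)
  sb <- .shellBins(hist@binWidth, nb, shell)
  vol <- sum(ref@siteVolumes[sb])
  if (vol <= 0)
    stop("zero shell volume in the reference state", call. = FALSE)
  nShell <- sum(hist@counts[sb])
  if (nShell == 0)
    warning("no molecules in the bulk shell: density is zero",
            call. = FALSE)
  perFrame <- colSums(hist@countsPerFrame[sb, , drop = FALSE]) / vol
  nf <- ncol(hist@countsPerFrame)
  list(rho = nShell / vol,
       molar = nShell / vol / (.NA_CONST * .A3_TO_L),
       sem = if (nf > 1) sd(perFrame) / sqrt(nf) else NA_real_,
       shell = shell,
       species = hist@species)
}

#' Kirkwood-Buff integral from minimum-distance counts
#'
#' \code{G(R) = (N(R) - N*(R)) / rho_c} on the bin grid, with the
#' reference-state cumulative count rescaled to the bulk density
#' (\code{N*(R) = rho_c * Vcum(R)}). Convergence is assessed from
#' \code{|G(Rdomain) - G(rMax)|}.
#'
#' @param hist a \code{\linkS4class{MinDistHistogram}}.
#' @param ref the matching \code{\linkS4class{ReferenceCounts}}.
#' @param rhoC bulk density in molecules/Angstrom^3; when NULL, estimated
#'   from \code{bulkShell} via \code{\link{bulkDensity}}.
#' @param Rdomain solute-domain radius for the convergence check (default
#'   20 Angstrom).
#' @param bulkShell shell for the bulk-density estimate.
#' @param convTol absolute convergence tolerance in Angstrom^3; default is
#'   3 x the SEM of G at rMax (or 1 Angstrom^3 if no spread is available).
#' @return a \code{\linkS4class{KBIResult}}.
#' @export
kbIntegral <- function(hist, ref, rhoC = NULL, Rdomain = 20,
                       bulkShell = c(20, 30), convTol = NULL) {
  .checkBinning(hist, ref)
  if (is.null(rhoC)) rhoC <- bulkDensity(hist, ref, bulkShell)$rho
  if (!is.numeric(rhoC) || rhoC <= 0)
    stop("rhoC must be a positive bulk density", call. = FALSE)
  Rgrid <- seq_len(length(hist@counts)) * hist@binWidth
  N <- cumsum(hist@counts)
  Vcum <- cumsum(ref@siteVolumes)
  G <- N / rhoC - Vcum
  perFrame <- apply(hist@countsPerFrame, 2, cumsum) / rhoC - Vcum
  nf <- ncol(perFrame)
  sem <- if (nf > 1) apply(perFrame, 1, sd) / sqrt(nf) else
    rep(NA_real_, length(G))
  iR <- which.min(abs(Rgrid - Rdomain))
  iEnd <- length(Rgrid)
  if (is.null(convTol))
    convTol <- if (is.finite(sem[iEnd]) && sem[iEnd] > 0)
      3 * sem[iEnd] else 1
  new("KBIResult",
      R = Rgrid, G = G, GLmol = G * .NA_CONST * .A3_TO_L,
      perFrame = perFrame, sem = sem, rhoC = rhoC,
      converged = abs(G[iR] - G[iEnd]) <= convTol,
      Rdomain = Rdomain, species = hist@species)
}

#' Merge solvent species into one pseudo-component
#'
#' Concatenates minimum-distance record sets of distinct species into a
#' single record set treated as one species (e.g. all anions as one
#' cosolvent, justified by bulk electroneutrality). The merged bulk density
#' is the sum of the component densities, which the downstream
#' \code{\link{bulkDensity}} estimate reproduces automatically.
#'
#' @param ... two or more record data.frames from
#'   \code{\link{minimumDistances}} over the same frames.
#' @param tag species tag for the merged pseudo-component.
#' @return a merged records data.frame.
#' @export
mergePseudoComponents <- function(..., tag = "cosolvent") {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]]))
    parts <- parts[[1]]
  if (!length(parts)) stop("no record sets to merge", call. = FALSE)
  mols <- lapply(parts, function(p) unique(p$molecule))
  if (length(Reduce(intersect, mols)) > 0 && length(parts) > 1L)
    stop("record sets overlap: the same molecules appear in more than one ",
         "component", call. = FALSE)
  nf <- unique(vapply(parts, function(p) {
    v <- attr(p, "nFrames"); if (is.null(v)) NA_integer_ else as.integer(v)
  }, 1L))
  rmx <- unique(vapply(parts, function(p) {
    v <- attr(p, "rMax"); if (is.null(v)) NA_real_ else v
  }, 1.0))
  if (length(nf) != 1L || length(rmx) != 1L)
    stop("record sets were computed with different frames or rMax",
         call. = FALSE)
  out <- do.call(rbind, parts)
  out$species <- tag
  attr(out, "nFrames") <- nf
  attr(out, "rMax") <- rmx
  attr(out, "boxVolume") <- attr(parts[[1]], "boxVolume")
  out
}

#' Preferential-solvation parameter
#'
#' \code{Gamma(R) = rho_c * (G_pc(R) - G_pw(R))}: positive when the
#' cosolvent's KB integral exceeds water's, i.e. when the cosolvent
#' preferentially solvates the solute and displaces water from its surface.
#'
#' @param kbiCosolvent \code{\linkS4class{KBIResult}} of the cosolvent.
#' @param kbiWater \code{\linkS4class{KBIResult}} of water.
#' @param rhoC cosolvent bulk density; defaults to the density stored in
#'   \code{kbiCosolvent}.
#' @return a \code{\linkS4class{GammaResult}}.
#' @export
preferentialSolvation <- function(kbiCosolvent, kbiWater, rhoC = NULL) {
  if (length(kbiCosolvent@R) != length(kbiWater@R) ||
      max(abs(kbiCosolvent@R - kbiWater@R)) > 1e-9)
    stop("KB integrals are on different R grids", call. = FALSE)
  if (is.null(rhoC)) rhoC <- kbiCosolvent@rhoC
  g <- rhoC * (kbiCosolvent@G - kbiWater@G)
  sem <- rhoC * sqrt(kbiCosolvent@sem^2 + kbiWater@sem^2)
  new("GammaResult", R = kbiCosolvent@R, gamma = g, sem = sem,
      rhoC = rhoC,
      cosolvent = paste(kbiCosolvent@species, collapse = "+"),
      water = paste(kbiWater@species, collapse = "+"))
}

#' Coordination numbers at a distance cutoff
#'
#' Mean number of molecules of each species whose minimum distance to the
#' solute is at most \code{cutoff}, with the SEM across frames.
#'
#' @param records output of \code{\link{minimumDistances}} (one or more
#'   species).
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return data.frame(species, cutoff, mean, sem, nFrames).
#' @export
coordinationNumber <- function(records, cutoff = 5) {
  rmx <- attr(records, "rMax")
  if (!is.null(rmx) && cutoff > rmx)
    stop("cutoff exceeds the record censoring radius", call. = FALSE)
  nFrames <- attr(records, "nFrames")
  if (is.null(nFrames)) nFrames <- length(unique(records$frame))
  frames <- sort(unique(records$frame))
  out <- do.call(rbind, lapply(split(records, records$species),
    function(rr) {
      hit <- !is.na(rr$rmin) & rr$rmin <= cutoff
      perFrame <- as.numeric(table(factor(rr$frame[hit], levels = frames)))
      data.frame(species = rr$species[1], cutoff = cutoff,
                 mean = sum(hit) / nFrames,
                 sem = if (nFrames > 1)
                   sd(perFrame) / sqrt(nFrames) else NA_real_,
                 nFrames = nFrames, stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Ion hydration numbers as a function of distance to the solute
#'
#' For every ion molecule, counts the water molecules whose minimum
#' (any-atom) distance to that ion is within each radius, then averages
#' those counts in bins of the ion's minimum distance to the solute.
#'
#' @param frames list of \code{Frame}.
#' @param topology the matching \code{Topology}.
#' @param ionSpecies ion species tag.
#' @param waterSpecies water species tag (default \code{"water"}).
#' @param radii hydration radii in Angstrom (default \code{c(5, 10)}).
#' @param soluteSpecies solute species tag.
#' @param distanceBinWidth width of the ion-to-solute distance bins,
#'   Angstrom.
#' @param rMax largest ion-to-solute distance considered.
#' @return data.frame(bin_lo, bin_hi, radius, waters, sem, n_ions): mean
#'   water count per ion in each distance bin, for each radius.
#' @export
bulkCoordination <- function(frames, topology, ionSpecies,
                             waterSpecies = "water", radii = c(5, 10),
                             soluteSpecies = "protein",
                             distanceBinWidth = 2, rMax = 30) {
  if (is(frames, "Frame")) frames <- list(frames)
  a <- atoms(topology)
  radii <- sort(radii)
  rcut <- max(radii)
  ionRows <- a[a$species_tag == ionSpecies, ]
  watRows <- a[a$species_tag == waterSpecies, ]
  if (!nrow(ionRows)) stop("no '", ionSpecies, "' species", call. = FALSE)
  if (!nrow(watRows)) stop("no '", waterSpecies, "' species", call. = FALSE)
  ionMols <- unique(ionRows$molecule_index)
  watMols <- unique(watRows$molecule_index)
  nb <- ceiling(rMax / distanceBinWidth)
  acc <- list()
  for (fr in frames) {
    box <- boxSides(fr)
    .checkCutoff(rcut, box, "hydration radius")
    x <- coords(fr)
    solRec <- minimumDistances(fr, topology, ionSpecies,
                               soluteSpecies = soluteSpecies, rMax = rMax)
    cross <- cpp_cross_min_distances(
      x[ionRows$atom_index, , drop = FALSE],
      match(ionRows$molecule_index, ionMols),
      x[watRows$atom_index, , drop = FALSE],
      match(watRows$molecule_index, watMols),
      length(watMols), box, rcut)
    for (rad in radii) {
      nw <- tabulate(cross$mol_a[cross$dmin <= rad], length(ionMols))
      acc[[length(acc) + 1L]] <- data.frame(
        rsol = solRec$rmin, waters = nw, radius = rad)
    }
  }
  df <- do.call(rbind, acc)
  df <- df[!is.na(df$rsol) & df$rsol < rMax, ]
  if (!nrow(df))
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      radius = numeric(0), waters = numeric(0),
                      sem = numeric(0), n_ions = integer(0)))
  df$bin <- pmin(nb, floor(df$rsol / distanceBinWidth) + 1L)
  out <- do.call(rbind, lapply(split(df, list(df$bin, df$radius),
                                     drop = TRUE), function(g) {
    data.frame(bin_lo = (g$bin[1] - 1) * distanceBinWidth,
               bin_hi = g$bin[1] * distanceBinWidth,
               radius = g$radius[1],
               waters = mean(g$waters),
               sem = if (nrow(g) > 1)
                 sd(g$waters) / sqrt(nrow(g)) else NA_real_,
               n_ions = nrow(g))
  }))
  out <- out[order(out$radius, out$bin_lo), ]
  rownames(out) <- NULL
  out
}
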