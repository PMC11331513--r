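## Reading/writing structures and trajectories; species and residue-class
## assignment. PDB parsing is delegated to bio3d; the CRYST1 box record,
## which bio3d does not expose, is taken from the file text.

.PROTEIN_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "HSD", "HSE", "HSP", "CYX", "MSE")

.WATER_RESIDUES <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "SPC", "T3P")

#' Default residue-name to species map
#'
#' Maps the 20 standard amino acids (plus common protonation-state variants)
#' to species \code{"protein"} and common water residue names to
#' \code{"water"}; any other residue name becomes its own species tag.
#'
#' @return named list of character vectors, species tag -> residue names.
#' @export
defaultSpeciesMap <- function() {
  list(protein = .PROTEIN_RESIDUES, water = .WATER_RESIDUES)
}

#' Default residue-class map (VMD-like)
#'
#' ASP/GLU acidic; LYS/ARG/HIS basic; SER/THR/ASN/GLN/TYR/CYS polar;
#' the remaining standard amino acids nonpolar. Unknown residue names are
#' classified \code{"other"}, never dropped.
#'
#' @return named character vector, residue name -> class.
#' @export
defaultResidueClasses <- function() {
  c(ASP = "acidic", GLU = "acidic",
    LYS = "basic", ARG = "basic", HIS = "basic",
    HID = "basic", HIE = "basic", HIP = "basic",
    SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
    TYR = "polar", CYS = "polar", CYX = "polar",
    GLY = "nonpolar", ALA = "nonpolar", VAL = "nonpolar",
    LEU = "nonpolar", ILE = "nonpolar", PRO = "nonpolar",
    PHE = "nonpolar", MET = "nonpolar", TRP = "nonpolar",
    MSE = "nonpolar")
}

.speciesOf <- function(residue_name, speciesMap) {
  out <- residue_name
  for (tag in names(speciesMap))
    out[residue_name %in% speciesMap[[tag]]] <- tag
  out
}

.elementOf <- function(atom_name) {
  # strip leading digits (PDB hydrogens like 1H), take leading letters
  nm <- sub("^[0-9]+", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA"), two, one)
}

#' Build a Topology from an atom table
#'
#' Groups atoms into molecules (one molecule per chain for the solute
#' species, one per residue block for solvents), assigns species tags from
#' residue names, and validates template homogeneity.
#'
#' @param atom_name,residue_name,residue_number,chain per-atom vectors.
#' @param element optional element symbols (derived from names if NULL).
#' @param speciesMap see \code{\link{defaultSpeciesMap}}.
#' @return a \code{Topology}.
#' @export
buildTopology <- function(atom_name, residue_name, residue_number, chain,
                          element = NULL,
                          speciesMap = defaultSpeciesMap()) {
  n <- length(atom_name)
  stopifnot(length(residue_name) == n, length(residue_number) == n,
            length(chain) == n)
  chain[is.na(chain) | chain == ""] <- " "
  if (is.null(element)) element <- .elementOf(atom_name)
  species <- .speciesOf(residue_name, speciesMap)

  # residue blocks: runs of constant (chain, residue_number, residue_name)
  key <- paste(chain, residue_number, residue_name, sep = "\r")
  block <- cumsum(c(TRUE, key[-1] != key[-n]))

  # molecules: solute = one per chain run; solvents = one per residue block
  solute <- species == "protein"
  molkey <- ifelse(solute, paste("P", chain, cumsum(c(TRUE,
              (solute[-1] != solute[-n]) | (chain[-1] != chain[-n])))),
              paste("B", block))
  molecule <- cumsum(c(TRUE, molkey[-1] != molkey[-n]))

  atoms <- data.frame(
    atom_index = seq_len(n),
    atom_name = atom_name,
    element = element,
    residue_name = residue_name,
    residue_index = block,
    molecule_index = molecule,
    species_tag = species,
    chain = chain,
    stringsAsFactors = FALSE)
  tryCatch(new("Topology", atoms = atoms), error = function(e)
    stop("inconsistent molecule templates: ", conditionMessage(e),
         call. = FALSE))
}

.readCryst1 <- function(path) {
  lines <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  f <- lines[[1]]
  sides <- as.numeric(c(substr(f, 7, 15), substr(f, 16, 24),
                        substr(f, 25, 33)))
  angles <- as.numeric(c(substr(f, 34, 40), substr(f, 41, 47),
                         substr(f, 48, 54)))
  if (any(abs(angles - 90) > 1e-3))
    stop("non-orthorhombic box in CRYST1 record: unsupported", call. = FALSE)
  sides
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records via \code{bio3d::read.pdb}, groups atoms into
#' molecules and species, and takes the orthorhombic box from the CRYST1
#' record (or from \code{box}, which overrides).
#'
#' @param path PDB file.
#' @param box optional numeric(3) side lengths in Angstrom; required when
#'   the file has no CRYST1 record.
#' @param speciesMap see \code{\link{defaultSpeciesMap}}.
#' @return list with elements \code{topology} (a \code{Topology}) and
#'   \code{frame} (a \code{Frame}).
#' @export
readStructure <- function(path, box = NULL,
                          speciesMap = defaultSpeciesMap()) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (is.null(box)) box <- .readCryst1(path)
  if (is.null(box))
    stop("no CRYST1 record in ", path,
         " and no box override given; supply box = c(a, b, c)",
         call. = FALSE)
  box <- .validateBox(box)
  topo <- buildTopology(atom_name = a$elety, residue_name = a$resid,
                        residue_number = a$resno, chain = a$chain,
                        element = if (all(nzchar(a$elesy) & !is.na(a$elesy)))
                          a$elesy else NULL,
                        speciesMap = speciesMap)
  xyz <- cbind(a$x, a$y, a$z)
  frame <- new("Frame", coords = xyz, box = box, frameIndex = 1L)
  list(topology = topo, frame = frame)
}

#' Write a structure as a canonical PDB file
#'
#' Emits a CRYST1 record followed by ATOM records through
#' \code{bio3d::write.pdb}. Residue and atom serials are wrapped to the PDB
#' field widths, so the output of a read/write round trip is stable.
#'
#' @param topology a \code{Topology}.
#' @param frame a \code{Frame} with matching atom count.
#' @param path output file.
#' @export
writeStructure <- function(topology, frame, path) {
  a <- atoms(topology)
  stopifnot(nrow(coords(frame)) == nrow(a))
  box <- boxSides(frame)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(coords(frame))),
                   type = rep("ATOM", nrow(a)),
                   resno = ((a$residue_index - 1L) %% 9999L) + 1L,
                   resid = a$residue_name,
                   eleno = ((a$atom_index - 1L) %% 99999L) + 1L,
                   elety = a$atom_name,
                   chain = ifelse(a$chain == " ", "", a$chain),
                   elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  cryst <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1], box[2], box[3], 90, 90, 90)
  writeLines(c(cryst, readLines(tmp, warn = FALSE)), path)
  invisible(path)
}

## ---- XYZ dialect: box carried on the comment line as "box: a b c" ------

#' Write frames as XYZ with box metadata
#'
#' Plain XYZ where each frame's comment line carries the orthorhombic box
#' as \code{frame <i> box: a b c}. Coordinates are written with 3 decimals.
#'
#' @param frames list of \code{Frame}.
#' @param topology the matching \code{Topology}.
#' @param path output file.
#' @export
writeTrajectoryXYZ <- function(frames, topology, path) {
  nm <- atoms(topology)$atom_name
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (fr in frames) {
    x <- coords(fr)
    stopifnot(nrow(x) == length(nm))
    b <- boxSides(fr)
    writeLines(c(as.character(length(nm)),
                 sprintf("frame %d box: %.4f %.4f %.4f",
                         frameIndex(fr), b[1], b[2], b[3]),
                 sprintf("%-4s %12.3f %12.3f %12.3f",
                         nm, x[, 1], x[, 2], x[, 3])), con)
  }
  invisible(path)
}

.readTrajectoryXYZ <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  n <- nAtoms(topology)
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ at line ", i, call. = FALSE)
    if (nat != n)
      stop(sprintf(
        "frame %d: atom count %d does not match topology (%d atoms)",
        fidx, nat, n), call. = FALSE)
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexec("box:\\s*([0-9.eE+-]+)\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)",
                            comment))[[1]]
    if (length(m) != 4L)
      stop(sprintf("frame %d: no 'box: a b c' metadata on comment line",
                   fidx), call. = FALSE)
    box <- .validateBox(as.numeric(m[2:4]))
    body <- lines[(i + 2L):(i + 1L + nat)]
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    xyz <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    fidx <- fidx + 1L
    frames[[fidx]] <- new("Frame", coords = xyz, box = box,
                          frameIndex = fidx)
    i <- i + 2L + nat
  }
  frames
}

.readTrajectoryDCD <- function(path, topology) {
  # bio3d returns the unit-cell matrix (a, b, c, alpha, beta, gamma per
  # frame) with cell = TRUE and the coordinates without it
  cell <- unclass(bio3d::read.dcd(path, verbose = FALSE, cell = TRUE))
  xyzmat <- unclass(bio3d::read.dcd(path, verbose = FALSE))
  if (is.null(dim(xyzmat))) xyzmat <- matrix(xyzmat, nrow = 1)
  if (nrow(cell) != nrow(xyzmat) || ncol(cell) != 6L)
    stop("DCD file carries no per-frame unit-cell information",
         call. = FALSE)
  n <- nAtoms(topology)
  frames <- vector("list", nrow(xyzmat))
  for (k in seq_len(nrow(xyzmat))) {
    if (ncol(xyzmat) != 3L * n)
      stop(sprintf(
        "frame %d: atom count %d does not match topology (%d atoms)",
        k - 1L, ncol(xyzmat) / 3L, n), call. = FALSE)
    ang <- cell[k, 4:6]
    if (any(abs(ang - 90) > 1e-3))
      stop("non-orthorhombic DCD unit cell: unsupported", call. = FALSE)
    frames[[k]] <- new("Frame",
                       coords = matrix(xyzmat[k, ], ncol = 3, byrow = TRUE),
                       box = as.numeric(cell[k, 1:3]), frameIndex = k)
  }
  frames
}

#' Read a coordinate trajectory
#'
#' Supports the XYZ dialect written by \code{\link{writeTrajectoryXYZ}}
#' (box on the comment line) and CHARMM/NAMD DCD with an orthorhombic unit
#' cell (via \code{bio3d::read.dcd}). XTC is not supported.
#'
#' @param path trajectory file (.xyz or .dcd).
#' @param topology the matching \code{Topology}; atom counts are checked
#'   per frame.
#' @return list of \code{Frame} in file order.
#' @export
readTrajectory <- function(path, topology) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    xyz = .readTrajectoryXYZ(path, topology),
    dcd = .readTrajectoryDCD(path, topology),
    xtc = stop("XTC input is not supported; convert to DCD or XYZ",
               call. = FALSE),
    stop("unsupported trajectory format: .", ext, call. = FALSE))
}

#' Write frames as a CHARMM-style DCD trajectory
#'
#' Minimal single-precision DCD writer with an orthorhombic unit-cell
#' record per frame, readable by \code{bio3d::read.dcd}.
#'
#' @param frames list of \code{Frame}.
#' @param topology the matching \code{Topology}.
#' @param path output file.
#' @export
writeTrajectoryDCD <- function(frames, topology, path) {
  n <- nAtoms(topology)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L)
  # header record: "CORD" + 20 control ints (crystal flag at slot 11,
  # CHARMM version 24 at slot 20)
  icntrl <- integer(20)
  icntrl[1] <- length(frames); icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[4] <- length(frames); icntrl[11] <- 1L; icntrl[20] <- 24L
  wInt(84L); writeChar("CORD", con, eos = NULL); wInt(icntrl); wInt(84L)
  title <- formatC("Written by solvkit", width = 80, flag = "-")
  wInt(4L + 80L); wInt(1L); writeChar(title, con, eos = NULL); wInt(4L + 80L)
  wInt(4L); wInt(n); wInt(4L)
  for (fr in frames) {
    stopifnot(nrow(coords(fr)) == n)
    b <- boxSides(fr)
    # CHARMM XTL order: a, cos(gamma), b, cos(beta), cos(alpha), c
    wInt(48L)
    writeBin(as.double(c(b[1], 0, b[2], 0, 0, b[3])), con, size = 8L)
    wInt(48L)
    x <- coords(fr)
    for (k in 1:3) {
      wInt(4L * n)
      writeBin(as.double(x[, k]), con, size = 4L)
      wInt(4L * n)
    }
  }
  invisible(path)
}

#' Classify solute residues
#'
#' Labels every residue of the solute species with its chemical class
#' (acidic, basic, polar, nonpolar); names absent from the map are labeled
#' \code{"other"} with a warning, never dropped.
#'
#' @param topology a \code{Topology} containing a \code{"protein"} species.
#' @param classMap named vector residue name -> class; see
#'   \code{\link{defaultResidueClasses}}.
#' @param soluteSpecies species tag of the solute.
#' @return data.frame(residue_index, residue_name, class) with one row per
#'   solute residue, plus a \code{"classCounts"} attribute.
#' @export
classifyResidues <- function(topology, classMap = defaultResidueClasses(),
                             soluteSpecies = "protein") {
  a <- atoms(topology)
  sol <- a[a$species_tag == soluteSpecies, ]
  if (!nrow(sol))
    stop("topology has no '", soluteSpecies, "' species", call. = FALSE)
  res <- sol[!duplicated(sol$residue_index),
             c("residue_index", "residue_name")]
  cls <- unname(classMap[res$residue_name])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("unknown residue name(s) classified as 'other': ",
            paste(unique(res$residue_name[unknown]), collapse = ", "),
            call. = FALSE)
    cls[unknown] <- "other"
  }
  out <- data.frame(res, class = cls, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "classCounts") <- table(out$class)
  out
}
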