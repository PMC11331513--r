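#' Accessors for solvkit objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x a solvkit object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setGeneric("speciesTags", function(x) standardGeneric("speciesTags"))
#' @rdname accessors
#' @export
setMethod("speciesTags", "Topology", function(x)
  unique(x@atoms$species_tag))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "Frame", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("boxSides", function(x) standardGeneric("boxSides"))
#' @rdname accessors
#' @export
setMethod("boxSides", "Frame", function(x) x@box)

#' @rdname accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setMethod("frameIndex", "Frame", function(x) x@frameIndex)

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setMethod("binCenters", "MinDistHistogram", function(x)
  (seq_len(length(x@counts)) - 0.5) * x@binWidth)
#' @rdname accessors
#' @export
setMethod("binCenters", "ReferenceCounts", function(x)
  (seq_len(length(x@refCounts)) - 0.5) * x@binWidth)

#' @rdname accessors
#' @export
setGeneric("siteCounts", function(x) standardGeneric("siteCounts"))
#' @rdname accessors
#' @export
setMethod("siteCounts", "MinDistHistogram", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("referenceSiteCounts",
           function(x) standardGeneric("referenceSiteCounts"))
#' @rdname accessors
#' @export
setMethod("referenceSiteCounts", "ReferenceCounts", function(x) x@refCounts)

#' @rdname accessors
#' @export
setGeneric("siteVolumes", function(x) standardGeneric("siteVolumes"))
#' @rdname accessors
#' @export
setMethod("siteVolumes", "ReferenceCounts", function(x) x@siteVolumes)

#' @rdname accessors
#' @export
setGeneric("mddf", function(x) standardGeneric("mddf"))
#' @rdname accessors
#' @export
setMethod("mddf", "MDDFResult", function(x)
  data.frame(r = x@r, gmd = x@gmd, undefined = x@undefined))

#' @rdname accessors
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))
#' @rdname accessors
#' @export
setMethod("contributions", "MDDFResult", function(x) x@contributions)

#' @rdname accessors
#' @export
setGeneric("kbi", function(x) standardGeneric("kbi"))
#' @rdname accessors
#' @export
setMethod("kbi", "KBIResult", function(x)
  data.frame(R = x@R, G = x@G, G_Lmol = x@GLmol, sem = x@sem))

#' Evaluate a KB integral at a given radius
#'
#' Returns G(R) at the grid point closest to \code{R}.
#'
#' @param x a \code{KBIResult}.
#' @param R radius in Angstrom.
#' @return G(R) in Angstrom^3.
#' @export
kbiAt <- function(x, R) {
  stopifnot(is(x, "KBIResult"))
  x@G[which.min(abs(x@R - R))]
}

#' @rdname accessors
#' @export
setGeneric("gammaCurve", function(x) standardGeneric("gammaCurve"))
#' @rdname accessors
#' @export
setMethod("gammaCurve", "GammaResult", function(x)
  data.frame(R = x@R, gamma = x@gamma, sem = x@sem))

#' Evaluate a preferential-solvation curve at a given radius
#'
#' @param x a \code{GammaResult}.
#' @param R radius in Angstrom.
#' @return Gamma(R), dimensionless.
#' @export
gammaAt <- function(x, R) {
  stopifnot(is(x, "GammaResult"))
  x@gamma[which.min(abs(x@R - R))]
}

#' @rdname accessors
#' @export
setGeneric("mapMatrix", function(x) standardGeneric("mapMatrix"))
#' @rdname accessors
#' @export
setMethod("mapMatrix", "ResidueDistanceMap", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("mapMatrix", "DifferenceMap", function(x) x@deltaCounts)
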