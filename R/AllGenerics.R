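#' @importClassesFrom Biostrings AAStringSet
NULL

#' Accessors for memdesign objects
#'
#' Small accessor generics: `designedSequence` returns the residue string of
#' a [DesignedProtein-class]; `segmentMap` and `helixPosition` its
#' per-residue annotations; `caCoords` the CA matrix of a
#' [BundleModel-class]; `kd`, `nSites`, `em`, `payload` and `truth` the
#' obvious slots of the fit and synthetic-data containers.
#'
#' @param x an object.
#' @return the slot value.
#' @name accessors
#' @aliases designedSequence segmentMap helixPosition caCoords kd nSites em
#'   payload truth
NULL

#' @rdname accessors
#' @export
setGeneric("designedSequence", function(x) standardGeneric("designedSequence"))
#' @rdname accessors
#' @export
setGeneric("segmentMap", function(x) standardGeneric("segmentMap"))
#' @rdname accessors
#' @export
setGeneric("helixPosition", function(x) standardGeneric("helixPosition"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("em", function(x) standardGeneric("em"))
#' @rdname accessors
#' @export
setGeneric("payload", function(x) standardGeneric("payload"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname accessors
setMethod("designedSequence", "DesignedProtein", function(x) x@sequence)
#' @rdname accessors
setMethod("segmentMap", "DesignedProtein", function(x) x@segmentMap)
#' @rdname accessors
setMethod("helixPosition", "DesignedProtein", function(x) x@helixPosition)
#' @rdname accessors
setMethod("caCoords", "BundleModel", function(x) x@caCoords)
#' @rdname accessors
setMethod("kd", "BindingFit", function(x) x@kd)
#' @rdname accessors
setMethod("kd", "KineticFit", function(x) x@kdKinetic)
#' @rdname accessors
setMethod("nSites", "BindingFit", function(x) x@nSites)
#' @rdname accessors
setMethod("em", "NernstFit", function(x) x@em)
#' @rdname accessors
setMethod("payload", "SyntheticDataset", function(x) x@payload)
#' @rdname accessors
setMethod("truth", "SyntheticDataset", function(x) x@truth)

setMethod("show", "HPPattern", function(object) {
  cat("HPPattern of length", nchar(object@symbols), "\n ", object@symbols, "\n")
})

setMethod("show", "DesignedProtein", function(object) {
  segs <- rle(object@segmentMap)
  cat("DesignedProtein,", nchar(object@sequence), "residues\n")
  cat(" segments:", paste(sprintf("%s(%d)", segs$values, segs$lengths),
                          collapse = " "), "\n")
  seq <- object@sequence
  for (i in seq(1L, nchar(seq), by = 60L))
    cat(" ", substr(seq, i, min(i + 59L, nchar(seq))), "\n", sep = "")
})

setMethod("show", "TMAlignment", function(object) {
  cat("TMAlignment:", length(object@seqs), "sequences x",
      unique(Biostrings::width(object@seqs)), "columns;",
      nrow(object@tmWindows), "TM windows\n")
})

setMethod("show", "BundleModel", function(object) {
  cat("BundleModel:", nrow(object@caCoords), "CA atoms, 4 antiparallel",
      "helices on a square lattice\n")
  cat(" spacing", object@params@interAxisSpacing, "A, membrane half-thickness",
      object@params@membraneHalfThickness, "A\n")
})

setMethod("show", "MutationPlan", function(object) {
  cat("MutationPlan (", object@mode, "-His):\n", sep = "")
  cat(" His sites: ",
      paste(sprintf("res %d (H%d pos %d, depth %.2f A)",
                    object@hisSites$chainRes, object@hisSites$helix,
                    object@hisSites$helixPos, object@hisSites$depth),
            collapse = "; "), "\n", sep = "")
  if (nrow(object@cavityMutations))
    cat(" cavity: ", paste(sprintf("%s%d%s", object@cavityMutations$from,
                                   object@cavityMutations$chainRes,
                                   object@cavityMutations$to),
                           collapse = ", "), "\n", sep = "")
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: Kd = %.3g +/- %.2g uM, n = %.3g sites/protomer\n",
              object@kd, object@se[["kd"]], object@nSites))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf(
    "KineticFit: kon = %.3g /uM/s, koff = %.3g /s, Kd(kinetic) = %.3g uM\n",
    object@kon, object@koff, object@kdKinetic))
})

setMethod("show", "NernstFit", function(object) {
  cat(sprintf("NernstFit: Em = %.1f +/- %.2g mV vs SHE (%g mV/decade)\n",
              object@em, object@se[["em"]], object@slopeMv))
})

setMethod("show", "TopologyScore", function(object) {
  cat(sprintf("TopologyScore: %s (inside K/R = %d, outside K/R = %d)\n",
              object@orientation, object@insidePositive,
              object@outsidePositive))
})

setMethod("show", "CompositionProperties", function(object) {
  cat(sprintf("CompositionProperties: MW %.2f Da, eps280 %g /M/cm (%d W, %d Y, %d cystine)\n",
              object@mwAverage, object@eps280, object@nTrp, object@nTyr,
              object@nCystine))
})

setMethod("show", "SECCalibration", function(object) {
  cat(sprintf("SECCalibration: Rs = %.3f + %.3f * log10(M); max |resid| %.3g nm\n",
              object@intercept, object@slope, max(abs(object@residuals))))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (seed ", object@provenance$seed, "): ",
      class(object@payload)[1], " payload\n truth: ",
      paste(names(object@truth), unlist(lapply(object@truth, function(v)
        paste(signif(unlist(v), 4), collapse = ","))),
        sep = "=", collapse = "; "), "\n", sep = "")
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d points, protein %.3g uM, pathlength %g cm\n",
              length(object@ligand), object@proteinConc, object@pathlength))
})

setMethod("show", "PotentiometrySeries", function(object) {
  cat(sprintf("PotentiometrySeries (%s): %d points, Eh %.0f..%.0f mV\n",
              object@sweep, length(object@eh), min(object@eh), max(object@eh)))
})
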