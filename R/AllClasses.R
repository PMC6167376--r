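#' @import methods
#' @importFrom stats approx coef lm median nls.control predict quantile rnorm
#'   sd setNames vcov
#' @importFrom utils read.csv write.csv head
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue classification scheme for hydrophobic/polar abstraction
#'
#' Maps each of the 20 standard amino acids to the binary class `h`
#' (hydrophobic) or `p` (polar) and carries the two consensus thresholds used
#' when abstracting an alignment: the fraction of glycine required for a
#' column to be emitted as `G`, and the fraction required for a single residue
#' to be reported as the column consensus.
#'
#' @slot classOf named character vector mapping one-letter residue codes to
#'   `"h"` or `"p"`.
#' @slot glyThreshold glycine conservation threshold in (0, 1].
#' @slot consensusThreshold modal-residue threshold in (0, 1].
#' @export
setClass("ResidueClassScheme",
  representation(classOf = "character",
                 glyThreshold = "numeric",
                 consensusThreshold = "numeric"))

setValidity("ResidueClassScheme", function(object) {
  msg <- character()
  if (!setequal(names(object@classOf), AA20))
    msg <- c(msg, "classOf must map exactly the 20 standard residues")
  if (!all(object@classOf %in% c("h", "p")))
    msg <- c(msg, "classes must be 'h' or 'p'")
  for (nm in c("glyThreshold", "consensusThreshold")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      msg <- c(msg, paste(nm, "must be a single value in (0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Binary hydrophobicity pattern
#'
#' A string over the alphabet `{h, p, G}` describing one transmembrane
#' segment: `h` hydrophobic, `p` polar, `G` conserved glycine.
#'
#' @slot symbols single character string over `{h, p, G}`.
#' @export
setClass("HPPattern", representation(symbols = "character"))

setValidity("HPPattern", function(object) {
  if (length(object@symbols) != 1L || nchar(object@symbols) < 1L)
    return("symbols must be a single non-empty string")
  ok <- strsplit(object@symbols, "")[[1]] %in% c("h", "p", "G")
  if (!all(ok)) return("pattern may contain only the symbols h, p and G")
  TRUE
})

#' Gapped alignment of small membrane proteins with marked TM windows
#'
#' @slot seqs an [Biostrings::AAStringSet] of equal-length gapped sequences
#'   (gap character `-`).
#' @slot tmWindows integer matrix with columns `start`, `end` (1-based,
#'   inclusive column ranges), one row per transmembrane domain, ordered and
#'   non-overlapping.
#' @export
setClass("TMAlignment",
  representation(seqs = "AAStringSet", tmWindows = "matrix"))

setValidity("TMAlignment", function(object) {
  msg <- character()
  if (length(object@seqs) < 1L) msg <- c(msg, "alignment is empty")
  w <- unique(Biostrings::width(object@seqs))
  if (length(w) > 1L) msg <- c(msg, "aligned sequences must have equal length")
  tw <- object@tmWindows
  if (ncol(tw) != 2L) msg <- c(msg, "tmWindows must have two columns (start, end)")
  else {
    if (any(tw[, 1] > tw[, 2])) msg <- c(msg, "window start must not exceed end")
    if (length(w) == 1L && any(tw > w)) msg <- c(msg, "window outside alignment width")
    if (nrow(tw) > 1L && any(tw[-1L, 1] <= tw[-nrow(tw), 2]))
      msg <- c(msg, "tmWindows must be ordered and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of one extramembrane loop
#'
#' The loop template is the fixed octapeptide `SSGXXGSS`; the placeholder `X`
#' carries the topology-determining charge (glutamate on the periplasmic
#' side, lysine on the cytoplasmic side, following the positive-inside rule).
#'
#' @slot xResidue `"E"` or `"K"`.
#' @slot side `"periplasmic"` or `"cytoplasmic"`.
#' @export
setClass("LoopSpec",
  representation(xResidue = "character", side = "character"))

setValidity("LoopSpec", function(object) {
  msg <- character()
  if (!object@xResidue %in% c("E", "K")) msg <- c(msg, "xResidue must be E or K")
  if (!object@side %in% c("periplasmic", "cytoplasmic"))
    msg <- c(msg, "side must be periplasmic or cytoplasmic")
  if (length(msg)) msg else TRUE
})

#' Specification of a single-chain four-helix construct
#'
#' @slot helixSequence the transmembrane helix sequence used for all four
#'   helices (21 residues for the reference design).
#' @slot loops list of exactly three [LoopSpec-class] objects.
#' @slot trpPosition 1-based chain position to replace with tryptophan, or
#'   `NA` for none.
#' @slot nTerminal N-terminal residue string (default `"M"`).
#' @slot epitope C-terminal epitope residue string.
#' @slot affinityTag affinity-tag residue string (may be empty).
#' @export
setClass("ConstructSpec",
  representation(helixSequence = "character", loops = "list",
                 trpPosition = "numeric", nTerminal = "character",
                 epitope = "character", affinityTag = "character"))

setValidity("ConstructSpec", function(object) {
  msg <- character()
  if (length(object@loops) != 3L) msg <- c(msg, "exactly 3 loops are required")
  else if (!all(vapply(object@loops, is, logical(1), "LoopSpec")))
    msg <- c(msg, "loops must be LoopSpec objects")
  if (!grepl("^[A-Z]+$", object@helixSequence))
    msg <- c(msg, "helixSequence must be an uppercase residue string")
  if (length(msg)) msg else TRUE
})

#' A designed protein with per-residue segment annotation
#'
#' @slot sequence full-chain residue string.
#' @slot segmentMap per-residue segment labels among `Nterm`, `H1`..`H4`,
#'   `L1`..`L3`, `epitope`, `tag`.
#' @slot helixPosition per-residue 1-based index within its helix
#'   (`NA` outside helices).
#' @export
setClass("DesignedProtein",
  representation(sequence = "character", segmentMap = "character",
                 helixPosition = "integer"))

setValidity("DesignedProtein", function(object) {
  n <- nchar(object@sequence)
  msg <- character()
  if (length(object@segmentMap) != n)
    msg <- c(msg, "segmentMap length must equal sequence length")
  if (length(object@helixPosition) != n)
    msg <- c(msg, "helixPosition length must equal sequence length")
  helixRes <- grepl("^H[1-4]$", object@segmentMap)
  if (any(is.na(object@helixPosition[helixRes])))
    msg <- c(msg, "helix residues must carry a helix position")
  if (length(msg)) msg else TRUE
})

#' Positive-inside topology score
#'
#' @slot orientation `"N_in_C_in"`, `"N_out_C_out"` or `"ambiguous"`.
#' @slot insidePositive count of K/R on the assigned inside.
#' @slot outsidePositive count of K/R on the assigned outside.
#' @slot score `insidePositive - outsidePositive`.
#' @export
setClass("TopologyScore",
  representation(orientation = "character", insidePositive = "integer",
                 outsidePositive = "integer", score = "integer"))

#' Sequence-derived composition properties
#'
#' @slot counts named integer vector of residue counts.
#' @slot mwAverage average (isotope-averaged) molecular weight, Da.
#' @slot eps280 molar extinction coefficient at 280 nm, /M/cm.
#' @slot nTrp,nTyr,nCystine chromophore counts entering `eps280`.
#' @export
setClass("CompositionProperties",
  representation(counts = "integer", mwAverage = "numeric", eps280 = "numeric",
                 nTrp = "integer", nTyr = "integer", nCystine = "integer"))

#' Geometric parameters of the idealized four-helix bundle
#'
#' All lengths in Angstrom. The bundle is four ideal alpha-helices on a
#' square lattice with consecutive helices antiparallel, embedded in a
#' membrane slab of half-thickness `membraneHalfThickness` centred at z = 0.
#'
#' @slot nResPerHelix residues per helix (default 21).
#' @slot risePerRes helical rise per residue (default 1.5).
#' @slot twistDeg helical twist per residue, degrees (default 100).
#' @slot helixRadius CA radius of the ideal helix (default 2.3).
#' @slot interAxisSpacing square-lattice spacing between adjacent helix axes
#'   (default 10).
#' @slot membraneHalfThickness half-thickness of the slab (default 15.75,
#'   half the 21 x 1.5 helical span).
#' @slot phaseDeg additional azimuthal phase applied to every helix after the
#'   polar-face alignment (default 0).
#' @export
setClass("BundleParams",
  representation(nResPerHelix = "numeric", risePerRes = "numeric",
                 twistDeg = "numeric", helixRadius = "numeric",
                 interAxisSpacing = "numeric",
                 membraneHalfThickness = "numeric", phaseDeg = "numeric"))

setValidity("BundleParams", function(object) {
  pos <- c("nResPerHelix", "risePerRes", "helixRadius", "interAxisSpacing",
           "membraneHalfThickness")
  bad <- pos[vapply(pos, function(nm) slot(object, nm) <= 0, logical(1))]
  if (length(bad)) paste("slots must be positive:", paste(bad, collapse = ", "))
  else TRUE
})

#' Idealized antiparallel four-helix bundle CA model
#'
#' @slot caCoords numeric matrix (one row per residue) of CA coordinates with
#'   columns x, y, z, in chain order over the four helices.
#' @slot helixAxes 4 x 3 matrix of unit axis vectors (alternating sign).
#' @slot membraneNormal unit vector, the slab normal (z).
#' @slot residueIndexMap data.frame with columns `helix`, `helixPos`,
#'   `chainRes`, `residue` mapping bundle rows to chain numbering.
#' @slot params the [BundleParams-class] used.
#' @slot center xy coordinates of the bundle axis.
#' @export
setClass("BundleModel",
  representation(caCoords = "matrix", helixAxes = "matrix",
                 membraneNormal = "numeric", residueIndexMap = "data.frame",
                 params = "BundleParams", center = "numeric"))

setValidity("BundleModel", function(object) {
  msg <- character()
  if (nrow(object@caCoords) != nrow(object@residueIndexMap))
    msg <- c(msg, "caCoords and residueIndexMap must agree in length")
  d <- object@helixAxes %*% t(object@helixAxes)
  if (max(abs(abs(d[cbind(1:3, 2:4)]) - 1)) > 1e-6)
    msg <- c(msg, "adjacent helix axes must be (anti)parallel unit vectors")
  if (any(d[cbind(1:3, 2:4)] > -1 + 1e-6))
    msg <- c(msg, "consecutive helices must be antiparallel")
  if (length(msg)) msg else TRUE
})

#' Histidine-site mutation plan
#'
#' @slot mode `"mono"` or `"bis"`.
#' @slot hisSites data.frame of candidate site(s): columns `chainRes`,
#'   `helix`, `helixPos`, `depth`, `facingAngle`.
#' @slot cavityMutations data.frame of hollowing mutations: columns
#'   `chainRes`, `helix`, `from`, `to`.
#' @export
setClass("MutationPlan",
  representation(mode = "character", hisSites = "data.frame",
                 cavityMutations = "data.frame"))

setValidity("MutationPlan", function(object) {
  msg <- character()
  if (!object@mode %in% c("mono", "bis")) msg <- c(msg, "mode must be mono or bis")
  n <- nrow(object@hisSites)
  if (object@mode == "mono" && n != 1L) msg <- c(msg, "mono plans carry one site")
  if (object@mode == "bis") {
    if (n != 2L) msg <- c(msg, "bis plans carry two sites")
    else {
      hx <- sort(object@hisSites$helix)
      if (!identical(hx, c(1L, 3L)) && !identical(hx, c(2L, 4L)))
        msg <- c(msg, "bis sites must sit on diagonally opposite helices")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Equilibrium titration series
#'
#' @slot proteinConc total protomer concentration, uM.
#' @slot ligand total ligand per point, uM (non-negative, non-decreasing).
#' @slot signal observed signal, AU.
#' @slot pathlength optical pathlength, cm.
#' @export
setClass("TitrationSeries",
  representation(proteinConc = "numeric", ligand = "numeric",
                 signal = "numeric", pathlength = "numeric"))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (object@proteinConc <= 0) msg <- c(msg, "proteinConc must be positive")
  if (length(object@ligand) != length(object@signal))
    msg <- c(msg, "ligand and signal must have equal length")
  if (any(object@ligand < 0)) msg <- c(msg, "ligand must be non-negative")
  if (is.unsorted(object@ligand)) msg <- c(msg, "ligand must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Equilibrium binding fit
#'
#' @slot kd apparent dissociation constant, uM.
#' @slot nSites binding sites per protomer (stoichiometry).
#' @slot signalPerBound signal per uM bound ligand, AU/uM.
#' @slot backgroundSlope signal per uM free ligand, AU/uM.
#' @slot se named standard errors of the fitted parameters.
#' @slot cov parameter covariance matrix.
#' @export
setClass("BindingFit",
  representation(kd = "numeric", nSites = "numeric",
                 signalPerBound = "numeric", backgroundSlope = "numeric",
                 se = "numeric", cov = "matrix"))

#' Kinetic binding fit
#'
#' @slot kon association rate, /uM/s.
#' @slot koff dissociation rate, /s (clamped at 0 if fitted negative).
#' @slot kobs data.frame of per-trace observed rates: columns `ligand`, `kobs`.
#' @slot kdKinetic koff/kon, uM.
#' @slot koffClamped TRUE when a negative fitted intercept was clamped to 0.
#' @slot se named standard errors for kon and koff.
#' @export
setClass("KineticFit",
  representation(kon = "numeric", koff = "numeric", kobs = "data.frame",
                 kdKinetic = "numeric", koffClamped = "logical",
                 se = "numeric"))

#' Absorbance spectrum
#'
#' @slot wavelength strictly increasing wavelength grid, nm.
#' @slot absorbance absorbance values, AU.
#' @slot stateLabel optional spectral state label.
#' @export
setClass("Spectrum",
  representation(wavelength = "numeric", absorbance = "numeric",
                 stateLabel = "character"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@absorbance))
    msg <- c(msg, "wavelength and absorbance must have equal length")
  if (any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Potentiometric titration sweep
#'
#' @slot eh ambient redox potential, mV vs SHE (strictly monotone).
#' @slot absorbance observed absorbance, AU.
#' @slot sweep `"reductive"` or `"oxidative"`.
#' @export
setClass("PotentiometrySeries",
  representation(eh = "numeric", absorbance = "numeric", sweep = "character"))

setValidity("PotentiometrySeries", function(object) {
  msg <- character()
  if (length(object@eh) != length(object@absorbance))
    msg <- c(msg, "eh and absorbance must have equal length")
  d <- diff(object@eh)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    msg <- c(msg, "eh must be strictly monotone within a sweep")
  if (!object@sweep %in% c("reductive", "oxidative"))
    msg <- c(msg, "sweep must be reductive or oxidative")
  if (length(msg)) msg else TRUE
})

#' One-electron Nernst fit
#'
#' @slot em midpoint potential, mV vs SHE.
#' @slot absMin,absMax asymptotic absorbances (oxidized / reduced).
#' @slot slopeMv Nernst slope, mV per decade (59 at 25 C unless freed).
#' @slot se named standard errors.
#' @slot cov parameter covariance matrix.
#' @export
setClass("NernstFit",
  representation(em = "numeric", absMin = "numeric", absMax = "numeric",
                 slopeMv = "numeric", se = "numeric", cov = "matrix"))

setValidity("NernstFit", function(object) {
  if (object@absMax <= object@absMin) "absMax must exceed absMin" else TRUE
})

#' Size-exclusion calibration against protein standards
#'
#' Linear model `Rs = a + b * log10(mass)` fitted to the standards; the
#' inverse map gives the apparent mass at a measured Stokes radius.
#'
#' @slot intercept,slope coefficients of the calibration line.
#' @slot residuals per-standard fit residuals (nm).
#' @slot standards the standards table used.
#' @export
setClass("SECCalibration",
  representation(intercept = "numeric", slope = "numeric",
                 residuals = "numeric", standards = "data.frame"))

#' Protein-detergent complex mass bookkeeping
#'
#' @slot pdcMass apparent mass of the protein-detergent complex, kDa.
#' @slot micelleMassRange (lo, hi) plausible micelle contribution, kDa.
#' @slot monomerMass protomer mass, kDa.
#' @slot protomerCount inferred protomers per complex.
#' @export
setClass("PDCEstimate",
  representation(pdcMass = "numeric", micelleMassRange = "numeric",
                 monomerMass = "numeric", protomerCount = "integer"))

#' Seeded synthetic dataset with attached ground truth
#'
#' @slot payload the generated data object.
#' @slot truth named list of the ground-truth parameters used.
#' @slot provenance named list echoing the generator configuration (seed,
#'   noise, sizes).
#' @export
setClass("SyntheticDataset",
  representation(payload = "ANY", truth = "list", provenance = "list"))
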