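# Idealized antiparallel four-helix bundle geometry and histidine-site
# selection. The bundle is a CA-only stand-in for a relaxed all-atom model:
# four ideal alpha-helices (rise 1.5 A/res, twist 100 deg/res, CA radius
# 2.3 A) on a square lattice, consecutive helices antiparallel, embedded in
# a membrane slab centred at z = 0.

circularDiff <- function(a) ((a + 180) %% 360) - 180

#' Bundle geometry parameters
#'
#' @param nResPerHelix residues per helix.
#' @param risePerRes helical rise, Angstrom per residue.
#' @param twistDeg helical twist, degrees per residue.
#' @param helixRadius CA radius of the ideal helix, Angstrom.
#' @param interAxisSpacing square-lattice spacing between adjacent helix
#'   axes, Angstrom.
#' @param membraneHalfThickness slab half-thickness, Angstrom (default half
#'   the 21-residue helical span).
#' @param phaseDeg extra azimuthal phase added to every helix after the
#'   polar-face alignment, degrees.
#' @return a [BundleParams-class].
#' @export
bundleParams <- function(nResPerHelix = 21, risePerRes = 1.5, twistDeg = 100,
                         helixRadius = 2.3, interAxisSpacing = 10,
                         membraneHalfThickness = 15.75, phaseDeg = 0) {
  p <- new("BundleParams", nResPerHelix = nResPerHelix,
           risePerRes = risePerRes, twistDeg = twistDeg,
           helixRadius = helixRadius, interAxisSpacing = interAxisSpacing,
           membraneHalfThickness = membraneHalfThickness, phaseDeg = phaseDeg)
  span <- (nResPerHelix - 1) * risePerRes
  if (span > 2 * membraneHalfThickness + 1e-9)
    message("note: helical span (", span,
            " A) exceeds the membrane slab thickness")
  p
}

# Azimuthal direction (degrees) of the polar face in helix-internal
# coordinates: circular mean of the two core polar positions. For the
# reference pattern these are the serines at positions 5 and 13; the
# position-21 serine sits at the membrane interface and is excluded.
polarFaceAngle <- function(polarPositions = c(5, 13), twistDeg = 100,
                           chirality = 1) {
  rho <- chirality * (polarPositions - 1) * twistDeg
  rho[1] + circularDiff(rho[2] - rho[1]) / 2
}

#' Build an idealized four-helix bundle from a designed protein
#'
#' Places the four helix segments of `protein` as ideal alpha-helices on a
#' square lattice in sequence order (so that diagonal pairs are helices
#' 1/3 and 2/4), alternating axis direction. Each helix is phased so that
#' its polar face - the circular mean of the azimuths of the core polar
#' pattern positions (`facePositions`) - points at the bundle axis,
#' reflecting the observation that the slightly polar faces of the
#' idealized helices pack against the bundle interior.
#'
#' Down-running helices are traversed N to C against the membrane normal, so
#' their apparent azimuthal progression is reversed (a right-handed helix
#' viewed along -z winds the other way).
#'
#' @param params a [BundleParams-class].
#' @param protein a [DesignedProtein-class] with four helix segments of
#'   `nResPerHelix` residues.
#' @param facePositions within-helix positions defining the inward polar
#'   face (default `c(5, 13)`, the core serines of the reference pattern).
#' @return a [BundleModel-class].
#' @examples
#' bundle <- buildBundle(bundleParams(), assembleConstruct(reampSpec()))
#' bundle
#' @export
buildBundle <- function(params = bundleParams(),
                        protein = assembleConstruct(reampSpec()),
                        facePositions = c(5, 13)) {
  stopifnot(is(params, "BundleParams"), is(protein, "DesignedProtein"))
  ann <- annotationTable(protein)
  helices <- paste0("H", 1:4)
  if (!all(helices %in% ann$segment))
    stop("protein must contain four helix segments H1-H4")
  n <- params@nResPerHelix
  lens <- vapply(helices, function(h) sum(ann$segment == h), integer(1))
  if (!all(lens == n))
    stop("helix length mismatch: expected ", n, " residues per helix, got ",
         paste(lens, collapse = ", "))
  s <- params@interAxisSpacing
  axesXY <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  center <- c(s / 2, s / 2)
  dirs <- c(1, -1, 1, -1)
  halfSpan <- (n - 1) * params@risePerRes / 2
  coords <- vector("list", 4L)
  maps <- vector("list", 4L)
  for (k in 1:4) {
    sigma <- dirs[k]
    rho <- sigma * (0:(n - 1)) * params@twistDeg
    face <- polarFaceAngle(facePositions, params@twistDeg, sigma)
    toC <- center - axesXY[k, ]
    phase <- atan2(toC[2], toC[1]) * 180 / pi - face + params@phaseDeg
    theta <- (phase + rho) * pi / 180
    z <- if (sigma > 0) -halfSpan + (0:(n - 1)) * params@risePerRes
         else halfSpan - (0:(n - 1)) * params@risePerRes
    coords[[k]] <- cbind(x = axesXY[k, 1] + params@helixRadius * cos(theta),
                         y = axesXY[k, 2] + params@helixRadius * sin(theta),
                         z = z)
    idx <- ann[ann$segment == helices[k], ]
    maps[[k]] <- data.frame(helix = k, helixPos = idx$helixPosition,
                            chainRes = idx$index, residue = idx$residue)
  }
  ca <- do.call(rbind, coords)
  map <- do.call(rbind, maps)
  rownames(ca) <- map$chainRes
  new("BundleModel", caCoords = ca,
      helixAxes = cbind(0, 0, dirs),
      membraneNormal = c(0, 0, 1),
      residueIndexMap = map, params = params, center = center)
}

bundleRow <- function(bundle, chainRes) {
  i <- match(chainRes, bundle@residueIndexMap$chainRes)
  if (any(is.na(i)))
    stop("residue(s) not in bundle: ",
         paste(chainRes[is.na(i)], collapse = ", "))
  i
}

facingAngles <- function(bundle) {
  map <- bundle@residueIndexMap
  s <- bundle@params@interAxisSpacing
  axesXY <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  vapply(seq_len(nrow(map)), function(i) {
    ax <- axesXY[map$helix[i], ]
    v <- bundle@caCoords[i, 1:2] - ax
    toC <- bundle@center - ax
    cosang <- sum(v * toC) / sqrt(sum(v^2) * sum(toC^2))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }, numeric(1))
}

#' Inward-facing residues of a bundle
#'
#' A residue faces inward when the angle between its CA direction (radially
#' out from its helix axis) and the vector from that axis toward the bundle
#' centre is at most `angularCutoffDeg`.
#'
#' @param bundle a [BundleModel-class].
#' @param angularCutoffDeg facing-angle cutoff in degrees (default 60).
#' @return data.frame of candidate sites: `chainRes`, `helix`, `helixPos`,
#'   `residue`, `depth` (Angstrom from the nearer membrane surface) and
#'   `facingAngle` (degrees).
#' @export
inwardFacing <- function(bundle, angularCutoffDeg = 60) {
  stopifnot(is(bundle, "BundleModel"))
  ang <- facingAngles(bundle)
  map <- bundle@residueIndexMap
  out <- data.frame(chainRes = map$chainRes, helix = map$helix,
                    helixPos = map$helixPos, residue = map$residue,
                    depth = burialDepth(bundle, map$chainRes),
                    facingAngle = ang)
  out[ang <= angularCutoffDeg + 1e-9, ]
}

#' Burial depth of residues in the membrane slab
#'
#' Distance along the membrane normal from the nearer slab surface; residues
#' outside the slab report depth 0.
#'
#' @param bundle a [BundleModel-class].
#' @param chainRes chain residue indices.
#' @return numeric vector of depths, Angstrom.
#' @export
burialDepth <- function(bundle, chainRes) {
  stopifnot(is(bundle, "BundleModel"))
  i <- bundleRow(bundle, chainRes)
  mht <- bundle@params@membraneHalfThickness
  pmax(0, mht - abs(bundle@caCoords[i, "z"]))
}

#' Select histidine sites for heme coordination
#'
#' Candidate sites are inward-facing residues whose burial depth lies within
#' `depthTarget +/- depthTol` (the bulk of the porphyrin ring must partition
#' into the membrane, placing the ligating residue roughly 10 Angstrom below
#' the surface). `mono` plans carry one such site. `bis` plans pair sites on
#' diagonally opposite helices (1/3 or 2/4) whose depths agree to within
#' `depthTol` and whose CA-CA distance falls in `bridgeWindow`, the span a
#' heme can bridge under bis-His iron coordination.
#'
#' @param bundle a [BundleModel-class].
#' @param mode `"mono"` or `"bis"`.
#' @param depthTarget target burial depth, Angstrom (default 10).
#' @param depthTol half-width of the depth band, also the maximum depth
#'   mismatch of a bis pair, Angstrom (default 4).
#' @param angularCutoffDeg inward-facing cutoff, degrees (default 60).
#' @param bridgeWindow CA-CA distance window for bis pairs, Angstrom
#'   (default `c(9, 14)`).
#' @return list of [MutationPlan-class] objects (cavity mutations unfilled),
#'   ordered by mean distance of the site depth(s) from `depthTarget`;
#'   empty list when no candidate qualifies.
#' @examples
#' bundle <- buildBundle()
#' plans <- selectHisSites(bundle, "bis")
#' plans[[1]]
#' @export
selectHisSites <- function(bundle, mode = c("mono", "bis"), depthTarget = 10,
                           depthTol = 4, angularCutoffDeg = 60,
                           bridgeWindow = c(9, 14)) {
  mode <- match.arg(mode)
  cand <- inwardFacing(bundle, angularCutoffDeg)
  cand <- cand[cand$depth >= depthTarget - depthTol &
               cand$depth <= depthTarget + depthTol, ]
  cols <- c("chainRes", "helix", "helixPos", "depth", "facingAngle")
  plans <- list()
  if (mode == "mono") {
    if (nrow(cand)) {
      ord <- order(abs(cand$depth - depthTarget), cand$chainRes)
      plans <- lapply(ord, function(i)
        new("MutationPlan", mode = "mono", hisSites = cand[i, cols],
            cavityMutations = emptyCavity()))
    }
  } else {
    if (nrow(cand) >= 2L) {
      idx <- which(outer(cand$helix, cand$helix,
                         function(a, b) abs(a - b) == 2L), arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      if (nrow(idx)) {
        keyed <- apply(idx, 1, function(ij) {
          i <- ij[1]; j <- ij[2]
          dd <- abs(cand$depth[i] - cand$depth[j])
          caca <- sqrt(sum((bundle@caCoords[bundleRow(bundle, cand$chainRes[i]), ] -
                            bundle@caCoords[bundleRow(bundle, cand$chainRes[j]), ])^2))
          c(dd = dd, caca = caca)
        })
        ok <- keyed["dd", ] <= depthTol &
              keyed["caca", ] >= bridgeWindow[1] &
              keyed["caca", ] <= bridgeWindow[2]
        idx <- idx[ok, , drop = FALSE]
        if (nrow(idx)) {
          score <- apply(idx, 1, function(ij)
            mean(abs(cand$depth[ij] - depthTarget)))
          idx <- idx[order(score), , drop = FALSE]
          plans <- lapply(seq_len(nrow(idx)), function(r)
            new("MutationPlan", mode = "bis",
                hisSites = cand[idx[r, ], cols],
                cavityMutations = emptyCavity()))
        }
      }
    }
  }
  plans
}

emptyCavity <- function() {
  data.frame(chainRes = integer(), helix = integer(),
             from = character(), to = character())
}

#' Hollow out the binding cavity around a histidine plan
#'
#' Lists every leucine whose CA lies within `clashCutoff` of the putative
#' heme centroid as an L-to-A mutation. For a bis plan the centroid is the
#' midpoint of the two histidine CAs; for a mono plan it is the point on the
#' bundle axis at the height of the single site (the porphyrin projects from
#' the ligating residue toward the bundle interior).
#'
#' @param bundle a [BundleModel-class].
#' @param plan a [MutationPlan-class] with `hisSites` filled.
#' @param clashCutoff CA-centroid distance below which a leucine is mutated,
#'   Angstrom (default 7).
#' @return the plan with `cavityMutations` filled (His sites themselves are
#'   never listed).
#' @export
cavityMutations <- function(bundle, plan, clashCutoff = 7) {
  stopifnot(is(bundle, "BundleModel"), is(plan, "MutationPlan"))
  if (!nrow(plan@hisSites)) stop("plan has no His sites")
  rows <- bundleRow(bundle, plan@hisSites$chainRes)
  centroid <- if (plan@mode == "bis") colMeans(bundle@caCoords[rows, ])
              else c(bundle@center, bundle@caCoords[rows, "z"])
  map <- bundle@residueIndexMap
  d <- sqrt(colSums((t(bundle@caCoords) - centroid)^2))
  hit <- map$residue == "L" & d <= clashCutoff &
         !(map$chainRes %in% plan@hisSites$chainRes)
  plan@cavityMutations <- data.frame(chainRes = map$chainRes[hit],
                                     helix = map$helix[hit],
                                     from = rep("L", sum(hit)),
                                     to = rep("A", sum(hit)))
  plan
}

three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")

#' Write a bundle CA trace as PDB
#'
#' Single-model PDB, chain A, CA atoms only, residue numbers from the chain
#' numbering of the designed protein. An optional mutation plan relabels the
#' His sites as HIS and the cavity mutations as ALA.
#'
#' @param bundle a [BundleModel-class].
#' @param file output path.
#' @param plan optional [MutationPlan-class] applied to the residue names.
#' @return `file`, invisibly.
#' @export
writeBundlePDB <- function(bundle, file, plan = NULL) {
  stopifnot(is(bundle, "BundleModel"))
  map <- bundle@residueIndexMap
  resid <- unname(three[map$residue])
  if (!is.null(plan)) {
    resid[map$chainRes %in% plan@hisSites$chainRes] <- "HIS"
    resid[map$chainRes %in% plan@cavityMutations$chainRes] <- "ALA"
  }
  bio3d::write.pdb(file = file, xyz = as.numeric(t(bundle@caCoords)),
                   resno = map$chainRes, resid = resid,
                   chain = rep("A", nrow(map)),
                   elety = rep("CA", nrow(map)))
  invisible(file)
}
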