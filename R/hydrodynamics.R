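# Oligomeric-state arithmetic for protein-detergent complexes (PDCs):
# sedimentation/Stokes mass, SEC calibration, micelle-series extrapolation
# and protomer counting.

#' Mass constant of the sedimentation-Stokes relation (kDa per Svedberg nm)
#' @export
ERICKSON_CONSTANT <- 4.205

#' Molecular mass from sedimentation coefficient and Stokes radius
#'
#' `M = 4.205 * S * Rs`, with `S` in Svedberg, `Rs` in nm and `M` in kDa.
#' No buoyancy correction is applied.
#'
#' @param sValue sedimentation coefficient, Svedberg.
#' @param stokesRadius Stokes radius, nm.
#' @return mass in kDa.
#' @examples
#' ericksonMass(4.2, 3.5)  # ~61.8 kDa
#' @export
ericksonMass <- function(sValue, stokesRadius) {
  if (any(sValue < 0) || any(stokesRadius < 0))
    stop("sValue and stokesRadius must be non-negative")
  ERICKSON_CONSTANT * sValue * stokesRadius
}

#' The reference SEC standards table
#'
#' Ferritin, aldolase, conalbumin and ovalbumin with their masses (kDa),
#' Stokes radii (nm) and, where applicable, sedimentation coefficients
#' (Svedberg).
#'
#' @return data.frame with columns `name`, `mass`, `stokesRadius`, `sValue`.
#' @export
secStandards <- function() {
  data.frame(name = c("Ferritin", "Aldolase", "Conalbumin", "Ovalbumin"),
             mass = c(440, 158, 75, 44),
             stokesRadius = c(6.1, 4.8, 3.6, 3.1),
             sValue = c(NA, 7.3, 5.1, 3.5))
}

#' Calibrate size-exclusion chromatography against protein standards
#'
#' Ordinary least squares of Stokes radius on log10(mass):
#' `Rs = a + b * log10(M)`. [apparentMass()] inverts the line.
#'
#' @param standards data.frame with columns `mass` (kDa) and `stokesRadius`
#'   (nm); at least 3 rows.
#' @return a [SECCalibration-class].
#' @examples
#' cal <- secCalibration(secStandards())
#' apparentMass(cal, 3.5)  # ~63 kDa
#' @export
secCalibration <- function(standards = secStandards()) {
  need <- c("mass", "stokesRadius")
  if (!all(need %in% names(standards)))
    stop("standards must have columns: ", paste(need, collapse = ", "))
  if (nrow(standards) < 3L) stop("at least 3 standards are required")
  if (any(standards$mass <= 0)) stop("standard masses must be positive")
  fit <- lm(stokesRadius ~ log10(mass), data = standards)
  new("SECCalibration", intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      residuals = unname(fit$residuals), standards = standards)
}

#' Apparent mass at a measured Stokes radius
#'
#' @param calibration a [SECCalibration-class].
#' @param stokesRadius Stokes radius, nm.
#' @return apparent mass in kDa.
#' @export
apparentMass <- function(calibration, stokesRadius) {
  stopifnot(is(calibration, "SECCalibration"))
  10^((stokesRadius - calibration@intercept) / calibration@slope)
}

#' Protein contribution to a PDC by micelle-series extrapolation
#'
#' Across a detergent series the apparent PDC mass is linear in micelle
#' mass; ordinary least squares of apparent mass on micelle mass
#' extrapolates to zero micelle, where the intercept is the protein
#' contribution.
#'
#' @param points data.frame with columns `micelleMass` and
#'   `apparentPdcMass` (kDa), one row per detergent; at least two distinct
#'   micelle masses.
#' @return list with `proteinMass` (intercept, kDa), `se` (its standard
#'   error; `NA` with 2 points), `slope`, and the `fit` object.
#' @examples
#' pts <- data.frame(micelleMass = c(20, 25, 33, 40),
#'                   apparentPdcMass = c(20, 25, 33, 40) + 43)
#' kunjiProteinMass(pts)$proteinMass  # 43
#' @export
kunjiProteinMass <- function(points) {
  need <- c("micelleMass", "apparentPdcMass")
  if (!all(need %in% names(points)))
    stop("points must have columns: ", paste(need, collapse = ", "))
  if (nrow(points) < 2L || length(unique(points$micelleMass)) < 2L)
    stop("at least two points with distinct micelle masses are required")
  fit <- lm(apparentPdcMass ~ micelleMass, data = points)
  sm <- suppressWarnings(summary(fit))$coefficients  # noise-free series
  list(proteinMass = unname(coef(fit)[1]),
       se = if (nrow(points) > 2L) unname(sm["(Intercept)", "Std. Error"])
            else NA_real_,
       slope = unname(coef(fit)[2]),
       fit = fit)
}

#' Protomer count of a protein-detergent complex
#'
#' `round((pdcMass - micelleMass) / monomerMass)`, at least 1.
#'
#' @param pdcMass apparent PDC mass, kDa.
#' @param micelleMass detergent micelle contribution, kDa.
#' @param monomerMass protomer mass, kDa.
#' @return integer protomer count.
#' @examples
#' protomerCount(65, 22.5, 13.8)  # 3
#' @export
protomerCount <- function(pdcMass, micelleMass, monomerMass) {
  if (any(c(pdcMass, micelleMass, monomerMass) <= 0))
    stop("all masses must be positive")
  if (pdcMass <= micelleMass)
    stop("pdcMass must exceed micelleMass")
  pmax(1L, as.integer(round((pdcMass - micelleMass) / monomerMass)))
}

#' Summarize a PDC mass estimate
#'
#' @param pdcMass apparent PDC mass, kDa.
#' @param micelleMassRange plausible (lo, hi) micelle contribution, kDa; the
#'   midpoint enters the protomer count.
#' @param monomerMass protomer mass, kDa.
#' @return a [PDCEstimate-class].
#' @export
pdcEstimate <- function(pdcMass, micelleMassRange = c(20, 25),
                        monomerMass) {
  mic <- mean(micelleMassRange)
  new("PDCEstimate", pdcMass = pdcMass, micelleMassRange = micelleMassRange,
      monomerMass = monomerMass,
      protomerCount = protomerCount(pdcMass, mic, monomerMass))
}

setMethod("show", "PDCEstimate", function(object) {
  cat(sprintf(
    "PDCEstimate: PDC %.1f kDa, micelle %.1f-%.1f kDa, monomer %.1f kDa -> %d protomers\n",
    object@pdcMass, object@micelleMassRange[1], object@micelleMassRange[2],
    object@monomerMass, object@protomerCount))
})
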