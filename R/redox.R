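# One-electron Nernst potentiometry: forward model, fitting, midpoint
# shifts and sweep hysteresis.

#' One-electron Nernst sigmoid
#'
#' `abs = absMin + (absMax - absMin) / (1 + 10^((eh - em) / slopeMv))`:
#' fully reduced (maximal signal) at strongly negative ambient potential,
#' midpoint at `eh = em`, 59 mV per decade at 25 C.
#'
#' @param eh ambient redox potential, mV vs SHE.
#' @param em midpoint potential, mV vs SHE.
#' @param absMin,absMax asymptotic absorbances (oxidized / reduced).
#' @param slopeMv Nernst slope, mV per decade (default 59, one electron at
#'   25 C).
#' @return absorbance.
#' @examples
#' nernstSignal(-133, em = -133, absMin = 0, absMax = 1)  # 0.5
#' @export
nernstSignal <- function(eh, em, absMin, absMax, slopeMv = 59) {
  absMin + (absMax - absMin) / (1 + 10^((eh - em) / slopeMv))
}

#' Construct a potentiometry sweep
#'
#' @param eh ambient potentials, mV vs SHE (strictly monotone).
#' @param absorbance observed absorbances, AU.
#' @param sweep `"reductive"` or `"oxidative"`.
#' @return a [PotentiometrySeries-class].
#' @export
potentiometrySeries <- function(eh, absorbance, sweep = "reductive") {
  new("PotentiometrySeries", eh = eh, absorbance = absorbance, sweep = sweep)
}

#' Fit a potentiometric sweep to the one-electron Nernst equation
#'
#' Nonlinear least squares with the slope fixed at `slopeMv` (59 mV per
#' decade for one electron at 25 C); `freeSlope = TRUE` frees it for
#' diagnostics. Requires at least 6 points spanning at least 120 mV, and
#' errors when the series shows no transition or the fitted midpoint falls
#' outside the sampled range.
#'
#' @param series a [PotentiometrySeries-class].
#' @param slopeMv fixed Nernst slope, mV per decade.
#' @param freeSlope fit the slope as well (default FALSE).
#' @return a [NernstFit-class].
#' @examples
#' eh <- seq(-260, 0, by = 10)
#' s <- potentiometrySeries(eh, nernstSignal(eh, -133, 0.1, 0.9))
#' fitNernst(s)
#' @export
fitNernst <- function(series, slopeMv = 59, freeSlope = FALSE) {
  stopifnot(is(series, "PotentiometrySeries"))
  eh <- series@eh; y <- series@absorbance
  if (length(eh) < 6L) stop("at least 6 points are required")
  if (diff(range(eh)) < 120)
    stop("sweep must span at least 120 mV")
  if (diff(range(y)) <= 1e-9 * max(1, max(abs(y))))
    stop("no transition: absorbance is constant across the sweep")
  em0 <- eh[which.min(abs(y - mean(range(y))))]
  start <- c(em = em0, absMin = min(y), absMax = max(y))
  if (freeSlope) start <- c(start, slope = slopeMv)
  resid <- function(p) {
    s <- if (freeSlope) p[["slope"]] else slopeMv
    nernstSignal(eh, p[["em"]], p[["absMin"]], p[["absMax"]], s) - y
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  cf <- coef(fit)
  if (cf[["em"]] < min(eh) || cf[["em"]] > max(eh))
    stop("fitted midpoint (", round(cf[["em"]], 1),
         " mV) lies outside the sampled range")
  vc <- lmCovariance(fit, length(y))
  new("NernstFit", em = unname(cf["em"]), absMin = unname(cf["absMin"]),
      absMax = unname(cf["absMax"]),
      slopeMv = if (freeSlope) unname(cf["slope"]) else slopeMv,
      se = sqrt(pmax(diag(vc), 0)), cov = vc)
}

#' Midpoint-potential shift between two fits
#'
#' @param fitVariant,fitParent [NernstFit-class] objects.
#' @return list with `shift` (`em(variant) - em(parent)`, mV) and `se`
#'   (propagated standard error).
#' @examples
#' # a +32 mV shift: emShift on fits at -101 and -133 mV
#' @export
emShift <- function(fitVariant, fitParent) {
  stopifnot(is(fitVariant, "NernstFit"), is(fitParent, "NernstFit"))
  list(shift = fitVariant@em - fitParent@em,
       se = sqrt(fitVariant@se[["em"]]^2 + fitParent@se[["em"]]^2))
}

#' Hysteresis between reductive and oxidative sweeps
#'
#' @param reductive,oxidative [NernstFit-class] objects fitted to the two
#'   sweep directions.
#' @param threshold flag hysteresis when `|Em_red - Em_ox|` exceeds this, mV
#'   (default 10).
#' @return list with `deltaEm` (mV, absolute) and logical `hysteresis`.
#' @export
sweepHysteresis <- function(reductive, oxidative, threshold = 10) {
  stopifnot(is(reductive, "NernstFit"), is(oxidative, "NernstFit"))
  d <- abs(reductive@em - oxidative@em)
  list(deltaEm = d, hysteresis = d > threshold)
}
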