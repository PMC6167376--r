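# Equilibrium and kinetic heme binding, Soret-state classification, and
# ABTS peroxidase turnover accounting.
#
# The equilibrium forward model is the single-site ligand-depletion
# quadratic: with total site concentration P = nSites * proteinConc and
# total ligand L,
#   bound = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2,
# appropriate when the protein concentration is comparable to Kd (1.4 uM
# protein vs ~2 uM Kd here), where a hyperbolic fit would be biased.

# Parameter covariance of a converged nls.lm fit: sigma^2 (J'J)^-1, with
# NA entries when the information matrix is singular.
lmCovariance <- function(fit, nObs) {
  cf <- coef(fit)
  sigma2 <- fit$deviance / max(1, nObs - length(cf))
  tryCatch(solve(fit$hessian) * sigma2, error = function(e)
    matrix(NA_real_, length(cf), length(cf),
           dimnames = list(names(cf), names(cf))))
}

boundLigand <- function(L, P, kd) {
  b <- P + L + kd
  disc <- b^2 - 4 * P * L
  disc[disc < 0] <- 0  # numerically tiny negatives only
  (b - sqrt(disc)) / 2
}

#' Construct a titration series
#'
#' @param ligand total ligand concentrations, uM (non-decreasing).
#' @param signal observed signal, AU.
#' @param proteinConc total protomer concentration, uM.
#' @param pathlength optical pathlength, cm.
#' @return a [TitrationSeries-class].
#' @export
titrationSeries <- function(ligand, signal, proteinConc, pathlength = 1) {
  new("TitrationSeries", proteinConc = proteinConc, ligand = ligand,
      signal = signal, pathlength = pathlength)
}

#' Forward-simulate an equilibrium binding isotherm
#'
#' Ligand-depletion single-site model plus a linear background from free
#' ligand (heme partitioning into empty micelles):
#' `signal = signalPerBound * bound + backgroundSlope * (L - bound)`.
#'
#' @param kd dissociation constant, uM.
#' @param nSites binding sites per protomer.
#' @param proteinConc total protomer concentration, uM.
#' @param ligand total ligand series, uM.
#' @param signalPerBound signal per uM bound ligand.
#' @param backgroundSlope signal per uM free ligand.
#' @param pathlength optical pathlength, cm (metadata).
#' @return a [TitrationSeries-class].
#' @export
simulateIsotherm <- function(kd, nSites, proteinConc, ligand,
                             signalPerBound = 0.1, backgroundSlope = 0,
                             pathlength = 1) {
  stopifnot(kd >= 0, nSites > 0, proteinConc > 0)
  P <- nSites * proteinConc
  bound <- boundLigand(ligand, P, kd)
  stopifnot(all(bound >= -1e-12))
  signal <- signalPerBound * bound + backgroundSlope * (ligand - bound)
  titrationSeries(ligand, signal, proteinConc, pathlength)
}

#' Fit an equilibrium binding isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the ligand-depletion
#' forward model. When a control series is supplied (ligand binding to the
#' parent protein, or buffer), its signal is interpolated onto the ligand
#' grid and subtracted point-wise before fitting, and the background slope
#' is then fixed at 0 unless `fitBackground = TRUE`.
#'
#' Multi-start over a small grid of (kd, nSites) initial values guards
#' against local minima; the best-SSE fit is returned.
#'
#' @param series a [TitrationSeries-class] with at least 5 points.
#' @param control optional control [TitrationSeries-class] to subtract.
#' @param fitBackground fit a linear free-ligand background term
#'   (default `is.null(control)`).
#' @return a [BindingFit-class].
#' @examples
#' s <- simulateIsotherm(2.2, 0.5, 1.4, seq(0, 8, by = 0.4))
#' fitIsotherm(s)
#' @export
fitIsotherm <- function(series, control = NULL,
                        fitBackground = is.null(control)) {
  stopifnot(is(series, "TitrationSeries"))
  L <- series@ligand
  y <- series@signal
  if (length(L) < 5L) stop("at least 5 titration points are required")
  if (!is.null(control)) {
    stopifnot(is(control, "TitrationSeries"))
    y <- y - approx(control@ligand, control@signal, xout = L, rule = 2)$y
  }
  if (diff(range(y)) <= max(1e-12, 1e-9 * max(abs(y), 1)))
    stop("flat signal: nothing to fit after background subtraction")
  Pc <- series@proteinConc
  # kd and nSites are optimized on the log scale: both are positive and the
  # sum-of-squares surface is far better conditioned there (a linear-scale
  # fit stalls against the kd > 0 boundary on near-stoichiometric data)
  model <- function(p) {
    b <- boundLigand(L, exp(p[["ln"]]) * Pc, exp(p[["lkd"]]))
    p[["spb"]] * b + if (fitBackground) p[["bg"]] * (L - b) else 0
  }
  # crude scale guess for the bound-signal coefficient
  spb0 <- (y[which.max(L >= Pc)] - y[1]) / max(Pc, L[2] - L[1])
  if (!is.finite(spb0) || spb0 == 0) spb0 <- diff(range(y)) / max(Pc, 1)
  best <- NULL
  for (n0 in c(0.5, 1, 2)) for (kd0 in c(0.2, 1, 5)) {
    start <- c(lkd = log(kd0), ln = log(n0), spb = spb0)
    if (fitBackground) start <- c(start, bg = 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = function(p) model(p) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$deviance)) {
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
  }
  if (is.null(best))
    stop("isotherm fit did not converge from any starting point")
  cf <- coef(best)
  kdHat <- exp(cf[["lkd"]]); nHat <- exp(cf[["ln"]])
  vc <- lmCovariance(best, length(y))
  seLog <- sqrt(pmax(diag(vc), 0))
  # delta method back to the natural scale
  se <- c(kd = kdHat * seLog[["lkd"]], nSites = nHat * seLog[["ln"]],
          signalPerBound = seLog[["spb"]])
  if (fitBackground) se <- c(se, backgroundSlope = seLog[["bg"]])
  new("BindingFit", kd = kdHat, nSites = nHat,
      signalPerBound = cf[["spb"]],
      backgroundSlope = if (fitBackground) cf[["bg"]] else 0,
      se = se, cov = vc)
}

#' Fit pseudo-first-order binding kinetics
#'
#' Each trace (recorded at a ligand concentration in pseudo-first-order
#' excess) is fit to a single exponential `A * exp(-kobs * t) + C`; the
#' observed rates are then regressed linearly on ligand concentration,
#' `kobs = kon * L + koff`, and the kinetic dissociation constant is
#' `koff / kon`. A negative fitted intercept is clamped to zero and
#' flagged.
#'
#' @param traces list of data.frames with columns `time` (s) and `signal`,
#'   each carrying its ligand concentration (uM) in an attribute `ligand`
#'   or a column `ligand`; at least 3 distinct concentrations.
#' @return a [KineticFit-class].
#' @export
fitKinetics <- function(traces) {
  if (length(traces) < 3L) stop("at least 3 traces are required")
  rows <- lapply(traces, function(tr) {
    lig <- if ("ligand" %in% names(tr)) tr$ligand[1] else attr(tr, "ligand")
    if (is.null(lig)) stop("each trace must carry its ligand concentration")
    t <- tr$time; yy <- tr$signal
    r <- suppressWarnings(cor(t, yy, method = "spearman"))
    if (is.finite(r) && abs(r) < 0.2)
      warning("trace at ", lig, " uM is not monotone; kobs may be unreliable")
    k0 <- log(2) / max(t[which.min(abs(yy - mean(range(yy))))], min(diff(t)))
    fit <- minpack.lm::nlsLM(yy ~ A * exp(-k * t) + C,
                             start = list(A = yy[1] - yy[length(yy)],
                                          C = yy[length(yy)], k = k0),
                             lower = c(A = -Inf, C = -Inf, k = 1e-9),
                             control = nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
    data.frame(ligand = lig, kobs = unname(coef(fit)["k"]))
  })
  kobs <- do.call(rbind, rows)
  lf <- lm(kobs ~ ligand, data = kobs)
  kon <- unname(coef(lf)["ligand"])
  koff <- unname(coef(lf)["(Intercept)"])
  clamped <- koff < 0
  if (clamped) koff <- 0
  if (kon <= 0) stop("fitted on-rate is not positive")
  sm <- summary(lf)$coefficients
  new("KineticFit", kon = kon, koff = koff, kobs = kobs,
      kdKinetic = koff / kon, koffClamped = clamped,
      se = c(kon = unname(sm["ligand", "Std. Error"]),
             koff = unname(sm["(Intercept)", "Std. Error"])))
}

SORET_CENTRES <- c(free_aqueous = 394, bound_oxidized = 415,
                   bound_reduced = 427)

#' Classify a heme spectrum by its Soret peak
#'
#' The Soret maximum is located within the 380-450 nm window and labelled by
#' the nearest reference centre - 394 nm free aqueous heme, 415 nm
#' bis-His-bound ferric, 427 nm bound ferrous - within a +/- `band` nm
#' acceptance band; anything else (including a flat spectrum) is
#' `"unclassified"`.
#'
#' @param spectrum a [Spectrum-class] covering 380-450 nm.
#' @param band half-width of the acceptance band, nm (default 6).
#' @param window Soret search window, nm.
#' @return list with `state`, `peak` (nm), and `secondaryPeaks` (nm of other
#'   local maxima in the window, strongest first).
#' @export
classifySoret <- function(spectrum, band = 6, window = c(380, 450)) {
  stopifnot(is(spectrum, "Spectrum"))
  wl <- spectrum@wavelength; ab <- spectrum@absorbance
  if (min(wl) > window[1] || max(wl) < window[2])
    stop("spectrum does not cover the Soret window ", window[1], "-",
         window[2], " nm")
  inWin <- wl >= window[1] & wl <= window[2]
  wlw <- wl[inWin]; abw <- ab[inWin]
  if (diff(range(abw)) <= 1e-6 * max(1, max(abs(abw))))
    return(list(state = "unclassified", peak = NA_real_,
                secondaryPeaks = numeric()))
  peak <- wlw[which.max(abw)]
  # interior local maxima
  d <- diff(abw)
  locmax <- which(c(FALSE, d[-length(d)] > 0 & d[-1] <= 0, FALSE))
  second <- setdiff(wlw[locmax][order(-abw[locmax])], peak)
  nearest <- which.min(abs(SORET_CENTRES - peak))
  state <- if (abs(SORET_CENTRES[nearest] - peak) <= band)
    names(SORET_CENTRES)[nearest] else "unclassified"
  list(state = state, peak = peak, secondaryPeaks = second)
}

#' Molar extinction coefficient of oxidized ABTS at 420 nm (/M/cm)
#' @export
ABTS_EPS420 <- 36000

#' Peroxidase turnovers per hemoprotein from an ABTS endpoint
#'
#' Oxidized ABTS (uM) by Beer-Lambert, `1e6 * dA420 / (36000 * pathlength)`,
#' divided by the hemoprotein concentration.
#'
#' @param deltaA420 endpoint absorbance change at 420 nm, AU.
#' @param pathlength optical pathlength, cm.
#' @param hemoproteinConc hemoprotein concentration, uM.
#' @return turnovers per hemoprotein.
#' @examples
#' abtsTurnovers(0.252, 1, 1)  # 7
#' @export
abtsTurnovers <- function(deltaA420, pathlength = 1, hemoproteinConc) {
  if (pathlength <= 0 || hemoproteinConc <= 0)
    stop("pathlength and hemoproteinConc must be positive")
  if (any(deltaA420 < 0)) stop("deltaA420 must be non-negative")
  oxidized <- 1e6 * deltaA420 / (ABTS_EPS420 * pathlength)
  oxidized / hemoproteinConc
}
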