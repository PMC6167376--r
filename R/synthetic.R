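# Seeded generators for every input the analysis modules consume. Each
# generator is a deterministic function of (seed, arguments) and returns a
# SyntheticDataset carrying the payload, the ground truth, and a provenance
# echo of the configuration.

syntheticDataset <- function(payload, truth, provenance) {
  new("SyntheticDataset", payload = payload, truth = truth,
      provenance = provenance)
}

# Sampling alphabets consistent with the default residue classes: the real
# template-family composition is not reproduced, only its abstraction
# behaviour.
HYDROPHOBIC_ALPHABET <- c("L", "I", "V", "F", "A", "M")
POLAR_ALPHABET <- c("S", "T", "N", "Q", "E", "K")

#' Generate an SMR-like alignment that abstracts to a given pattern
#'
#' Emulates a small alignment of four-TM membrane proteins (eight sequences
#' by default, matching the size of the reference template set): for each of
#' four TM windows, `h` columns are sampled uniformly from a hydrophobic
#' alphabet, `p` columns from a polar alphabet, and `G` columns are glycine
#' in enough sequences (at least `ceiling(glyThreshold * n)`, the rest
#' Bernoulli) to guarantee the conservation rule fires. Loop columns are
#' sampled freely from the polar alphabet. By construction,
#' [abstractPattern()] over the default scheme recovers `pattern` from the
#' consensus of every window.
#'
#' @param seed integer seed.
#' @param pattern an [HPPattern-class] (default the reference pattern).
#' @param nSequences number of sequences (>= 2; default 8).
#' @param loopLength residues between TM windows (default 8).
#' @param glyProb per-sequence glycine probability in `G` columns beyond the
#'   guaranteed core (default 0.9).
#' @param scheme a [ResidueClassScheme-class] (its `glyThreshold` sets the
#'   guaranteed glycine core).
#' @return a [SyntheticDataset-class] whose payload is a
#'   [TMAlignment-class]; truth records the pattern.
#' @examples
#' aln <- payload(genSMRAlignment(1))
#' cons <- consensusFromAlignment(aln)
#' abstractPattern(cons$TM1)
#' @export
genSMRAlignment <- function(seed, pattern = reampPattern(), nSequences = 8,
                            loopLength = 8, glyProb = 0.9,
                            scheme = residueClassScheme()) {
  if (nSequences < 2L) stop("at least 2 sequences are required")
  validObject(pattern)
  sym <- strsplit(pattern@symbols, "")[[1]]
  tmLen <- length(sym)
  withr::with_seed(seed, {
    sampleColumn <- function(s) {
      if (s == "h") sample(HYDROPHOBIC_ALPHABET, nSequences, replace = TRUE)
      else if (s == "p") sample(POLAR_ALPHABET, nSequences, replace = TRUE)
      else {
        nCore <- ceiling(scheme@glyThreshold * nSequences)
        col <- ifelse(stats::runif(nSequences) < glyProb, "G",
                      sample(HYDROPHOBIC_ALPHABET, nSequences, replace = TRUE))
        core <- sample(nSequences, nCore)
        col[core] <- "G"
        col
      }
    }
    blocks <- list()
    windows <- matrix(0L, nrow = 4, ncol = 2)
    colStart <- 1L
    for (w in 1:4) {
      tm <- do.call(cbind, lapply(sym, sampleColumn))
      windows[w, ] <- c(colStart, colStart + tmLen - 1L)
      blocks[[length(blocks) + 1L]] <- tm
      colStart <- colStart + tmLen
      if (w < 4) {
        loop <- matrix(sample(POLAR_ALPHABET, nSequences * loopLength,
                              replace = TRUE), nrow = nSequences)
        blocks[[length(blocks) + 1L]] <- loop
        colStart <- colStart + loopLength
      }
    }
    m <- do.call(cbind, blocks)
    seqs <- setNames(apply(m, 1, paste, collapse = ""),
                     sprintf("synthetic_smr_%02d", seq_len(nSequences)))
  })
  aln <- TMAlignment(seqs, windows)
  syntheticDataset(aln, truth = list(pattern = pattern@symbols),
                   provenance = list(seed = seed, nSequences = nSequences,
                                     loopLength = loopLength,
                                     glyProb = glyProb))
}

#' Generate a heme-binding titration series
#'
#' Forward model from [simulateIsotherm()] plus homoscedastic Gaussian
#' noise. The ligand series mimics cumulative small-aliquot additions of a
#' concentrated stock; `dilutionCorrection` (on by default) reports the
#' dilution-corrected total ligand exactly as an experimenter would.
#'
#' @param seed integer seed.
#' @param kd dissociation constant, uM (default 2.2).
#' @param nSites sites per protomer (default 0.5, the bis-His convention of
#'   one heme per two histidines).
#' @param proteinConc protomer concentration, uM (default 1.4).
#' @param maxLigand approximate top total-ligand concentration, uM.
#' @param nPoints number of titration points (default 25).
#' @param noiseSd Gaussian noise sd, AU (default 0).
#' @param signalPerBound,backgroundSlope forward-model coefficients.
#' @param stockConc aliquot stock concentration, uM (default 150).
#' @param sampleVolume starting volume, ml (default 1).
#' @param dilutionCorrection apply volume correction to the nominal series.
#' @return a [SyntheticDataset-class] whose payload is a
#'   [TitrationSeries-class].
#' @export
genIsotherm <- function(seed, kd = 2.2, nSites = 0.5, proteinConc = 1.4,
                        maxLigand = 8, nPoints = 25, noiseSd = 0,
                        signalPerBound = 0.1, backgroundSlope = 0.002,
                        stockConc = 150, sampleVolume = 1,
                        dilutionCorrection = TRUE) {
  stopifnot(kd >= 0, nSites > 0, proteinConc > 0, maxLigand >= 0)
  if (maxLigand == 0) {
    nominal <- 0
  } else {
    aliquot <- maxLigand * sampleVolume / (stockConc * (nPoints - 1)) * 1000
    addedUl <- aliquot * (0:(nPoints - 1))
    vol <- sampleVolume + if (dilutionCorrection) addedUl / 1000 else 0
    nominal <- (stockConc * addedUl / 1000) / vol
  }
  series <- simulateIsotherm(kd, nSites, proteinConc, nominal,
                             signalPerBound, backgroundSlope)
  noisy <- withr::with_seed(seed,
    series@signal + rnorm(length(nominal), 0, noiseSd))
  payload <- titrationSeries(nominal, noisy, proteinConc)
  syntheticDataset(payload,
                   truth = list(kd = kd, nSites = nSites,
                                signalPerBound = signalPerBound,
                                backgroundSlope = backgroundSlope),
                   provenance = list(seed = seed, noiseSd = noiseSd,
                                     nPoints = nPoints,
                                     maxLigand = maxLigand,
                                     dilutionCorrection = dilutionCorrection))
}

#' Generate potentiometric sweeps
#'
#' Nernst sigmoid plus Gaussian noise. The payload holds a reductive sweep
#' and an oxidative sweep; `hysteresisOffset` displaces the oxidative
#' midpoint to emulate slow-equilibration hysteresis.
#'
#' @param seed integer seed.
#' @param em midpoint potential, mV vs SHE.
#' @param absMin,absMax asymptotic absorbances.
#' @param ehGrid ambient-potential grid, mV (must span the transition).
#' @param noiseSd Gaussian noise sd, AU.
#' @param hysteresisOffset oxidative-sweep midpoint displacement, mV
#'   (default 0).
#' @return a [SyntheticDataset-class]; payload is a list with elements
#'   `reductive` and `oxidative` ([PotentiometrySeries-class]).
#' @export
genPotentiometry <- function(seed, em = -133, absMin = 0.1, absMax = 0.9,
                             ehGrid = seq(em + 130, em - 130, by = -10),
                             noiseSd = 0, hysteresisOffset = 0) {
  if (min(ehGrid) > em || max(ehGrid) < em)
    stop("ehGrid must span the transition at em")
  red <- sort(ehGrid, decreasing = TRUE)  # reductive: high to low potential
  ox <- sort(ehGrid)
  withr::with_seed(seed, {
    yr <- nernstSignal(red, em, absMin, absMax) +
      rnorm(length(red), 0, noiseSd)
    yo <- nernstSignal(ox, em + hysteresisOffset, absMin, absMax) +
      rnorm(length(ox), 0, noiseSd)
  })
  payload <- list(reductive = potentiometrySeries(red, yr, "reductive"),
                  oxidative = potentiometrySeries(ox, yo, "oxidative"))
  syntheticDataset(payload,
                   truth = list(em = em, absMin = absMin, absMax = absMax,
                                hysteresisOffset = hysteresisOffset),
                   provenance = list(seed = seed, noiseSd = noiseSd,
                                     nPoints = length(ehGrid)))
}

#' Generate pseudo-first-order kinetic traces
#'
#' Exponential approach to equilibrium with `kobs = kon * L + koff` at each
#' ligand concentration, plus Gaussian noise.
#'
#' @param seed integer seed.
#' @param kon association rate, /uM/s.
#' @param koff dissociation rate, /s.
#' @param ligand ligand concentrations, uM (pseudo-first-order excess).
#' @param tMax trace duration, s; defaults to 5 half-lives of the slowest
#'   trace.
#' @param nT points per trace.
#' @param amplitude signal amplitude, AU.
#' @param noiseSd Gaussian noise sd, AU.
#' @return a [SyntheticDataset-class]; payload is a list of trace
#'   data.frames (`time`, `signal`, attribute `ligand`).
#' @export
genKinetics <- function(seed, kon = 1.0, koff = 1.7,
                        ligand = c(5, 10, 20, 40), tMax = NULL, nT = 60,
                        amplitude = 0.2, noiseSd = 0) {
  stopifnot(kon > 0, koff >= 0, length(ligand) >= 1)
  kSlow <- kon * min(ligand) + koff
  if (is.null(tMax)) tMax <- 5 * log(2) / kSlow
  traces <- withr::with_seed(seed, lapply(ligand, function(L) {
    k <- kon * L + koff
    t <- seq(0, tMax, length.out = nT)
    tr <- data.frame(time = t,
                     signal = amplitude * exp(-k * t) +
                       rnorm(nT, 0, noiseSd))
    attr(tr, "ligand") <- L
    tr
  }))
  syntheticDataset(traces, truth = list(kon = kon, koff = koff,
                                        kdKinetic = koff / kon),
                   provenance = list(seed = seed, noiseSd = noiseSd,
                                     ligand = ligand, nT = nT))
}

#' Generate a detergent micelle series
#'
#' Apparent PDC mass = micelle mass + protein mass + noise, one point per
#' detergent.
#'
#' @param seed integer seed.
#' @param proteinMass protein contribution, kDa (default 43).
#' @param micelleMasses micelle masses, kDa (>= 2 values).
#' @param noiseSd Gaussian noise sd, kDa.
#' @return a [SyntheticDataset-class]; payload is a data.frame with columns
#'   `detergent`, `micelleMass`, `apparentPdcMass`.
#' @export
genMicelleSeries <- function(seed, proteinMass = 43,
                             micelleMasses = c(20, 25, 33, 40),
                             noiseSd = 0) {
  if (length(micelleMasses) < 2L)
    stop("at least 2 micelle masses are required")
  app <- withr::with_seed(seed,
    micelleMasses + proteinMass + rnorm(length(micelleMasses), 0, noiseSd))
  payload <- data.frame(
    detergent = sprintf("detergent_%02d", seq_along(micelleMasses)),
    micelleMass = micelleMasses, apparentPdcMass = app)
  syntheticDataset(payload, truth = list(proteinMass = proteinMass),
                   provenance = list(seed = seed, noiseSd = noiseSd))
}

#' Generate a heme absorbance spectrum
#'
#' Gaussian Soret band at the centre of the requested spectral state
#' (394 nm free aqueous, 415 nm bound oxidized, 427 nm bound reduced), with
#' optional Q-band bumps for the bound states, plus Gaussian noise.
#'
#' @param seed integer seed.
#' @param state one of `"free_aqueous"`, `"bound_oxidized"`,
#'   `"bound_reduced"`.
#' @param amplitude Soret amplitude, AU.
#' @param width Soret Gaussian sd, nm.
#' @param qBands add Q-region features for bound states (default TRUE).
#' @param wavelengths wavelength grid, nm.
#' @param noiseSd Gaussian noise sd, AU.
#' @return a [SyntheticDataset-class]; payload is a [Spectrum-class].
#' @export
genSpectrum <- function(seed, state = c("bound_oxidized", "free_aqueous",
                                        "bound_reduced"),
                        amplitude = 1, width = 12, qBands = TRUE,
                        wavelengths = seq(350, 700, by = 1), noiseSd = 0) {
  state <- match.arg(state)
  centre <- SORET_CENTRES[[state]]
  ab <- amplitude * exp(-(wavelengths - centre)^2 / (2 * width^2))
  if (qBands && state != "free_aqueous") {
    q <- if (state == "bound_reduced") c(530, 560) else c(535, 565)
    for (qc in q)
      ab <- ab + 0.12 * amplitude * exp(-(wavelengths - qc)^2 / (2 * 8^2))
  }
  ab <- withr::with_seed(seed, ab + rnorm(length(ab), 0, noiseSd))
  payload <- new("Spectrum", wavelength = wavelengths, absorbance = ab,
                 stateLabel = state)
  syntheticDataset(payload, truth = list(state = state, centre = centre),
                   provenance = list(seed = seed, noiseSd = noiseSd,
                                     amplitude = amplitude, width = width))
}
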