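test_that("ligand-depletion forward model: limits, conservation, oracle", {
  L <- seq(0, 8, by = 0.25)
  P <- 0.7
  # Kd -> 0 limit: stoichiometric titration with breakpoint at L = P
  s0 <- simulateIsotherm(1e-12, 0.5, 1.4, L, signalPerBound = 1)
  expect_equal(s0@signal, pmin(L, P), tolerance = 1e-5)
  # L = 0 gives zero bound and zero signal
  expect_identical(simulateIsotherm(2.2, 0.5, 1.4, 0)@signal, 0)
  # closed form vs root-finding oracle, including the Kd = P = L corner
  for (kdv in c(0.3, 1.4, 2.2, 5)) {
    s <- simulateIsotherm(kdv, 0.5, 1.4, L, signalPerBound = 1)
    expect_equal(s@signal, oracleBound(L, P, kdv), tolerance = 1e-10)
  }
  # mass bookkeeping: 0 <= bound <= min(L, P)
  s <- simulateIsotherm(2.2, 1, 1.4, L, signalPerBound = 1)
  expect_true(all(s@signal >= -1e-12))
  expect_true(all(s@signal <= pmin(L, 1.4) + 1e-12))
})

test_that("equilibrium fits recover parameters on the noise-free grid", {
  L <- payload(genIsotherm(1, noiseSd = 0, backgroundSlope = 0))@ligand
  for (kdTrue in c(0.5, 2.2, 2.9, 5.6)) for (nTrue in c(0.5, 1)) {
    s <- simulateIsotherm(kdTrue, nTrue, 1.4, L, signalPerBound = 0.1)
    fit <- fitIsotherm(s, fitBackground = FALSE)
    expect_equal(kd(fit), kdTrue, tolerance = 1e-4)
    expect_equal(nSites(fit), nTrue, tolerance = 1e-4)
  }
})

test_that("stoichiometric breakpoint reports the designed site counts", {
  # kd << P: the fitted stoichiometry reads off the breakpoint, matching
  # the one-heme-per-His-pair (0.5) and one-per-His (1) conventions
  L <- seq(0, 6, by = 0.2)
  for (nTrue in c(0.5, 1)) {
    s <- simulateIsotherm(0.01, nTrue, 1.4, L, signalPerBound = 0.1)
    fit <- fitIsotherm(s, fitBackground = FALSE)
    expect_equal(nSites(fit), nTrue, tolerance = 0.02)
  }
})

test_that("control subtraction removes the nonspecific background", {
  d <- genIsotherm(5, kd = 2.2, nSites = 0.5, noiseSd = 0,
                   backgroundSlope = 0.004)
  ser <- payload(d)
  ctl <- titrationSeries(ser@ligand, 0.004 * ser@ligand, proteinConc = 1.4)
  fit <- fitIsotherm(ser, control = ctl)
  expect_equal(kd(fit), 2.2, tolerance = 1e-4)
  # a series equal to its own control is flat and rejected
  expect_error(fitIsotherm(ser, control = ser), "flat signal")
  expect_error(fitIsotherm(titrationSeries(c(0, 1, 2), c(0, 1, 2), 1.4)),
               "at least 5")
})

test_that("kinetic fits recover kobs, kon, koff and their ratio", {
  fit <- fitKinetics(payload(genKinetics(1, kon = 1.0, koff = 1.7,
                                         noiseSd = 0)))
  expect_equal(fit@kon, 1.0, tolerance = 1e-6)
  expect_equal(fit@koff, 1.7, tolerance = 1e-6)
  expect_equal(kd(fit), 1.7, tolerance = 1e-6)
  expect_false(fit@koffClamped)
  # koff = 0 gives kd = 0
  fit0 <- fitKinetics(payload(genKinetics(2, kon = 0.8, koff = 0,
                                          noiseSd = 0)))
  expect_equal(kd(fit0), 0, tolerance = 1e-6)
  # order invariance
  tr <- payload(genKinetics(3, kon = 1.0, koff = 1.7, noiseSd = 0))
  expect_equal(kd(fitKinetics(rev(tr))), kd(fitKinetics(tr)),
               tolerance = 1e-12)
  expect_error(fitKinetics(tr[1:2]), "at least 3")
})

test_that("Soret classification labels the three spectral states", {
  expect_identical(classifySoret(payload(genSpectrum(1, "free_aqueous")))$state,
                   "free_aqueous")
  expect_identical(
    classifySoret(payload(genSpectrum(1, "bound_oxidized")))$state,
    "bound_oxidized")
  expect_identical(
    classifySoret(payload(genSpectrum(1, "bound_reduced")))$state,
    "bound_reduced")
  # flat spectrum is unclassified
  flat <- new("Spectrum", wavelength = seq(350, 700, 1),
              absorbance = rep(0.2, 351), stateLabel = NA_character_)
  expect_identical(classifySoret(flat)$state, "unclassified")
  # two bands, 427 dominant: reduced, with the 394 feature reported
  wl <- seq(350, 700, 1)
  ab <- 0.5 * exp(-(wl - 394)^2 / 288) + exp(-(wl - 427)^2 / 288)
  two <- classifySoret(new("Spectrum", wavelength = wl, absorbance = ab,
                           stateLabel = NA_character_))
  expect_identical(two$state, "bound_reduced")
  expect_identical(two$peak, 427)
  expect_true(any(abs(two$secondaryPeaks - 394) <= 3))
  # a peak far from every reference centre is unclassified
  odd <- classifySoret(new("Spectrum", wavelength = wl,
                           absorbance = exp(-(wl - 405)^2 / 288),
                           stateLabel = NA_character_))
  expect_identical(odd$state, "unclassified")
  narrow <- new("Spectrum", wavelength = seq(390, 440, 1),
                absorbance = rep(1, 51), stateLabel = NA_character_)
  expect_error(classifySoret(narrow), "does not cover")
})

test_that("ABTS turnover accounting is Beer-Lambert linear", {
  expect_identical(abtsTurnovers(0, 1, 1), 0)
  expect_equal(abtsTurnovers(0.252, 1, 1), 7.0, tolerance = 1e-12)
  # linear in absorbance, inverse in pathlength
  expect_equal(abtsTurnovers(2 * 0.252, 1, 1), 14.0)
  expect_equal(abtsTurnovers(0.252, 2, 1), 3.5)
  expect_error(abtsTurnovers(0.1, 0, 1), "positive")
  expect_error(abtsTurnovers(-0.1, 1, 1), "non-negative")
})
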