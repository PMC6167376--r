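test_that("sedimentation-Stokes mass formula and bilinearity", {
  expect_equal(ericksonMass(4.2, 3.5), 61.8135, tolerance = 1e-12)
  expect_equal(round(ericksonMass(4.2, 3.5), -1), 60)
  expect_identical(ericksonMass(0, 5.0), 0)
  expect_equal(ericksonMass(7.3, 4.8), 147.3, tolerance = 0.1)
  for (k in c(0.5, 2, 10))
    expect_equal(ericksonMass(k * 4.2, 3.5), k * ericksonMass(4.2, 3.5))
  expect_error(ericksonMass(-1, 3), "non-negative")
})

test_that("SEC calibration matches textbook regression and the standards", {
  std <- secStandards()
  cal <- secCalibration(std)
  # independent regression oracle on Rs vs log10(M)
  line <- oracleLine(log10(std$mass), std$stokesRadius)
  expect_equal(cal@intercept, unname(line["a"]), tolerance = 1e-9)
  expect_equal(cal@slope, unname(line["b"]), tolerance = 1e-9)
  oracleMass <- 10^((3.5 - line["a"]) / line["b"])
  expect_equal(apparentMass(cal, 3.5), unname(oracleMass), tolerance = 1e-9)
  # within 10% of the reported 65 kDa apparent mass at Rs 3.5 nm
  expect_lt(abs(apparentMass(cal, 3.5) - 65) / 65, 0.10)

  # each standard round-trips within its fit residual
  for (i in seq_len(nrow(std))) {
    rsHat <- cal@intercept + cal@slope * log10(std$mass[i])
    expect_equal(std$stokesRadius[i] - rsHat, cal@residuals[i],
                 tolerance = 1e-9)
  }
  # monotone increasing in Rs
  rs <- seq(2, 7, by = 0.5)
  expect_true(all(diff(apparentMass(cal, rs)) > 0))

  # two distinct standards duplicated: the line passes through both
  dup <- std[c(2, 2, 4, 4), ]
  cal2 <- secCalibration(dup)
  expect_equal(apparentMass(cal2, 4.8), 158, tolerance = 1e-6)
  expect_equal(apparentMass(cal2, 3.1), 44, tolerance = 1e-6)

  expect_error(secCalibration(std[1:2, ]), "at least 3")
})

test_that("micelle-series extrapolation recovers the protein contribution", {
  pts <- data.frame(micelleMass = c(20, 25, 33, 40),
                    apparentPdcMass = c(20, 25, 33, 40) + 43)
  k <- kunjiProteinMass(pts)
  expect_equal(k$proteinMass, 43, tolerance = 1e-9)
  expect_equal(k$slope, 1, tolerance = 1e-9)

  # slope != 1 still returns the exact intercept on collinear data
  pts2 <- data.frame(micelleMass = c(10, 20, 30),
                     apparentPdcMass = 1.7 * c(10, 20, 30) + 28.5)
  expect_equal(kunjiProteinMass(pts2)$proteinMass, 28.5, tolerance = 1e-9)

  expect_error(kunjiProteinMass(
    data.frame(micelleMass = c(20, 20), apparentPdcMass = c(60, 65))),
    "distinct micelle masses")
  expect_error(kunjiProteinMass(data.frame(micelleMass = 20)),
               "must have columns")
})

test_that("protomer counting rounds the detergent-corrected mass ratio", {
  expect_identical(protomerCount(65, 22.5, 13.8), 3L)
  expect_identical(protomerCount(60, 22.5, 13.8), 3L)
  expect_identical(protomerCount(22.5 + 13.8, 22.5, 13.8), 1L)
  expect_error(protomerCount(20, 22.5, 13.8), "exceed")
  expect_error(protomerCount(65, -1, 13.8), "positive")
  # monotone: non-decreasing in PDC mass, non-increasing in micelle mass
  pdc <- seq(30, 120, by = 5)
  expect_true(all(diff(vapply(pdc, protomerCount, integer(1),
                              micelleMass = 22.5, monomerMass = 13.8)) >= 0))
  mic <- seq(5, 50, by = 5)
  expect_true(all(diff(vapply(mic, function(m)
    protomerCount(65, m, 13.8), integer(1))) <= 0))

  est <- pdcEstimate(65, c(20, 25), 13.8)
  expect_identical(est@protomerCount, 3L)
})
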