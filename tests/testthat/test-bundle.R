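bundleFixture <- function(...) buildBundle(bundleParams(...), reampProtein())

test_that("idealized bundle satisfies alpha-helical and lattice geometry", {
  b <- bundleFixture()
  ca <- caCoords(b)
  expect_identical(nrow(ca), 84L)

  map <- b@residueIndexMap
  s <- b@params@interAxisSpacing
  axesXY <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  for (h in 1:4) {
    rows <- which(map$helix == h)
    seg <- ca[rows, ]
    # consecutive CA-CA distance 3.8 +/- 0.1 A
    d <- sqrt(rowSums((seg[-1, ] - seg[-nrow(seg), ])^2))
    expect_true(all(abs(d - 3.8) <= 0.1))
    # twist: projected azimuthal step around the axis = 100 +/- 0.5 deg
    ang <- atan2(seg[, 2] - axesXY[h, 2], seg[, 1] - axesXY[h, 1]) * 180 / pi
    step <- abs(((diff(ang) + 180) %% 360) - 180)
    expect_true(all(abs(step - 100) <= 0.5))
  }
  # consecutive helices antiparallel
  dots <- b@helixAxes[1:3, ] %*% t(b@helixAxes)[, 2:4]
  expect_equal(unname(diag(dots)), rep(-1, 3), tolerance = 1e-9)
  # diagonal axis separation = spacing * sqrt(2)
  expect_equal(sqrt(sum((axesXY[1, ] - axesXY[3, ])^2)), s * sqrt(2),
               tolerance = 1e-12)

  # helix-count mismatch is rejected
  noHelix <- assembleConstruct(constructSpec("LLLLL", epitope = "",
                                             affinityTag = ""))
  expect_error(buildBundle(bundleParams(), noHelix), "helix length mismatch")
})

test_that("inward-facing selection is monotone in the angular cutoff", {
  b <- bundleFixture()
  all180 <- inwardFacing(b, 180)
  expect_identical(nrow(all180), 84L)
  at60 <- inwardFacing(b, 60)
  at0 <- inwardFacing(b, 0)
  expect_true(all(at0$chainRes %in% at60$chainRes))
  expect_true(all(at60$chainRes %in% all180$chainRes))
  # the serine at helix-2 pattern position 5 (chain residue 35) is inward
  expect_true(35 %in% at60$chainRes)
})

test_that("burial depth is distance from the nearer membrane surface", {
  b <- bundleFixture()
  mht <- b@params@membraneHalfThickness
  map <- b@residueIndexMap
  # mid-membrane residue (z = 0): depth equals the half-thickness
  mid <- map$chainRes[map$helix == 1 & map$helixPos == 11]
  expect_equal(unname(burialDepth(b, mid)), mht, tolerance = 1e-12)
  # residues outside a thinner slab report zero
  expect_message(thin <- bundleFixture(membraneHalfThickness = 14),
                 "exceeds the membrane slab")
  ends <- map$chainRes[map$helixPos %in% c(1, 21) & map$helix == 1]
  expect_identical(unname(burialDepth(thin, ends)), c(0, 0))
  # helix-2 position 5 falls inside the default selection band [6, 14]
  d35 <- unname(burialDepth(b, 35))
  expect_true(d35 >= 6 && d35 <= 14)
  expect_error(burialDepth(b, 999), "not in bundle")
})

test_that("histidine-site selection honours facing, depth and diagonals", {
  b <- bundleFixture()
  mono <- selectHisSites(b, "mono")
  expect_true(length(mono) > 0)
  expect_true(all(vapply(mono, function(p) nrow(p@hisSites) == 1L,
                         logical(1))))
  expect_true(35 %in% vapply(mono, function(p) p@hisSites$chainRes,
                             numeric(1)))
  band <- vapply(mono, function(p) p@hisSites$depth, numeric(1))
  expect_true(all(band >= 6 & band <= 14))

  bis <- selectHisSites(b, "bis")
  expect_true(length(bis) > 0)
  for (p in bis) {
    hx <- sort(p@hisSites$helix)
    expect_true(identical(hx, c(1L, 3L)) || identical(hx, c(2L, 4L)))
    expect_lte(abs(diff(p@hisSites$depth)), 4)
    caca <- sqrt(sum((caCoords(b)[as.character(p@hisSites$chainRes[1]), ] -
                      caCoords(b)[as.character(p@hisSites$chainRes[2]), ])^2))
    expect_true(caca >= 9 && caca <= 14)
  }
  # a helix-2/helix-4 pair containing residue 35 exists (the published
  # bis-His site sits on helices 2 and 4)
  has35on24 <- any(vapply(bis, function(p)
    35 %in% p@hisSites$chainRes && setequal(p@hisSites$helix, c(2L, 4L)),
    logical(1)))
  expect_true(has35on24)

  # an unreachable depth band yields an empty list, not an error
  expect_identical(selectHisSites(b, "bis", depthTarget = 40, depthTol = 1),
                   list())
})

test_that("cavity hollowing lists flanking leucines, monotone in cutoff", {
  b <- bundleFixture()
  bis <- selectHisSites(b, "bis")
  p35 <- Filter(function(p) setequal(p@hisSites$chainRes, c(35, 94)), bis)[[1]]
  hollow <- cavityMutations(b, p35)
  expect_gt(nrow(hollow@cavityMutations), 0)
  expect_true(all(hollow@cavityMutations$from == "L"))
  expect_true(all(hollow@cavityMutations$to == "A"))
  # flanking helices (1 or 3) are represented, His helices are spared sites
  expect_true(any(hollow@cavityMutations$helix %in% c(1L, 3L)))
  expect_false(any(hollow@cavityMutations$chainRes %in% c(35, 94)))

  expect_identical(nrow(cavityMutations(b, p35, 0)@cavityMutations), 0L)
  small <- cavityMutations(b, p35, 6)@cavityMutations$chainRes
  large <- cavityMutations(b, p35, 9)@cavityMutations$chainRes
  expect_true(all(small %in% large))

  # mono plans hollow around the projected heme centroid on the bundle axis
  m35 <- Filter(function(p) p@hisSites$chainRes == 35,
                selectHisSites(b, "mono"))[[1]]
  hm <- cavityMutations(b, m35, 8)
  expect_true(all(hm@cavityMutations$from == "L"))
})

test_that("PDB output round-trips coordinates and applies mutation plans", {
  b <- bundleFixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  writeBundlePDB(b, f)
  lines <- readLines(f)
  expect_identical(sum(grepl("^ATOM", lines)), 84L)
  pdb <- bio3d::read.pdb(f)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(xyz - unname(caCoords(b)))), 1e-3)

  plan <- cavityMutations(b, selectHisSites(b, "mono")[[1]])
  writeBundlePDB(b, f, plan = plan)
  pdb2 <- bio3d::read.pdb(f)
  expect_identical(
    unique(pdb2$atom$resid[pdb2$atom$resno %in% plan@hisSites$chainRes]),
    "HIS")
})
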