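test_that("column consensus reports modal residues, class markers and errors", {
  # eight-sequence toy alignment, one TM window of 3 columns:
  # col 1 unanimous L; col 2 mixed hydrophobics with no majority; col 3
  # polar with a serine majority
  cols <- cbind(rep("L", 8),
                c("L", "I", "V", "F", "L", "A", "L", "M"),
                c("S", "S", "S", "S", "S", "T", "N", "S"))
  aln <- TMAlignment(apply(cols, 1, paste, collapse = ""),
                     tmWindows = c(1, 3))
  cons <- consensusFromAlignment(aln)
  expect_named(cons, "TM1")
  expect_identical(cons$TM1$consensus, c("L", "h", "S"))

  expect_error(consensusFromAlignment(TMAlignment("LLL", c(1, 5))),
               "outside alignment width")
  expect_error(TMAlignment(character(0), c(1, 3)))
})

test_that("gap-majority columns are dropped before windowing", {
  seqs <- c("L-LS", "L-LS", "LALS", "L-LS")
  aln <- TMAlignment(seqs, c(1, 4))
  cons <- consensusFromAlignment(aln)
  expect_identical(cons$TM1$column, c(1L, 3L, 4L))
  expect_identical(cons$TM1$consensus, c("L", "L", "S"))
})

test_that("abstraction maps residues to classes and conserved G", {
  expect_identical(abstractPattern("LLLLL")@symbols, "hhhhh")
  expect_identical(abstractPattern("LSLSG")@symbols, "hphpG")
  # explicit glycine frequencies beat the letter itself
  expect_identical(
    abstractPattern(c("L", "G"), glyFreq = c(0, 0.4))@symbols, "hp")
  expect_error(abstractPattern("LXZ"), "unknown residue code: X")
  # the reference consensus abstracts to the printed 21-position pattern
  ideal <- idealizeSequence(reampPattern())
  glyf <- ifelse(strsplit(ideal, "")[[1]] == "G", 1, 0)
  expect_identical(abstractPattern(ideal, glyFreq = glyf)@symbols,
                   "hhhhpGhGhhhhphhGhhhhp")
})

test_that("idealization substitutes L at h, S at p, keeps G", {
  expect_identical(idealizeSequence("hhhhpGhGhhhhphhGhhhhp"),
                   "LLLLSGLGLLLLSLLGLLLLS")
  expect_identical(idealizeSequence("h"), "L")
  expect_identical(idealizeSequence("pGp"), "SGS")
  expect_error(idealizeSequence("hxp"))
})

test_that("design rules are a fixed point under abstraction", {
  set.seed(11)
  for (rep in 1:20) {
    p <- randomPattern(sample(8:30, 1))
    ideal <- idealizeSequence(p)
    glyf <- ifelse(strsplit(ideal, "")[[1]] == "G", 1, 0)
    back <- abstractPattern(ideal, glyFreq = glyf)
    expect_identical(idealizeSequence(back), ideal)
  }
})

test_that("assembly yields the designed 133-residue chain with W50 in H2", {
  prot <- reampProtein()
  expect_s4_class(prot, "DesignedProtein")
  seq <- designedSequence(prot)
  expect_identical(nchar(seq), 133L)
  expect_identical(substr(seq, 50, 50), "W")
  expect_identical(segmentMap(prot)[50], "H2")
  expect_identical(helixPosition(prot)[50], 20L)
  # segment boundaries under the documented convention
  ann <- annotationTable(prot)
  expect_identical(range(ann$index[ann$segment == "H2"]), c(31L, 51L))
  expect_identical(range(ann$index[ann$segment == "L3"]), c(81L, 88L))
  # TM alphabet is exactly {L,S,G,W}; loops contribute only {S,G,E,K}
  tmRes <- ann$residue[grepl("^H[1-4]$", ann$segment)]
  expect_setequal(unique(tmRes), c("L", "S", "G", "W"))
  loopRes <- ann$residue[grepl("^L[1-3]$", ann$segment)]
  expect_true(all(loopRes %in% c("S", "G", "E", "K")))
})

test_that("assembly arithmetic, trp placement errors and loop-side warning", {
  bare <- constructSpec(idealizeSequence(reampPattern()), epitope = "",
                        affinityTag = "")
  expect_identical(nchar(designedSequence(assembleConstruct(bare))), 109L)
  badTrp <- constructSpec(idealizeSequence(reampPattern()), trpPosition = 25)
  expect_error(assembleConstruct(badTrp), "helix segment")
  flipped <- constructSpec(idealizeSequence(reampPattern()),
                           loops = list(loopSpec("K", "periplasmic"),
                                        loopSpec("E", "cytoplasmic"),
                                        loopSpec("E", "periplasmic")))
  expect_warning(assembleConstruct(flipped), "positive-inside")
})

test_that("positive-inside scoring predicts the designed topology", {
  prot <- reampProtein()
  ts <- positiveInsideScore(prot)
  expect_identical(ts@orientation, "N_in_C_in")
  expect_identical(ts@insidePositive, 3L)  # loop-2 KK + epitope K
  expect_identical(ts@outsidePositive, 0L)

  # antisymmetry under side flip, and an unchanged prediction
  flip <- c(Nterm = "out", L1 = "in", L2 = "out", L3 = "in", Cterm = "out")
  tf <- positiveInsideScore(prot, flip)
  expect_identical(tf@score, -ts@score)
  expect_identical(tf@orientation, "N_in_C_in")

  # no charged residues anywhere: ambiguous
  neutral <- assembleConstruct(constructSpec(
    idealizeSequence(reampPattern()),
    loops = list(loopSpec("E", "periplasmic"), loopSpec("E", "periplasmic"),
                 loopSpec("E", "periplasmic")),
    epitope = "", affinityTag = ""))
  expect_warning(ignore <- positiveInsideScore(neutral,
    c(Nterm = "in", L1 = "out", L2 = "in", L3 = "out")), NA)
  expect_identical(positiveInsideScore(neutral,
    c(Nterm = "in", L1 = "out", L2 = "in", L3 = "out"))@orientation,
    "ambiguous")

  expect_error(positiveInsideScore(prot, c(Nterm = "in", L1 = "out")),
               "unassigned")
})

test_that("hydrophobic moment matches the brute-force wheel oracle", {
  scale2 <- c(L = 1, S = -1, G = -1, W = 1)
  m <- hydrophobicMoment("LLLLSGLGLLLLSLLGLLLLS", scale = scale2)
  expect_equal(m$moment, oracleMoment("LLLLSGLGLLLLSLLGLLLLS", scale2),
               tolerance = 1e-12)

  set.seed(4)
  kdScale <- kyteDoolittle()
  for (rep in 1:25) {
    helix <- paste(sample(names(kdScale), 21, replace = TRUE), collapse = "")
    expect_equal(hydrophobicMoment(helix)$moment,
                 oracleMoment(helix, kdScale), tolerance = 1e-9)
  }

  # homopolymer: all terms share one scale value, so the moment equals that
  # value times the geometric wheel sum (exactly zero on full 18-residue
  # turns, small but nonzero otherwise)
  expect_equal(hydrophobicMoment(strrep("L", 18))$moment, 0,
               tolerance = 1e-9)
  expect_equal(hydrophobicMoment("LLLLL")$moment,
               oracleMoment("LLLLL", kdScale), tolerance = 1e-12)
  # alternating 10-mer agrees with the oracle too
  expect_equal(hydrophobicMoment("LSLSLSLSLS", scale = scale2)$moment,
               oracleMoment("LSLSLSLSLS", scale2), tolerance = 1e-12)

  expect_error(hydrophobicMoment("LLX"), "missing from scale")
  expect_error(hydrophobicMoment("LL"), "at least 3")
})

test_that("composition properties: counts, mass and extinction", {
  props <- compositionProperties(reampProtein())
  expect_identical(props@nTrp, 1L)
  expect_identical(props@nTyr, 0L)
  expect_identical(props@eps280, 5500)
  expect_identical(sum(props@counts), 133L)

  gg <- compositionProperties("GG")
  expect_equal(gg@mwAverage, 132.12, tolerance = 1e-3)
  expect_identical(compositionProperties("LSG")@eps280, 0)
  # hand-computed tripeptide: W + Y + C, all-paired convention has no
  # cystine from a single Cys
  wyc <- compositionProperties("WYC")
  expect_identical(wyc@eps280, 5500 + 1490)
  expect_identical(compositionProperties("WYCC")@eps280, 5500 + 1490 + 125)
  expect_equal(wyc@mwAverage, 186.2132 + 163.1760 + 103.1388 + 18.01528,
               tolerance = 1e-6)
  expect_error(compositionProperties("LLB"), "nonstandard")
  expect_error(compositionProperties(""), "empty")
})
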