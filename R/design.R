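# Consensus abstraction and minimal-sequence design.
#
# The design route is: aligned natural TM helices -> per-column consensus ->
# binary h/p (+ conserved G) pattern -> idealized minimal sequence (L at h,
# S at p, G retained) -> assembled single-chain four-helix construct.

#' Default hydrophobic/polar residue classification
#'
#' Hydrophobic class `h` = \{A, C, F, I, L, M, V, W, Y\}; all other standard
#' residues are polar (`p`). Glycine is classed `p` but is handled by the
#' conservation rule during abstraction, not by its class.
#'
#' @param hydrophobic character vector of one-letter codes forming class `h`.
#' @param glyThreshold column glycine frequency at or above which a position
#'   is emitted as `G` (default 0.5).
#' @param consensusThreshold modal-residue frequency required to report a
#'   residue (rather than a class marker) as the column consensus
#'   (default 0.5).
#' @return a [ResidueClassScheme-class].
#' @examples
#' scheme <- residueClassScheme()
#' scheme@classOf[c("L", "S", "G")]
#' @export
residueClassScheme <- function(hydrophobic = c("A", "C", "F", "I", "L", "M",
                                               "V", "W", "Y"),
                               glyThreshold = 0.5,
                               consensusThreshold = 0.5) {
  cls <- setNames(ifelse(AA20 %in% hydrophobic, "h", "p"), AA20)
  new("ResidueClassScheme", classOf = cls, glyThreshold = glyThreshold,
      consensusThreshold = consensusThreshold)
}

#' Construct an HPPattern
#'
#' @param symbols a string over `{h, p, G}`.
#' @return an [HPPattern-class].
#' @examples
#' reampPattern()
#' @export
HPPattern <- function(symbols) new("HPPattern", symbols = symbols)

#' The reference transmembrane pattern of the minimal design
#'
#' The 21-position pattern to which the per-helix consensus of the small
#' multidrug resistance (SMR) template family abstracts.
#'
#' @return an [HPPattern-class] of length 21.
#' @export
reampPattern <- function() HPPattern("hhhhpGhGhhhhphhGhhhhp")

#' Construct a TM alignment
#'
#' @param seqs named character vector or [Biostrings::AAStringSet] of
#'   equal-length gapped sequences (`-` for gaps).
#' @param tmWindows two-column matrix (start, end) of 1-based inclusive
#'   column ranges marking the transmembrane domains.
#' @return a [TMAlignment-class].
#' @export
TMAlignment <- function(seqs, tmWindows) {
  if (!is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  if (!is.matrix(tmWindows))  # flat (start, end, start, end, ...) vector
    tmWindows <- matrix(tmWindows, ncol = 2L, byrow = TRUE)
  storage.mode(tmWindows) <- "integer"
  dimnames(tmWindows) <- list(NULL, c("start", "end"))
  new("TMAlignment", seqs = seqs, tmWindows = tmWindows)
}

alignmentMatrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln@seqs), ""))
}

#' Per-column consensus of the transmembrane windows of an alignment
#'
#' Columns with more than `gapDropThreshold` gaps are dropped before
#' windowing. For each remaining column inside each TM window the modal
#' residue is reported when its (non-gap) frequency reaches the scheme's
#' `consensusThreshold`; otherwise the marker (`h` or `p`) of the modal
#' residue class is emitted. Column-wise glycine frequencies are carried
#' along for the abstraction step.
#'
#' @param aln a [TMAlignment-class].
#' @param scheme a [ResidueClassScheme-class].
#' @param gapDropThreshold columns whose gap fraction exceeds this value are
#'   dropped (default 0.5).
#' @return named list (one element per TM window) of data.frames with
#'   columns `column` (original alignment column), `consensus` (residue or
#'   class marker) and `glyFreq`.
#' @export
consensusFromAlignment <- function(aln, scheme = residueClassScheme(),
                                   gapDropThreshold = 0.5) {
  stopifnot(is(aln, "TMAlignment"), is(scheme, "ResidueClassScheme"))
  if (length(aln@seqs) == 0L) stop("empty alignment")
  m <- alignmentMatrix(aln)
  width <- ncol(m)
  if (any(aln@tmWindows > width)) stop("TM window outside alignment width")
  gapFrac <- colMeans(m == "-")
  keep <- gapFrac <= gapDropThreshold
  out <- vector("list", nrow(aln@tmWindows))
  for (w in seq_len(nrow(aln@tmWindows))) {
    cols <- seq(aln@tmWindows[w, 1], aln@tmWindows[w, 2])
    cols <- cols[keep[cols]]
    cons <- character(length(cols))
    glyf <- numeric(length(cols))
    for (j in seq_along(cols)) {
      col <- m[, cols[j]]
      col <- col[col != "-"]
      bad <- setdiff(unique(col), AA20)
      if (length(bad))
        stop("unknown residue code in alignment: ", paste(bad, collapse = ", "))
      tab <- sort(table(col), decreasing = TRUE)
      modal <- names(tab)[1]
      glyf[j] <- mean(col == "G")
      cons[j] <- if (tab[1] / length(col) >= scheme@consensusThreshold) modal
                 else unname(scheme@classOf[modal])
    }
    out[[w]] <- data.frame(column = cols, consensus = cons, glyFreq = glyf)
  }
  names(out) <- paste0("TM", seq_along(out))
  out
}

#' Abstract a consensus into a binary h/p (+G) pattern
#'
#' Each consensus symbol is mapped to its class (`h` or `p`); positions whose
#' column-wise glycine frequency reaches the scheme's `glyThreshold` are
#' emitted as `G` instead. Class markers `h`/`p` already present in the
#' consensus pass through unchanged.
#'
#' @param consensus a residue-or-marker string, character vector of symbols,
#'   or one window data.frame from [consensusFromAlignment()] (in which case
#'   its `glyFreq` column is used).
#' @param scheme a [ResidueClassScheme-class].
#' @param glyFreq optional numeric vector of per-position glycine
#'   frequencies; when omitted and `consensus` is a plain string, a literal
#'   `G` consensus is treated as conserved.
#' @return an [HPPattern-class].
#' @examples
#' abstractPattern("LSLSG")   # "hphpG"
#' @export
abstractPattern <- function(consensus, scheme = residueClassScheme(),
                            glyFreq = NULL) {
  if (is.data.frame(consensus)) {
    glyFreq <- consensus$glyFreq
    consensus <- consensus$consensus
  }
  if (length(consensus) == 1L && nchar(consensus) > 1L)
    consensus <- strsplit(consensus, "")[[1]]
  n <- length(consensus)
  if (is.null(glyFreq)) glyFreq <- ifelse(consensus == "G", 1, 0)
  stopifnot(length(glyFreq) == n)
  sym <- character(n)
  for (i in seq_len(n)) {
    if (glyFreq[i] >= scheme@glyThreshold) { sym[i] <- "G"; next }
    ci <- consensus[i]
    if (ci %in% c("h", "p")) sym[i] <- ci
    else if (ci %in% names(scheme@classOf)) sym[i] <- unname(scheme@classOf[ci])
    else stop("unknown residue code: ", ci)
  }
  HPPattern(paste(sym, collapse = ""))
}

#' Idealize a pattern into the minimal sequence
#'
#' Leucine at every `h` position, serine at every `p` position, glycine
#' retained at `G`.
#'
#' @param pattern an [HPPattern-class] or a pattern string.
#' @return residue string of the same length.
#' @examples
#' idealizeSequence(reampPattern())  # "LLLLSGLGLLLLSLLGLLLLS"
#' @export
idealizeSequence <- function(pattern) {
  if (is(pattern, "HPPattern")) pattern <- pattern@symbols
  else validObject(HPPattern(pattern))
  chartr("hp", "LS", pattern)
}

#' Construct a loop specification
#'
#' @param xResidue `"E"` or `"K"`, substituted at the two `X` positions of
#'   the fixed template `SSGXXGSS`.
#' @param side `"periplasmic"` or `"cytoplasmic"`.
#' @return a [LoopSpec-class].
#' @export
loopSpec <- function(xResidue, side) {
  new("LoopSpec", xResidue = xResidue, side = side)
}

loopSequence <- function(loop) {
  chartr("X", loop@xResidue, "SSGXXGSS")
}

#' Construct specification for a single-chain four-helix design
#'
#' @param helixSequence transmembrane helix residue string (used four times).
#' @param loops list of three [LoopSpec-class] objects.
#' @param trpPosition 1-based chain position replaced by tryptophan
#'   (`NA` for none).
#' @param nTerminal N-terminal residue string.
#' @param epitope C-terminal epitope (default the V5 epitope).
#' @param affinityTag affinity-tag residue string (default deca-histidine;
#'   `""` for none).
#' @return a [ConstructSpec-class].
#' @export
constructSpec <- function(helixSequence,
                          loops = list(loopSpec("E", "periplasmic"),
                                       loopSpec("K", "cytoplasmic"),
                                       loopSpec("E", "periplasmic")),
                          trpPosition = NA_real_,
                          nTerminal = "M",
                          epitope = "GKPIPNPLLGLDST",
                          affinityTag = "HHHHHHHHHH") {
  new("ConstructSpec", helixSequence = helixSequence, loops = loops,
      trpPosition = trpPosition, nTerminal = nTerminal, epitope = epitope,
      affinityTag = affinityTag)
}

#' The reference minimal-construct specification
#'
#' The default single-chain design: Met, four copies of the idealized
#' 21-residue helix, loops `SSGEEGSS` / `SSGKKGSS` / `SSGEEGSS` (glutamate
#' periplasmic, lysine cytoplasmic per the positive-inside rule), a single
#' tryptophan at chain position 50 (near the end of helix 2) as optical
#' probe, the V5 epitope, and a C-terminal affinity tag. With the default
#' deca-histidine tag the chain is 133 residues.
#'
#' @param tag `"his10"`, `"none"`, or an explicit residue string.
#' @return a [ConstructSpec-class].
#' @export
reampSpec <- function(tag = "his10") {
  tagSeq <- switch(tag, his10 = "HHHHHHHHHH", none = "", tag)
  constructSpec(idealizeSequence(reampPattern()), trpPosition = 50,
                affinityTag = tagSeq)
}

#' Assemble a construct specification into a designed protein
#'
#' Concatenates `nTerminal + H1 + L1 + H2 + L2 + H3 + L3 + H4 + epitope +
#' tag`, substitutes tryptophan at `trpPosition` (which must fall inside a
#' helix segment), and records the per-residue segment map and within-helix
#' positions. Residue numbering is 1-based at the first N-terminal residue;
#' with the defaults H1 spans 2-22, L1 23-30, H2 31-51, L2 52-59, H3 60-80,
#' L3 81-88 and H4 89-109.
#'
#' A lysine-carrying loop declared periplasmic triggers a warning: under the
#' positive-inside rule K belongs on the cytoplasmic side.
#'
#' @param spec a [ConstructSpec-class].
#' @return a [DesignedProtein-class].
#' @examples
#' prot <- assembleConstruct(reampSpec())
#' nchar(designedSequence(prot))
#' @export
assembleConstruct <- function(spec) {
  stopifnot(is(spec, "ConstructSpec"))
  validObject(spec)
  for (i in seq_along(spec@loops)) {
    lp <- spec@loops[[i]]
    if (lp@xResidue == "K" && lp@side != "cytoplasmic")
      warning("loop ", i, " carries lysine on the ", lp@side,
              " side; the positive-inside rule places K cytoplasmically")
  }
  segs <- list(Nterm = spec@nTerminal,
               H1 = spec@helixSequence,
               L1 = loopSequence(spec@loops[[1]]),
               H2 = spec@helixSequence,
               L2 = loopSequence(spec@loops[[2]]),
               H3 = spec@helixSequence,
               L3 = loopSequence(spec@loops[[3]]),
               H4 = spec@helixSequence,
               epitope = spec@epitope,
               tag = spec@affinityTag)
  segs <- segs[nchar(unlist(segs)) > 0]
  lens <- nchar(unlist(segs))
  segMap <- rep(names(segs), lens)
  seq <- paste(unlist(segs), collapse = "")
  helixPos <- rep(NA_integer_, nchar(seq))
  helixPos[grepl("^H[1-4]$", segMap)] <-
    unlist(lapply(lens[grepl("^H", names(segs))], seq_len))
  if (!is.na(spec@trpPosition)) {
    tp <- as.integer(spec@trpPosition)
    if (tp < 1L || tp > nchar(seq) || !grepl("^H[1-4]$", segMap[tp]))
      stop("trpPosition ", tp, " does not fall inside a helix segment")
    substr(seq, tp, tp) <- "W"
  }
  new("DesignedProtein", sequence = seq, segmentMap = segMap,
      helixPosition = helixPos)
}

#' Per-residue annotation table of a designed protein
#'
#' @param protein a [DesignedProtein-class].
#' @return data.frame with columns `index`, `residue`, `segment`,
#'   `helixPosition`.
#' @export
annotationTable <- function(protein) {
  stopifnot(is(protein, "DesignedProtein"))
  data.frame(index = seq_len(nchar(protein@sequence)),
             residue = strsplit(protein@sequence, "")[[1]],
             segment = protein@segmentMap,
             helixPosition = protein@helixPosition)
}

#' Positive-inside topology score
#'
#' Counts lysine and arginine residues on each side of the membrane under a
#' given side assignment of the extramembrane segments (the N-terminal amine
#' itself is not counted). The predicted orientation is the assignment whose
#' inside carries more K/R; a tie is reported as `"ambiguous"`.
#'
#' @param protein a [DesignedProtein-class].
#' @param loopSides named character vector assigning each extramembrane
#'   segment present in the protein (among `Nterm`, `L1`, `L2`, `L3`,
#'   `epitope`, `tag`) to `"in"` or `"out"`. `epitope`/`tag` default to the
#'   `Cterm` entry when given as `Cterm`. The default is the designed
#'   N-in/C-in topology.
#' @return a [TopologyScore-class]; `score` is inside minus outside K/R for
#'   the *given* assignment.
#' @examples
#' positiveInsideScore(assembleConstruct(reampSpec()))
#' @export
positiveInsideScore <- function(protein,
                                loopSides = c(Nterm = "in", L1 = "out",
                                              L2 = "in", L3 = "out",
                                              Cterm = "in")) {
  stopifnot(is(protein, "DesignedProtein"))
  sides <- loopSides
  if ("Cterm" %in% names(sides)) {
    sides <- c(sides[names(sides) != "Cterm"],
               epitope = unname(sides[["Cterm"]]),
               tag = unname(sides[["Cterm"]]))
  }
  extra <- unique(protein@segmentMap[!grepl("^H[1-4]$", protein@segmentMap)])
  missing <- setdiff(extra, names(sides))
  if (length(missing))
    stop("unassigned extramembrane segment(s): ",
         paste(missing, collapse = ", "))
  if (!all(sides[extra] %in% c("in", "out")))
    stop("sides must be 'in' or 'out'")
  res <- strsplit(protein@sequence, "")[[1]]
  pos <- res %in% c("K", "R") & protein@segmentMap %in% extra
  inside <- sum(pos & sides[protein@segmentMap] == "in", na.rm = TRUE)
  outside <- sum(pos & sides[protein@segmentMap] == "out", na.rm = TRUE)
  ntermIn <- identical(unname(sides[[if ("Nterm" %in% extra) "Nterm"
                                     else extra[1]]]), "in")
  orientation <- if (inside == outside) "ambiguous"
    else if ((inside > outside) == ntermIn) "N_in_C_in" else "N_out_C_out"
  new("TopologyScore", orientation = orientation,
      insidePositive = as.integer(inside),
      outsidePositive = as.integer(outside),
      score = as.integer(inside - outside))
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
kyteDoolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Helical hydrophobic moment
#'
#' The per-residue hydrophobic moment of a helix: the magnitude of the
#' vector sum of the residue hydrophobicities placed at successive angles of
#' `twistDeg` around the helical wheel, divided by the number of residues.
#'
#' @param helix residue string (length >= 3).
#' @param scale named numeric hydrophobicity scale covering every residue in
#'   `helix` (default Kyte-Doolittle).
#' @param twistDeg helical twist per residue in degrees (default 100, the
#'   ideal alpha-helix).
#' @return list with `moment` (per-residue magnitude), `directionDeg` (angle
#'   of the moment on the wheel, degrees, relative to residue 1) and
#'   `total` (unnormalized magnitude).
#' @examples
#' hydrophobicMoment("LLLLSGLGLLLLSLLGLLLLS",
#'                   scale = c(L = 1, S = -1, G = -1))$moment
#' @export
hydrophobicMoment <- function(helix, scale = kyteDoolittle(),
                              twistDeg = 100) {
  res <- strsplit(helix, "")[[1]]
  if (length(res) < 3L) stop("helix must contain at least 3 residues")
  missing <- setdiff(res, names(scale))
  if (length(missing))
    stop("residue(s) missing from scale: ", paste(missing, collapse = ", "))
  ang <- (seq_along(res) - 1) * twistDeg * pi / 180
  h <- unname(scale[res])
  vx <- sum(h * cos(ang)); vy <- sum(h * sin(ang))
  total <- sqrt(vx^2 + vy^2)
  list(moment = total / length(res),
       directionDeg = atan2(vy, vx) * 180 / pi,
       total = total)
}

# Isotope-averaged residue masses (Da) and the water correction.
RESIDUE_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
                  V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
                  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
                  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
                  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.01528

#' Composition-derived physical properties
#'
#' Residue counts, average molecular weight (sum of isotope-averaged residue
#' masses plus one water) and the 280 nm molar extinction coefficient
#' `eps280 = 5500 nW + 1490 nY + 125 nCystine` (/M/cm).
#'
#' @param x a [DesignedProtein-class] or residue string.
#' @param cystines number of cystine (disulfide) pairs contributing at
#'   280 nm; default assumes all cysteines are paired (`floor(nC / 2)`).
#' @return a [CompositionProperties-class].
#' @examples
#' compositionProperties(assembleConstruct(reampSpec()))
#' @export
compositionProperties <- function(x, cystines = NULL) {
  seq <- if (is(x, "DesignedProtein")) x@sequence else x
  if (!nzchar(seq)) stop("sequence is empty")
  res <- strsplit(seq, "")[[1]]
  bad <- setdiff(res, AA20)
  if (length(bad))
    stop("nonstandard residue(s): ", paste(unique(bad), collapse = ", "))
  counts <- table(factor(res, levels = AA20))
  counts <- setNames(as.integer(counts), AA20)
  nTrp <- counts[["W"]]; nTyr <- counts[["Y"]]
  if (is.null(cystines)) cystines <- counts[["C"]] %/% 2L
  mw <- sum(RESIDUE_MASS[res]) + WATER_MASS
  eps <- 5500 * nTrp + 1490 * nTyr + 125 * cystines
  new("CompositionProperties", counts = counts, mwAverage = mw,
      eps280 = eps, nTrp = as.integer(nTrp), nTyr = as.integer(nTyr),
      nCystine = as.integer(cystines))
}
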