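# Shared readers and writers: aligned FASTA, designed-construct FASTA,
# annotation tables, and the delimited-table dialects used by the analysis
# modules. FASTA goes through Biostrings; delimited tables are validated
# against a simple column schema with errors naming the offending cell.

#' Read an aligned FASTA file as a TM alignment
#'
#' @param path FASTA file with equal-length gapped sequences (`-` gaps).
#' @param tmWindows two-column matrix or length-2n vector of 1-based
#'   (start, end) column ranges for the transmembrane windows.
#' @return a [TMAlignment-class].
#' @export
readAlignedFasta <- function(path, tmWindows) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  TMAlignment(seqs, tmWindows)
}

#' Write sequences as FASTA
#'
#' @param x a [DesignedProtein-class], named character vector, or
#'   [Biostrings::AAStringSet]; lines wrap at 60 columns.
#' @param path output path.
#' @param name record name used for a [DesignedProtein-class].
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, name = "designed_construct") {
  if (is(x, "DesignedProtein")) x <- setNames(x@sequence, name)
  if (!is(x, "AAStringSet")) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector (possibly empty).
#' @export
readFasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Write the per-residue annotation table of a designed protein as TSV
#'
#' @param protein a [DesignedProtein-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTable <- function(protein, path) {
  utils::write.table(annotationTable(protein), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a delimited file with '# key=value' header lines; returns
# list(meta=..., data=...). Validates required columns and numeric cells,
# naming the offending row/column on failure.
readKeyedTable <- function(path, requiredCols, numericCols = requiredCols,
                           sep = ",") {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in metaLines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=")[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- read.csv(text = lines[!grepl("^#", lines)], sep = sep,
                 stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(requiredCols, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in intersect(numericCols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop("non-numeric value '", df[[col]][bad[1]], "' in column '", col,
           "', row ", bad[1], " of ", path)
    df[[col]] <- v
  }
  list(meta = meta, data = df)
}

#' Read a titration CSV
#'
#' Expects columns `ligand_uM` and `signal`, preceded by comment headers
#' `# protein_uM=...` and optionally `# pathlength_cm=...`.
#'
#' @param path CSV path.
#' @return a [TitrationSeries-class].
#' @export
readTitrationCSV <- function(path) {
  x <- readKeyedTable(path, c("ligand_uM", "signal"))
  if (is.null(x$meta$protein_uM))
    stop("titration CSV must carry a '# protein_uM=' header line")
  titrationSeries(x$data$ligand_uM, x$data$signal,
                  proteinConc = as.numeric(x$meta$protein_uM),
                  pathlength = if (is.null(x$meta$pathlength_cm)) 1
                               else as.numeric(x$meta$pathlength_cm))
}

#' Write a titration series as CSV
#'
#' @param series a [TitrationSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTitrationCSV <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# protein_uM=%g", series@proteinConc),
               sprintf("# pathlength_cm=%g", series@pathlength),
               "ligand_uM,signal"), con)
  utils::write.table(data.frame(series@ligand, series@signal), con,
                     sep = ",", col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a potentiometry CSV
#'
#' Expects columns `eh_mV`, `absorbance` and optionally `sweep`.
#'
#' @param path CSV path.
#' @return a list of [PotentiometrySeries-class], one per sweep present.
#' @export
readPotentiometryCSV <- function(path) {
  x <- readKeyedTable(path, c("eh_mV", "absorbance"),
                      numericCols = c("eh_mV", "absorbance"))
  df <- x$data
  if (is.null(df$sweep)) df$sweep <- "reductive"
  lapply(split(df, df$sweep), function(d)
    potentiometrySeries(d$eh_mV, d$absorbance, d$sweep[1]))
}

#' Read an SEC standards CSV
#'
#' Expects columns `name`, `mass_kDa`, `rs_nm` and optionally `s_value`.
#'
#' @param path CSV path.
#' @return data.frame with columns `name`, `mass`, `stokesRadius`,
#'   `sValue`.
#' @export
readStandardsCSV <- function(path) {
  x <- readKeyedTable(path, c("name", "mass_kDa", "rs_nm"),
                      numericCols = c("mass_kDa", "rs_nm", "s_value"))
  data.frame(name = x$data$name, mass = x$data$mass_kDa,
             stokesRadius = x$data$rs_nm,
             sValue = if (is.null(x$data$s_value)) NA_real_
                      else x$data$s_value)
}

#' Read a micelle-series CSV
#'
#' Expects columns `detergent`, `micelle_mass_kDa`, `apparent_mass_kDa`.
#'
#' @param path CSV path.
#' @return data.frame with columns `detergent`, `micelleMass`,
#'   `apparentPdcMass`.
#' @export
readMicelleCSV <- function(path) {
  x <- readKeyedTable(path,
                      c("detergent", "micelle_mass_kDa", "apparent_mass_kDa"),
                      numericCols = c("micelle_mass_kDa", "apparent_mass_kDa"))
  data.frame(detergent = x$data$detergent,
             micelleMass = x$data$micelle_mass_kDa,
             apparentPdcMass = x$data$apparent_mass_kDa)
}
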