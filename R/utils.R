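# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PHENOTYPE_CATEGORIES <- c("both", "major_only", "minor_only", "absent")
GENOTYPE_LEVELS <- c("major_hom", "het", "minor_hom")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Collapse isoleucine to leucine
#'
#' Isoleucine and leucine are isobaric and indistinguishable by the
#' collision-induced fragmentation used for peptide identification; sequences
#' are compared after mapping I to L wherever the equivalence rule applies.
#'
#' @param x character vector of amino-acid sequences.
#' @return character vector with every I replaced by L.
#' @export
ilCollapse <- function(x) chartr("I", "L", x)

## Validate amino-acid strings against the 20-letter alphabet.
checkAminoAcids <- function(x, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("non-amino-acid character in %s: %s", what,
                 paste(utils::head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Strip flanking-residue notation from a peptide string
#'
#' Peptide exports often carry the preceding and following residue as in
#' \code{"R.LEGEINTYR.A"}; a single leading \code{"X."} and trailing
#' \code{".X"} token (where X is a residue or \code{-} for a protein
#' terminus) are removed.
#'
#' @param x character vector of peptide strings.
#' @return bare peptide sequences.
#' @export
stripFlanks <- function(x) {
  x <- sub("^[A-Z-]\\.", "", x)
  sub("\\.[A-Z-]$", "", x)
}

#' Parse inline peptide modification annotations
#'
#' Parses strings of the form \code{"M7:Oxidation (M); C8:Carbamidomethylation"}
#' into a data frame of positions and modification names. Empty strings,
#' \code{NA} and \code{"-"} denote an unmodified peptide.
#'
#' @param x a single modification annotation string.
#' @param sep token separator, default \code{";"}.
#' @return data.frame with columns \code{position} (integer, 1-based within
#'   the peptide) and \code{name}.
#' @export
parseModifications <- function(x, sep = ";") {
  empty <- data.frame(position = integer(), name = character(),
                      stringsAsFactors = FALSE)
  if (length(x) != 1L || is.na(x) || !nzchar(trimws(x)) || trimws(x) == "-")
    return(empty)
  tokens <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  m <- regmatches(tokens, regexec("^([A-Z]?)([0-9]+):(.+)$", tokens))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop(sprintf("unparseable modification token: '%s'",
                 tokens[which(bad)[1]]), call. = FALSE)
  }
  data.frame(
    position = as.integer(vapply(m, `[`, "", 3L)),
    name = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

## TRUE when a modification annotation carries a deamidation at `position`.
hasDeamidationAt <- function(modString, position) {
  mods <- parseModifications(modString)
  any(mods$position == position & grepl("deamid", mods$name, ignore.case = TRUE))
}

## Derive the four-level phenotype category from the two detection booleans.
phenotypeFromBooleans <- function(major, minor) {
  ifelse(major & minor, "both",
         ifelse(major, "major_only",
                ifelse(minor, "minor_only", "absent")))
}

## Sniff the field separator of a delimited text file: tab unless the header
## contains commas and no tabs.
sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return("\t")
  if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
}

## Read everything as character (single-letter amino acids like "T" must
## not become logicals); readers convert numeric fields explicitly.
readDelim <- function(path, sep = "auto") {
  if (identical(sep, "auto")) sep <- sniffSep(path)
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

writeDelim <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
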