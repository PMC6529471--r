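#' Read a protein FASTA file
#'
#' Reads protein sequences and returns them keyed by accession, taken as the
#' first whitespace-delimited token of each header. Sequences are uppercased
#' and validated against the 20-letter amino-acid alphabet; duplicate
#' accessions are rejected.
#'
#' @param path path to a FASTA file of protein sequences.
#' @return a named [Biostrings::AAStringSet] (accession -> sequence). An
#'   empty file yields an empty set with a warning.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 example", "MAR", "LEK"), fa)
#' readProteinFasta(fa)
#' @importFrom Biostrings readAAStringSet AAStringSet writeXStringSet
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (file.size(path) == 0L ||
      !any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    warning(sprintf("empty FASTA file: %s", path))
    return(Biostrings::AAStringSet())
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA in %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  acc <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyNA(acc) || !all(nzchar(acc)))
    stop(sprintf("malformed FASTA header in %s", path), call. = FALSE)
  dup <- acc[duplicated(acc)]
  if (length(dup))
    stop(sprintf("duplicate accession(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  seqs <- toupper(as.character(set))
  checkAminoAcids(seqs, what = sprintf("FASTA sequences in %s", path))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- acc
  out
}

#' Write a protein FASTA file
#'
#' @param proteome a named [Biostrings::AAStringSet] or named character
#'   vector of protein sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProteinFasta <- function(proteome, path) {
  if (is.character(proteome)) proteome <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(proteome, path)
  invisible(path)
}
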