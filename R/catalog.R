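# GVP catalog construction: variant application, in-silico tryptic
# digestion, and enumeration of major/minor variant peptides per SNP.

DEAMIDATION_MAP <- c(N = "D", Q = "E")

#' Apply a single amino-acid variant to a protein sequence
#'
#' Substitutes one residue, guarding against stale coordinates by requiring
#' the reference residue at the stated position.
#'
#' @param sequence protein sequence (character scalar or
#'   [Biostrings::AAString]).
#' @param position 1-based residue position.
#' @param refAa expected residue at \code{position}.
#' @param altAa replacement residue.
#' @return the mutated sequence as a character scalar.
#' @examples
#' applyVariant("MARLEGEINTYRAK", 10, "T", "M")
#' @export
applyVariant <- function(sequence, position, refAa, altAa) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  position <- as.integer(position)
  if (position < 1L || position > n)
    stop(sprintf("position %d outside sequence of length %d", position, n),
         call. = FALSE)
  found <- substr(sequence, position, position)
  if (found != refAa)
    stop(sprintf("reference mismatch at position %d: expected %s, found %s",
                 position, refAa, found), call. = FALSE)
  substr(sequence, position, position) <- altAa
  sequence
}

## 0-based cleavage boundaries of a tryptic digest: position i is a boundary
## when the protein is cut after residue i. Always includes 0 and nchar(seq).
trypticBoundaries <- function(sequence, prolineRule = FALSE) {
  n <- nchar(sequence)
  if (n == 0L) return(0L)
  res <- strsplit(sequence, "")[[1]]
  cut <- which(res %in% c("K", "R"))
  if (prolineRule && length(cut)) {
    followedByP <- cut < n & res[pmin(cut + 1L, n)] == "P"
    cut <- cut[!followedByP]
  }
  unique(c(0L, cut, n))
}

#' In-silico tryptic digestion
#'
#' Enumerates all peptides obtainable by cleaving after lysine or arginine
#' with up to \code{maxMissed} internal missed cleavage sites. With
#' \code{prolineRule}, cleavage is suppressed when the residue following
#' K/R is proline.
#'
#' @param sequence protein sequence (character scalar, case-insensitive).
#' @param maxMissed maximum number of internal missed cleavages (>= 0).
#' @param prolineRule suppress cleavage before proline.
#' @return data.frame with columns \code{peptide}, \code{start} (1-based),
#'   \code{end} (1-based inclusive) and \code{missed_cleavages}. Empty input
#'   yields an empty frame.
#' @examples
#' digestProtein("MARLEGEINTYRAK", maxMissed = 1)
#' @export
digestProtein <- function(sequence, maxMissed = 0L, prolineRule = FALSE) {
  stopifnot(maxMissed >= 0L)
  sequence <- toupper(as.character(sequence))
  empty <- data.frame(peptide = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) == 0L) return(empty)
  b <- trypticBoundaries(sequence, prolineRule)
  nSeg <- length(b) - 1L
  if (nSeg < 1L) return(empty)
  out <- vector("list", maxMissed + 1L)
  for (m in 0:min(maxMissed, nSeg - 1L)) {
    i <- seq_len(nSeg - m)            # first segment index of each window
    start <- b[i] + 1L
    end <- b[i + m + 1L]
    out[[m + 1L]] <- data.frame(
      peptide = substring(sequence, start, end),
      start = start, end = end, missed_cleavages = m,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## All tryptic windows of `sequence` covering residue `position`.
siteWindows <- function(sequence, position, maxMissed, prolineRule) {
  d <- digestProtein(sequence, maxMissed, prolineRule)
  d[d$start <= position & d$end >= position, , drop = FALSE]
}

## Semi-specific truncations of a window (one non-tryptic terminus) still
## covering `position`, with length >= minLength. Returns (start, end) pairs.
semiSpecificWindows <- function(start, end, position, minLength) {
  safeSeq <- function(from, to) if (from > to) integer(0) else seq(from, to)
  endN <- safeSeq(max(position, start + minLength - 1L), end - 1L)
  keepN <- if (length(endN)) data.frame(start = start, end = endN) else NULL
  startC <- safeSeq(start + 1L, min(position, end - minLength + 1L))
  keepC <- if (length(startC)) data.frame(start = startC, end = end) else NULL
  out <- rbind(keepN, keepC)
  if (is.null(out)) return(out)
  out <- out[out$end - out$start + 1L >= minLength &
             out$start <= position & out$end >= position, , drop = FALSE]
  out
}

#' Build the major/minor GVP catalog
#'
#' For each missense SNP, digests the major- and minor-allele protein
#' sequences and retains all peptide windows covering the variant site. The
#' window set is the union over the two alleles, so major and minor records
#' always share coordinates and differ only at the variant residue; a window
#' that is not fully tryptic in one allele (e.g. when the variant creates or
#' removes a cleavage site) is flagged \code{semi_specific} for that allele.
#' With \code{semiSpecific = TRUE}, single-terminus truncations of
#' site-covering windows are additionally admitted, mirroring the
#' non-tryptic variant peptides observed in keratin-associated proteins.
#'
#' Records are flagged \code{discriminative = FALSE} when the major and
#' minor peptides are indistinguishable under I/L equivalence, and
#' \code{modification_confounded = TRUE} when one allele's peptide maps onto
#' the other's by deamidation (N->D or Q->E) at the variant site.
#' \code{shared_window = TRUE} marks records whose peptide window also
#' covers another catalog SNP on the same protein (multi-variant haplotypes
#' are not resolved, only flagged).
#'
#' @param snps validated missense SNP table (see [validateSnpTable()]); the
#'   reference proteome must carry the major allele at each variant site.
#' @param proteome named [Biostrings::AAStringSet] or character vector of
#'   protein sequences keyed by accession.
#' @param maxMissed maximum internal missed cleavages (default 3, the
#'   permissive setting used for hair-shaft digests).
#' @param prolineRule suppress cleavage before proline (default FALSE).
#' @param semiSpecific admit single-terminus truncations (default FALSE).
#' @param minLength,maxLength peptide length bounds for detectability.
#' @return a \linkS4class{GVPCatalog}.
#' @export
buildCatalog <- function(snps, proteome, maxMissed = 3L, prolineRule = FALSE,
                         semiSpecific = FALSE, minLength = 5L,
                         maxLength = 50L) {
  snps <- validateSnpTable(as.data.frame(snps))
  seqs <- if (is.character(proteome)) proteome else
    stats::setNames(as.character(proteome), names(proteome))
  missing <- setdiff(snps$protein_accession, names(seqs))
  if (length(missing)) {
    bad <- snps$snp_id[snps$protein_accession %in% missing]
    stop(sprintf("SNP accession(s) missing from proteome: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  recs <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    s <- snps[i, ]
    ref <- toupper(seqs[[s$protein_accession]])
    pos <- s$residue_position
    if (pos > nchar(ref))
      stop(sprintf("%s: residue_position %d beyond protein %s (length %d)",
                   s$snp_id, pos, s$protein_accession, nchar(ref)),
           call. = FALSE)
    found <- substr(ref, pos, pos)
    if (found != s$major_aa)
      stop(sprintf("%s: reference mismatch at %s position %d: expected %s, found %s",
                   s$snp_id, s$protein_accession, pos, s$major_aa, found),
           call. = FALSE)
    alleleSeqs <- c(major = ref,
                    minor = applyVariant(ref, pos, s$major_aa, s$minor_aa))
    winMajor <- siteWindows(alleleSeqs[["major"]], pos, maxMissed, prolineRule)
    winMinor <- siteWindows(alleleSeqs[["minor"]], pos, maxMissed, prolineRule)
    windows <- unique(rbind(winMajor[c("start", "end")],
                            winMinor[c("start", "end")]))
    windows$semi <- FALSE
    if (semiSpecific && nrow(windows)) {
      extra <- do.call(rbind, lapply(seq_len(nrow(windows)), function(k) {
        semiSpecificWindows(windows$start[k], windows$end[k], pos, minLength)
      }))
      if (!is.null(extra) && nrow(extra)) {
        extra <- unique(extra)
        extra$semi <- TRUE
        windows <- rbind(windows, extra)
        windows <- windows[!duplicated(windows[c("start", "end")]), ,
                           drop = FALSE]
      }
    }
    len <- windows$end - windows$start + 1L
    windows <- windows[len >= minLength & len <= maxLength, , drop = FALSE]
    if (!nrow(windows)) next
    trypticKey <- list(
      major = paste(winMajor$start, winMajor$end),
      minor = paste(winMinor$start, winMinor$end)
    )
    perAllele <- lapply(c("major", "minor"), function(allele) {
      aseq <- alleleSeqs[[allele]]
      pep <- substring(aseq, windows$start, windows$end)
      inner <- vapply(seq_len(nrow(windows)), function(k) {
        bInner <- setdiff(trypticBoundaries(pep[k], prolineRule),
                          c(0L, nchar(pep[k])))
        length(bInner)
      }, integer(1))
      data.frame(
        snp_id = s$snp_id, gene = s$gene,
        protein_accession = s$protein_accession,
        allele_type = allele, sequence = pep,
        start = windows$start, end = windows$end,
        preceding_residue = ifelse(windows$start == 1L, "-",
                                   substr(aseq, windows$start - 1L,
                                          windows$start - 1L)),
        missed_cleavages = inner,
        semi_specific = windows$semi |
          !(paste(windows$start, windows$end) %in% trypticKey[[allele]]),
        stringsAsFactors = FALSE
      )
    })
    disc <- ilCollapse(perAllele[[1]]$sequence) !=
      ilCollapse(perAllele[[2]]$sequence)
    confMinor <- identical(unname(DEAMIDATION_MAP[s$major_aa]), s$minor_aa)
    confMajor <- identical(unname(DEAMIDATION_MAP[s$minor_aa]), s$major_aa)
    perAllele[[1]]$discriminative <- disc
    perAllele[[2]]$discriminative <- disc
    perAllele[[1]]$modification_confounded <- confMajor
    perAllele[[2]]$modification_confounded <- confMinor
    recs[[i]] <- rbind(perAllele[[1]], perAllele[[2]])
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) {
    records <- data.frame(
      snp_id = character(), gene = character(),
      protein_accession = character(), allele_type = character(),
      sequence = character(), start = integer(), end = integer(),
      preceding_residue = character(), missed_cleavages = integer(),
      semi_specific = logical(), discriminative = logical(),
      modification_confounded = logical(), stringsAsFactors = FALSE
    )
  }
  rownames(records) <- NULL
  ## flag windows that also cover a different catalog SNP on the same protein
  records$shared_window <- vapply(seq_len(nrow(records)), function(k) {
    r <- records[k, ]
    other <- snps[snps$protein_accession == r$protein_accession &
                  snps$snp_id != r$snp_id, , drop = FALSE]
    any(other$residue_position >= r$start & other$residue_position <= r$end)
  }, logical(1))
  new("GVPCatalog", records = records, snps = snps,
      params = list(maxMissed = maxMissed, prolineRule = prolineRule,
                    semiSpecific = semiSpecific, minLength = minLength,
                    maxLength = maxLength))
}

#' Write a GVP catalog to TSV
#'
#' @param catalog a \linkS4class{GVPCatalog}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  writeDelim(gvpRecords(catalog), path)
}
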