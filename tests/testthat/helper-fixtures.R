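# Fixtures and independent oracles used across the suite. Everything is
# built in code; no data files.

## Independent brute-force digestion oracle: enumerate every substring
## window (i, j) whose flanks are cleavage boundaries, counting internal
## cleavage sites as missed cleavages. Kept deliberately naive.
bruteForceDigest <- function(sequence, maxMissed, prolineRule = FALSE) {
  n <- nchar(sequence)
  res <- strsplit(toupper(sequence), "")[[1]]
  isBoundary <- function(i) {           # cut after residue i?
    if (i == 0L || i == n) return(TRUE)
    if (!res[i] %in% c("K", "R")) return(FALSE)
    if (prolineRule && i < n && res[i + 1L] == "P") return(FALSE)
    TRUE
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!isBoundary(i - 1L) || !isBoundary(j)) next
      internal <- if (j - 1L >= i)
        sum(vapply(i:(j - 1L), isBoundary, logical(1))) else 0L
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(res[i:j], collapse = ""),
        start = i, end = j, missed_cleavages = internal,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  d <- d[d$missed_cleavages <= maxMissed, , drop = FALSE]
  d[order(d$start, d$end), ]
}

randomSequence <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                             "H", "I", "K", "L", "M", "N",
                                             "P", "Q", "R", "S", "T", "V",
                                             "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## Scaffold carrying the KRT32-style T/M variant: tryptic digest of the
## major form yields the peptide LEGEINTYR with the variant at its 7th
## residue (protein position 10).
krt32Fixture <- function() {
  protein <- "MARLEGEINTYRAKSEVTLWK"
  snps <- data.frame(
    snp_id = "rs2071563", gene = "KRT32", protein_accession = "P_KRT32",
    residue_position = 10L, major_aa = "T", minor_aa = "M",
    f_major_hom = 0.49, f_het = 0.42, f_minor_hom = 0.09,
    stringsAsFactors = FALSE
  )
  list(proteome = c(P_KRT32 = protein), snps = validateSnpTable(snps))
}

makeManifest <- function(nIndividuals = 3L, locations = c("head", "arm",
                                                          "pubic"),
                         nReplicates = 4L) {
  simulateManifest(simulationConfig(nIndividuals = nIndividuals,
                                    locations = locations,
                                    nReplicates = nReplicates, seed = 1L))
}

makeObservation <- function(sample_id, sequence, modifications = "",
                            accession = "P1", area = 1e6) {
  data.frame(sample_id = sample_id, sequence = sequence,
             modifications = modifications, protein_accessions = accession,
             precursor_area = area, stringsAsFactors = FALSE)
}

## Independent pair enumerator for comparison categories.
bruteForcePairCategories <- function(manifest) {
  n <- nrow(manifest)
  cats <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sameInd <- manifest$individual_id[i] == manifest$individual_id[j]
      sameLoc <- manifest$body_location[i] == manifest$body_location[j]
      cats <- c(cats, if (sameInd && sameLoc) "replicate"
                      else if (sameInd) "within_individual"
                      else "between_individual")
    }
  }
  cats
}

## Hand-applied panel filters on a call table (independent of selectPanel).
bruteForcePanel <- function(calls, snps) {
  ids <- unique(calls$snp_id)
  keep <- character(0)
  for (s in ids) {
    sub <- calls[calls$snp_id == s, ]
    if (any(sub$call == "FP")) next
    majorClean <- all(sub$call[sub$allele_type == "major"] %in% c("TP", "TN"))
    minorClean <- all(sub$call[sub$allele_type == "minor"] %in% c("TP", "TN"))
    if (!majorClean && !minorClean) next
    if (!grepl("^rs", s)) next
    keep <- c(keep, s)
  }
  tab <- snps[snps$snp_id %in% keep, ]
  panel <- character(0)
  for (g in unique(tab$gene)) {
    sub <- tab[tab$gene == g, ]
    sub <- sub[order(sub$maf, sub$snp_id), ]
    panel <- c(panel, sub$snp_id[1L])
  }
  sort(panel)
}

## Build a one-column GVPProfileSet via the public path: detection states
## over a synthetic catalog with chosen frequencies.
profileFromCategories <- function(categories, freqs) {
  n <- length(categories)
  stopifnot(n <= 10L)
  tag <- c("A", "C", "D", "E", "F", "G", "H", "S", "V", "W")[seq_len(n)]
  # one distinct scaffold per locus so peptides never cross-match
  scaffolds <- sprintf("MA%sATAAKGGGR", tag)
  snps <- data.frame(
    snp_id = sprintf("rs%02d", seq_len(n)), gene = sprintf("G%d", seq_len(n)),
    protein_accession = sprintf("P%d", seq_len(n)), residue_position = 5L,
    major_aa = "T", minor_aa = "M",
    f_major_hom = freqs[, 1], f_het = freqs[, 2], f_minor_hom = freqs[, 3],
    stringsAsFactors = FALSE)
  proteome <- stats::setNames(scaffolds, snps$protein_accession)
  cat <- buildCatalog(snps, proteome, maxMissed = 0)
  manifest <- data.frame(sample_id = "S1", individual_id = "I1",
                         body_location = "head", replicate = 1L)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    rows <- NULL
    if (categories[i] %in% c("major_only", "both"))
      rows <- rbind(rows, makeObservation("S1", sprintf("MA%sATAAK", tag[i]),
                                          accession = snps$protein_accession[i]))
    if (categories[i] %in% c("minor_only", "both"))
      rows <- rbind(rows, makeObservation("S1", sprintf("MA%sAMAAK", tag[i]),
                                          accession = snps$protein_accession[i]))
    rows
  }))
  if (is.null(obs))
    obs <- data.frame(sample_id = character(0), sequence = character(0),
                      modifications = character(0),
                      protein_accessions = character(0),
                      precursor_area = numeric(0), stringsAsFactors = FALSE)
  st <- matchObservations(obs, cat, manifest)
  buildProfiles(st, snps$snp_id)
}

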