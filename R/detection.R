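# Matching of per-sample peptide observations to the GVP catalog, and the
# per-sample protein-profile metrics.

#' Match peptide observations to the GVP catalog
#'
#' A GVP counts as detected in a sample when any observed bare peptide
#' sequence (modifications stripped) equals the GVP sequence, comparing
#' after I->L collapse when \code{ilEquiv} is TRUE. Detection is
#' presence/absence only; precursor areas play no role here. Observations
#' that match no catalog record are ordinary peptides and are ignored.
#'
#' With \code{strictConfounded}, a modification-confounded record (one whose
#' peptide can arise from the other allele by deamidation) is only counted
#' when the matching observation carries no deamidation at the variant site.
#'
#' @param observations observation data.frame (see [readPsmTable()]).
#' @param catalog a \linkS4class{GVPCatalog}.
#' @param manifest sample manifest; every manifest sample gets a detection
#'   state even with no observations.
#' @param ilEquiv compare sequences under I/L equivalence (default TRUE).
#' @param strictConfounded guard confounded records against deamidation
#'   mimicry (default FALSE).
#' @return a \linkS4class{DetectionStates} (SNP loci x samples).
#' @export
matchObservations <- function(observations, catalog, manifest,
                              ilEquiv = TRUE, strictConfounded = FALSE) {
  manifest <- validateManifest(manifest, extensible = TRUE)
  rec <- gvpRecords(catalog)
  snps <- catalogSnps(catalog)
  samples <- manifest$sample_id
  snpIds <- snps$snp_id
  maj <- matrix(FALSE, nrow = length(snpIds), ncol = length(samples),
                dimnames = list(snpIds, samples))
  min_ <- maj

  canon <- if (ilEquiv) ilCollapse else identity
  recSeq <- canon(rec$sequence)
  pos <- snps$residue_position[match(rec$snp_id, snps$snp_id)]
  siteInPep <- pos - rec$start + 1L

  obsBySample <- split(seq_len(nrow(observations)), observations$sample_id)
  for (sample in intersect(samples, names(obsBySample))) {
    idx <- obsBySample[[sample]]
    seqObs <- canon(observations$sequence[idx])
    hits <- which(recSeq %in% seqObs)
    for (k in hits) {
      if (strictConfounded && rec$modification_confounded[k]) {
        rows <- idx[seqObs == recSeq[k]]
        clean <- !vapply(observations$modifications[rows], hasDeamidationAt,
                         logical(1), position = siteInPep[k],
                         USE.NAMES = FALSE)
        if (!any(clean)) next
      }
      r <- match(rec$snp_id[k], snpIds)
      if (rec$allele_type[k] == "major") maj[r, sample] <- TRUE
      else min_[r, sample] <- TRUE
    }
  }
  new("DetectionStates", SummarizedExperiment(
    assays = S4Vectors::SimpleList(majorDetected = maj, minorDetected = min_),
    rowData = S4Vectors::DataFrame(snps, row.names = snpIds),
    colData = S4Vectors::DataFrame(manifest, row.names = samples)
  ))
}

#' Per-sample protein-profile metrics
#'
#' Counts, per sample: distinct protein accessions, distinct bare peptide
#' sequences, amino acids (summed length of the distinct peptide
#' sequences), and, when detection states are supplied, the numbers of SNPs
#' inferred from major and from minor GVPs.
#'
#' @param observations observation data.frame.
#' @param states optional \linkS4class{DetectionStates} providing the SNP
#'   counts (otherwise NA).
#' @return data.frame with columns \code{sample_id}, \code{n_proteins},
#'   \code{n_unique_peptides}, \code{n_amino_acids}, \code{n_snps_major},
#'   \code{n_snps_minor}.
#' @export
profileMetrics <- function(observations, states = NULL) {
  samples <- unique(observations$sample_id)
  if (!is.null(states)) samples <- union(samples, colnames(states))
  rows <- lapply(samples, function(sample) {
    o <- observations[observations$sample_id == sample, , drop = FALSE]
    peps <- unique(o$sequence)
    accs <- unique(unlist(strsplit(o$protein_accessions, ";", fixed = TRUE)))
    accs <- accs[nzchar(accs)]
    data.frame(
      sample_id = sample,
      n_proteins = length(accs),
      n_unique_peptides = length(peps),
      n_amino_acids = sum(nchar(peps)),
      n_snps_major = if (is.null(states)) NA_integer_ else
        sum(majorDetected(states)[, sample]),
      n_snps_minor = if (is.null(states)) NA_integer_ else
        sum(minorDetected(states)[, sample]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write detection states to TSV
#'
#' One row per (sample, SNP) with the two detection booleans and the derived
#' phenotype category.
#'
#' @param states a \linkS4class{DetectionStates}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeDetectionStates <- function(states, path) {
  maj <- majorDetected(states)
  df <- data.frame(
    sample_id = rep(colnames(maj), each = nrow(maj)),
    snp_id = rep(rownames(maj), times = ncol(maj)),
    major_detected = as.vector(maj),
    minor_detected = as.vector(minorDetected(states)),
    stringsAsFactors = FALSE
  )
  df$phenotype_category <- phenotypeFromBooleans(df$major_detected,
                                                 df$minor_detected)
  writeDelim(df, path)
}
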