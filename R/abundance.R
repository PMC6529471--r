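# Label-free quantification: precursor-area normalization, protein
# roll-up, differential expression across body locations, and the
# SNP-identification-frequency vs protein-abundance correlation screen.

#' Normalize precursor areas and roll up to protein abundances
#'
#' Duplicate observations of one peptide sequence within a sample are
#' collapsed to a unique peptide (maximum area, accession sets merged).
#' Each unique peptide's area is divided by the sample's total
#' unique-peptide area, removing bias from different on-column mass
#' loadings; protein abundance is the sum of normalized areas of the
#' peptides assigned to it. Peptides mapping to several accessions
#' contribute to each and are flagged shared.
#'
#' @param observations observation data.frame with precursor areas.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{abundance} (proteins x samples); \code{metadata()} carries
#'   \code{sampleTotalArea} (raw totals) and \code{sharedPeptides}.
#'   Samples with zero total area are excluded with a warning.
#' @export
proteinAbundance <- function(observations) {
  ## collapse duplicates to unique peptides per sample
  key <- paste(observations$sample_id, observations$sequence, sep = "\r")
  ord <- order(key, -observations$precursor_area)
  obs <- observations[ord, , drop = FALSE]
  first <- !duplicated(key[ord])
  accBySeq <- tapply(observations$protein_accessions, key,
                     function(a) paste(sort(unique(unlist(
                       strsplit(a, ";", fixed = TRUE)))), collapse = ";"))
  uniq <- obs[first, , drop = FALSE]
  uniq$protein_accessions <- unname(accBySeq[key[ord][first]])

  totals <- tapply(uniq$precursor_area, uniq$sample_id, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    warning(sprintf("excluding sample(s) with zero total area: %s",
                    paste(zero, collapse = ", ")))
    uniq <- uniq[!uniq$sample_id %in% zero, , drop = FALSE]
    totals <- totals[!names(totals) %in% zero]
  }
  uniq$norm_area <- uniq$precursor_area / totals[uniq$sample_id]

  accList <- strsplit(uniq$protein_accessions, ";", fixed = TRUE)
  nAcc <- lengths(accList)
  long <- data.frame(
    sample_id = rep(uniq$sample_id, nAcc),
    accession = unlist(accList),
    norm_area = rep(uniq$norm_area, nAcc),
    stringsAsFactors = FALSE
  )
  samples <- sort(unique(uniq$sample_id))
  proteins <- sort(unique(long$accession))
  mat <- matrix(0, nrow = length(proteins), ncol = length(samples),
                dimnames = list(proteins, samples))
  agg <- tapply(long$norm_area,
                list(long$accession, long$sample_id), sum)
  agg[is.na(agg)] <- 0
  mat[rownames(agg), colnames(agg)] <- agg
  shared <- unique(uniq$sequence[nAcc > 1L])
  SummarizedExperiment(
    assays = S4Vectors::SimpleList(abundance = mat),
    metadata = list(sampleTotalArea = totals, sharedPeptides = shared)
  )
}

## Significance stars matching the conventional thresholds.
starLevel <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "")))
}

#' Per-protein differential expression across body locations
#'
#' For each protein, fits a two-factor analysis of variance of normalized
#' abundance on body location, individual and their interaction, followed
#' by Tukey HSD post-hoc contrasts between locations. Proteins absent from
#' a sample enter with abundance zero, so presence/absence proteins are
#' comparable across locations. Constant-abundance proteins are skipped
#' and noted.
#'
#' @param abundance result of [proteinAbundance()] (or a proteins x samples
#'   matrix).
#' @param manifest sample manifest.
#' @param alpha significance level for flagging.
#' @return data.frame, one row per tested protein, with F statistics and
#'   p-values for the location, individual and interaction terms, the
#'   significant location contrasts with star levels, and a
#'   \code{significant} flag for the location effect. The
#'   \code{"skipped"} attribute lists proteins with constant abundance.
#' @export
differentialExpression <- function(abundance, manifest, alpha = 0.05) {
  mat <- if (is(abundance, "SummarizedExperiment"))
    assay(abundance, "abundance") else abundance
  manifest <- validateManifest(manifest, extensible = TRUE)
  ## zero-fill to the full manifest
  full <- matrix(0, nrow = nrow(mat), ncol = nrow(manifest),
                 dimnames = list(rownames(mat), manifest$sample_id))
  common <- intersect(colnames(mat), manifest$sample_id)
  full[, common] <- mat[, common]
  loc <- factor(manifest$body_location)
  ind <- factor(manifest$individual_id)
  skipped <- character(0)
  rows <- lapply(rownames(full), function(p) {
    y <- full[p, ]
    if (stats::sd(y) == 0) {
      skipped <<- c(skipped, p)
      return(NULL)
    }
    fit <- stats::aov(y ~ loc * ind)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    getF <- function(t) tab[match(t, terms), "F value"]
    getP <- function(t) tab[match(t, terms), "Pr(>F)"]
    tk <- tryCatch(stats::TukeyHSD(fit, "loc")$loc, error = function(e) NULL)
    contrasts <- if (is.null(tk)) "" else {
      sig <- tk[, "p adj"] <= alpha
      paste(sprintf("%s%s", rownames(tk)[sig],
                    starLevel(tk[sig, "p adj"])), collapse = ";")
    }
    data.frame(
      accession = p,
      f_location = getF("loc"), p_location = getP("loc"),
      f_individual = getF("ind"), p_individual = getP("ind"),
      f_interaction = getF("loc:ind"), p_interaction = getP("loc:ind"),
      significant = getP("loc") <= alpha,
      significant_contrasts = contrasts,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(), f_location = numeric(),
                      p_location = numeric(), f_individual = numeric(),
                      p_individual = numeric(), f_interaction = numeric(),
                      p_interaction = numeric(), significant = logical(),
                      significant_contrasts = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' SNP identification frequency vs protein abundance
#'
#' For each SNP, computes per (individual, body location) group the
#' fraction of replicates in which the SNP was detected (either GVP form)
#' and the group's mean abundance of the SNP's protein, then tests for a
#' positive product-moment correlation (one-sided). Groups in which the
#' individual does not carry the SNP can be excluded upstream by
#' restricting the detection states. Zero-variance inputs yield an
#' undefined correlation, reported as such.
#'
#' @param states a \linkS4class{DetectionStates} whose \code{rowData}
#'   carries \code{protein_accession}.
#' @param abundance result of [proteinAbundance()].
#' @return data.frame with one row per SNP: \code{snp_id},
#'   \code{n_groups}, \code{r}, \code{p_value}, \code{note}.
#' @export
snpAbundanceCorrelation <- function(states, abundance) {
  mat <- assay(abundance, "abundance")
  manifest <- as.data.frame(colData(states))
  detected <- majorDetected(states) | minorDetected(states)
  rd <- as.data.frame(rowData(states))
  group <- paste(manifest$individual_id, manifest$body_location, sep = "\r")
  rows <- lapply(seq_len(nrow(states)), function(i) {
    acc <- rd$protein_accession[i]
    freq <- tapply(detected[i, manifest$sample_id], group, mean)
    ab <- if (acc %in% rownames(mat)) {
      abVals <- stats::setNames(rep(0, nrow(manifest)), manifest$sample_id)
      common <- intersect(colnames(mat), manifest$sample_id)
      abVals[common] <- mat[acc, common]
      tapply(abVals[manifest$sample_id], group, mean)
    } else stats::setNames(rep(0, length(freq)), names(freq))
    base <- data.frame(snp_id = rd$snp_id[i], n_groups = length(freq),
                       stringsAsFactors = FALSE)
    if (length(freq) < 3L) {
      base$r <- NA_real_; base$p_value <- NA_real_
      base$note <- "fewer than 3 groups"
    } else if (stats::sd(freq) == 0 || stats::sd(ab) == 0) {
      base$r <- NA_real_; base$p_value <- NA_real_
      base$note <- "zero variance: correlation undefined"
    } else {
      ct <- stats::cor.test(ab, freq, alternative = "greater",
                            method = "pearson")
      base$r <- unname(ct$estimate); base$p_value <- ct$p.value
      base$note <- ""
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an abundance matrix to TSV
#'
#' @param abundance result of [proteinAbundance()].
#' @param path output TSV path (proteins x samples).
#' @return the path, invisibly.
#' @export
writeAbundance <- function(abundance, path) {
  mat <- assay(abundance, "abundance")
  df <- data.frame(accession = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeDelim(df, path)
}
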