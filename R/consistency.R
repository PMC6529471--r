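# Exome-proteome consistency classification and panel selection.

#' Classify detection states against exome genotypes
#'
#' Produces one call per (sample, SNP, allele type). An allele is present in
#' a genotype unless the individual is homozygous for the other allele
#' (major present unless minor_hom; minor present unless major_hom). The
#' call is TP when a present allele's GVP was detected, FN when it was not,
#' FP when an absent allele's GVP was detected, TN otherwise.
#'
#' @param states a \linkS4class{DetectionStates}.
#' @param genotypes long genotype table (see [readGenotypes()]); every
#'   (individual, SNP) pair under analysis must be present.
#' @return data.frame with columns \code{sample_id}, \code{individual_id},
#'   \code{body_location}, \code{snp_id}, \code{allele_type}, \code{call}.
#' @export
classifyCalls <- function(states, genotypes) {
  manifest <- as.data.frame(colData(states))
  maj <- majorDetected(states)
  min_ <- minorDetected(states)
  grid <- expand.grid(snp_id = rownames(maj), sample_id = colnames(maj),
                      stringsAsFactors = FALSE)
  mi <- match(grid$sample_id, manifest$sample_id)
  grid$individual_id <- manifest$individual_id[mi]
  grid$body_location <- manifest$body_location[mi]
  grid$genotype <- genotypeLookup(genotypes, grid$individual_id, grid$snp_id)
  detected <- cbind(major = as.vector(maj), minor = as.vector(min_))
  out <- lapply(c("major", "minor"), function(allele) {
    present <- if (allele == "major") grid$genotype != "minor_hom"
               else grid$genotype != "major_hom"
    det <- detected[, allele]
    data.frame(
      sample_id = grid$sample_id,
      individual_id = grid$individual_id,
      body_location = grid$body_location,
      snp_id = grid$snp_id,
      allele_type = allele,
      call = ifelse(present,
                    ifelse(det, "TP", "FN"),
                    ifelse(det, "FP", "TN")),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exome-proteome consistent SNPs
#'
#' A SNP is consistent for an allele type within a scope when every call in
#' scope is a true positive or true negative.
#'
#' @param calls classification calls from [classifyCalls()].
#' @param scope \code{"per_location"} (one set per body location per allele
#'   type) or \code{"all_samples"} (consistency across every sample).
#' @return for \code{"all_samples"}, a list with elements \code{major} and
#'   \code{minor}, each a character vector of SNP ids; for
#'   \code{"per_location"}, the same structure nested inside a per-location
#'   list.
#' @export
consistentSnps <- function(calls, scope = c("all_samples", "per_location")) {
  scope <- match.arg(scope)
  consistentIn <- function(df) {
    lapply(stats::setNames(c("major", "minor"), c("major", "minor")),
           function(allele) {
      sub <- df[df$allele_type == allele, , drop = FALSE]
      ok <- tapply(sub$call %in% c("TP", "TN"), sub$snp_id, all)
      sort(names(ok)[ok])
    })
  }
  if (scope == "all_samples") return(consistentIn(calls))
  lapply(split(calls, calls$body_location), consistentIn)
}

#' Select a robust SNP panel
#'
#' Applies the panel-selection criteria in order: (1) remove every SNP with
#' at least one false-positive call for either allele anywhere; (2) keep
#' SNPs whose calls are all TP/TN across all samples for the major or the
#' minor allele type; (3) merge the two allele-type lists into one locus
#' list; (4) drop SNPs without a Reference SNP ID (\code{"rs..."}), whose
#' population genotype frequencies are unknown; (5) within each gene keep
#' the SNP with the lowest minor allele frequency (ties broken by
#' lexicographically smallest snp_id), a conservative guard against linkage
#' disequilibrium between markers in one gene.
#'
#' @param calls classification calls from [classifyCalls()].
#' @param snps validated SNP table covering the SNPs in \code{calls}.
#' @param perLocation when TRUE (default), the per-location consistent SNP
#'   sets are recorded in the report.
#' @return a \linkS4class{PanelReport}.
#' @export
selectPanel <- function(calls, snps, perLocation = TRUE) {
  snps <- validateSnpTable(as.data.frame(snps))
  snpIds <- sort(unique(calls$snp_id))
  stageRemoved <- stats::setNames(rep(NA_character_, length(snpIds)), snpIds)
  reason <- stats::setNames(rep(NA_character_, length(snpIds)), snpIds)

  ## (1) false-positive removal
  fpSnps <- sort(unique(calls$snp_id[calls$call == "FP"]))
  stageRemoved[fpSnps] <- "fp_removal"
  reason[fpSnps] <- "false positive call observed"
  afterFp <- setdiff(snpIds, fpSnps)

  ## (2) all-sample consistency for either allele type
  cons <- consistentSnps(calls[calls$snp_id %in% afterFp, , drop = FALSE],
                         scope = "all_samples")
  afterConsistency <- sort(union(cons$major, cons$minor))
  dropped <- setdiff(afterFp, afterConsistency)
  stageRemoved[dropped] <- "all_sample_consistency"
  reason[dropped] <- "false negative call in some sample for both allele types"

  ## (3) overlap merge already realized by the union above

  ## (4) rsID requirement
  hasRsid <- grepl("^rs", afterConsistency)
  dropped <- afterConsistency[!hasRsid]
  stageRemoved[dropped] <- "rsid"
  reason[dropped] <- "no Reference SNP ID (HGVS notation)"
  afterRsid <- afterConsistency[hasRsid]

  ## (5) one SNP per gene, lowest MAF, ties lexicographic
  cand <- snps[match(afterRsid, snps$snp_id), , drop = FALSE]
  panel <- character(0)
  for (g in sort(unique(cand$gene))) {
    sub <- cand[cand$gene == g, , drop = FALSE]
    sub <- sub[order(sub$maf, sub$snp_id), , drop = FALSE]
    panel <- c(panel, sub$snp_id[1L])
    if (nrow(sub) > 1L) {
      losers <- sub$snp_id[-1L]
      stageRemoved[losers] <- "one_per_gene"
      reason[losers] <- sprintf("higher MAF than %s in gene %s",
                                sub$snp_id[1L], g)
    }
  }
  panel <- sort(panel)
  stageRemoved[panel] <- "panel"
  reason[panel] <- "selected"

  counts <- c(
    input = length(snpIds),
    after_fp_removal = length(afterFp),
    after_consistency = length(afterConsistency),
    after_rsid = length(afterRsid),
    panel = length(panel)
  )
  byLocation <- if (perLocation && "body_location" %in% names(calls)) {
    consistentSnps(calls[calls$snp_id %in% afterFp, , drop = FALSE],
                   scope = "per_location")
  } else list()
  new("PanelReport",
      panel = panel,
      counts = as.integer(counts) |> stats::setNames(names(counts)),
      provenance = data.frame(snp_id = snpIds,
                              stage = unname(stageRemoved[snpIds]),
                              reason = unname(reason[snpIds]),
                              stringsAsFactors = FALSE),
      consistentByLocation = byLocation)
}

#' Write a panel report
#'
#' @param report a \linkS4class{PanelReport}.
#' @param tsvPath path for the per-SNP provenance TSV.
#' @param jsonPath optional path for a JSON provenance log (counts, panel,
#'   per-location consistent sets).
#' @return \code{tsvPath}, invisibly.
#' @importFrom jsonlite write_json
#' @export
writePanelReport <- function(report, tsvPath, jsonPath = NULL) {
  writeDelim(panelProvenance(report), tsvPath)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(counts = as.list(panelCounts(report)),
           panel = panelSnps(report),
           consistent_by_location = report@consistentByLocation),
      jsonPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsvPath)
}
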