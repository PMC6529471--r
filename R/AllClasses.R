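#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' GVPCatalog: major/minor genetically variant peptide catalog
#'
#' Container for the catalog of genetically variant peptides (GVPs) derived
#' from a missense SNP table and a reference proteome. Each catalog record is
#' one peptide window covering a variant site, for one allele (major or
#' minor). Major and minor records for a SNP share window coordinates and
#' differ only at the variant residue.
#'
#' @slot records data.frame of GVP records (one row per SNP x allele x
#'   peptide window) with columns \code{snp_id}, \code{gene},
#'   \code{allele_type}, \code{sequence}, \code{start}, \code{end},
#'   \code{preceding_residue}, \code{missed_cleavages}, \code{semi_specific},
#'   \code{discriminative}, \code{modification_confounded},
#'   \code{shared_window}.
#' @slot snps data.frame of the missense SNP loci the catalog was built from.
#' @slot params list of digestion parameters used to build the catalog.
#'
#' @seealso [buildCatalog()], [gvpRecords()], [catalogSnps()]
#' @export
setClass("GVPCatalog",
         slots = c(records = "data.frame",
                   snps = "data.frame",
                   params = "list"))

setValidity("GVPCatalog", function(object) {
  rec <- object@records
  needed <- c("snp_id", "gene", "allele_type", "sequence", "start", "end",
              "preceding_residue", "missed_cleavages", "semi_specific",
              "discriminative", "modification_confounded", "shared_window")
  miss <- setdiff(needed, names(rec))
  if (length(miss))
    return(sprintf("records is missing columns: %s",
                   paste(miss, collapse = ", ")))
  if (nrow(rec) && !all(rec$allele_type %in% c("major", "minor")))
    return("allele_type must be 'major' or 'minor'")
  if (nrow(rec) && !all(rec$snp_id %in% object@snps$snp_id))
    return("records reference SNPs absent from the snps slot")
  TRUE
})

#' DetectionStates: per-sample SNP detection matrix
#'
#' A \linkS4class{SummarizedExperiment} whose rows are SNP loci and whose
#' columns are samples, with two logical assays \code{majorDetected} and
#' \code{minorDetected} recording whether the major / minor GVP of each SNP
#' was observed in each sample. \code{rowData} carries the SNP annotation
#' (gene, alleles, genotype frequencies) and \code{colData} the sample
#' manifest.
#'
#' @seealso [matchObservations()], [majorDetected()], [phenotypeCategories()]
#' @export
setClass("DetectionStates", contains = "SummarizedExperiment")

setValidity("DetectionStates", function(object) {
  an <- assayNames(object)
  if (!all(c("majorDetected", "minorDetected") %in% an))
    return("assays 'majorDetected' and 'minorDetected' are required")
  if (!is.logical(assay(object, "majorDetected")) ||
      !is.logical(assay(object, "minorDetected")))
    return("detection assays must be logical matrices")
  TRUE
})

#' GVPProfileSet: phenotype categories and observed phenotype frequencies
#'
#' A \linkS4class{SummarizedExperiment} whose rows are panel SNP loci and
#' whose columns are samples (or individuals, for expected profiles). The
#' \code{category} assay holds the detected phenotype category at each locus
#' (\code{both}, \code{major_only}, \code{minor_only}, \code{absent}) and the
#' \code{frequency} assay the corresponding observed phenotype frequency
#' (\code{NA} where the locus is absent).
#'
#' @seealso [buildProfiles()], [expectedProfiles()], [sampleRMP()]
#' @export
setClass("GVPProfileSet", contains = "SummarizedExperiment")

setValidity("GVPProfileSet", function(object) {
  an <- assayNames(object)
  if (!all(c("category", "frequency") %in% an))
    return("assays 'category' and 'frequency' are required")
  cat <- assay(object, "category")
  if (!all(cat %in% PHENOTYPE_CATEGORIES))
    return("category assay contains values outside the phenotype categories")
  freq <- assay(object, "frequency")
  absent <- cat == "absent"
  if (any(!is.na(freq[absent])))
    return("absent loci must have NA frequency")
  present <- !absent & !is.na(freq)
  if (any(freq[present] <= 0 | freq[present] > 1))
    return("frequencies must lie in (0, 1]")
  TRUE
})

#' PanelReport: provenance-tracked SNP panel selection
#'
#' Result of applying the panel-selection criteria to exome-proteome
#' consistency calls: false-positive removal, all-sample consistency for
#' either allele type, merging of major/minor overlap, requirement of a
#' Reference SNP ID, and one SNP per gene (lowest minor allele frequency).
#'
#' @slot panel character vector of selected SNP ids.
#' @slot counts named integer vector of SNP counts after each filter.
#' @slot provenance data.frame recording, per input SNP, the filter at which
#'   it was removed (or \code{"panel"}) and the reason.
#' @slot consistentByLocation list of per-location consistent SNP sets per
#'   allele type (empty when no manifest was supplied).
#'
#' @seealso [selectPanel()]
#' @export
setClass("PanelReport",
         slots = c(panel = "character",
                   counts = "integer",
                   provenance = "data.frame",
                   consistentByLocation = "list"))

setValidity("PanelReport", function(object) {
  if (!all(object@panel %in% object@provenance$snp_id))
    return("panel contains SNPs without provenance records")
  TRUE
})
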