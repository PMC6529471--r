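# Accessors and show methods for the package's S4 containers.

#' @rdname GVPCatalog-class
#' @export
setMethod("gvpRecords", "GVPCatalog", function(x) x@records)

#' @rdname GVPCatalog-class
#' @export
setMethod("catalogSnps", "GVPCatalog", function(x) x@snps)

setMethod("show", "GVPCatalog", function(object) {
  rec <- object@records
  cat(sprintf("GVPCatalog with %d GVP records over %d SNP loci (%d genes)\n",
              nrow(rec), nrow(object@snps),
              length(unique(object@snps$gene))))
  if (nrow(rec)) {
    cat(sprintf("  major records: %d  minor records: %d\n",
                sum(rec$allele_type == "major"),
                sum(rec$allele_type == "minor")))
    cat(sprintf("  non-discriminative: %d  modification-confounded: %d  shared-window: %d\n",
                sum(!rec$discriminative), sum(rec$modification_confounded),
                sum(rec$shared_window)))
  }
  p <- object@params
  if (length(p))
    cat(sprintf("  digestion: max %d missed cleavages, proline rule %s, semi-specific %s\n",
                p$maxMissed, ifelse(isTRUE(p$prolineRule), "on", "off"),
                ifelse(isTRUE(p$semiSpecific), "on", "off")))
  invisible(NULL)
})

#' @rdname DetectionStates-class
#' @export
setMethod("majorDetected", "DetectionStates",
          function(x) assay(x, "majorDetected"))

#' @rdname DetectionStates-class
#' @export
setMethod("minorDetected", "DetectionStates",
          function(x) assay(x, "minorDetected"))

#' @rdname DetectionStates-class
#' @export
setMethod("phenotypeCategories", "DetectionStates", function(x) {
  maj <- assay(x, "majorDetected")
  min_ <- assay(x, "minorDetected")
  out <- matrix(phenotypeFromBooleans(maj, min_),
                nrow = nrow(maj), dimnames = dimnames(maj))
  out
})

setMethod("show", "DetectionStates", function(object) {
  cat(sprintf("DetectionStates: %d SNP loci x %d samples\n",
              nrow(object), ncol(object)))
  cats <- table(factor(phenotypeCategories(object),
                       levels = PHENOTYPE_CATEGORIES))
  cat("  phenotype categories:",
      paste(sprintf("%s=%d", names(cats), cats), collapse = "  "), "\n")
  invisible(NULL)
})

#' @rdname GVPProfileSet-class
#' @export
setMethod("phenotypeCategories", "GVPProfileSet",
          function(x) assay(x, "category"))

#' @rdname GVPProfileSet-class
#' @export
setMethod("profileFrequencies", "GVPProfileSet",
          function(x) assay(x, "frequency"))

setMethod("show", "GVPProfileSet", function(object) {
  cat(sprintf("GVPProfileSet: %d panel loci x %d profiles\n",
              nrow(object), ncol(object)))
  nonAbsent <- colSums(assay(object, "category") != "absent")
  cat(sprintf("  non-absent loci per profile: %s (median %s)\n",
              paste(range(nonAbsent), collapse = "-"),
              stats::median(nonAbsent)))
  invisible(NULL)
})

#' @rdname PanelReport-class
#' @export
setMethod("panelSnps", "PanelReport", function(x) x@panel)

#' @rdname PanelReport-class
#' @export
setMethod("panelCounts", "PanelReport", function(x) x@counts)

#' @rdname PanelReport-class
#' @export
setMethod("panelProvenance", "PanelReport", function(x) x@provenance)

setMethod("show", "PanelReport", function(object) {
  cat("PanelReport\n")
  cn <- names(object@counts)
  for (i in seq_along(object@counts))
    cat(sprintf("  %-22s %d\n", cn[i], object@counts[i]))
  cat("  panel:", paste(object@panel, collapse = ", "), "\n")
  invisible(NULL)
})
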