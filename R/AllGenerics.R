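#' @rdname GVPCatalog-class
#' @param x a \linkS4class{GVPCatalog}.
#' @export
setGeneric("gvpRecords", function(x) standardGeneric("gvpRecords"))

#' @rdname GVPCatalog-class
#' @export
setGeneric("catalogSnps", function(x) standardGeneric("catalogSnps"))

#' @rdname DetectionStates-class
#' @param x a \linkS4class{DetectionStates}.
#' @export
setGeneric("majorDetected", function(x) standardGeneric("majorDetected"))

#' @rdname DetectionStates-class
#' @export
setGeneric("minorDetected", function(x) standardGeneric("minorDetected"))

#' @rdname DetectionStates-class
#' @export
setGeneric("phenotypeCategories",
           function(x) standardGeneric("phenotypeCategories"))

#' @rdname GVPProfileSet-class
#' @param x a \linkS4class{GVPProfileSet}.
#' @export
setGeneric("profileFrequencies",
           function(x) standardGeneric("profileFrequencies"))

#' @rdname PanelReport-class
#' @param x a \linkS4class{PanelReport}.
#' @export
setGeneric("panelSnps", function(x) standardGeneric("panelSnps"))

#' @rdname PanelReport-class
#' @export
setGeneric("panelCounts", function(x) standardGeneric("panelCounts"))

#' @rdname PanelReport-class
#' @export
setGeneric("panelProvenance", function(x) standardGeneric("panelProvenance"))
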