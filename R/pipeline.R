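# End-to-end orchestration: simulate or load inputs, build the catalog,
# match observations, classify against genotypes, select the panel, build
# and compare profiles, compute RMPs and abundances, and write every
# intermediate table.

#' Run the full GVP analysis pipeline
#'
#' Chains every stage on either a simulated study (when \code{study} is a
#' [simulationConfig()] or the result of [simulateStudy()]) or on tables
#' read from disk via the \code{paths} argument (named list with elements
#' \code{proteome}, \code{snps}, \code{manifest}, \code{genotypes},
#' \code{psms}). When \code{outDir} is given, all intermediate artifacts
#' are written as TSV plus a provenance JSON recording the run
#' configuration and seed.
#'
#' @param study a \code{SimulationConfig}, a [simulateStudy()] result, or
#'   NULL when \code{paths} is used.
#' @param paths named list of input file paths (alternative to
#'   \code{study}).
#' @param outDir optional output directory.
#' @param ilEquiv,strictConfounded matching flags (see
#'   [matchObservations()]).
#' @param maxMissed,prolineRule,semiSpecific,minLength,maxLength catalog
#'   parameters, used when the catalog is not already built.
#' @return list with \code{catalog}, \code{states}, \code{metrics},
#'   \code{calls}, \code{panel} (a \linkS4class{PanelReport}),
#'   \code{profiles}, \code{expected}, \code{rmp}, \code{expectedRmp},
#'   \code{comparisons}, \code{categoryTest}, \code{abundance},
#'   \code{differentialExpression}.
#' @export
runPipeline <- function(study = NULL, paths = NULL, outDir = NULL,
                        ilEquiv = TRUE, strictConfounded = FALSE,
                        maxMissed = 3L, prolineRule = FALSE,
                        semiSpecific = FALSE, minLength = 5L,
                        maxLength = 50L) {
  if (inherits(study, "SimulationConfig")) study <- simulateStudy(study)
  if (is.null(study)) {
    if (is.null(paths))
      stop("either a study/config or input paths are required", call. = FALSE)
    proteome <- readProteinFasta(paths$proteome)
    snps <- readSnpTable(paths$snps)
    study <- list(
      proteome = proteome, snps = snps,
      manifest = readManifest(paths$manifest),
      genotypes = readGenotypes(paths$genotypes),
      observations = readPsmTable(paths$psms),
      catalog = buildCatalog(snps, proteome, maxMissed = maxMissed,
                             prolineRule = prolineRule,
                             semiSpecific = semiSpecific,
                             minLength = minLength, maxLength = maxLength)
    )
  }
  catalog <- study$catalog
  states <- matchObservations(study$observations, catalog, study$manifest,
                              ilEquiv = ilEquiv,
                              strictConfounded = strictConfounded)
  metrics <- profileMetrics(study$observations, states)
  calls <- classifyCalls(states, study$genotypes)
  panel <- selectPanel(calls, study$snps)
  profiles <- buildProfiles(states, panel)
  expected <- expectedProfiles(study$genotypes, study$snps, panel,
                               manifest = study$manifest)
  rmp <- sampleRMP(profiles)
  expectedRmp <- sampleRMP(expected)
  comparisons <- pairwiseCompare(profiles)
  categoryTest <- tryCatch(compareCategoryTest(comparisons$comparisons),
                           error = function(e) NULL)
  abundance <- proteinAbundance(study$observations)
  de <- differentialExpression(abundance, study$manifest)
  result <- list(catalog = catalog, states = states, metrics = metrics,
                 calls = calls, panel = panel, profiles = profiles,
                 expected = expected, rmp = rmp, expectedRmp = expectedRmp,
                 comparisons = comparisons, categoryTest = categoryTest,
                 abundance = abundance, differentialExpression = de)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCatalog(catalog, file.path(outDir, "catalog.tsv"))
    writeDetectionStates(states, file.path(outDir, "detection_states.tsv"))
    writeDelim(metrics, file.path(outDir, "profile_metrics.tsv"))
    writeDelim(calls, file.path(outDir, "consistency_calls.tsv"))
    writePanelReport(panel, file.path(outDir, "panel.tsv"),
                     file.path(outDir, "panel.json"))
    writeProfiles(profiles, file.path(outDir, "profiles.tsv"))
    writeDelim(rmp, file.path(outDir, "rmp.tsv"))
    writeComparisons(comparisons, file.path(outDir, "comparisons.tsv"))
    writeDelim(comparisons$summary, file.path(outDir,
                                              "comparison_summary.tsv"))
    writeAbundance(abundance, file.path(outDir, "abundance.tsv"))
    writeDelim(de, file.path(outDir, "differential_expression.tsv"))
    prov <- list(
      package = "GVPprofiler",
      version = as.character(utils::packageVersion("GVPprofiler")),
      seed = if (!is.null(study$config)) study$config$seed else NA,
      parameters = list(ilEquiv = ilEquiv,
                        strictConfounded = strictConfounded,
                        maxMissed = maxMissed, prolineRule = prolineRule,
                        semiSpecific = semiSpecific)
    )
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
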