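# GVP profiles: observed phenotype frequencies, random match
# probabilities, pairwise profile differences, and the rank-based
# comparison-category test.

#' Observed phenotype frequency for a detected category
#'
#' When only one GVP form is detected at a locus, the genotype cannot be
#' resolved beyond "carries that allele", so the observed phenotype
#' frequency is the sum of the matching homozygote frequency and the
#' heterozygote frequency. Detection of both forms is consistent only with
#' the heterozygote. Absent loci carry no frequency and are skipped in RMP
#' computation.
#'
#' @param category phenotype category vector (\code{both},
#'   \code{major_only}, \code{minor_only}, \code{absent}).
#' @param freqs genotype-frequency triple \code{c(f_major_hom, f_het,
#'   f_minor_hom)}, or a matrix with those columns (one row per category
#'   element).
#' @return numeric vector of observed phenotype frequencies (\code{NA} for
#'   absent).
#' @examples
#' phenotypeFrequency("minor_only", c(0.49, 0.42, 0.09))  # 0.51
#' @export
phenotypeFrequency <- function(category, freqs) {
  if (is.null(dim(freqs))) {
    stopifnot(length(freqs) == 3L)
    freqs <- matrix(freqs, nrow = length(category), ncol = 3L, byrow = TRUE)
  }
  stopifnot(all(category %in% PHENOTYPE_CATEGORIES))
  out <- rep(NA_real_, length(category))
  out[category == "major_only"] <-
    freqs[category == "major_only", 1L] + freqs[category == "major_only", 2L]
  out[category == "minor_only"] <-
    freqs[category == "minor_only", 3L] + freqs[category == "minor_only", 2L]
  out[category == "both"] <- freqs[category == "both", 2L]
  out
}

## Assemble a GVPProfileSet from a category matrix (loci x profiles) and a
## panel SNP table supplying the genotype frequencies.
makeProfileSet <- function(categories, panelSnps, colInfo) {
  freqCols <- as.matrix(panelSnps[c("f_major_hom", "f_het", "f_minor_hom")])
  freq <- matrix(NA_real_, nrow = nrow(categories), ncol = ncol(categories),
                 dimnames = dimnames(categories))
  for (j in seq_len(ncol(categories)))
    freq[, j] <- phenotypeFrequency(categories[, j], freqCols)
  new("GVPProfileSet", SummarizedExperiment(
    assays = S4Vectors::SimpleList(category = categories, frequency = freq),
    rowData = S4Vectors::DataFrame(panelSnps, row.names = panelSnps$snp_id),
    colData = S4Vectors::DataFrame(colInfo, row.names = colnames(categories))
  ))
}

#' Build observed GVP profiles over a panel
#'
#' Restricts detection states to the panel loci and derives, per sample,
#' the phenotype category and observed phenotype frequency at each locus.
#'
#' @param states a \linkS4class{DetectionStates}.
#' @param panel character vector of panel SNP ids, or a
#'   \linkS4class{PanelReport}.
#' @return a \linkS4class{GVPProfileSet} (panel loci x samples).
#' @export
buildProfiles <- function(states, panel) {
  if (is(panel, "PanelReport")) panel <- panelSnps(panel)
  missing <- setdiff(panel, rownames(states))
  if (length(missing))
    stop(sprintf("panel SNP(s) absent from detection states: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sub <- states[panel, ]
  categories <- phenotypeCategories(sub)
  makeProfileSet(categories, as.data.frame(rowData(sub)),
                 as.data.frame(colData(sub)))
}

#' Expected GVP profiles from genotypes
#'
#' The theoretical profile of an individual assumes every GVP consistent
#' with the genotype is detected: major homozygotes show only the major
#' form, heterozygotes both, minor homozygotes only the minor form.
#'
#' @param genotypes long genotype table.
#' @param snps validated SNP table covering the panel.
#' @param panel character vector of panel SNP ids (or a
#'   \linkS4class{PanelReport}).
#' @param manifest optional manifest; when given, one expected profile per
#'   sample (that of its individual), otherwise one per individual.
#' @return a \linkS4class{GVPProfileSet}.
#' @export
expectedProfiles <- function(genotypes, snps, panel, manifest = NULL) {
  if (is(panel, "PanelReport")) panel <- panelSnps(panel)
  snps <- validateSnpTable(as.data.frame(snps))
  panelTab <- snps[match(panel, snps$snp_id), , drop = FALSE]
  if (anyNA(panelTab$snp_id))
    stop("panel SNP(s) absent from the SNP table", call. = FALSE)
  if (is.null(manifest)) {
    cols <- sort(unique(genotypes$individual_id))
    individuals <- cols
    colInfo <- data.frame(individual_id = individuals, row.names = cols)
  } else {
    manifest <- validateManifest(manifest, extensible = TRUE)
    cols <- manifest$sample_id
    individuals <- manifest$individual_id
    colInfo <- manifest
  }
  catMap <- c(major_hom = "major_only", het = "both", minor_hom = "minor_only")
  categories <- matrix(NA_character_, nrow = length(panel),
                       ncol = length(cols), dimnames = list(panel, cols))
  for (j in seq_along(cols)) {
    g <- genotypeLookup(genotypes, rep(individuals[j], length(panel)), panel)
    categories[, j] <- unname(catMap[g])
  }
  makeProfileSet(categories, panelTab, colInfo)
}

#' Random match probability of GVP profiles
#'
#' The RMP of a profile is the product of the observed phenotype
#' frequencies over its non-absent loci: the probability that a random
#' member of the population shows a GVP pattern consistent with the
#' profile. Absent loci are skipped. A profile with no non-absent locus has
#' no defined RMP and is reported as \code{NA} with a warning.
#'
#' @param profiles a \linkS4class{GVPProfileSet}.
#' @return data.frame with columns \code{sample_id}, \code{rmp} and
#'   \code{one_in} (\code{round(1 / rmp)}), one row per profile.
#' @export
sampleRMP <- function(profiles) {
  freq <- profileFrequencies(profiles)
  rmp <- apply(freq, 2L, function(f) {
    f <- f[!is.na(f)]
    if (!length(f)) NA_real_ else prod(f)
  })
  if (anyNA(rmp))
    warning(sprintf("%d profile(s) with all loci absent: RMP undefined",
                    sum(is.na(rmp))))
  data.frame(sample_id = colnames(freq), rmp = unname(rmp),
             one_in = round(1 / unname(rmp)), stringsAsFactors = FALSE)
}

#' Number of differing loci between two profiles
#'
#' Counts panel loci at which the phenotype categories of two profiles do
#' not match exactly; absent versus non-absent counts as a difference even
#' though absent loci are skipped in RMP computation.
#'
#' @param a,b category vectors named by SNP id (or single-column
#'   \linkS4class{GVPProfileSet}s).
#' @return integer count of differing loci.
#' @export
profileDifference <- function(a, b) {
  asVec <- function(x) {
    if (is(x, "GVPProfileSet")) {
      stopifnot(ncol(x) == 1L)
      stats::setNames(assay(x, "category")[, 1L], rownames(x))
    } else x
  }
  a <- asVec(a); b <- asVec(b)
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)) || length(a) != length(b))
    stop("profiles are over different panels", call. = FALSE)
  sum(a != b[names(a)])
}

## Comparison category of a sample pair given manifest rows.
comparisonCategory <- function(indA, locA, indB, locB) {
  ifelse(indA == indB,
         ifelse(locA == locB, "replicate", "within_individual"),
         "between_individual")
}

#' Pairwise GVP profile comparisons
#'
#' Enumerates every unordered pair of profiles once, counts profile
#' differences, and assigns each pair a comparison category: replicate
#' (same individual, same body location), within-individual (same
#' individual, different location) or between-individual. Summaries
#' (n, mean, s.d. of differences) are reported per category and, for
#' between-individual pairs, per individual pair.
#'
#' @param profiles a \linkS4class{GVPProfileSet} whose \code{colData}
#'   carries \code{individual_id} and \code{body_location}.
#' @return list with \code{comparisons} (one row per pair) and
#'   \code{summary} (per-group n, mean, sd).
#' @export
pairwiseCompare <- function(profiles) {
  if (ncol(profiles) < 2L) stop("need at least two profiles", call. = FALSE)
  cd <- as.data.frame(colData(profiles))
  categories <- assay(profiles, "category")
  n <- ncol(categories)
  pairs <- utils::combn(n, 2L)
  ia <- pairs[1L, ]; ib <- pairs[2L, ]
  nDiff <- vapply(seq_len(ncol(pairs)), function(k) {
    sum(categories[, ia[k]] != categories[, ib[k]])
  }, integer(1))
  cmp <- data.frame(
    sample_a = colnames(categories)[ia],
    sample_b = colnames(categories)[ib],
    individual_a = cd$individual_id[ia],
    individual_b = cd$individual_id[ib],
    category = comparisonCategory(cd$individual_id[ia], cd$body_location[ia],
                                  cd$individual_id[ib], cd$body_location[ib]),
    n_differences = nDiff,
    stringsAsFactors = FALSE
  )
  cmp$group <- ifelse(
    cmp$category == "between_individual",
    paste0("between:", pmin(cmp$individual_a, cmp$individual_b), "-",
           pmax(cmp$individual_a, cmp$individual_b)),
    cmp$category
  )
  summ <- do.call(rbind, lapply(split(cmp, cmp$group), function(g) {
    data.frame(group = g$group[1L], category = g$category[1L],
               n = nrow(g), mean = mean(g$n_differences),
               sd = stats::sd(g$n_differences), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(comparisons = cmp, summary = summ)
}

## Dunn (1964) rank-based post-hoc z tests with tie correction; p-values
## Bonferroni-adjusted over the pairs tested.
dunnPosthoc <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(length(lev), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    sigma <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[i] + 1 / ns[j]))
    ## fully tied data: no rank variance, no separation
    z <- if (sigma == 0) 0 else (rbar[i] - rbar[j]) / sigma
    data.frame(group1 = lev[i], group2 = lev[j], z = unname(z),
               p_value = unname(2 * stats::pnorm(-abs(z))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(out$p_value * nrow(out), 1)
  out
}

#' Test profile-difference variation across comparison categories
#'
#' Kruskal-Wallis omnibus test across the comparison groups (replicate,
#' within-individual, and one group per individual pair for
#' between-individual comparisons) followed by Dunn post-hoc pairwise rank
#' tests with Bonferroni adjustment.
#'
#' @param comparisons the \code{comparisons} element of
#'   [pairwiseCompare()]'s result (or a compatible data.frame with
#'   \code{group} and \code{n_differences}).
#' @param alpha significance level used for the \code{significant} flag.
#' @return list with \code{kruskal} (the \code{htest}), \code{pairwise}
#'   (Dunn z, raw and adjusted p per group pair), and \code{n}.
#' @export
compareCategoryTest <- function(comparisons, alpha = 0.05) {
  sizes <- table(comparisons$group)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("excluding group(s) with < 2 comparisons: %s",
                    paste(small, collapse = ", ")))
    comparisons <- comparisons[!comparisons$group %in% small, , drop = FALSE]
  }
  if (length(unique(comparisons$group)) < 2L)
    stop("need at least two non-empty comparison groups", call. = FALSE)
  kw <- stats::kruskal.test(n_differences ~ factor(group),
                            data = comparisons)
  pw <- dunnPosthoc(comparisons$n_differences, comparisons$group)
  pw$significant <- pw$p_adjusted <= alpha
  list(kruskal = kw, pairwise = pw, n = nrow(comparisons))
}

#' Expected pairwise-comparison category sizes
#'
#' For a balanced design of I individuals x L body locations x R
#' replicates, the unordered sample pairs split into I*L*choose(R,2)
#' replicate pairs, I*(choose(L*R,2) - L*choose(R,2)) within-individual
#' pairs and choose(I,2)*(L*R)^2 between-individual pairs.
#'
#' @param nIndividuals,nLocations,nReplicates design dimensions.
#' @return named numeric vector with the three category sizes and the total.
#' @export
comparisonDesignCounts <- function(nIndividuals, nLocations, nReplicates) {
  I <- nIndividuals; L <- nLocations; R <- nReplicates
  repl <- I * L * choose(R, 2)
  within <- I * (choose(L * R, 2) - L * choose(R, 2))
  between <- choose(I, 2) * (L * R)^2
  c(replicate = repl, within_individual = within,
    between_individual = between, total = repl + within + between)
}

#' Write profiles and comparisons to disk
#'
#' @param profiles a \linkS4class{GVPProfileSet}.
#' @param path output TSV path (samples x loci, category and frequency
#'   columns interleaved per locus).
#' @return the path, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  categories <- assay(profiles, "category")
  freq <- assay(profiles, "frequency")
  df <- data.frame(sample_id = colnames(categories),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(categories))) {
    df[[paste0(rownames(categories)[i], "_category")]] <- categories[i, ]
    df[[paste0(rownames(categories)[i], "_frequency")]] <- freq[i, ]
  }
  writeDelim(df, path)
}

#' @rdname writeProfiles
#' @param comparisons result of [pairwiseCompare()].
#' @export
writeComparisons <- function(comparisons, path) {
  writeDelim(comparisons$comparisons, path)
}
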