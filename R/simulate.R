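# Synthetic-data generator emulating the single-hair study design:
# 3 individuals x 3 body locations x 4 replicates, Hardy-Weinberg
# genotypes, per-GVP detection dropout, optional false positives, and
# location-specific protein-abundance effects.

## Residues allowed at simulated variant sites: excludes K/R-neutral
## ambiguity sources (I/L isobars and the deamidation-confusable N/D, Q/E
## pairs) so simulated panel loci are discriminative, like the study's.
SAFE_VARIANT_AA <- c("A", "S", "T", "V", "F", "Y", "H", "W", "M", "G", "C")

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. Defaults mirror the
#' study design: 3 individuals, head/arm/pubic hair, 4 replicates each.
#'
#' @param nIndividuals number of individuals.
#' @param locations body-location labels.
#' @param nReplicates replicates per individual per location.
#' @param nSnps number of missense SNP loci.
#' @param mafRange range from which per-SNP minor allele frequencies are
#'   drawn uniformly.
#' @param sensitivity per-GVP detection probability for a carried allele
#'   (dropout is 1 - sensitivity, independent per GVP per sample).
#' @param falsePositiveRate probability of emitting a GVP the individual
#'   does not carry.
#' @param nBackgroundProteins number of non-variant background proteins.
#' @param backgroundPeptidesPerSample background peptides sampled per
#'   sample.
#' @param deFraction fraction of background proteins given
#'   location-specific differential abundance.
#' @param locationEffects named multiplicative abundance effects per
#'   location for differentially expressed proteins.
#' @param areaMeanLog,areaSdLog log-normal parameters of precursor areas.
#' @param hgvsFraction fraction of SNPs without a Reference SNP ID (HGVS
#'   identifier instead).
#' @param twoSnpGeneFraction fraction of SNPs placed as a second SNP in an
#'   already-used gene (exercises the one-SNP-per-gene rule).
#' @param seed random seed (mandatory; all randomness flows from it).
#' @return a validated \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nIndividuals = 3L,
                             locations = c("head", "arm", "pubic"),
                             nReplicates = 4L,
                             nSnps = 30L,
                             mafRange = c(0.05, 0.5),
                             sensitivity = 0.9,
                             falsePositiveRate = 0,
                             nBackgroundProteins = 40L,
                             backgroundPeptidesPerSample = 120L,
                             deFraction = 0.2,
                             locationEffects = c(head = 1, arm = 0.5,
                                                 pubic = 2),
                             areaMeanLog = log(1e7),
                             areaSdLog = 1,
                             hgvsFraction = 0.1,
                             twoSnpGeneFraction = 0.15,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  stopifnot(
    nIndividuals >= 1L, nReplicates >= 1L, length(locations) >= 1L,
    nSnps >= 1L,
    sensitivity >= 0, sensitivity <= 1,
    falsePositiveRate >= 0, falsePositiveRate < 1,
    all(mafRange >= 0), all(mafRange <= 0.5),
    all(locations %in% names(locationEffects))
  )
  structure(list(
    nIndividuals = as.integer(nIndividuals), locations = locations,
    nReplicates = as.integer(nReplicates), nSnps = as.integer(nSnps),
    mafRange = mafRange, sensitivity = sensitivity,
    falsePositiveRate = falsePositiveRate,
    nBackgroundProteins = as.integer(nBackgroundProteins),
    backgroundPeptidesPerSample = as.integer(backgroundPeptidesPerSample),
    deFraction = deFraction, locationEffects = locationEffects,
    areaMeanLog = areaMeanLog, areaSdLog = areaSdLog,
    hgvsFraction = hgvsFraction,
    twoSnpGeneFraction = twoSnpGeneFraction,
    seed = as.integer(seed)
  ), class = "SimulationConfig")
}

## One synthetic protein as concatenated tryptic segments: each segment is
## 6-12 non-K/R residues followed by K or R, so 0-missed peptides fall in
## the detectable 5-50 length range.
randomProtein <- function(nSegments = 10L) {
  body <- vapply(seq_len(nSegments), function(i) {
    len <- sample(6:12, 1L)
    paste0(paste(sample(setdiff(AA_ALPHABET, c("K", "R")), len,
                        replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
  paste(body, collapse = "")
}

#' Simulate the reference set: proteome and missense SNP table
#'
#' Generates synthetic variant-bearing proteins (major allele in the
#' reference), a missense SNP table with Hardy-Weinberg genotype
#' frequencies, background proteins, and the background peptide pool. A
#' configurable fraction of SNPs lack rsIDs and a fraction share a gene
#' with another SNP, so the panel filters have work to do.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{proteome} ([Biostrings::AAStringSet]),
#'   \code{snps} (validated SNP table), \code{backgroundPeptides}
#'   (accession/peptide pool) and \code{deProteins} (accessions with
#'   location effects).
#' @export
simulateReferenceSet <- function(config) {
  set.seed(config$seed)
  n <- config$nSnps
  nSecond <- if (n >= 2L) round(n * config$twoSnpGeneFraction) else 0L
  nGenes <- n - nSecond
  geneOf <- c(seq_len(nGenes), sample(seq_len(nGenes), nSecond,
                                      replace = FALSE))
  genes <- sprintf("GENE%03d", geneOf)
  accs <- sprintf("P_GENE%03d", seq_len(nGenes))

  proteins <- stats::setNames(
    vapply(seq_len(nGenes), function(i) randomProtein(10L), character(1)),
    accs)

  nHgvs <- round(n * config$hgvsFraction)
  isHgvs <- rep(FALSE, n)
  if (nHgvs > 0L) isHgvs[sample(n, nHgvs)] <- TRUE

  rows <- vector("list", n)
  usedSegments <- list()
  for (i in seq_len(n)) {
    acc <- sprintf("P_GENE%03d", geneOf[i])
    seq <- proteins[[acc]]
    segBounds <- trypticBoundaries(seq)
    nSeg <- length(segBounds) - 1L
    avail <- setdiff(2:(nSeg - 1L), usedSegments[[acc]])
    segIdx <- if (length(avail) == 1L) avail else sample(avail, 1L)
    usedSegments[[acc]] <- c(usedSegments[[acc]], segIdx)
    segStart <- segBounds[segIdx] + 1L
    segEnd <- segBounds[segIdx + 1L]
    ## interior position, clear of the terminal K/R
    posRange <- (segStart + 1L):(segEnd - 2L)
    pos <- if (length(posRange) == 1L) posRange else sample(posRange, 1L)
    pair <- sample(SAFE_VARIANT_AA, 2L)
    seq <- applyVariant(seq, pos, substr(seq, pos, pos), pair[1L])
    proteins[[acc]] <- seq
    q <- stats::runif(1L, config$mafRange[1L], config$mafRange[2L])
    rows[[i]] <- data.frame(
      snp_id = if (isHgvs[i])
        sprintf("%d:g.%d %s > %s", i, 1e6 + i, "G", "T")
      else sprintf("rs%06d", 100000L + i),
      gene = genes[i], protein_accession = acc,
      residue_position = pos, major_aa = pair[1L], minor_aa = pair[2L],
      f_major_hom = (1 - q)^2, f_het = 2 * q * (1 - q), f_minor_hom = q^2,
      stringsAsFactors = FALSE
    )
  }
  snps <- validateSnpTable(do.call(rbind, rows))

  bkgAccs <- sprintf("BKG%03d", seq_len(config$nBackgroundProteins))
  bkg <- stats::setNames(
    vapply(bkgAccs, function(a) randomProtein(9L), character(1)), bkgAccs)
  pool <- do.call(rbind, lapply(bkgAccs, function(a) {
    d <- digestProtein(bkg[[a]], maxMissed = 0L)
    d <- d[nchar(d$peptide) >= 5L & nchar(d$peptide) <= 50L, , drop = FALSE]
    data.frame(accession = a, peptide = d$peptide, stringsAsFactors = FALSE)
  }))
  nDe <- round(config$nBackgroundProteins * config$deFraction)
  deProteins <- if (nDe > 0L) sample(bkgAccs, nDe) else character(0)
  list(
    proteome = Biostrings::AAStringSet(c(proteins, bkg)),
    snps = snps,
    backgroundPeptides = pool,
    deProteins = deProteins
  )
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Per individual and SNP, draws a genotype with probabilities
#' (1-q)^2, 2q(1-q), q^2 for minor allele frequency q.
#'
#' @param config a [simulationConfig()].
#' @param snps validated SNP table (MAF column used as q).
#' @return long genotype data.frame.
#' @export
simulateGenotypes <- function(config, snps) {
  set.seed(config$seed + 1L)
  individuals <- sprintf("I%d", seq_len(config$nIndividuals))
  grid <- expand.grid(individual_id = individuals, snp_id = snps$snp_id,
                      stringsAsFactors = FALSE)
  q <- snps$maf[match(grid$snp_id, snps$snp_id)]
  grid$genotype <- vapply(q, function(qi) {
    sample(GENOTYPE_LEVELS, 1L,
           prob = c((1 - qi)^2, 2 * qi * (1 - qi), qi^2))
  }, character(1))
  grid[order(grid$individual_id, grid$snp_id), ] -> out
  rownames(out) <- NULL
  out
}

#' Simulate the sample manifest
#'
#' @param config a [simulationConfig()].
#' @return manifest data.frame for the full crossed design.
#' @export
simulateManifest <- function(config) {
  grid <- expand.grid(
    replicate = seq_len(config$nReplicates),
    body_location = config$locations,
    individual_id = sprintf("I%d", seq_len(config$nIndividuals)),
    stringsAsFactors = FALSE
  )
  grid$sample_id <- sprintf("%s_%s_r%d", grid$individual_id,
                            grid$body_location, grid$replicate)
  validateManifest(grid[c("sample_id", "individual_id", "body_location",
                          "replicate")],
                   locations = config$locations)
}

## Canonical emitted peptide per (snp, allele): the fully tryptic 0-missed
## record; falls back to the fewest-missed-cleavage record.
canonicalGvps <- function(catalog) {
  rec <- gvpRecords(catalog)
  rec <- rec[order(rec$snp_id, rec$allele_type, rec$semi_specific,
                   rec$missed_cleavages), ]
  rec[!duplicated(paste(rec$snp_id, rec$allele_type)), , drop = FALSE]
}

#' Simulate per-sample peptide observations with detection dropout
#'
#' For each sample and each GVP whose allele the individual carries, the
#' canonical GVP peptide is emitted with probability \code{sensitivity};
#' with probability \code{falsePositiveRate} a GVP the individual does not
#' carry is emitted. Background peptides are added with log-normal areas,
#' scaled multiplicatively per body location for the differentially
#' expressed proteins. A truth table records every carried allele and
#' whether it was emitted.
#'
#' @param config a [simulationConfig()].
#' @param ref reference set from [simulateReferenceSet()].
#' @param genotypes genotype table from [simulateGenotypes()].
#' @param catalog \linkS4class{GVPCatalog} built from \code{ref}.
#' @param manifest manifest from [simulateManifest()].
#' @return list with \code{observations} (PSM-style data.frame) and
#'   \code{truth} (sample x SNP x allele carried/emitted table).
#' @export
simulateObservations <- function(config, ref, genotypes, catalog, manifest) {
  set.seed(config$seed + 2L)
  canon <- canonicalGvps(catalog)
  snps <- catalogSnps(catalog)
  s <- config$sensitivity
  fp <- config$falsePositiveRate
  obsRows <- list()
  truthRows <- list()
  for (r in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[r]
    ind <- manifest$individual_id[r]
    loc <- manifest$body_location[r]
    g <- genotypeLookup(genotypes, rep(ind, nrow(snps)), snps$snp_id)
    for (allele in c("major", "minor")) {
      carried <- if (allele == "major") g != "minor_hom" else g != "major_hom"
      emitP <- ifelse(carried, s, fp)
      emitted <- stats::runif(nrow(snps)) < emitP
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        sample_id = sid, snp_id = snps$snp_id, allele_type = allele,
        carried = carried, emitted = emitted, stringsAsFactors = FALSE
      )
      if (any(emitted)) {
        hit <- canon[match(paste(snps$snp_id[emitted], allele),
                           paste(canon$snp_id, canon$allele_type)), ,
                     drop = FALSE]
        obsRows[[length(obsRows) + 1L]] <- data.frame(
          sample_id = sid, sequence = hit$sequence, modifications = "",
          protein_accessions = hit$protein_accession,
          precursor_area = stats::rlnorm(nrow(hit), config$areaMeanLog,
                                         config$areaSdLog),
          stringsAsFactors = FALSE
        )
      }
    }
    nBkg <- min(config$backgroundPeptidesPerSample,
                nrow(ref$backgroundPeptides))
    pick <- ref$backgroundPeptides[sample(nrow(ref$backgroundPeptides),
                                          nBkg), , drop = FALSE]
    effect <- ifelse(pick$accession %in% ref$deProteins,
                     config$locationEffects[[loc]], 1)
    obsRows[[length(obsRows) + 1L]] <- data.frame(
      sample_id = sid, sequence = pick$peptide, modifications = "",
      protein_accessions = pick$accession,
      precursor_area = effect * stats::rlnorm(nBkg, config$areaMeanLog,
                                              config$areaSdLog),
      stringsAsFactors = FALSE
    )
  }
  observations <- do.call(rbind, obsRows)
  truth <- do.call(rbind, truthRows)
  rownames(observations) <- rownames(truth) <- NULL
  list(observations = observations, truth = truth)
}

#' Simulate a complete study
#'
#' Chains the reference-set, genotype, manifest, catalog and observation
#' generators under a single seed, optionally writing every artifact in
#' the file formats the readers consume.
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory; when given, writes
#'   \code{proteome.fasta}, \code{snps.tsv}, \code{manifest.tsv},
#'   \code{genotypes.tsv}, \code{psms.tsv}, \code{catalog.tsv} and
#'   \code{truth.json}.
#' @return list with \code{config}, \code{proteome}, \code{snps},
#'   \code{genotypes}, \code{manifest}, \code{catalog},
#'   \code{observations}, \code{truth}, \code{deProteins}.
#' @export
simulateStudy <- function(config, dir = NULL) {
  ref <- simulateReferenceSet(config)
  genotypes <- simulateGenotypes(config, ref$snps)
  manifest <- simulateManifest(config)
  catalog <- buildCatalog(ref$snps, ref$proteome, maxMissed = 3L)
  sim <- simulateObservations(config, ref, genotypes, catalog, manifest)
  out <- list(config = config, proteome = ref$proteome, snps = ref$snps,
              genotypes = genotypes, manifest = manifest, catalog = catalog,
              observations = sim$observations, truth = sim$truth,
              deProteins = ref$deProteins)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeProteinFasta(out$proteome, file.path(dir, "proteome.fasta"))
    writeSnpTable(out$snps, file.path(dir, "snps.tsv"))
    writeManifest(out$manifest, file.path(dir, "manifest.tsv"))
    writeGenotypes(out$genotypes, file.path(dir, "genotypes.tsv"))
    writePsmTable(out$observations, file.path(dir, "psms.tsv"))
    writeCatalog(out$catalog, file.path(dir, "catalog.tsv"))
    jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                         dataframe = "rows")
  }
  out
}

#' Exact replicate mismatch probability at one locus
#'
#' Enumerates the 4x4 table of phenotype-category outcomes for two
#' independent replicates of one individual at one locus, given the
#' genotype, per-GVP detection sensitivity and false-positive rate, and
#' returns the probability that the two categories differ.
#'
#' @param genotype one of \code{major_hom}, \code{het}, \code{minor_hom}.
#' @param sensitivity per-GVP detection probability for carried alleles.
#' @param falsePositiveRate emission probability for uncarried alleles.
#' @return the mismatch probability.
#' @examples
#' replicateMismatchProbability("het", 0.8)
#' @export
replicateMismatchProbability <- function(genotype, sensitivity,
                                         falsePositiveRate = 0) {
  stopifnot(genotype %in% GENOTYPE_LEVELS)
  pMaj <- if (genotype != "minor_hom") sensitivity else falsePositiveRate
  pMin <- if (genotype != "major_hom") sensitivity else falsePositiveRate
  p <- c(both = pMaj * pMin,
         major_only = pMaj * (1 - pMin),
         minor_only = (1 - pMaj) * pMin,
         absent = (1 - pMaj) * (1 - pMin))
  1 - sum(p^2)
}
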