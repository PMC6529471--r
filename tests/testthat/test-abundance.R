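test_that("normalized roll-up matches the worked arithmetic", {
  obs <- rbind(makeObservation("S1", "AAAAK", accession = "X", area = 2),
               makeObservation("S1", "CCCCK", accession = "X", area = 3),
               makeObservation("S1", "DDDDK", accession = "Y", area = 5))
  ab <- proteinAbundance(obs)
  mat <- SummarizedExperiment::assay(ab, "abundance")
  expect_equal(mat["X", "S1"], 0.5)
  expect_equal(mat["Y", "S1"], 0.5)
  # single-protein sample normalizes to 1
  one <- proteinAbundance(makeObservation("S2", "AAAAK", accession = "Z",
                                          area = 42))
  expect_equal(SummarizedExperiment::assay(one)["Z", "S2"], 1)
})

test_that("roll-up equals a brute-force two-pass computation", {
  set.seed(404)
  obs <- do.call(rbind, lapply(1:200, function(i) {
    makeObservation(sprintf("S%d", sample(3, 1)),
                    randomSequence(sample(6:10, 1)),
                    accession = sprintf("P%d", sample(8, 1)),
                    area = runif(1, 1, 100))
  }))
  mat <- SummarizedExperiment::assay(proteinAbundance(obs), "abundance")
  for (s in unique(obs$sample_id)) {
    sub <- obs[obs$sample_id == s, ]
    # pass 1: collapse duplicates (max), total area
    peps <- tapply(sub$precursor_area, sub$sequence, max)
    # pass 2: per-protein sum of normalized areas
    for (p in unique(sub$protein_accessions)) {
      mine <- names(peps) %in% sub$sequence[sub$protein_accessions == p]
      expect_equal(mat[p, s], sum(peps[mine]) / sum(peps))
    }
    expect_equal(sum(tapply(peps / sum(peps), names(peps), sum)), 1)
  }
})

test_that("duplicate peptides collapse to the maximum area", {
  obs <- rbind(makeObservation("S1", "AAAAK", accession = "X", area = 10),
               makeObservation("S1", "AAAAK", accession = "X", area = 2),
               makeObservation("S1", "CCCCK", accession = "Y", area = 10))
  mat <- SummarizedExperiment::assay(proteinAbundance(obs), "abundance")
  expect_equal(mat["X", "S1"], 0.5)
})

test_that("shared peptides contribute to every mapped protein", {
  obs <- rbind(makeObservation("S1", "AAAAK", accession = "X;Y", area = 4),
               makeObservation("S1", "CCCCK", accession = "Y", area = 4))
  ab <- proteinAbundance(obs)
  mat <- SummarizedExperiment::assay(ab, "abundance")
  expect_equal(mat["X", "S1"], 0.5)
  expect_equal(mat["Y", "S1"], 1.0)
  expect_equal(S4Vectors::metadata(ab)$sharedPeptides, "AAAAK")
})

test_that("per-sample scaling of raw areas leaves abundances unchanged", {
  set.seed(55)
  obs <- do.call(rbind, lapply(1:60, function(i) {
    makeObservation(sprintf("S%d", sample(2, 1)),
                    randomSequence(7),
                    accession = sprintf("P%d;P%d", sample(5, 1), sample(5, 1)),
                    area = runif(1, 1, 50))
  }))
  scaled <- obs
  scale <- c(S1 = 17.3, S2 = 0.004)
  scaled$precursor_area <- obs$precursor_area * scale[obs$sample_id]
  m1 <- SummarizedExperiment::assay(proteinAbundance(obs), "abundance")
  m2 <- SummarizedExperiment::assay(proteinAbundance(scaled), "abundance")
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("normalization is idempotent", {
  obs <- rbind(makeObservation("S1", "AAAAK", accession = "X", area = 2),
               makeObservation("S1", "CCCCK", accession = "Y", area = 6))
  m1 <- SummarizedExperiment::assay(proteinAbundance(obs), "abundance")
  renorm <- obs
  peps <- tapply(obs$precursor_area, obs$sequence, max)
  renorm$precursor_area <- obs$precursor_area / sum(peps)
  m2 <- SummarizedExperiment::assay(proteinAbundance(renorm), "abundance")
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("zero-total-area samples are excluded with a warning", {
  obs <- rbind(makeObservation("S1", "AAAAK", accession = "X", area = 0),
               makeObservation("S2", "AAAAK", accession = "X", area = 5))
  expect_warning(ab <- proteinAbundance(obs), "zero total area")
  expect_equal(colnames(SummarizedExperiment::assay(ab)), "S2")
})

test_that("a constant protein is skipped and a strong location effect found", {
  manifest <- makeManifest()
  set.seed(66)
  sigma <- 0.02
  found <- 0L
  for (run in 1:25) {
    y <- 0.3 + rnorm(36, sd = sigma) +
      ifelse(manifest$body_location == "pubic", 5 * sigma, 0)
    mat <- rbind(DE1 = y, FLAT = rep(0.5, 36))
    colnames(mat) <- manifest$sample_id
    de <- differentialExpression(mat, manifest)
    expect_equal(attr(de, "skipped"), "FLAT")
    hit <- de$significant[de$accession == "DE1"] &&
      grepl("pubic", de$significant_contrasts[de$accession == "DE1"])
    found <- found + as.integer(hit)
  }
  expect_gte(found / 25, 0.99)
})

test_that("a protein present in one sample is zero-filled without error", {
  manifest <- makeManifest()
  obs <- rbind(
    do.call(rbind, lapply(manifest$sample_id, function(s)
      makeObservation(s, "AAAAK", accession = "COMMON", area = 10))),
    makeObservation(manifest$sample_id[1], "CCCCK", accession = "RARE",
                    area = 10))
  de <- differentialExpression(proteinAbundance(obs), manifest)
  expect_true("RARE" %in% de$accession)
})

test_that("SNP-abundance correlation recovers exact and degenerate cases", {
  cfg <- simulationConfig(nSnps = 3L, seed = 8L)
  study <- simulateStudy(cfg)
  st <- matchObservations(study$observations, study$catalog, study$manifest)
  ab <- proteinAbundance(study$observations)
  rep_ <- snpAbundanceCorrelation(st, ab)
  expect_equal(nrow(rep_), 3L)
  expect_equal(rep_$n_groups, rep(9L, 3L))
  # cross-check computed r against the direct formula on one SNP
  detected <- majorDetected(st) | minorDetected(st)
  manifest <- as.data.frame(SummarizedExperiment::colData(st))
  grp <- paste(manifest$individual_id, manifest$body_location)
  for (i in which(!is.na(rep_$r))) {
    acc <- study$snps$protein_accession[
      study$snps$snp_id == rep_$snp_id[i]]
    freq <- tapply(detected[i, manifest$sample_id], grp, mean)
    mat <- SummarizedExperiment::assay(ab)
    abv <- rep(0, nrow(manifest)); names(abv) <- manifest$sample_id
    common <- intersect(colnames(mat), names(abv))
    abv[common] <- mat[acc, common]
    abMean <- tapply(abv[manifest$sample_id], grp, mean)
    expect_equal(rep_$r[i], sum((freq - mean(freq)) * (abMean - mean(abMean))) /
                   sqrt(sum((freq - mean(freq))^2) *
                          sum((abMean - mean(abMean))^2)),
                 tolerance = 1e-12)
  }
  # identically-1 frequency has undefined correlation
  allOn <- st
  SummarizedExperiment::assay(allOn, "majorDetected")[] <- TRUE
  rep2 <- snpAbundanceCorrelation(allOn, ab)
  expect_true(all(grepl("undefined", rep2$note)))
})

test_that("a perfectly linear positive relation gives r = 1", {
  snps <- data.frame(snp_id = "rs1", gene = "G", protein_accession = "P",
                     residue_position = 5L, major_aa = "T", minor_aa = "M",
                     f_major_hom = 0.49, f_het = 0.42, f_minor_hom = 0.09)
  cat <- buildCatalog(snps, c(P = "MAAATAAKGGGR"))
  manifest <- makeManifest(3L, c("head", "arm", "pubic"), 4L)
  # detection frequency rises with abundance across (individual, location)
  grp <- paste(manifest$individual_id, manifest$body_location)
  lvl <- match(grp, unique(grp))  # 1..9
  emit <- manifest$replicate <= ceiling(lvl * 4 / 9)
  obs <- do.call(rbind, lapply(which(emit), function(r)
    makeObservation(manifest$sample_id[r], "MAAATAAK", accession = "P",
                    area = lvl[r])))
  bkg <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(r)
    makeObservation(manifest$sample_id[r], "CCCCCK", accession = "B",
                    area = 10)))
  allObs <- rbind(obs, bkg)
  st <- matchObservations(allObs, cat, manifest)
  rep_ <- snpAbundanceCorrelation(st, proteinAbundance(allObs))
  expect_gt(rep_$r, 0.9)
  expect_lt(rep_$p_value, 0.01)
})
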