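test_that("classification follows the presence/detection contingency", {
  fx <- krt32Fixture()
  cat <- buildCatalog(fx$snps, fx$proteome)
  manifest <- data.frame(sample_id = c("S1", "S2", "S3"),
                         individual_id = c("A", "B", "C"),
                         body_location = "head", replicate = 1L)
  obs <- rbind(makeObservation("S1", "LEGEINTYR"),   # A het: major TP, minor FN
               makeObservation("S2", "LEGEINMYR"))   # B major_hom: minor FP
  st <- matchObservations(obs, cat, manifest)
  geno <- data.frame(individual_id = c("A", "B", "C"),
                     snp_id = "rs2071563",
                     genotype = c("het", "major_hom", "minor_hom"))
  calls <- classifyCalls(st, geno)
  getCall <- function(s, a)
    calls$call[calls$sample_id == s & calls$allele_type == a]
  expect_equal(getCall("S1", "major"), "TP")
  expect_equal(getCall("S1", "minor"), "FN")
  expect_equal(getCall("S2", "minor"), "FP")
  # B's major allele is present but its GVP was not observed
  expect_equal(getCall("S2", "major"), "FN")
  # C minor_hom with nothing detected: major TN, minor FN
  expect_equal(getCall("S3", "major"), "TN")
  expect_equal(getCall("S3", "minor"), "FN")
})

test_that("classification errors on a missing genotype naming the pair", {
  fx <- krt32Fixture()
  cat <- buildCatalog(fx$snps, fx$proteome)
  manifest <- data.frame(sample_id = "S1", individual_id = "A",
                         body_location = "head", replicate = 1L)
  st <- matchObservations(makeObservation("S1", "LEGEINTYR"), cat, manifest)
  geno <- data.frame(individual_id = "Z", snp_id = "rs2071563",
                     genotype = "het")
  expect_error(classifyCalls(st, geno), "missing genotype.*A, rs2071563")
})

test_that("consistent SNP sets equal a brute-force group filter", {
  set.seed(99)
  grid <- expand.grid(sample_id = sprintf("S%02d", 1:12),
                      snp_id = sprintf("rs%d", 1:6),
                      allele_type = c("major", "minor"),
                      stringsAsFactors = FALSE)
  grid$body_location <- rep(rep(c("head", "arm", "pubic"), each = 4L),
                            times = 12L)
  grid$call <- sample(c("TP", "TN", "FN", "FP"), nrow(grid), replace = TRUE,
                      prob = c(0.45, 0.4, 0.1, 0.05))
  got <- consistentSnps(grid, scope = "per_location")
  for (loc in unique(grid$body_location)) {
    for (al in c("major", "minor")) {
      sub <- grid[grid$body_location == loc & grid$allele_type == al, ]
      want <- sort(unique(sub$snp_id[!sub$snp_id %in%
        sub$snp_id[!sub$call %in% c("TP", "TN")]]))
      expect_equal(got[[loc]][[al]], want)
    }
  }
  # all-sample scope equals the intersection over locations
  all_ <- consistentSnps(grid, scope = "all_samples")
  for (al in c("major", "minor")) {
    expect_equal(all_[[al]],
                 sort(Reduce(intersect, lapply(got, `[[`, al))))
  }
})

test_that("a SNP clean everywhere is retained; one FN drops one location only", {
  grid <- expand.grid(sample_id = sprintf("S%02d", 1:12),
                      snp_id = "rs1", allele_type = "minor",
                      stringsAsFactors = FALSE)
  grid$body_location <- rep(c("head", "arm", "pubic"), each = 4L)
  grid$call <- "TP"
  got <- consistentSnps(grid, scope = "per_location")
  expect_true(all(vapply(got, function(l) "rs1" %in% l$minor, logical(1))))
  expect_true("rs1" %in% consistentSnps(grid)$minor)
  grid$call[grid$body_location == "arm"][1] <- "FN"
  got <- consistentSnps(grid, scope = "per_location")
  expect_false("rs1" %in% got$arm$minor)
  expect_true("rs1" %in% got$head$minor)
  expect_true("rs1" %in% got$pubic$minor)
})

## A 10-SNP fixture whose panel outcome is worked out by hand:
## rs01 clean everywhere                      -> panel (gene G1)
## rs02 one FP                                -> removed at filter 1
## rs03 FN on major, clean minor              -> survives consistency
## rs04 FN on both allele types               -> removed at filter 2
## hgvs05 clean but no rsID                   -> removed at filter 4
## rs06/rs07 same gene G5, maf 0.30/0.10      -> rs07 kept (lowest MAF)
## rs08 clean (gene G6)                       -> panel
## rs09 FP on minor only                      -> removed at filter 1
## rs10 clean, ties rs08 on gene? no, gene G7 -> panel
tenSnpFixture <- function() {
  ids <- c("rs01", "rs02", "rs03", "rs04", "17:g.1 G > T", "rs06", "rs07",
           "rs08", "rs09", "rs10")
  genes <- c("G1", "G2", "G3", "G4", "G45", "G5", "G5", "G6", "G65", "G7")
  maf <- c(0.2, 0.2, 0.2, 0.2, 0.2, 0.30, 0.10, 0.2, 0.2, 0.2)
  snps <- data.frame(
    snp_id = ids, gene = genes, protein_accession = "P",
    residue_position = 5L, major_aa = "A", minor_aa = "S",
    f_major_hom = (1 - maf)^2, f_het = 2 * maf * (1 - maf),
    f_minor_hom = maf^2, stringsAsFactors = FALSE)
  grid <- expand.grid(sample_id = sprintf("S%d", 1:4), snp_id = ids,
                      allele_type = c("major", "minor"),
                      stringsAsFactors = FALSE)
  grid$body_location <- rep(c("head", "head", "arm", "arm"), times = 20L)
  grid$individual_id <- "I1"
  grid$call <- "TP"
  grid$call[grid$snp_id == "rs02" & grid$sample_id == "S1" &
              grid$allele_type == "minor"] <- "FP"
  grid$call[grid$snp_id == "rs03" & grid$sample_id == "S2" &
              grid$allele_type == "major"] <- "FN"
  grid$call[grid$snp_id == "rs04" & grid$sample_id == "S3"] <- "FN"
  grid$call[grid$snp_id == "rs09" & grid$sample_id == "S4" &
              grid$allele_type == "minor"] <- "FP"
  list(snps = validateSnpTable(snps), calls = grid)
}

test_that("panel selection reproduces the hand-applied filters", {
  fx <- tenSnpFixture()
  rep_ <- selectPanel(fx$calls, fx$snps)
  expect_equal(panelSnps(rep_),
               sort(c("rs01", "rs03", "rs07", "rs08", "rs10")))
  expect_equal(panelSnps(rep_), bruteForcePanel(fx$calls, fx$snps))
  counts <- panelCounts(rep_)
  expect_equal(unname(counts["input"]), 10L)
  expect_equal(unname(counts["after_fp_removal"]), 8L)   # rs02, rs09 out
  expect_equal(unname(counts["after_consistency"]), 7L)  # rs04 out
  expect_equal(unname(counts["after_rsid"]), 6L)         # hgvs out
  expect_equal(unname(counts["panel"]), 5L)              # rs06 out
  prov <- panelProvenance(rep_)
  expect_equal(prov$stage[prov$snp_id == "rs02"], "fp_removal")
  expect_equal(prov$stage[prov$snp_id == "rs04"], "all_sample_consistency")
  expect_equal(prov$stage[prov$snp_id == "17:g.1 G > T"], "rsid")
  expect_equal(prov$stage[prov$snp_id == "rs06"], "one_per_gene")
  # every exclusion has a recorded reason
  expect_true(all(nzchar(prov$reason)))
})

test_that("panel SNPs carry zero FP calls and selection is order-invariant", {
  fx <- tenSnpFixture()
  rep_ <- selectPanel(fx$calls, fx$snps)
  fpSnps <- unique(fx$calls$snp_id[fx$calls$call == "FP"])
  expect_length(intersect(panelSnps(rep_), fpSnps), 0L)
  expect_lte(length(panelSnps(rep_)), length(unique(fx$snps$gene)))
  set.seed(5)
  shuffled <- fx$calls[sample(nrow(fx$calls)), ]
  expect_equal(panelSnps(selectPanel(shuffled, fx$snps)), panelSnps(rep_))
})

test_that("MAF ties in one gene break lexicographically", {
  fx <- tenSnpFixture()
  snps <- fx$snps
  snps$maf[snps$snp_id %in% c("rs06", "rs07")] <- 0.25
  rep_ <- selectPanel(fx$calls, snps)
  expect_true("rs06" %in% panelSnps(rep_))
  expect_false("rs07" %in% panelSnps(rep_))
})
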