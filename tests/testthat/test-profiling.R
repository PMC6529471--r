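test_that("phenotype frequencies follow the genotype-frequency sum rule", {
  freqs <- c(0.49, 0.42, 0.09)
  expect_equal(phenotypeFrequency("minor_only", freqs), 0.51)
  expect_equal(phenotypeFrequency("major_only", freqs), 0.91)
  expect_equal(phenotypeFrequency("both", freqs), 0.42)
  expect_true(is.na(phenotypeFrequency("absent", freqs)))
})

test_that("major_only + minor_only - both = 1 for any valid triple", {
  set.seed(21)
  for (i in 1:50) {
    f <- as.vector(stats::rmultinom(1, 1000, prob = runif(3))) / 1000
    expect_equal(phenotypeFrequency("major_only", f) +
                   phenotypeFrequency("minor_only", f) -
                   phenotypeFrequency("both", f), 1)
  }
})

test_that("RMP is the product of frequencies over non-absent loci", {
  # two het loci at f_het = 0.5 each
  p <- profileFromCategories(c("both", "both"),
                             matrix(c(0.25, 0.5, 0.25), 2, 3, byrow = TRUE))
  r <- sampleRMP(p)
  expect_equal(r$rmp, 0.25)
  expect_equal(r$one_in, 4)
})

test_that("a locus with frequency 1 leaves the RMP unchanged", {
  freqs <- matrix(c(0.36, 0.48, 0.16,
                    0, 1, 0), 2, 3, byrow = TRUE)
  pBoth <- profileFromCategories(c("major_only", "both"), freqs)
  pOne <- profileFromCategories(c("major_only", "absent"), freqs)
  expect_equal(sampleRMP(pBoth)$rmp, sampleRMP(pOne)$rmp)
})

test_that("eight-locus RMP matches the hand product to 12 decimals", {
  fr <- c(0.91, 0.55, 0.62, 0.75, 0.58, 0.64, 0.87, 0.69)
  # categories major_only with triples arranged so the observed frequency
  # (f_major_hom + f_het) equals fr at each locus
  freqs <- cbind(fr - 0.05, 0.05, 1 - fr)
  p <- profileFromCategories(rep("major_only", 8L), freqs)
  hand <- prod(fr)  # independent hand product
  expect_equal(sampleRMP(p)$rmp, hand, tolerance = 1e-12)
})

test_that("an all-absent profile has undefined RMP, not 1", {
  p <- profileFromCategories(c("absent", "absent"),
                             matrix(c(0.25, 0.5, 0.25), 2, 3, byrow = TRUE))
  expect_warning(r <- sampleRMP(p), "undefined")
  expect_true(is.na(r$rmp))
})

test_that("profile difference counts mismatched loci and needs equal panels", {
  a <- c(rs1 = "both", rs2 = "major_only", rs3 = "absent")
  expect_equal(profileDifference(a, a), 0L)
  b <- c(rs1 = "major_only", rs2 = "major_only", rs3 = "minor_only")
  expect_equal(profileDifference(a, b), 2L)
  # absent vs non-absent is a difference
  expect_equal(profileDifference(c(rs1 = "absent"), c(rs1 = "both")), 1L)
  expect_error(profileDifference(a, c(rs9 = "both", rs2 = "both",
                                      rs3 = "both")),
               "different panels")
})

test_that("profile difference is a metric on 3-locus category vectors", {
  cats <- c("both", "major_only", "minor_only", "absent")
  space <- expand.grid(a = cats, b = cats, c = cats,
                       stringsAsFactors = FALSE)
  vecs <- lapply(seq_len(nrow(space)), function(i)
    c(rs1 = space$a[i], rs2 = space$b[i], rs3 = space$c[i]))
  n <- length(vecs)  # 64
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- profileDifference(vecs[[i]], vecs[[j]])
  expect_true(all(D >= 0))
  expect_equal(D, t(D))                        # symmetry
  expect_equal(which(D == 0), which(diag(n) == 1))  # identity
  for (k in seq_len(n))                        # triangle inequality
    expect_true(all(D <= outer(D[, k], D[k, ], `+`)))
})

test_that("expected profiles map genotypes to categories", {
  fx <- krt32Fixture()
  geno <- data.frame(individual_id = c("A", "B", "C"),
                     snp_id = "rs2071563",
                     genotype = c("major_hom", "het", "minor_hom"))
  p <- expectedProfiles(geno, fx$snps, "rs2071563")
  expect_equal(unname(phenotypeCategories(p)[1, ]),
               c("major_only", "both", "minor_only"))
  expect_equal(unname(profileFrequencies(p)[1, ]), c(0.91, 0.42, 0.51))
})

test_that("the 3x3x4 design yields 630 comparisons split 54/144/432", {
  manifest <- makeManifest()
  n <- nrow(manifest)
  snps <- data.frame(snp_id = "rs1", gene = "G", protein_accession = "P",
                     residue_position = 5L, major_aa = "T", minor_aa = "M",
                     f_major_hom = 0.49, f_het = 0.42, f_minor_hom = 0.09)
  cat <- buildCatalog(snps, c(P = "MAAATAAKGGGR"))
  st <- matchObservations(makeObservation(manifest$sample_id[1], "MAAATAAK"),
                          cat, manifest)
  cmp <- pairwiseCompare(buildProfiles(st, "rs1"))
  expect_equal(nrow(cmp$comparisons), choose(n, 2))
  expect_equal(nrow(cmp$comparisons), 630L)
  tab <- table(cmp$comparisons$category)
  expect_equal(unname(tab[c("replicate", "within_individual",
                            "between_individual")]),
               c(54L, 144L, 432L), ignore_attr = TRUE)
})

test_that("category sizes follow the design formula for random designs", {
  set.seed(17)
  for (i in 1:5) {
    I <- sample(2:4, 1); L <- sample(2:3, 1); R <- sample(2:4, 1)
    manifest <- makeManifest(I, c("head", "arm", "pubic")[seq_len(L)], R)
    want <- comparisonDesignCounts(I, L, R)
    cats <- bruteForcePairCategories(manifest)
    expect_equal(sum(cats == "replicate"), unname(want["replicate"]))
    expect_equal(sum(cats == "within_individual"),
                 unname(want["within_individual"]))
    expect_equal(sum(cats == "between_individual"),
                 unname(want["between_individual"]))
    expect_equal(length(cats), unname(want["total"]))
    expect_equal(unname(want["total"]), choose(I * L * R, 2))
  }
})

test_that("two samples from one individual and location compare as replicate", {
  manifest <- data.frame(sample_id = c("S1", "S2"), individual_id = "I1",
                         body_location = "head", replicate = 1:2)
  snps <- data.frame(snp_id = "rs1", gene = "G", protein_accession = "P",
                     residue_position = 5L, major_aa = "T", minor_aa = "M",
                     f_major_hom = 0.49, f_het = 0.42, f_minor_hom = 0.09)
  cat <- buildCatalog(snps, c(P = "MAAATAAKGGGR"))
  st <- matchObservations(makeObservation("S1", "MAAATAAK"), cat, manifest)
  cmp <- pairwiseCompare(buildProfiles(st, "rs1"))
  expect_equal(nrow(cmp$comparisons), 1L)
  expect_equal(cmp$comparisons$category, "replicate")
  expect_equal(cmp$comparisons$n_differences, 1L)
})

test_that("identical difference values give no significant pairs", {
  cmp <- data.frame(group = rep(c("replicate", "within_individual",
                                  "between:I1-I2"), each = 10L),
                    n_differences = 3L)
  res <- suppressWarnings(compareCategoryTest(cmp))
  expect_false(any(res$pairwise$significant))
})

test_that("an extreme zero group separates from both five-valued groups", {
  cmp <- data.frame(group = rep(c("g0", "g5a", "g5b"), each = 8L),
                    n_differences = rep(c(0L, 5L, 5L), each = 8L))
  res <- compareCategoryTest(cmp)
  pw <- res$pairwise
  sep <- pw$significant[pw$group1 == "g0" | pw$group2 == "g0"]
  expect_true(all(sep))
  expect_false(pw$significant[pw$group1 == "g5a" & pw$group2 == "g5b"])
})

test_that("groups with fewer than two members are excluded with a warning", {
  cmp <- data.frame(group = c(rep("a", 5), rep("b", 5), "c"),
                    n_differences = c(rnorm(10), 1))
  expect_warning(res <- compareCategoryTest(cmp), "excluding group")
  expect_equal(res$n, 10L)
})

test_that("between-individual separation is detected at study-like effects", {
  # group sizes and means mirroring the study design (8-locus panel,
  # replicate ~1.2 vs between ~5 differences), scaled-down run count
  set.seed(29)
  hits <- 0L
  for (run in 1:50) {
    cmp <- data.frame(
      group = c(rep("replicate", 18), rep("within_individual", 48),
                rep("between:I1-I2", 48)),
      n_differences = c(rbinom(18, 8, 0.15), rbinom(48, 8, 0.13),
                        rbinom(48, 8, 0.62)))
    res <- suppressWarnings(compareCategoryTest(cmp))
    pw <- res$pairwise
    sig <- pw$significant[(pw$group1 == "between:I1-I2" &
                             pw$group2 == "replicate") |
                          (pw$group1 == "replicate" &
                             pw$group2 == "between:I1-I2")]
    if (isTRUE(sig)) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})
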