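# Delimited-table readers and writers: missense SNP annotations, sample
# manifests, exome genotype tables, and peptide-spectrum-match exports.
# All tables are TSV by default, CSV accepted (separator sniffed from the
# header). Residue positions are 1-based throughout.

DEFAULT_LOCATIONS <- c("head", "arm", "pubic")
FREQ_TOL <- 1e-6

#' Validate and finalize a missense SNP table
#'
#' Checks the invariants of a missense SNP annotation table: distinct
#' major/minor amino acids, genotype-frequency triple summing to one, and a
#' minor allele frequency in [0, 0.5]. The MAF is computed from the genotype
#' frequencies (minor-homozygote frequency plus half the heterozygote
#' frequency) when not supplied.
#'
#' @param snps data.frame with columns \code{snp_id}, \code{gene},
#'   \code{protein_accession}, \code{residue_position}, \code{major_aa},
#'   \code{minor_aa}, \code{f_major_hom}, \code{f_het}, \code{f_minor_hom}
#'   and optionally \code{maf}.
#' @return the validated table with a \code{maf} column.
#' @export
validateSnpTable <- function(snps) {
  needed <- c("snp_id", "gene", "protein_accession", "residue_position",
              "major_aa", "minor_aa", "f_major_hom", "f_het", "f_minor_hom")
  miss <- setdiff(needed, names(snps))
  if (length(miss))
    stop(sprintf("SNP table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (col in c("f_major_hom", "f_het", "f_minor_hom"))
    snps[[col]] <- as.numeric(snps[[col]])
  if (!is.null(snps$maf)) snps$maf <- as.numeric(snps$maf)
  snps$residue_position <- as.integer(snps$residue_position)
  if (any(snps$residue_position < 1L))
    stop("residue_position must be a positive 1-based integer", call. = FALSE)
  checkAminoAcids(snps$major_aa, "major_aa")
  checkAminoAcids(snps$minor_aa, "minor_aa")
  same <- snps$major_aa == snps$minor_aa
  if (any(same))
    stop(sprintf("major_aa equals minor_aa for: %s",
                 paste(snps$snp_id[same], collapse = ", ")), call. = FALSE)
  tot <- snps$f_major_hom + snps$f_het + snps$f_minor_hom
  bad <- abs(tot - 1) > FREQ_TOL
  if (any(bad))
    stop(sprintf("genotype frequencies do not sum to 1 for: %s",
                 paste(snps$snp_id[bad], collapse = ", ")), call. = FALSE)
  if (any(snps$f_major_hom < 0 | snps$f_het < 0 | snps$f_minor_hom < 0))
    stop("genotype frequencies must be non-negative", call. = FALSE)
  if (is.null(snps$maf))
    snps$maf <- snps$f_minor_hom + snps$f_het / 2
  if (any(snps$maf > 0.5 + FREQ_TOL))
    stop(sprintf("minor allele frequency exceeds 0.5 for: %s",
                 paste(snps$snp_id[snps$maf > 0.5 + FREQ_TOL], collapse = ", ")),
         call. = FALSE)
  dup <- snps$snp_id[duplicated(snps$snp_id)]
  if (length(dup))
    stop(sprintf("duplicate snp_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  snps
}

#' Read a missense SNP annotation table
#'
#' @param path delimited text file (TSV default, CSV accepted) with the
#'   columns described in [validateSnpTable()]. Identifiers may be rsIDs
#'   (\code{"rs..."}) or HGVS strings for loci without a Reference SNP ID.
#' @param sep field separator, \code{"auto"} to sniff.
#' @return validated SNP data.frame with computed \code{maf}.
#' @export
readSnpTable <- function(path, sep = "auto") {
  validateSnpTable(readDelim(path, sep))
}

#' @rdname readSnpTable
#' @param snps validated SNP table.
#' @export
writeSnpTable <- function(snps, path) writeDelim(snps, path)

#' Read a sample manifest
#'
#' The manifest maps each sample to its individual, body location and
#' replicate number. Sample ids must be unique, as must
#' (individual, location, replicate) triples.
#'
#' @param path delimited file with columns \code{sample_id},
#'   \code{individual_id}, \code{body_location}, \code{replicate}.
#' @param locations allowed body-location labels.
#' @param extensible when TRUE, labels outside \code{locations} are accepted.
#' @param sep field separator, \code{"auto"} to sniff.
#' @return validated manifest data.frame.
#' @export
readManifest <- function(path, locations = DEFAULT_LOCATIONS,
                         extensible = FALSE, sep = "auto") {
  validateManifest(readDelim(path, sep), locations, extensible)
}

#' @rdname readManifest
#' @param manifest manifest data.frame.
#' @export
validateManifest <- function(manifest, locations = DEFAULT_LOCATIONS,
                             extensible = FALSE) {
  needed <- c("sample_id", "individual_id", "body_location", "replicate")
  miss <- setdiff(needed, names(manifest))
  if (length(miss))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  manifest$replicate <- as.integer(manifest$replicate)
  if (any(is.na(manifest$replicate)) || any(manifest$replicate < 1L))
    stop("replicate must be a positive integer", call. = FALSE)
  if (!extensible) {
    unknown <- setdiff(unique(manifest$body_location), locations)
    if (length(unknown))
      stop(sprintf("unknown body location(s): %s (use extensible = TRUE to allow)",
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest", call. = FALSE)
  key <- paste(manifest$individual_id, manifest$body_location,
               manifest$replicate)
  if (anyDuplicated(key))
    stop("duplicate (individual, location, replicate) in manifest",
         call. = FALSE)
  manifest
}

#' @rdname readManifest
#' @export
writeManifest <- function(manifest, path) writeDelim(manifest, path)

#' Read an exome genotype table
#'
#' @param path delimited file with columns \code{individual_id},
#'   \code{snp_id}, \code{genotype}; genotype one of \code{major_hom},
#'   \code{het}, \code{minor_hom}.
#' @param sep field separator, \code{"auto"} to sniff.
#' @return long-format genotype data.frame.
#' @export
readGenotypes <- function(path, sep = "auto") {
  g <- readDelim(path, sep)
  needed <- c("individual_id", "snp_id", "genotype")
  miss <- setdiff(needed, names(g))
  if (length(miss))
    stop(sprintf("genotype table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- !g$genotype %in% GENOTYPE_LEVELS
  if (any(bad))
    stop(sprintf("invalid genotype value(s): %s",
                 paste(unique(g$genotype[bad]), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(paste(g$individual_id, g$snp_id)))
    stop("duplicate (individual, SNP) rows in genotype table", call. = FALSE)
  g
}

#' @rdname readGenotypes
#' @param genotypes genotype data.frame.
#' @export
writeGenotypes <- function(genotypes, path) writeDelim(genotypes, path)

## Genotype lookup: returns genotype for (individual, snp), erroring on gaps.
genotypeLookup <- function(genotypes, individuals, snpIds) {
  key <- paste(genotypes$individual_id, genotypes$snp_id, sep = "\r")
  want <- paste(individuals, snpIds, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx)) {
    missing <- unique(paste0("(", individuals[is.na(idx)], ", ",
                             snpIds[is.na(idx)], ")"))
    stop(sprintf("missing genotype for: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  genotypes$genotype[idx]
}

#' Describe the column layout of a PSM export
#'
#' Peptide-spectrum-match exports differ in column naming between search
#' engines; a dialect maps the mandatory fields onto the file's columns so
#' exports can be adapted without code changes.
#'
#' @param sample,peptide,modifications,accession,area column names in the
#'   export holding the sample id, peptide string (optionally with
#'   flanking-residue notation), inline modification annotation, protein
#'   accession(s), and precursor ion peak area.
#' @param accessionSep separator between multiple accessions in one cell.
#' @param sep field separator of the file, \code{"auto"} to sniff.
#' @return a named list usable as the \code{dialect} of [readPsmTable()].
#' @export
psmDialect <- function(sample = "sample_id", peptide = "peptide",
                       modifications = "modifications",
                       accession = "protein_accessions",
                       area = "precursor_area",
                       accessionSep = ";", sep = "auto") {
  list(sample = sample, peptide = peptide, modifications = modifications,
       accession = accession, area = area, accessionSep = accessionSep,
       sep = sep)
}

#' Read a peptide-spectrum-match table
#'
#' Reads a per-sample peptide observation export. Peptide strings are
#' stripped of flanking-residue notation (\code{"R.LEGEINTYR.A"} ->
#' \code{"LEGEINTYR"}), modification annotations are validated, and rows
#' with missing or zero peak area are admitted with area 0. Rows whose
#' modification annotation cannot be parsed are skipped, counted, and
#' reported via a warning and the \code{"n_skipped"} attribute.
#'
#' @param path delimited text export.
#' @param dialect column mapping from [psmDialect()].
#' @return data.frame of peptide observations with canonical columns
#'   \code{sample_id}, \code{sequence}, \code{modifications},
#'   \code{protein_accessions}, \code{precursor_area}; attribute
#'   \code{n_skipped} gives the number of rows dropped for parse errors.
#' @export
readPsmTable <- function(path, dialect = psmDialect()) {
  raw <- readDelim(path, dialect$sep)
  mandatory <- c(dialect$sample, dialect$peptide, dialect$accession)
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop(sprintf("PSM table is missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  n <- nrow(raw)
  mods <- if (dialect$modifications %in% names(raw))
    as.character(raw[[dialect$modifications]]) else rep("", n)
  area <- if (dialect$area %in% names(raw))
    suppressWarnings(as.numeric(raw[[dialect$area]])) else rep(0, n)
  area[is.na(area)] <- 0
  if (any(area < 0))
    stop("negative precursor area in PSM table", call. = FALSE)
  obs <- data.frame(
    sample_id = trimws(as.character(raw[[dialect$sample]])),
    sequence = stripFlanks(trimws(toupper(as.character(raw[[dialect$peptide]])))),
    modifications = trimws(mods),
    protein_accessions = gsub("\\s", "",
                              as.character(raw[[dialect$accession]])),
    precursor_area = area,
    stringsAsFactors = FALSE
  )
  if (nrow(obs)) checkAminoAcids(obs$sequence, "peptide sequences")
  bad <- vapply(obs$modifications, function(m) {
    inherits(tryCatch(parseModifications(m), error = identity), "error")
  }, logical(1), USE.NAMES = FALSE)
  if (any(bad)) {
    warning(sprintf("skipped %d PSM row(s) with unparseable modifications",
                    sum(bad)))
    obs <- obs[!bad, , drop = FALSE]
    rownames(obs) <- NULL
  }
  empty <- !nzchar(obs$sequence)
  if (any(empty)) stop("empty peptide sequence in PSM table", call. = FALSE)
  attr(obs, "n_skipped") <- sum(bad)
  obs
}

#' @rdname readPsmTable
#' @param observations canonical observation data.frame.
#' @export
writePsmTable <- function(observations, path) {
  out <- observations
  names(out)[names(out) == "sequence"] <- "peptide"
  writeDelim(out, path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys override the defaults returned when
#'   \code{path} is NULL (catalog parameters, matching flags, PSM dialect
#'   column names, panel options, seed).
#' @return configuration list.
#' @importFrom yaml read_yaml
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(
    maxMissed = 3L, prolineRule = FALSE, semiSpecific = FALSE,
    minLength = 5L, maxLength = 50L,
    ilEquiv = TRUE, strictConfounded = FALSE,
    locations = DEFAULT_LOCATIONS,
    dialect = psmDialect(),
    seed = 1L
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
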