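---
title: "Inferring SNPs from genetically variant peptides: methods and design"
author: "GVPprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring SNPs from genetically variant peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GVPprofiler)
```

## The inference problem

A missense SNP substitutes one amino acid in a protein. When that protein
is recovered from a hair shaft and digested with trypsin, the peptide
spanning the variant site carries either the major-allele or the
minor-allele residue; observing one of these *genetically variant peptides*
(GVPs) by LC-MS/MS is evidence about the donor's genotype at that SNP.
Because peptide detection in data-dependent acquisition is stochastic —
a GVP may simply not be selected for fragmentation in a given run — the
inference is deliberately conservative: detection states are reduced to a
four-level phenotype category per (sample, locus), and population
frequencies are attached to categories, not to hard genotype calls.

The pipeline has five stages, each usable on its own:
catalog construction, observation matching, exome-consistency panel
selection, profile scoring, and label-free abundance analysis. A
synthetic-data generator provides the inputs for validation.

## Catalog construction

`buildCatalog()` digests both allele forms of each variant protein and
keeps every peptide window covering the variant site.

* **Cleavage model.** Trypsin cleaves after K and R. The proline rule
  (no cleavage before P) is available but **off by default**: permissive
  digestion maximizes candidate recall, and observed peptide sets from
  hair digests include peptides on both sides of K/R-P junctions. The
  flag exists for users who want the stricter rule.
* **Missed cleavages.** Default `maxMissed = 3`. Hair keratins digest
  inefficiently (coiled-coil cores are poorly accessible), so peptides
  with up to three internal uncut K/R sites are routinely identified and
  three missed cleavages is the setting used in single-hair peptide
  identification workflows.
* **Length bounds.** Peptides of 5–50 residues are retained. Shorter
  peptides are rarely identifiable with confidence and longer ones fall
  outside typical precursor selection; the bounds are practical
  detectability limits, not biological ones.
* **Window union.** A variant that creates or removes a K/R site (e.g. a
  G→R substitution) changes the digest of one allele but not the other.
  The catalog takes the union of site-covering windows over the two
  alleles and emits both allele forms for every window, so major and
  minor records always align coordinate-for-coordinate; a record whose
  window is not fully tryptic in its own allele is flagged
  `semi_specific`. This keeps the major/minor window sets identical — an
  invariant the matcher and profiler rely on.
* **Semi-specific truncations.** Keratin-associated proteins yield many
  non-tryptic peptides (cleavage after cysteine or serine is observed in
  their Cys/Ser-rich repeats). With `semiSpecific = TRUE`, every
  single-terminus truncation of a site-covering window (length ≥ 5) is
  admitted as a candidate. Off by default, because fully tryptic
  catalogs are much smaller and cover the common case.
* **Ambiguity flags.** Isoleucine and leucine are isobaric and
  indistinguishable by low-energy CID/HCD fragmentation, so an I/L
  variant yields `discriminative = FALSE` records. If one allele's
  peptide can arise from the other's by deamidation (major N with minor
  D, or Q with E), the mimicked record is flagged
  `modification_confounded`; with `strictConfounded = TRUE` the matcher
  then requires site-clean evidence (no deamidation reported at the
  variant position).
* **Multi-variant windows.** When two catalog SNPs fall inside one
  peptide window (as happens in keratin-associated-protein gene
  clusters), the records are flagged `shared_window` but the evidence is
  not partitioned between the loci — resolving shared-peptide evidence
  among linked SNPs would require haplotype modelling that is out of
  scope.

## Matching and detection states

Matching is exact full-sequence equality of bare peptides (modifications
stripped), after I→L collapse when `ilEquiv = TRUE` (default). Presence
of a single PSM suffices for a detection: no area or count threshold is
applied, because any such threshold would trade false negatives for false
positives in a way the downstream consistency filters already handle
explicitly. Precursor areas are ignored here and used only by the
abundance module.

## Panel selection

`classifyCalls()` scores each (sample, SNP, allele form) against the
individual's exome genotype: an allele is *present* unless the individual
is homozygous for the other allele, and calls are TP/FN/FP/TN
accordingly. `selectPanel()` then applies ordered filters:

1. **False-positive removal.** Any SNP with ≥ 1 FP call for *either*
   allele form anywhere is removed. A SNP whose minor form draws FPs is
   removed even if its major form is clean: an FP indicates the GVP
   sequence is not specific to the allele (or the catalog is wrong), and
   that affects the locus as a marker, not just one form.
2. **All-sample consistency.** A SNP survives if, for at least one allele
   form, every call across all samples is TP or TN. These are the loci
   with the lowest false-negative rates, hence the best chance of
   appearing in every specimen.
3. **Overlap merge.** The major-consistent and minor-consistent lists are
   merged into one locus list.
4. **rsID requirement.** Loci without a Reference SNP ID are dropped —
   without one, population genotype frequencies are unavailable and the
   locus cannot contribute to a match probability.
5. **One SNP per gene.** Within a gene, the SNP with the lowest minor
   allele frequency is kept (ties broken by lexicographically smallest
   id, which never occurs with real frequency data). This is a
   conservative guard against linkage disequilibrium between markers in
   one gene; explicit LD modelling is out of scope.

Filters 4 and 5 commute in effect only if every gene's lowest-MAF SNP has
an rsID; applying the rsID filter first (as here) guarantees the kept SNP
is usable, and makes the intermediate counts reproducible.

## Profile scoring

The observed phenotype frequency at a locus is a sum of population
genotype frequencies consistent with what was seen: `major_only` scores
f_MM + f_Mm, `minor_only` scores f_mm + f_Mm, and absent loci carry no
frequency and are skipped. For **both forms detected** the unique
consistent genotype is the heterozygote, so the category scores f_Mm;
this is the only category whose frequency is not a sum, and it is also
what makes expected profiles (below) well defined. The RMP is the product
of frequencies over non-absent loci; a profile with every locus absent
has *no* RMP (returned as `NA` with a warning, never 1).

**Expected profiles** assume every GVP consistent with the genotype is
detected: homozygotes show one form, heterozygotes both. Under zero-noise
simulation the observed profile equals the expected profile exactly, a
property the test suite checks end to end. Expected profiles take no
account of detection dropout; they are the full-detection benchmark
against which observed RMPs are compared.

**Profile differences** count loci whose categories differ, with
absent-vs-detected counting as a difference even though absent loci are
skipped in the RMP — the two rules serve different statistics (profile
similarity vs match probability) and are kept independent. The difference
is a metric on category vectors (symmetry, identity, triangle
inequality), verified exhaustively over all 4³ category vectors on
three-locus panels.

Comparison categories follow the design: replicate (same individual and
body location), within-individual (same individual, different location),
between-individual. For a balanced I × L × R design the category sizes
are I·L·C(R,2), I·(C(LR,2) − L·C(R,2)) and C(I,2)·(LR)²; the 3 × 3 × 4
study design gives 54 + 144 + 432 = 630 pairs. Group variation is tested
with a Kruskal–Wallis omnibus over five groups (replicate, within, and
one group per individual pair) and Dunn's rank-based post-hoc z tests
with tie correction and Bonferroni adjustment. The Dunn test is
implemented in the package (the standard 1964 statistic); the omnibus
test, ANOVA, Tukey HSD and correlation tests come from `stats`.

## Abundance analysis

Duplicate PSMs of one peptide in a sample are collapsed to the maximum
area — robust to repeated sampling of one precursor, and insensitive to
the unknown number of MS scans per peptide. Each unique peptide's area is
divided by the per-sample total (removing on-column load differences: any
per-sample rescaling of raw areas leaves the table unchanged, verified to
1e-12), and protein abundance is the sum over assigned peptides. Peptides
shared between accessions contribute to each and are flagged; the
normalization denominator counts each unique peptide once regardless of
how many proteins it maps to, so shared peptides inflate protein sums but
not the scale. Differential expression uses a per-protein two-way ANOVA
(location, individual, interaction) with Tukey HSD location contrasts;
proteins missing from a sample enter as zeros so presence/absence
proteins are comparable, and constant proteins are skipped with a note.

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes:

* **Design:** 3 individuals × {head, arm, pubic} × 4 replicates
  (36 samples), the single-hair study layout.
* **Loci:** default 30 missense SNPs — between the 8-SNP panel scale and
  the several dozen loci that survive false-positive screening in real
  hair data. MAFs are drawn uniformly on [0.05, 0.5] and genotypes follow
  Hardy–Weinberg proportions. About 10% of loci get HGVS-style
  identifiers instead of rsIDs and about 15% share a gene with another
  SNP, so panel filters 4 and 5 are exercised.
* **Variant sites** use amino-acid pairs excluding I/L and the
  deamidation-confusable N/D and Q/E pairs, so simulated panel loci are
  discriminative — as the loci that survive into real panels are.
* **Detection:** each carried GVP is observed with probability
  `sensitivity` (default 0.9, a realistic per-peptide detection rate for
  moderately abundant hair peptides under data-dependent acquisition),
  independently per GVP and sample. Independence is the simplest faithful
  model of the acquisition stochasticity that causes dropout; it omits
  run-to-run chromatographic correlation, so simulated replicates are
  slightly *more* independent than real ones. False positives are off by
  default (`falsePositiveRate = 0`) and available for robustness studies.
* **Areas** are log-normal (meanlog = log 1e7, sdlog = 1, matching the
  10⁶–10⁸ precursor-area range of hair peptides); location effects act
  multiplicatively on the means of a 20% subset of background proteins
  (arm × 0.5, pubic × 2), mirroring location-specific differential
  expression with pubic-enriched, arm-depleted proteins.
* **Not modelled:** spectra, retention time, charge states, PTM-bearing
  observations, chimeric or mis-assigned PSMs, and correlated dropout.
  Passing tests therefore validate the analytic machinery under the
  stated statistical assumptions — they do not certify performance on
  real spectra, where search-engine error and correlated detection enter.

All randomness flows from one mandatory seed; the same seed reproduces
byte-identical artifacts.

## Numerical and degenerate-input choices

* Genotype-frequency triples must sum to 1 within 1e-6; MAF is computed
  as f_mm + f_Mm/2 and must not exceed 0.5.
* Frequencies attached to profiles lie in (0, 1]; absent loci are NA by
  construction and validity checks enforce this.
* Ties in Dunn's test use the standard tie correction; fully tied data
  yield z = 0 (no separation) rather than 0/0.
* Empty inputs degrade gracefully: empty FASTA → empty set with warning;
  empty observation list → all-absent states; zero-total-area samples are
  excluded from quantification with a warning; all-absent profiles have
  undefined RMP.
* Reference mismatches (stale SNP coordinates) and missing genotypes are
  hard errors naming the offending locus or pair — silent coordinate
  drift is the classic failure mode of variant-to-protein mapping.

## Problem sizes in the test suite

The suite validates digestion against a brute-force window enumerator on
200 random sequences (length ≤ 80, up to 4 missed cleavages, both proline
settings), panel selection against hand-applied filters on a 10-SNP
fixture, metric axioms exhaustively on 3-locus panels, zero-noise
end-to-end recovery on an 8-locus study, and dropout calibration on 2000
simulated replicate pairs against the exactly enumerated per-genotype
mismatch probability. These sizes give tight oracle agreement while
keeping the default test run around half a minute.

## Known limitations

* Shared-peptide evidence among linked SNPs is flagged, not resolved.
* Expected profiles ignore dropout; observed-vs-expected RMP gaps grow
  as sensitivity falls.
* The RMP assumes marker independence; the one-SNP-per-gene rule reduces
  but does not eliminate LD effects, and no population-substructure
  (theta) correction is applied.
* Matching is exact-sequence only; a semi-specific observed form matches
  only if the corresponding record exists in the catalog.

## Session info

```{r}
sessionInfo()
```
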