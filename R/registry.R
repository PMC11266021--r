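# Locus registries for the KIR gene cluster and the classical HLA loci.
#
# The KIR complex is a copy-number-variable cluster delimited by four
# framework genes (KIR3DL3 ... KIR3DP1 | KIR2DL4 ... KIR3DL2) that split it
# into a centromeric and a telomeric segment. Several genes occur as
# positional variants (KIR2DL5A/B, cen/tel copies of KIR2DS3 and KIR2DS5,
# and the wt/Del forms of KIR2DS4); copy numbers are tracked per positional
# variant while allele names follow IPD-KIR gene-level nomenclature.

# KIR loci that carry IPD-KIR allele names
.kir_allele_loci <- c(
  "KIR3DL3", "KIR2DS2", "KIR2DL2", "KIR2DL3", "KIR2DP1", "KIR2DL1",
  "KIR3DP1", "KIR2DL4", "KIR3DL1", "KIR3DS1", "KIR2DL5", "KIR2DL5A",
  "KIR2DL5B", "KIR2DS3", "KIR2DS5", "KIR2DS1", "KIR2DS4", "KIR3DL2"
)

# copy-number loci measured per individual (one cohort column each)
.kir_cnv_loci <- c(
  "KIR3DL3", "KIR2DS2", "KIR2DL2", "KIR2DL3", "KIR2DP1", "KIR2DL1",
  "KIR3DP1", "KIR2DL4", "KIR3DL1", "KIR3DS1", "KIR2DL5A", "KIR2DL5B",
  "KIR2DS3C", "KIR2DS3T", "KIR2DS5C", "KIR2DS5T", "KIR2DS1",
  "KIR2DS4wt", "KIR2DS4Del", "KIR3DL2"
)

# union loci: copy number computed as the sum of their positional parts
.kir_union_loci <- list(
  KIR2DL5 = c("KIR2DL5A", "KIR2DL5B"),
  KIR2DS3 = c("KIR2DS3C", "KIR2DS3T"),
  KIR2DS5 = c("KIR2DS5C", "KIR2DS5T"),
  KIR2DS4 = c("KIR2DS4wt", "KIR2DS4Del")
)

# framework genes: present on essentially every haplotype
.kir_framework_loci <- c("KIR3DL3", "KIR3DP1", "KIR2DL4", "KIR3DL2")

# nomenclature locus under which each cnv locus's alleles are named
.kir_cnv_allele_locus <- c(
  KIR3DL3 = "KIR3DL3", KIR2DS2 = "KIR2DS2", KIR2DL2 = "KIR2DL2",
  KIR2DL3 = "KIR2DL3", KIR2DP1 = "KIR2DP1", KIR2DL1 = "KIR2DL1",
  KIR3DP1 = "KIR3DP1", KIR2DL4 = "KIR2DL4", KIR3DL1 = "KIR3DL1",
  KIR3DS1 = "KIR3DS1", KIR2DL5A = "KIR2DL5A", KIR2DL5B = "KIR2DL5B",
  KIR2DS3C = "KIR2DS3", KIR2DS3T = "KIR2DS3", KIR2DS5C = "KIR2DS5",
  KIR2DS5T = "KIR2DS5", KIR2DS1 = "KIR2DS1", KIR2DS4wt = "KIR2DS4",
  KIR2DS4Del = "KIR2DS4", KIR3DL2 = "KIR3DL2"
)

.hla_loci <- c("A", "B", "C", "DRB1", "DRB3", "DRB4", "DRB5",
               "DQA1", "DQB1", "DPA1", "DPB1", "G")

# cohort HLA genotype slots; DRB345 holds whichever of DRB3/4/5 is present
.hla_cohort_loci <- c("A", "B", "C", "DRB1", "DRB345", "DQA1", "DQB1", "G")

# pseudo-locus for the HLA-G 14-bp insertion/deletion 3'UTR variant
.hlag14_locus <- "HLAG14BP"
.hlag14_alleles <- c("INS", "DEL")

#' Locus registries
#'
#' Accessors for the locus registries used throughout the package: KIR
#' copy-number loci (including the cen/tel positional variants of KIR2DS3
#' and KIR2DS5, the A/B copies of KIR2DL5 and the wt/Del forms of KIR2DS4),
#' the derived union loci, the four framework genes, and the HLA loci held
#' in a cohort.
#'
#' @return Character vector of locus names (`kir_union_loci()` returns a
#'   named list mapping each union locus to its parts).
#' @export
kir_cnv_loci <- function() .kir_cnv_loci

#' @rdname kir_cnv_loci
#' @export
kir_union_loci <- function() .kir_union_loci

#' @rdname kir_cnv_loci
#' @export
kir_framework_loci <- function() .kir_framework_loci

#' @rdname kir_cnv_loci
#' @export
hla_cohort_loci <- function() .hla_cohort_loci

# all markers accepted as a bare locus-presence marker
.presence_loci <- function() c(.kir_cnv_loci, names(.kir_union_loci))
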