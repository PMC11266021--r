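---
title: "Methods: HLA/KIR case-control association with kirhla"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA/KIR case-control association with kirhla}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirhla)
```

## The analysis problem

`kirhla` implements a case-control association workflow for the two most
polymorphic immune gene complexes in the human genome: the HLA loci
(class I A, B, C, G and class II DRB1/3/4/5, DQA1, DQB1) and the KIR
cluster. KIR genes are special in two ways that shape every design choice
in this package. First, the cluster is copy-number variable: haplotypes
differ in gene content, organized as a centromeric and a telomeric
segment delimited by four framework genes (KIR3DL3, KIR3DP1, KIR2DL4,
KIR3DL2) that are present on essentially every haplotype. Association
must therefore be tested at three levels — gene presence, integer copy
number, and allele carriage within carriers. Second, most KIR receptors
are only functional in individuals who also carry the cognate HLA class I
ligand (the A3/A11, Bw4-80I/80T, and C1/C2 motifs), which motivates
receptor-ligand pair tests and a summed signed interaction score.

The package covers the full workflow: allele nomenclature, a cohort data
model, nearest-neighbour control matching in principal-component (PC)
space, PC-adjusted logistic association with iterative conditioning and
multiple-testing control, fixed-effect meta-analysis across ancestry
strata, and a synthetic-cohort generator used to validate every step.

## Nomenclature and protein-level grouping

HLA alleles are handled at two-field (protein-level) resolution; deeper
resolution is truncated before any comparison. KIR alleles are digit
strings whose first three digits identify the protein, so
`protein_group()` collapses e.g. KIR2DL4\*00103 and KIR2DL4\*00102 into
the protein group KIR2DL4\*001 — the level at which "alleles with amino
acid changes" are compared. Genotype ambiguities (several allele sets
compatible with sequencing data) are resolved by `resolve_ambiguity()` to
the candidate with the largest *product* of population frequencies. The
joint product (rather than, say, the maximum single-allele frequency) is
the natural choice when candidate sets are interpreted as independent
draws from the population pool; it is also the only scheme that is
monotone in every member allele. Alleles missing from the reference
table receive a floor frequency of 1e-6 so that unlisted sets lose to
any listed set but still compare deterministically among themselves;
exact ties break lexicographically on the sorted canonical names.

## Cohort model

A cohort stores, per individual: phenotype (case/control), tumour
subgroup (teratoma / other tumour / non-paraneoplastic / unknown),
ancestry and genotyping-platform labels (their combination is the
analysis stratum), diploid HLA calls, per-locus KIR copy numbers with
allele multisets (`"cn:allele1,allele2"` tokens on disk; the multiset
size must equal the copy number), the HLA-G 14-bp ins/del genotype, and
PC coordinates in PLINK `.eigenvec` layout. Copy numbers are tracked for
the positional variants separately (KIR2DL5A/B; cen/tel copies of
KIR2DS3 and KIR2DS5; KIR2DS4 full-length vs the 22-bp deletion form),
with union loci (KIR2DL5, KIR2DS3, KIR2DS5, KIR2DS4) computed as sums.
Missing HLA calls are excluded per marker (complete-case); carrier
denominators count individuals with a non-missing call at the locus, and
DRB3/4/5 absence is treated as a valid (non-missing) state.

## Control matching

`match_controls()` reproduces the standard PC-matching step: each case
receives its `k` nearest controls (default 10) by Euclidean distance on
the leading PCs (default 10), restricted to controls of the same
ancestry-by-platform stratum. Matching is without replacement by
default, because re-used controls would silently inflate the effective
sample size; since greedy without-replacement matching depends on case
order, cases are processed in a seeded random order so no case
systematically gets first pick. Distance ties break on control id.
With replacement, the result is provably order-independent and equals
exhaustive nearest-neighbour search, which the test suite verifies
against a brute-force oracle.

## Association engine

The basic test is a maximum-likelihood logistic regression of case
status on a coded marker plus the first three PCs, with a Wald p-value.
Wald (rather than likelihood-ratio) tests are used because they are what
standard GLM summaries report and they make the per-marker effect, SE
and p internally consistent (`OR = exp(beta)` exactly). Markers can be
coded as carrier indicators (>= 1 copy), integer copy numbers, or
interaction scores. Three numerical safeguards matter in this data type:

* **Separation / zero variance.** Rare KIR alleles frequently separate
  perfectly or are monomorphic in a stratum. Such fits are flagged
  unestimable and *excluded from the multiple-testing family* rather
  than assigned p = 1, mirroring the field practice of dropping
  low-frequency alleles.
* **Collinearity under conditioning.** Gene-content loci on the same
  haplotype segment can be in perfect LD. Before fitting, the marker is
  checked (by QR rank) against the covariate block; a marker that adds
  no rank is unestimable. Without this check, the fit would silently
  drop the conditioning covariate and re-report the unconditional
  effect, defeating the purpose of conditioning.
* **Frequency threshold.** Only markers with carrier frequency >= 5% in
  cases or controls enter the adjustment family (Benjamini-Hochberg FDR
  by default, Bonferroni for the HLA family); rarer markers are reported
  unadjusted and flagged exploratory.

`conditional_scan()` separates independent signals from linkage: it
repeatedly fits all remaining markers with the previously selected
markers as covariates and moves the most significant marker (by adjusted
p, default threshold 0.05) into the conditioning set until nothing
remains significant. The trace is deterministic given the cohort; ties
break on marker name.

Tumour-subgroup contrasts are expressed through the carrier-frequency
groups (`teratoma`, `non_teratoma`) and by fitting on subsets, covering
both teratoma-vs-non-teratoma and each-vs-controls designs.

## Receptor-ligand model

The bundled motif table assigns two-field HLA-A/B/C alleles to A3, A11,
Bw4-80I, Bw4-80T, C1 or C2 (every HLA-C allotype is C1 or C2 by the
residue-80 dimorphism; B\*46:01 and B\*73:01 carry C1; class II alleles
are never ligands). An effective pair exists when the receptor gene is
carried and the ligand state is satisfied; patterns include single
motifs and composite HLA-C states (C1_C1, C1_C2, C2_C2), because
inhibitory input through KIR2DL2/3 depends on C1 dose as well as
presence. The signed weight table (magnitude 1-3, inhibitory or
activating per pair) is a *configuration file*, not a fitted model: the
scoring scheme's form is fixed but its values are conventional, so the
bundled defaults (e.g. KIR2DL1-C2 inhibitory 3, KIR2DS1-C2 activating 2,
with Bw4 split into 80I/80T and collapsible via
`load_score_table(collapse_bw4 = TRUE)`) can be replaced file-for-file
without code change. Scores sum to a total inhibitory score, a total
activating score, and net = activating - inhibitory. Score association
uses both a logistic GLM of phenotype on the score and a
proportional-odds ordinal regression of the score on phenotype (both PC
adjusted); with a two-level score the ordinal model degenerates exactly
to a logistic fit, which is implemented as such.

## Meta-analysis

Per-stratum effects are combined by inverse-variance (SE-weighted)
fixed-effect meta-analysis — the scheme appropriate when per-stratum
effects and SEs are available — with Cochran's Q on k-1 df for
heterogeneity and a per-stratum direction string ("+" non-negative, "-"
negative, "?" not examined; the sign of an exact zero renders "+" by a
fixed convention). Before each stratum fit, PCs are recomputed within
the stratum (SVD of the centred coordinates) so that adjustment uses
axes of variation specific to that ancestry group. Strata with
unestimable fits contribute "?" and are excluded from weighting.

## The synthetic-cohort generator

`simulate_cohort()` generates the structure the analyses assume, and its
defaults are fixed study conditions, not tuning knobs:

* **KIR haplotypes.** Two centromeric and two telomeric segments per
  individual, drawn from gene-content haplotypes per ancestry: cenA
  (KIR2DL3/2DP1/2DL1) versus cenB variants carrying
  KIR2DS2/2DL2/2DL5B with either KIR2DS3C or KIR2DS5C; telA with
  full-length or deleted KIR2DS4 versus telB variants carrying
  KIR3DS1/2DL5A/2DS1 with either KIR2DS5T or KIR2DS3T. Framework genes
  ride every segment, so their copy number is always 2. Segment
  frequencies are illustrative, loosely informed by published European
  control frequencies (KIR2DL5B gene presence near 20%, KIR2DL4\*00103
  carriage near 12%); they are defaults to exercise the machinery, not
  population estimates. A consequence worth knowing when interpreting
  results: loci on the same segment set (e.g. KIR2DL5B and KIR2DS2) are
  in perfect LD in simulated data, which real cohorts only approximate.
* **HLA.** The class II block is drawn from a haplotype table (including
  DRB1\*01:01~DQA1\*01:01~DQB1\*05:01) with an independent residual pool
  standing in for recombinants; class I, DRB3/4/5 and HLA-G alleles are
  independent per-locus draws. Class I pools only include alleles
  covered by the bundled motif table.
* **Population structure.** Three ancestry clusters at fixed PC
  centroids separated by 15 within-cluster SDs (centroid distance 6,
  SD 0.4), echoing discrete ethnic groups; this makes stratum-restricted
  matching and stratified regression meaningfully testable.
* **Disease model.** Phenotypes are assigned by rejection sampling from
  `P(case) = plogis(intercept + sum(log_OR * coding))` with carrier or
  additive-copy coding per planted effect, until the case and control
  quotas fill; an unreachable quota (extreme intercept) errors after a
  capped number of rounds instead of spinning. Everything is
  reproducible from a single seed.

What the generator does *not* emulate: within-segment recombination,
realistic LD decay between HLA and KIR (they are simulated as unlinked,
as they are in reality on chromosomes 6 and 19), allele-level linkage to
segment background, and genotyping error. Passing tests therefore
demonstrate the statistical machinery under clean conditions, not
robustness to real-data artefacts.

## Validation design and problem sizes

The test suite validates each estimator against an independent oracle:
unadjusted logistic fits against the closed-form 2x2 log-OR, matching
against exhaustive search, the meta-analysis against closed-form
algebra (and `metafor`'s fixed-effect implementation), BH adjustment
against the hand-computed step-up. Calibration and recovery use the
generator: type-I error is estimated from 2,000 null marker tests
(cohorts of 2,000 cases + 2,000 controls), and planted carrier log-ORs
of 0.4/0.7/1.1 plus an additive copy-number effect of 0.54 are required
to be recovered with mean absolute bias below 0.05 over 100 replicates
at n = 20,000. For null and recovery simulations the model intercept is
set to 0 so that case and control quotas fill at comparable rates — a
balanced-sampling design choice; the logistic effect estimate is
invariant to the intercept under case-control sampling. The worked
examples reconstruct published carrier counts (82/323 vs 190/1519;
17/323 vs 20/1519) and verify the reported frequencies exactly at
printed precision.

## Limitations

Adjusted odds ratios from the original multi-ethnic patient data cannot
be reproduced here because the individual-level genotypes are not
public; the acceptance surface is therefore the synthetic reproduction
plus the count-level worked examples. Firth-penalized regression is not
implemented (rare-allele effects rely on the unestimable-flagging
policy instead), the meta-analysis is fixed-effect only, and the score
table ships with conventional rather than fitted weights.
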