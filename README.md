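# kirhla

Case-control association analysis for the HLA and KIR immune gene
complexes.

Natural-killer-cell receptors encoded in the KIR cluster recognize
subsets of HLA class I allotypes, and both gene families are prime
candidates in autoimmune and infection-associated neurological disease —
anti-NMDA-receptor encephalitis being the motivating example. Testing
them jointly is statistically awkward: the KIR cluster is copy-number
variable (haplotypes differ in gene content, organized into centromeric
and telomeric segments delimited by four framework genes), alleles are
only comparable after protein-level grouping, receptors are functional
only alongside their HLA ligand (A3/A11, Bw4-80I/80T, C1/C2 motifs), and
multi-ethnic cohorts demand PC-matched controls with per-ancestry
analysis combined by meta-analysis. `kirhla` packages that entire
workflow for geneticists running sequencing-based KIR/HLA case-control
studies.

## What it computes

For a marker *m* coded as a carrier indicator, an integer copy number,
or an interaction score, the core model is the PC-adjusted logistic
regression

    logit P(case) = b0 + beta * x_m + g1 PC1 + g2 PC2 + g3 PC3,

reported as OR = exp(beta) with Wald tests, a 5% carrier-frequency
family for FDR/Bonferroni adjustment, and iterative conditioning (refit
with previously significant markers as covariates) to separate
independent signals from linkage. Per-stratum effects are combined by
inverse-variance fixed-effect meta-analysis, w_i = 1/se_i^2, with
Cochran's Q heterogeneity and per-cohort direction strings. A
receptor-ligand layer classifies HLA alleles into KIR-ligand motifs,
enumerates effective pairs (receptor carried and ligand present) and
sums configurable signed weights (1-3, inhibitory vs activating) into
per-individual inhibitory / activating / net scores. A synthetic-cohort
generator with cen/tel KIR haplotype structure, HLA linkage blocks,
ancestry PC clusters and planted logistic effects underpins validation.

## Worked example

Simulate a cohort at the scale of a sequenced encephalitis study
(323 cases, 1,519 controls, three ancestry strata) with two planted
effects — a carrier effect on the KIR2DL4\*00103 allele (OR 1.98) and an
additive copy-number effect on KIR2DL5B (OR 1.72/copy) — then match,
test, and condition:

```r
library(kirhla)

eff <- effect_config(intercept = -2,
                     marker = c("KIR2DL4*00103", "KIR2DL5B"),
                     coding = c("carrier", "additive_copy"),
                     log_or = c(log(1.98), log(1.72)))
cohort  <- simulate_cohort(eff = eff, n_cases = 323, n_controls = 1519, seed = 42)
m       <- match_controls(cohort, cohort, k = 4, seed = 42)
matched <- apply_match(cohort, m)

assoc_logistic(matched, "KIR2DL4*00103")
#>     beta     se or_value     p case_freq control_freq
#> 1 0.5646 0.1636   1.7588 6e-04    0.1981       0.1231

assoc_cnv(matched, "KIR2DL5B")$additive
#>     beta     se or_value     p
#> 1 0.5126 0.1301   1.6697 1e-04

conditional_scan(matched, c("KIR2DL4*00103", "KIR2DL5B", "KIR2DS2"))
#>   iteration        marker      beta or_value            p        p_adj conditioned_on
#> 1         1 KIR2DL4*00103 0.5646489 1.758830 0.0005564310 0.0008020141
#> 2         2      KIR2DL5B 0.4853762 1.624786 0.0008227926 0.0008227926  KIR2DL4*00103
```

Both planted signals are recovered near their planted sizes (OR 1.76
and 1.67 per copy at this sample size) and the conditional scan keeps
them as independent hits while KIR2DS2 — which rides the same
centromeric segments as KIR2DL5B — is correctly absorbed. The
per-stratum meta-analysis agrees:

```r
per <- assoc_by_stratum(matched, "KIR2DL5B", coding = "additive_copy")
meta_fixed(per$beta, per$se, labels = per$stratum)
#> <kir_meta> effect 0.5174 (SE 0.1312), p = 8e-05, direction +++, het p = 0.418
```

Interaction scores summarize each individual's expected NK inhibitory
and activating input from their carried receptor-ligand pairs:

```r
head(score_cohort(matched), 3)
#>   individual_id inhibitory activating net
#> 1     IND000001          7          1  -6
#> 2     IND000002          5          2  -3
#> 3     IND000003          1          0  -1
```

`run_pipeline()` chains simulate → match → associate (alleles, CNV,
pairs, scores) → condition → meta into a seeded, reproducible report
bundle; `inst/scripts/run_pipeline.R` wraps it for the shell. The
methods vignette (`vignettes/kirhla-methods.Rmd`) documents the model,
defaults and numerical safeguards.

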