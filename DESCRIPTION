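Package: kirhla
Title: HLA and KIR Immunogenetic Case-Control Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control association analysis of the HLA and KIR
    immune gene complexes: IPD-IMGT/HLA and IPD-KIR allele nomenclature
    parsing with protein-level grouping and frequency-based ambiguity
    resolution; a cohort data model covering diploid HLA genotypes, KIR
    copy-number variation with allele multisets, principal-component
    coordinates and stratum labels; nearest-neighbour control matching in
    principal-component space; classification of HLA class I allotypes into
    KIR-ligand motifs (A3, A11, Bw4-80I/80T, C1, C2) with signed
    receptor-ligand interaction scoring; carrier-frequency, copy-number and
    score association by principal-component-adjusted logistic regression
    with iterative conditioning and multiple-testing control; fixed-effect
    inverse-variance meta-analysis across ancestry strata with Cochran
    heterogeneity; and a multi-ethnic synthetic-cohort generator with
    centromeric/telomeric KIR haplotype structure, HLA linkage blocks and
    planted effects under a logistic disease model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
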