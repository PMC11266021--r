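# Fixtures are built in code. toy_row()/toy_cohort() give a small
# hand-constructed cohort with known genotypes; sim_cohort_cached() memoizes
# moderately sized simulated cohorts shared across tests in one file run.

toy_row <- function(id, phenotype = "control", subgroup = "unknown",
                    ancestry = "EUR", platform = "Illumina",
                    hlag_14bp = "ins/del", ...) {
  row <- list(
    individual_id = id, phenotype = phenotype, subgroup = subgroup,
    ancestry = ancestry, platform = platform, hlag_14bp = hlag_14bp,
    A.1 = "A*02:01", A.2 = "A*01:01",
    B.1 = "B*07:02", B.2 = "B*08:01",
    C.1 = "C*07:01", C.2 = "C*07:02",
    DRB1.1 = "DRB1*15:01", DRB1.2 = "DRB1*07:01",
    DRB345.1 = "DRB5*01:01", DRB345.2 = NA_character_,
    DQA1.1 = "DQA1*01:02", DQA1.2 = "DQA1*02:01",
    DQB1.1 = "DQB1*06:02", DQB1.2 = "DQB1*02:02",
    G.1 = "G*01:01", G.2 = "G*01:04",
    # cenA/cenA + telA/telA genotype
    KIR3DL3 = "2:00101,00301", KIR2DS2 = "0:", KIR2DL2 = "0:",
    KIR2DL3 = "2:00101,00201", KIR2DP1 = "2:00201,00201",
    KIR2DL1 = "2:00101,00302", KIR3DP1 = "2:00301,00301",
    KIR2DL4 = "2:00101,00102", KIR3DL1 = "2:00101,00201",
    KIR3DS1 = "0:", KIR2DL5A = "0:", KIR2DL5B = "0:",
    KIR2DS3C = "0:", KIR2DS3T = "0:", KIR2DS5C = "0:", KIR2DS5T = "0:",
    KIR2DS1 = "0:", KIR2DS4wt = "1:00101", KIR2DS4Del = "1:00301",
    KIR3DL2 = "2:00101,00301"
  )
  override <- list(...)
  row[names(override)] <- override
  as.data.frame(row, stringsAsFactors = FALSE)
}

toy_cohort <- function(rows = NULL, n_pcs = 3) {
  if (is.null(rows)) rows <- list(
    # case carrying KIR2DL4*00103, KIR2DL5B (cenB), A3 + Bw4-80I, C1/C2
    toy_row("P1", phenotype = "case", subgroup = "teratoma",
            A.1 = "A*03:01", A.2 = "A*11:01",
            B.1 = "B*57:01", B.2 = "B*07:02",
            C.1 = "C*04:01", C.2 = "C*07:02",
            DRB1.1 = "DRB1*01:01", DRB1.2 = "DRB1*11:01",
            DQA1.1 = "DQA1*01:01", DQA1.2 = "DQA1*05:05",
            DQB1.1 = "DQB1*05:01", DQB1.2 = "DQB1*03:01",
            KIR2DL4 = "2:00102,00103",
            KIR3DL3 = "2:00301,00302",
            KIR2DS2 = "1:00101", KIR2DL2 = "1:00101",
            KIR2DL5B = "1:00201", KIR2DS3C = "1:00103",
            hlag_14bp = "del/del"),
    # case, A3 homozygote, C1/C1, cenA/telB
    toy_row("P2", phenotype = "case", subgroup = "non_paraneoplastic",
            A.1 = "A*03:01", A.2 = "A*03:01",
            C.1 = "C*07:01", C.2 = "C*07:02",
            KIR3DS1 = "1:01301", KIR2DL5A = "1:00101",
            KIR2DS5T = "1:00201", KIR2DS1 = "1:00201",
            KIR3DL1 = "1:00101", KIR2DS4wt = "1:00101", KIR2DS4Del = "0:"),
    # control, C2/C2
    toy_row("P3", C.1 = "C*04:01", C.2 = "C*05:01", hlag_14bp = "ins/ins"),
    # control, all-none class I, missing HLA-G 14bp
    toy_row("P4", A.1 = "A*02:01", A.2 = "A*02:01",
            B.1 = "B*07:02", B.2 = "B*35:01",
            C.1 = "C*01:02", C.2 = "C*03:04",
            hlag_14bp = NA_character_),
    # control with the B*46:01 C1 exception and a DRB3 allele
    toy_row("P5", B.1 = "B*46:01", B.2 = "B*44:02",
            DRB345.1 = "DRB3*03:01", DRB345.2 = "DRB3*01:01"),
    # control with missing HLA-C calls
    toy_row("P6", C.1 = NA_character_, C.2 = NA_character_)
  )
  d <- do.call(rbind, rows)
  pcs <- matrix(seq_len(nrow(d) * n_pcs) / 10, nrow(d), n_pcs)
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  rownames(pcs) <- d$individual_id
  new_cohort(d, pcs)
}

# memoized simulated cohorts (per R session)
.sim_cache <- new.env(parent = emptyenv())
sim_cohort_cached <- function(n_cases = 150, n_controls = 750, seed = 42,
                              eff = effect_config()) {
  key <- paste(n_cases, n_controls, seed, digest_eff(eff), sep = "_")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_cohort(eff = eff, n_cases = n_cases,
                                         n_controls = n_controls, seed = seed)
  .sim_cache[[key]]
}

digest_eff <- function(eff) {
  paste(eff$intercept, paste(eff$effects$marker, eff$effects$coding,
                             eff$effects$log_or, collapse = ";"), sep = "|")
}

# minimal cohort realizing a 2x2 carrier table at one marker column, with
# flat PCs so adjusted fits reduce to the crude comparison
cohort_2x2 <- function(a, b, c, d, marker_col = "KIR2DL5B",
                       carrier_tok = "1:00201", null_tok = "0:") {
  n <- a + b + c + d
  tmpl <- toy_row("x")
  dd <- tmpl[rep(1L, n), , drop = FALSE]
  dd$individual_id <- sprintf("i%05d", seq_len(n))
  dd$phenotype <- rep(c("case", "control"), c(a + b, c + d))
  dd[[marker_col]] <- rep(c(carrier_tok, null_tok, carrier_tok, null_tok),
                          c(a, b, c, d))
  rownames(dd) <- NULL
  pcs <- matrix(0, n, 3, dimnames = list(dd$individual_id, paste0("PC", 1:3)))
  new_cohort(dd, pcs)
}

pc_frame <- function(ids, coords, stratum = "EUR|X") {
  coords <- as.matrix(coords)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  data.frame(individual_id = ids, stratum = stratum, coords,
             stringsAsFactors = FALSE, check.names = FALSE)
}

# exhaustive nearest-neighbour oracle (with-replacement semantics)
nn_oracle <- function(ca, co, k, pcs_used) {
  pc_cols <- paste0("PC", seq_len(pcs_used))
  do.call(rbind, lapply(seq_len(nrow(ca)), function(i) {
    pool <- co[co$stratum == ca$stratum[i], , drop = FALSE]
    d <- sqrt(rowSums(sweep(as.matrix(pool[, pc_cols, drop = FALSE]), 2,
                            as.numeric(ca[i, pc_cols]), `-`)^2))
    ord <- order(d, pool$individual_id)[seq_len(min(k, nrow(pool)))]
    data.frame(case_id = ca$individual_id[i], control_id = pool$individual_id[ord],
               rank = seq_along(ord), distance = d[ord], stringsAsFactors = FALSE)
  }))
}

# an in-code allele frequency table for ambiguity-resolution tests
toy_freq_table <- function() {
  as_freq_table(data.frame(
    locus = c("KIR2DL4", "KIR2DL4", "KIR2DL4", "KIR2DL4"),
    allele = c("00101", "00102", "00103", "00501"),
    population = "EUR",
    frequency = c(0.30, 0.25, 0.01, 0.02),
    stringsAsFactors = FALSE))
}
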