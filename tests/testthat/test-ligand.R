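test_that("the bundled motif table satisfies the model's structural rules", {
  mt <- load_motif_table()
  expect_true(all(mt$motif[mt$locus == "HLA-C"] %in% c("C1", "C2")))
  expect_false(anyDuplicated(paste(mt$locus, mt$allele)) > 0)
  expect_true(all(startsWith(mt$allele[mt$motif == "A3"], "03")))
  expect_true(all(startsWith(mt$allele[mt$motif == "A11"], "11")))
})

test_that("motif classification handles dimorphisms, exceptions and class II", {
  expect_equal(classify_motif("C*04:01"), "C2")
  expect_equal(classify_motif("C*07:02"), "C1")
  expect_equal(classify_motif("B*46:01"), "C1")   # C1-carrying HLA-B exception
  expect_equal(classify_motif("B*57:01"), "Bw4-80I")
  expect_equal(classify_motif("B*44:02"), "Bw4-80T")
  expect_equal(classify_motif("A*03:01"), "A3")
  expect_equal(classify_motif("A*11:01"), "A11")
  expect_equal(classify_motif("DQB1*05:01"), "none")
  expect_equal(classify_motif("G*01:01"), "none")
  # higher-resolution input truncates to two fields
  expect_equal(classify_motif("C*04:01:01"), "C2")
  # unknown class I allele
  expect_equal(classify_motif("C*99:99"), "unknown")
  expect_error(classify_motif("KIR2DL4*00103"), "HLA")
})

test_that("ligand states aggregate the two HLA-C motifs into a C-state", {
  co <- toy_cohort()
  st <- ligand_state(co)
  expect_equal(st$c_state, c("C1_C2", "C1_C1", "C2_C2", "C1_C1", "C1_C1", NA))
  expect_equal(st$has_A3, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(st$has_A11, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(st$has_Bw4_80I, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # B*46:01 contributes C1 through an HLA-B allele
  expect_true(st$has_C1[5])
  expect_equal(st$has_Bw4_80T[5], TRUE)  # via B*44:02
  # P4 carries no ligand motif besides its C1 alleles
  expect_false(any(st$has_A3[4], st$has_A11[4], st$has_Bw4_80I[4],
                   st$has_Bw4_80T[4], st$has_C2[4]))
})

test_that("effective pairs require both receptor and ligand state", {
  co <- toy_cohort()
  pr <- enumerate_pairs(co)
  # P3: KIR2DL1 carried, C2_C2 -> (KIR2DL1, C2) effective
  expect_true(pr["P3", "KIR2DL1_C2"])
  expect_true(pr["P3", "KIR2DL1_C2_C2"])
  # P3 lacks KIR2DL2 -> no KIR2DL2 pair under any state
  expect_false(any(pr["P3", grep("^KIR2DL2_", colnames(pr))]))
  # P4 carries KIR3DL1 but no Bw4 -> no (KIR3DL1, Bw4) pair
  expect_false(pr["P4", "KIR3DL1_Bw4"])
  # missing HLA-C: composite C-states unavailable, receptor pairs with C
  # patterns off
  expect_false(any(pr["P6", grep("_C1_C2$", colnames(pr))]))
  # brute-force containment: every pair implies carried receptor + motif
  st <- ligand_state(co)
  for (j in seq_len(ncol(pr))) {
    nm <- colnames(pr)[j]
    us <- regexpr("_", nm, fixed = TRUE)
    loc <- substr(nm, 1, us - 1); pat <- substr(nm, us + 1, nchar(nm))
    carried <- kir_copy_number(co, loc) >= 1
    sat <- kirhla:::.pattern_satisfied(st, pat)
    sat[is.na(sat)] <- FALSE
    expect_true(all(!pr[, j] | (carried & sat)))
  }
})

test_that("interaction scores add signed weights with net = activating - inhibitory", {
  st <- load_score_table()
  expect_true(all(st$weight %in% 1:3))
  s <- score_individual(c("KIR2DL1_C2", "KIR2DS1_C2"), st)
  expect_equal(s, list(inhibitory = 3L, activating = 2L, net = -1L))
  expect_equal(score_individual(character(0), st),
               list(inhibitory = 0L, activating = 0L, net = 0L))
  # all-weights-1 table turns the inhibitory total into a pair count
  flat <- st
  flat$weight <- 1L
  pairs <- paste(st$kir_locus, st$pattern, sep = "_")[st$class == "inhibitory"]
  expect_equal(score_individual(pairs, flat)$inhibitory, length(pairs))
  # monotonicity: adding an inhibitory pair never increases net
  base <- score_individual(c("KIR2DS1_C2"), st)
  more <- score_individual(c("KIR2DS1_C2", "KIR2DL3_C1"), st)
  expect_lte(more$net, base$net)
  expect_gte(score_individual(c("KIR2DS1_C2", "KIR2DS2_C1"), st)$net, base$net)
})

test_that("cohort-level scores are consistent and reproducible", {
  co <- sim_cohort_cached()
  sc <- score_cohort(co)
  expect_equal(sc$net, sc$activating - sc$inhibitory)
  expect_true(all(sc$inhibitory >= 0) && all(sc$activating >= 0))
  # scoring through a precomputed pair matrix gives the identical result
  pr <- enumerate_pairs(co)
  sc2 <- score_cohort(co, pairs = pr)
  expect_equal(sc, sc2)
})

test_that("Bw4 rows can be collapsed onto the unsplit epitope", {
  st <- load_score_table(collapse_bw4 = TRUE)
  expect_false(any(st$pattern %in% c("Bw4-80I", "Bw4-80T")))
  # KIR3DL1 keeps the stronger (80I) weight after collapsing
  expect_equal(st$weight[st$kir_locus == "KIR3DL1" & st$pattern == "Bw4"], 3L)
})

test_that("custom score tables are validated on load", {
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(kir_locus = "KIR2DL1", pattern = "C2",
                              class = "inhibitory", weight = 5), bad,
                   row.names = FALSE)
  expect_error(load_score_table(bad), "1..3")
  utils::write.csv(data.frame(kir_locus = "KIR9XX1", pattern = "C2",
                              class = "inhibitory", weight = 2), bad,
                   row.names = FALSE)
  expect_error(load_score_table(bad), "unknown KIR locus")
})
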