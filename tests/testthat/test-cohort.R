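test_that("carrier indicators cover alleles, protein groups, gene presence and HLA-G", {
  co <- toy_cohort()
  # P1 carries KIR2DL4*00103 (alleles 00102,00103)
  expect_equal(carrier_indicator(co, "KIR2DL4*00103"),
               c(1L, 0L, 0L, 0L, 0L, 0L))
  # protein-group marker matches any *001xx carrier (everyone has 00101/00102)
  expect_equal(carrier_indicator(co, "KIR2DL4*001"), rep(1L, 6))
  # gene presence: only P1 carries KIR2DL5B
  expect_equal(carrier_indicator(co, "KIR2DL5B"), c(1L, 0L, 0L, 0L, 0L, 0L))
  # union locus: KIR2DL5 = 2DL5A + 2DL5B (P1 via B, P2 via A)
  expect_equal(carrier_indicator(co, "KIR2DL5"), c(1L, 1L, 0L, 0L, 0L, 0L))
  # HLA allele at two-field resolution
  expect_equal(carrier_indicator(co, "DRB1*01:01"), c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(carrier_indicator(co, "HLA-A*03:01"), c(1L, 1L, 0L, 0L, 0L, 0L))
  # DRB3/4/5 markers look in the shared slot
  expect_equal(carrier_indicator(co, "DRB3*03:01"), c(0L, 0L, 0L, 0L, 1L, 0L))
  # HLA-G 14-bp ins/del; NA genotype propagates
  expect_equal(carrier_indicator(co, "HLAG14BP*DEL"),
               c(1L, 1L, 0L, NA_integer_, 1L, 1L))
  expect_error(carrier_indicator(co, "KIR9XX1"), "unknown marker")
})

test_that("carrier frequencies count non-missing denominators per group", {
  co <- toy_cohort()
  cf <- carrier_frequency(co, "KIR2DL4*00103", "case")
  expect_equal(cf$count, 1L)
  expect_equal(cf$n, 2L)
  expect_equal(cf$freq, 0.5)
  # HLA-G del in controls: P4 missing -> n = 3
  gf <- carrier_frequency(co, "HLAG14BP*DEL", "control")
  expect_equal(gf$n, 3L)
  expect_equal(gf$count, 2L)
  tf <- carrier_frequency(co, "KIR2DL5B", "teratoma")
  expect_equal(tf, list(count = 1L, n = 1L, freq = 1))
  expect_equal(carrier_frequency(co, "KIR2DL5B", "non_teratoma")$count, 0L)
})

test_that("carriers of an allele are a subset of locus-presence carriers", {
  co <- sim_cohort_cached()
  for (loc in c("KIR2DL4", "KIR2DL5B", "KIR3DL1")) {
    pres <- carrier_indicator(co, loc)
    als <- unique(unlist(kir_alleles(co, loc)))
    for (al in als) {
      ind <- carrier_indicator(co, paste0(loc, "*", al))
      expect_true(all(pres[ind == 1L] == 1L))
    }
  }
  # carrier frequency is invariant under record permutation
  set.seed(5)
  perm <- sample(cohort_size(co))
  co_p <- subset_cohort(co, perm)
  for (m in c("KIR2DL5B", "DRB1*01:01", "KIR2DL4*00103"))
    expect_equal(carrier_frequency(co_p, m, "control"),
                 carrier_frequency(co, m, "control"))
})

test_that("cohort validation rejects duplicates and multiset mismatches", {
  co <- toy_cohort()
  d <- co$data
  d2 <- d; d2$individual_id[2] <- d2$individual_id[1]
  expect_error(new_cohort(d2, co$pcs), "duplicate")
  d3 <- d; d3$KIR2DL5B[1] <- "2:00201"  # claims 2 copies, lists 1 allele
  expect_error(new_cohort(d3, co$pcs), "KIR2DL5B")
  expect_error(new_cohort(d, co$pcs[, 1:2]), "3 principal components")
})

test_that("cohort TSV + eigenvec round-trip reproduces the cohort", {
  co <- sim_cohort_cached(25, 25, seed = 9)
  g <- withr::local_tempfile(fileext = ".tsv")
  p <- withr::local_tempfile(fileext = ".txt")
  write_cohort(co, g, p, header_comment = "round-trip fixture")
  back <- read_cohort(g, p)
  expect_equal(back$data, co$data)
  expect_equal(back$pcs, co$pcs, tolerance = 1e-12)

  # an empty cohort round-trips through header-only files
  co0 <- subset_cohort(co, integer(0))
  expect_equal(cohort_size(co0), 0L)
  write_cohort(co0, g, p)
  back0 <- read_cohort(g, p)
  expect_equal(cohort_size(back0), 0L)
  expect_equal(names(back0$data), names(co$data))

  # missing hlag_14bp serializes as NA and is recovered as missing
  co2 <- toy_cohort()
  write_cohort(co2, g, p)
  back2 <- read_cohort(g, p)
  expect_true(is.na(back2$data$hlag_14bp[4]))
  expect_equal(back2$data$hlag_14bp, co2$data$hlag_14bp)
})

test_that("individuals absent from the PC table are dropped with a warning", {
  co <- sim_cohort_cached(25, 25, seed = 9)
  g <- withr::local_tempfile(fileext = ".tsv")
  p <- withr::local_tempfile(fileext = ".txt")
  write_cohort(co, g, p)
  pcs <- readLines(p)
  writeLines(pcs[-2], p)  # drop the first individual's PC row
  expect_warning(back <- read_cohort(g, p), "missing from PC table")
  expect_equal(cohort_size(back), cohort_size(co) - 1L)
  expect_false(co$data$individual_id[1] %in% back$data$individual_id)
})
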