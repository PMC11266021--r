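test_that("simulation is byte-identical under a fixed seed", {
  eff <- effect_config(-2, "KIR2DL5B", "additive_copy", 0.54)
  a <- simulate_cohort(eff = eff, n_cases = 120, n_controls = 240, seed = 7)
  b <- simulate_cohort(eff = eff, n_cases = 120, n_controls = 240, seed = 7)
  expect_identical(a$data, b$data)
  expect_identical(a$pcs, b$pcs)
  c <- simulate_cohort(eff = eff, n_cases = 120, n_controls = 240, seed = 8)
  expect_false(identical(a$data, c$data))
})

test_that("expected copy number follows segment frequencies exactly", {
  hap <- default_haplotype_config()
  # KIR2DL5B sits on both cenB segments
  cb <- sum(hap$cen$freq["EUR", c("cenB1", "cenB2")])
  expect_equal(expected_copy_number(hap, "KIR2DL5B", "EUR"), 2 * cb)
  # a hand-set segment frequency propagates linearly
  hap2 <- hap
  hap2$cen$freq["EUR", ] <- c(cenA = 0.70, cenB1 = 0.20, cenB2 = 0.10)
  expect_equal(expected_copy_number(hap2, "KIR2DL5B", "EUR"), 0.6)
  # framework genes are on every haplotype
  for (fw in kir_framework_loci())
    expect_equal(expected_copy_number(hap, fw, "EUR"), 2)
  # union locus = sum of parts
  expect_equal(expected_copy_number(hap, "KIR2DS3", "EUR"),
               expected_copy_number(hap, "KIR2DS3C", "EUR") +
               expected_copy_number(hap, "KIR2DS3T", "EUR"))
  # a locus absent from all segments of a config has expectation 0
  hap3 <- hap
  hap3$tel$segments$telB1 <- setdiff(hap3$tel$segments$telB1, "KIR2DS5T")
  expect_equal(expected_copy_number(hap3, "KIR2DS5T", "EUR"), 0)
  expect_error(expected_copy_number(hap, "KIR9XX1", "EUR"), "unknown")
})

test_that("simulated copy numbers converge to their expectation", {
  hap <- default_haplotype_config()
  strata_eur <- data.frame(ancestry = "EUR", platform = "Illumina", prop = 1)
  co <- simulate_cohort(hap, effect_config(0), n_cases = 5000, n_controls = 5000,
                        strata = strata_eur, seed = 31)
  n <- cohort_size(co)
  for (loc in c("KIR2DL5B", "KIR2DL1", "KIR2DS1", "KIR2DS4Del")) {
    cn <- kir_copy_number(co, loc)
    exp_cn <- expected_copy_number(hap, loc, "EUR")
    se <- stats::sd(cn) / sqrt(n)
    expect_lt(abs(mean(cn) - exp_cn), 3 * se + 1e-9)
  }
  # framework loci never drop to zero copies
  for (fw in kir_framework_loci())
    expect_true(all(kir_copy_number(co, fw) >= 1L))
})

test_that("HLA haplotype and allele frequencies are recovered", {
  hap <- default_haplotype_config()
  strata_eur <- data.frame(ancestry = "EUR", platform = "Illumina", prop = 1)
  co <- simulate_cohort(hap, effect_config(0), n_cases = 5000, n_controls = 5000,
                        strata = strata_eur, seed = 32)
  n2 <- 2 * cohort_size(co)
  # DRB1*01:01 allele frequency = haplotype freq + residual pool contribution
  hfreq <- hap$hla_hap_freq["EUR", "H1"]
  resid <- 1 - sum(hap$hla_hap_freq["EUR", ])
  pool <- hap$hla_pools$DRB1
  p_exp <- hfreq + resid * pool$freq[pool$allele == "DRB1*01:01"]
  obs <- (sum(co$data$DRB1.1 == "DRB1*01:01") +
          sum(co$data$DRB1.2 == "DRB1*01:01")) / n2
  expect_lt(abs(obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n2))
  # the intact haplotype itself appears at >= its configured frequency
  hap_hit <- co$data$DRB1.1 == "DRB1*01:01" & co$data$DQA1.1 == "DQA1*01:01" &
    co$data$DQB1.1 == "DQB1*05:01"
  expect_gt(mean(hap_hit), hfreq - 3 * sqrt(hfreq * (1 - hfreq) / cohort_size(co)))
})

test_that("null simulation shows no case-control frequency separation", {
  co <- sim_cohort_cached(2000, 2000, seed = 77, eff = effect_config(0))
  for (m in c("KIR2DL5B", "KIR2DL4*00103", "DRB1*11:01", "A*03:01")) {
    fc <- carrier_frequency(co, m, "case")
    fk <- carrier_frequency(co, m, "control")
    pooled <- (fc$count + fk$count) / (fc$n + fk$n)
    sd_diff <- sqrt(pooled * (1 - pooled) * (1 / fc$n + 1 / fk$n))
    expect_lt(abs(fc$freq - fk$freq), 3 * sd_diff + 1e-9)
  }
})

test_that("a planted carrier effect is visible in the crude log-OR", {
  eff <- effect_config(0, "A*03:01", "carrier", 0.7)
  co <- simulate_cohort(eff = eff, n_cases = 3000, n_controls = 3000, seed = 55)
  ind <- carrier_indicator(co, "A*03:01")
  y <- co$data$phenotype == "case"
  tab <- crude_or(sum(ind & y), sum(!ind & y), sum(ind & !y), sum(!ind & !y))
  expect_lt(abs(tab$log_or - 0.7), 0.2)
})

test_that("unreachable quotas error out instead of spinning", {
  expect_error(
    simulate_cohort(eff = effect_config(-30), n_cases = 50, n_controls = 50,
                    seed = 1, max_batches = 3L),
    "unreachable")
})

test_that("haplotype configs survive a YAML round-trip", {
  hap <- default_haplotype_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_haplotype_config(hap, path)
  back <- read_haplotype_config(path)
  expect_equal(back$cen$freq, hap$cen$freq)
  expect_equal(back$tel$segments, hap$tel$segments)
  expect_equal(back$kir_alleles, hap$kir_alleles)
  expect_equal(back$hla_pools, hap$hla_pools)
  expect_equal(back$hla_hap_freq, hap$hla_hap_freq)
  # a config edited into an invalid state is rejected
  hap$cen$freq["EUR", "cenA"] <- 0.5
  expect_error(validate_haplotype_config(hap), "sum to 1")
})
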