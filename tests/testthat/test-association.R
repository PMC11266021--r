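test_that("crude odds ratios follow the 2x2 closed form", {
  # Table-style worked example: 82/241 carrier cases, 190/1329 controls
  r <- crude_or(82, 241, 190, 1329)
  expect_equal(round(r$or, 3), 2.380)
  expect_equal(r$log_or, log((82 * 1329) / (241 * 190)))
  expect_equal(r$se, sqrt(1/82 + 1/241 + 1/190 + 1/1329))
  expect_equal(crude_or(10, 10, 10, 10)$or, 1)
  # zero cell engages the Haldane-Anscombe correction
  z <- crude_or(0, 10, 5, 10)
  expect_true(is.finite(z$log_or))
  expect_equal(z$or, (0.5 * 10.5) / (10.5 * 5.5))
  expect_error(crude_or(-1, 2, 3, 4), "negative")
})

test_that("unadjusted logistic fits reproduce the crude log-OR", {
  set.seed(101)
  for (i in 1:20) {
    cells <- sample(5:60, 4, replace = TRUE)
    co <- cohort_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- assoc_logistic(co, "KIR2DL5B", n_pcs = 0)
    ref <- crude_or(cells[1], cells[2], cells[3], cells[4])
    expect_equal(fit$beta, ref$log_or, tolerance = 1e-6)
    expect_equal(fit$or_value, exp(fit$beta), tolerance = 1e-12)
    expect_equal(fit$se, ref$se, tolerance = 1e-4)
    # flat PCs drop out: adjusted fit equals the crude one
    fit3 <- assoc_logistic(co, "KIR2DL5B", n_pcs = 3)
    expect_equal(fit3$beta, ref$log_or, tolerance = 1e-6)
  }
})

test_that("carrier counts in results match the printed-table convention", {
  co <- cohort_2x2(82, 241, 190, 1329)
  fit <- assoc_logistic(co, "KIR2DL5B", n_pcs = 0)
  expect_equal(fit$case_count, 82L)
  expect_equal(fit$case_n, 323L)
  expect_equal(round(fit$case_freq, 3), 0.254)
  expect_equal(fit$control_count, 190L)
  expect_equal(round(fit$control_freq, 3), 0.125)
})

test_that("separation and zero variance are flagged unestimable", {
  co <- cohort_2x2(25, 0, 0, 25)   # marker == phenotype: separation
  fit <- assoc_logistic(co, "KIR2DL5B", n_pcs = 0)
  expect_false(fit$estimable)
  co2 <- cohort_2x2(20, 0, 20, 0)  # everyone carries: zero variance
  fit2 <- assoc_logistic(co2, "KIR2DL5B", n_pcs = 0)
  expect_false(fit2$estimable)
})

test_that("copy-number tests run both codings and flag constant loci", {
  co <- sim_cohort_cached()
  r <- assoc_cnv(co, "KIR2DL5B")
  expect_true(r$presence$estimable)
  expect_true(r$additive$estimable)
  expect_equal(r$presence$coding, "carrier")
  expect_equal(r$additive$coding, "additive_copy")
  # framework locus with constant copy number -> not applicable
  fw <- assoc_cnv(co, "KIR3DL2")
  expect_false(fw$additive$estimable)
  expect_match(fw$additive$covariates, "n/a")
})

test_that("planted additive and carrier CNV effects agree in sign", {
  eff <- effect_config(0, "KIR2DL5B", "additive_copy", 0.54)
  co <- simulate_cohort(eff = eff, n_cases = 2500, n_controls = 2500, seed = 61)
  r <- assoc_cnv(co, "KIR2DL5B")
  expect_gt(r$additive$beta, 0)
  expect_gt(r$presence$beta, 0)
  expect_lt(abs(r$additive$beta - 0.54), 0.25)
})

test_that("Benjamini-Hochberg adjustment reproduces the hand-computed step-up", {
  res <- data.frame(marker = paste0("m", 1:4), p = c(0.001, 0.011, 0.039, 0.041),
                    estimable = TRUE, case_freq = 0.2, control_freq = 0.2)
  out <- adjust_pvalues(res, "bh_fdr", 0.05)
  expect_equal(out$p_adj, c(0.004, 0.022, 0.041, 0.041))
  # Bonferroni on a single in-family p is the identity (m = 1)
  one <- adjust_pvalues(res[1, ], "bonferroni", 0.05)
  expect_equal(one$p_adj, one$p)
  expect_equal(adjust_pvalues(res[1, ], "bh_fdr", 0.05)$p_adj, res$p[1])
})

test_that("markers under the frequency threshold leave the adjustment family", {
  res <- data.frame(marker = paste0("m", 1:3), p = c(0.001, 0.02, 0.04),
                    estimable = c(TRUE, TRUE, TRUE),
                    case_freq = c(0.04, 0.20, 0.04),
                    control_freq = c(0.04, 0.01, 0.06))
  out <- adjust_pvalues(res, "bh_fdr", 0.05)
  expect_true(out$exploratory[1])    # 4%/4%: below threshold in both groups
  expect_true(is.na(out$p_adj[1]))
  expect_false(out$exploratory[2])   # 20% in cases suffices
  expect_false(out$exploratory[3])   # 6% in controls suffices
  # adjusted p are monotone in raw-p order and never below raw p
  fam <- which(!out$exploratory)
  expect_true(all(out$p_adj[fam] >= out$p[fam]))
  o <- order(out$p[fam])
  expect_true(all(diff(out$p_adj[fam][o]) >= 0))
})

test_that("conditioning separates linked from independent signals", {
  # KIR2DL5B and KIR2DS2 ride the same centromeric segments (perfect LD):
  # after the first is selected, the second is collinear and the scan stops
  eff <- effect_config(0, "KIR2DL5B", "carrier", 0.8)
  co <- simulate_cohort(eff = eff, n_cases = 1200, n_controls = 2400, seed = 71)
  tr <- conditional_scan(co, c("KIR2DL5B", "KIR2DS2"), alpha = 0.05)
  expect_equal(nrow(tr), 1L)
  expect_true(tr$marker[1] %in% c("KIR2DL5B", "KIR2DS2"))
  expect_equal(tr$conditioned_on[1], "")

  # two unlinked planted effects (centromeric presence + telomeric presence)
  eff2 <- effect_config(0, c("KIR2DL5B", "KIR2DS1"), c("carrier", "carrier"),
                        c(0.8, 0.8))
  co2 <- simulate_cohort(eff = eff2, n_cases = 1200, n_controls = 2400, seed = 72)
  tr2 <- conditional_scan(co2, c("KIR2DL5B", "KIR2DS1"), alpha = 0.05)
  expect_setequal(tr2$marker, c("KIR2DL5B", "KIR2DS1"))
  expect_equal(tr2$iteration, 1:2)
  expect_equal(tr2$conditioned_on[2], tr2$marker[1])

  # the trace is reproducible bit-for-bit
  expect_identical(tr2, conditional_scan(co2, c("KIR2DL5B", "KIR2DS1"),
                                         alpha = 0.05))
})

test_that("pair-presence association recovers a planted receptor-ligand signal", {
  # enrich C2 homozygotes among carriers of KIR2DL1 via a carrier effect on
  # an HLA-C C2 allele; the (KIR2DL1, C2) pair then separates cases
  eff <- effect_config(0, "C*04:01", "carrier", 0.9)
  co <- simulate_cohort(eff = eff, n_cases = 1500, n_controls = 1500, seed = 81)
  r <- pair_presence_assoc(co, "KIR2DL1_C2")
  expect_true(r$estimable)
  expect_gt(r$beta, 0)
  expect_lt(r$p, 0.01)
  # a pair absent from everyone is unestimable
  co_toy <- toy_cohort()
  r0 <- pair_presence_assoc(co_toy, "KIR2DL2_C2_C2")
  expect_false(r0$estimable)
})

test_that("score regressions agree with an explicit logistic fit on binary scores", {
  co <- sim_cohort_cached()
  n <- cohort_size(co)
  set.seed(91)
  s <- rbinom(n, 1, 0.4)
  scores <- data.frame(individual_id = co$data$individual_id,
                       inhibitory = s, activating = 0L, net = -s)
  sa <- score_assoc(co, "inhibitory", scores = scores)
  # with a two-level score the proportional-odds fit collapses to logistic
  y <- as.integer(co$data$phenotype == "case")
  pc <- co$pcs[, 1:3]
  ref <- suppressWarnings(glm(s ~ y + pc, family = binomial()))
  expect_equal(unname(sa$ordinal$beta), unname(coef(ref)["y"]), tolerance = 1e-6)
  # glm leg reports the phenotype-on-score direction
  ref2 <- glm(y ~ s + pc, family = binomial())
  expect_equal(sa$glm$beta, unname(coef(ref2)["s"]), tolerance = 1e-6)
  # constant score is unestimable
  scores0 <- transform(scores, inhibitory = 1L)
  sa0 <- score_assoc(co, "inhibitory", scores = scores0)
  expect_false(sa0$glm$estimable)
})

test_that("per-stratum fits feed the meta-analysis with intra-stratum PCs", {
  eff <- effect_config(0, "KIR2DL5B", "carrier", 0.7)
  co <- simulate_cohort(eff = eff, n_cases = 900, n_controls = 1800, seed = 95)
  per <- assoc_by_stratum(co, "KIR2DL5B")
  expect_equal(nrow(per), length(unique(cohort_strata(co))))
  expect_true(any(per$estimable))
  mm <- meta_fixed(per$beta, per$se, labels = per$stratum)
  expect_gt(mm$effect, 0)
  expect_equal(nchar(mm$direction), nrow(per))
})
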