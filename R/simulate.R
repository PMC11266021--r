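# Synthetic multi-ethnic cohort generator.
#
# Each individual receives two centromeric and two telomeric KIR segments
# (gene-content haplotypes drawn per ancestry), per-locus allele draws for
# every carried KIR gene copy, two HLA haplotypes for the class II
# DRB1~DQA1~DQB1 block (with an independent residual pool standing in for
# recombinant haplotypes) plus independent class I / DRB3-4-5 / HLA-G
# draws, an HLA-G 14-bp ins/del genotype, and Gaussian PC coordinates
# centred on an ancestry-specific centroid. Disease status is assigned by
# rejection sampling from a logistic model
#   P(case) = plogis(intercept + sum(effect * coding))
# until the requested case and control quotas are met, so planted carrier
# or additive copy-number effects are recoverable as log-odds ratios.

.default_ancestries <- c("EUR", "EAS", "AFR")

#' Default haplotype configuration
#'
#' Ships gene-content frequencies for the centromeric (cenA; cenB variants
#' carrying KIR2DS3C or KIR2DS5C) and telomeric (telA with KIR2DS4wt or
#' KIR2DS4Del; telB variants carrying KIR2DS5T or KIR2DS3T) KIR segments,
#' allele pools for the polymorphic KIR loci, an HLA class II haplotype
#' table (including DRB1*01:01~DQA1*01:01~DQB1*05:01) with residual
#' per-locus pools, and PC cluster geometry for three ancestry groups.
#' Frequencies are illustrative, loosely informed by published European
#' control frequencies (e.g. KIR2DL5B gene presence near 20%); they are
#' defaults to exercise the analysis machinery, not population estimates.
#'
#' @return A list of class `haplotype_config`.
#' @export
default_haplotype_config <- function() {
  cen_segments <- list(
    cenA  = c("KIR3DL3", "KIR2DL3", "KIR2DP1", "KIR2DL1", "KIR3DP1"),
    cenB1 = c("KIR3DL3", "KIR2DS2", "KIR2DL2", "KIR2DL5B", "KIR2DS3C", "KIR3DP1"),
    cenB2 = c("KIR3DL3", "KIR2DS2", "KIR2DL2", "KIR2DL5B", "KIR2DS5C", "KIR3DP1")
  )
  tel_segments <- list(
    telAwt  = c("KIR2DL4", "KIR3DL1", "KIR2DS4wt", "KIR3DL2"),
    telAdel = c("KIR2DL4", "KIR3DL1", "KIR2DS4Del", "KIR3DL2"),
    telB1   = c("KIR2DL4", "KIR3DS1", "KIR2DL5A", "KIR2DS5T", "KIR2DS1", "KIR3DL2"),
    telB2   = c("KIR2DL4", "KIR3DS1", "KIR2DL5A", "KIR2DS3T", "KIR2DS1", "KIR3DL2")
  )
  cen_freq <- rbind(
    EUR = c(cenA = 0.895, cenB1 = 0.075, cenB2 = 0.030),
    EAS = c(cenA = 0.940, cenB1 = 0.040, cenB2 = 0.020),
    AFR = c(cenA = 0.820, cenB1 = 0.120, cenB2 = 0.060)
  )
  tel_freq <- rbind(
    EUR = c(telAwt = 0.310, telAdel = 0.510, telB1 = 0.130, telB2 = 0.050),
    EAS = c(telAwt = 0.350, telAdel = 0.450, telB1 = 0.150, telB2 = 0.050),
    AFR = c(telAwt = 0.420, telAdel = 0.400, telB1 = 0.120, telB2 = 0.060)
  )
  pool <- function(...) {
    x <- c(...)
    data.frame(allele = names(x), freq = unname(x), stringsAsFactors = FALSE)
  }
  kir_alleles <- list(
    KIR3DL3   = pool("00101" = 0.40, "00201" = 0.20, "00301" = 0.1340,
                     "00302" = 0.0065, "00901" = 0.2595),
    KIR2DS2   = pool("00101" = 1.00),
    KIR2DL2   = pool("00101" = 0.55, "00301" = 0.45),
    KIR2DL3   = pool("00101" = 0.60, "00201" = 0.40),
    KIR2DP1   = pool("00201" = 1.00),
    KIR2DL1   = pool("00101" = 0.30, "00201" = 0.25, "00302" = 0.353, "00401" = 0.097),
    KIR3DP1   = pool("00301" = 1.00),
    KIR2DL4   = pool("00101" = 0.40, "00102" = 0.185, "00103" = 0.065,
                     "00501" = 0.20, "00802" = 0.15),
    KIR3DL1   = pool("00101" = 0.35, "00201" = 0.30, "00401" = 0.20, "01502" = 0.15),
    KIR3DS1   = pool("01301" = 0.95, "01401" = 0.05),
    KIR2DL5A  = pool("00101" = 0.60, "00501" = 0.40),
    KIR2DL5B  = pool("00201" = 0.92, "00202" = 0.05, "00601" = 0.03),
    KIR2DS3C  = pool("00103" = 0.80, "00201" = 0.20),
    KIR2DS3T  = pool("00103" = 0.70, "00201" = 0.30),
    KIR2DS5C  = pool("00201" = 1.00),
    KIR2DS5T  = pool("00201" = 0.85, "00301" = 0.15),
    KIR2DS1   = pool("00201" = 0.70, "00202" = 0.30),
    KIR2DS4wt  = pool("00101" = 0.85, "00201" = 0.15),
    KIR2DS4Del = pool("00301" = 0.60, "00601" = 0.40),
    KIR3DL2   = pool("00101" = 0.25, "00201" = 0.20, "00301" = 0.30,
                     "00701" = 0.15, "01001" = 0.10)
  )
  hla_haplotypes <- data.frame(
    DRB1 = c("DRB1*01:01", "DRB1*11:01", "DRB1*15:01", "DRB1*03:01",
             "DRB1*07:01", "DRB1*13:02"),
    DQA1 = c("DQA1*01:01", "DQA1*05:05", "DQA1*01:02", "DQA1*05:01",
             "DQA1*02:01", "DQA1*01:02"),
    DQB1 = c("DQB1*05:01", "DQB1*03:01", "DQB1*06:02", "DQB1*02:01",
             "DQB1*02:02", "DQB1*06:04"),
    stringsAsFactors = FALSE
  )
  hap_freq <- rbind(
    EUR = c(0.090, 0.090, 0.140, 0.130, 0.130, 0.045),
    EAS = c(0.060, 0.060, 0.060, 0.040, 0.060, 0.030),
    AFR = c(0.040, 0.080, 0.070, 0.080, 0.090, 0.040)
  )
  colnames(hap_freq) <- paste0("H", seq_len(nrow(hla_haplotypes)))
  hla_pools <- list(
    A = pool("A*01:01" = 0.14, "A*02:01" = 0.28, "A*03:01" = 0.13,
             "A*11:01" = 0.06, "A*24:02" = 0.10, "A*23:01" = 0.04,
             "A*25:01" = 0.02, "A*26:01" = 0.04, "A*32:01" = 0.04,
             "A*29:02" = 0.03, "A*31:01" = 0.03, "A*68:01" = 0.04,
             "A*30:01" = 0.03, "A*33:01" = 0.02),
    B = pool("B*07:02" = 0.12, "B*08:01" = 0.10, "B*44:02" = 0.09,
             "B*44:03" = 0.05, "B*51:01" = 0.06, "B*57:01" = 0.03,
             "B*58:01" = 0.02, "B*27:05" = 0.04, "B*37:01" = 0.02,
             "B*18:01" = 0.05, "B*35:01" = 0.10, "B*40:01" = 0.06,
             "B*15:01" = 0.07, "B*13:02" = 0.03, "B*46:01" = 0.02,
             "B*52:01" = 0.02, "B*53:01" = 0.02, "B*14:02" = 0.03,
             "B*38:01" = 0.02, "B*39:01" = 0.02, "B*55:01" = 0.02,
             "B*56:01" = 0.01),
    C = pool("C*01:02" = 0.04, "C*02:02" = 0.05, "C*03:03" = 0.06,
             "C*03:04" = 0.08, "C*04:01" = 0.12, "C*05:01" = 0.08,
             "C*06:02" = 0.09, "C*07:01" = 0.14, "C*07:02" = 0.14,
             "C*08:02" = 0.04, "C*12:02" = 0.02, "C*12:03" = 0.06,
             "C*14:02" = 0.02, "C*15:02" = 0.03, "C*16:01" = 0.03),
    DRB1 = pool("DRB1*01:01" = 0.09, "DRB1*03:01" = 0.13, "DRB1*04:01" = 0.09,
                "DRB1*07:01" = 0.14, "DRB1*08:01" = 0.03, "DRB1*09:01" = 0.02,
                "DRB1*10:01" = 0.01, "DRB1*11:01" = 0.09, "DRB1*11:04" = 0.03,
                "DRB1*12:01" = 0.02, "DRB1*13:01" = 0.06, "DRB1*13:02" = 0.05,
                "DRB1*14:01" = 0.03, "DRB1*15:01" = 0.14, "DRB1*15:02" = 0.02,
                "DRB1*16:01" = 0.05),
    DQA1 = pool("DQA1*01:01" = 0.11, "DQA1*01:02" = 0.18, "DQA1*01:03" = 0.06,
                "DQA1*02:01" = 0.13, "DQA1*03:01" = 0.08, "DQA1*03:03" = 0.06,
                "DQA1*04:01" = 0.04, "DQA1*05:01" = 0.18, "DQA1*05:05" = 0.16),
    DQB1 = pool("DQB1*02:01" = 0.12, "DQB1*02:02" = 0.11, "DQB1*03:01" = 0.18,
                "DQB1*03:02" = 0.10, "DQB1*03:03" = 0.05, "DQB1*04:02" = 0.04,
                "DQB1*05:01" = 0.12, "DQB1*05:02" = 0.03, "DQB1*05:03" = 0.03,
                "DQB1*06:02" = 0.12, "DQB1*06:03" = 0.05, "DQB1*06:04" = 0.04,
                "DQB1*06:01" = 0.01),
    DRB345 = pool("DRB3*01:01" = 0.25, "DRB3*02:02" = 0.20, "DRB3*03:01" = 0.05,
                  "DRB4*01:03" = 0.25, "DRB5*01:01" = 0.12, "ABSENT" = 0.13),
    G = pool("G*01:01" = 0.55, "G*01:03" = 0.20, "G*01:04" = 0.15,
             "G*01:06" = 0.10)
  )
  structure(list(
    ancestries = .default_ancestries,
    pc = list(
      n_pcs = 10L,
      sd = 0.4,
      centroids = rbind(EUR = c(0, 0), EAS = c(6, 0), AFR = c(0, 6))
    ),
    cen = list(segments = cen_segments, freq = cen_freq),
    tel = list(segments = tel_segments, freq = tel_freq),
    kir_alleles = kir_alleles,
    hla_haplotypes = hla_haplotypes,
    hla_hap_freq = hap_freq,
    hla_pools = hla_pools,
    hlag_del_freq = c(EUR = 0.55, EAS = 0.45, AFR = 0.40)
  ), class = "haplotype_config")
}

#' Validate a haplotype configuration
#'
#' Checks that segment frequencies sum to 1 per ancestry, allele pools sum
#' to 1 per locus, framework genes (KIR3DL3, KIR3DP1 centromeric; KIR2DL4,
#' KIR3DL2 telomeric) sit on every segment, and HLA haplotype frequencies
#' leave a non-negative residual.
#'
#' @param hap A `haplotype_config`.
#' @return `hap`, invisibly, or an error.
#' @export
validate_haplotype_config <- function(hap) {
  tol <- 1e-6
  for (side in c("cen", "tel")) {
    fr <- hap[[side]]$freq
    if (!setequal(colnames(fr), names(hap[[side]]$segments)))
      stop(side, " frequency columns must match segment names")
    if (any(abs(rowSums(fr) - 1) > tol))
      stop(side, " segment frequencies must sum to 1 per ancestry")
  }
  for (g in c("KIR3DL3", "KIR3DP1"))
    if (!all(vapply(hap$cen$segments, function(s) g %in% s, logical(1))))
      stop("framework gene ", g, " missing from a centromeric segment")
  for (g in c("KIR2DL4", "KIR3DL2"))
    if (!all(vapply(hap$tel$segments, function(s) g %in% s, logical(1))))
      stop("framework gene ", g, " missing from a telomeric segment")
  carried <- unique(unlist(c(hap$cen$segments, hap$tel$segments)))
  if (!all(carried %in% .kir_cnv_loci))
    stop("unknown KIR locus in segment definitions: ",
         paste(setdiff(carried, .kir_cnv_loci), collapse = ", "))
  for (loc in carried) {
    p <- hap$kir_alleles[[loc]]
    if (is.null(p)) stop("no allele pool for carried locus ", loc)
    if (abs(sum(p$freq) - 1) > tol) stop("allele pool for ", loc, " must sum to 1")
  }
  if (any(rowSums(hap$hla_hap_freq) > 1 + tol))
    stop("HLA haplotype frequencies exceed 1; no residual mass left")
  for (loc in names(hap$hla_pools))
    if (abs(sum(hap$hla_pools[[loc]]$freq) - 1) > tol)
      stop("HLA pool for ", loc, " must sum to 1")
  invisible(hap)
}

#' Planted-effect configuration for the disease model
#'
#' @param intercept Baseline log-odds of disease.
#' @param marker Character vector of markers (syntax as in
#'   [carrier_indicator()]; additive effects require a KIR copy-number or
#'   union locus).
#' @param coding `"carrier"` or `"additive_copy"` per effect.
#' @param log_or Planted log-odds ratio per effect.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(intercept = -2, marker = character(0),
                          coding = character(0), log_or = numeric(0)) {
  stopifnot(length(marker) == length(coding), length(marker) == length(log_or),
            all(coding %in% c("carrier", "additive_copy")), all(is.finite(log_or)),
            is.finite(intercept))
  structure(list(intercept = intercept,
                 effects = data.frame(marker = as.character(marker),
                                      coding = as.character(coding),
                                      log_or = as.numeric(log_or),
                                      stringsAsFactors = FALSE)),
            class = "effect_config")
}

#' Default stratum composition
#'
#' Three ancestry-by-platform strata with a European-descent majority,
#' applied to both cases and controls.
#'
#' @return Data frame with columns `ancestry`, `platform`, `prop`.
#' @export
default_strata <- function() {
  data.frame(ancestry = c("EUR", "EAS", "AFR"),
             platform = c("Illumina", "Affymetrix", "Affymetrix"),
             prop = c(0.70, 0.15, 0.15),
             stringsAsFactors = FALSE)
}

# split a total into quota counts proportional to prop (largest remainder)
.quota <- function(n, prop) {
  raw <- n * prop / sum(prop)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1L
  }
  as.integer(k)
}

.sample_idx <- function(n, prob) {
  sample.int(length(prob), n, replace = TRUE, prob = prob)
}

# segment-membership matrix: segments x loci
.segment_membership <- function(segments, loci) {
  m <- vapply(loci, function(l) vapply(segments, function(s) l %in% s, logical(1)),
              logical(length(segments)))
  matrix(as.integer(m), nrow = length(segments), dimnames = list(NULL, loci))
}

# draw a raw genotype batch of size n for one ancestry/platform stratum.
# Raw form keeps KIR copy numbers and the two per-locus allele draws as
# matrices so the disease model can be evaluated without building (and
# re-parsing) a cohort; only accepted individuals are stringified.
.sim_batch <- function(hap, n, ancestry, platform, Mc, Mt) {
  cen_names <- names(hap$cen$segments)
  tel_names <- names(hap$tel$segments)
  c1 <- .sample_idx(n, hap$cen$freq[ancestry, cen_names])
  c2 <- .sample_idx(n, hap$cen$freq[ancestry, cen_names])
  t1 <- .sample_idx(n, hap$tel$freq[ancestry, tel_names])
  t2 <- .sample_idx(n, hap$tel$freq[ancestry, tel_names])
  cn <- Mc[c1, , drop = FALSE] + Mc[c2, , drop = FALSE] +
        Mt[t1, , drop = FALSE] + Mt[t2, , drop = FALSE]

  core <- data.frame(individual_id = rep(NA_character_, n), phenotype = "control",
                     subgroup = "unknown", ancestry = ancestry,
                     platform = platform, hlag_14bp = NA_character_,
                     stringsAsFactors = FALSE)

  # HLA-G 14-bp ins/del genotype
  pdel <- hap$hlag_del_freq[[ancestry]]
  g1 <- stats::runif(n) < pdel
  g2 <- stats::runif(n) < pdel
  core$hlag_14bp <- ifelse(g1 & g2, "del/del",
                    ifelse(!g1 & !g2, "ins/ins", "ins/del"))

  # class II haplotype block with residual recombinant pool
  hf <- hap$hla_hap_freq[ancestry, ]
  hprob <- c(hf, residual = 1 - sum(hf))
  h1 <- .sample_idx(n, hprob)
  h2 <- .sample_idx(n, hprob)
  nhap <- nrow(hap$hla_haplotypes)
  draw_pool <- function(locus, n) {
    p <- hap$hla_pools[[locus]]
    p$allele[.sample_idx(n, p$freq)]
  }
  for (locus in c("DRB1", "DQA1", "DQB1")) {
    a1 <- ifelse(h1 <= nhap, hap$hla_haplotypes[[locus]][pmin(h1, nhap)], NA)
    a2 <- ifelse(h2 <= nhap, hap$hla_haplotypes[[locus]][pmin(h2, nhap)], NA)
    a1[is.na(a1)] <- draw_pool(locus, sum(is.na(a1)))
    a2[is.na(a2)] <- draw_pool(locus, sum(is.na(a2)))
    core[[paste0(locus, ".1")]] <- a1
    core[[paste0(locus, ".2")]] <- a2
  }
  for (locus in c("A", "B", "C", "DRB345", "G")) {
    a1 <- draw_pool(locus, n)
    a2 <- draw_pool(locus, n)
    a1[a1 == "ABSENT"] <- NA
    a2[a2 == "ABSENT"] <- NA
    core[[paste0(locus, ".1")]] <- a1
    core[[paste0(locus, ".2")]] <- a2
  }

  # two allele draws per measured KIR locus; the multiset keeps the first
  # cn of them
  loci <- colnames(cn)
  ka1 <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))
  ka2 <- ka1
  for (loc in loci) {
    if (!any(cn[, loc] > 0L)) next
    p <- hap$kir_alleles[[loc]]
    ka1[, loc] <- p$allele[.sample_idx(n, p$freq)]
    ka2[, loc] <- p$allele[.sample_idx(n, p$freq)]
  }

  npc <- hap$pc$n_pcs
  centro <- rep(0, npc)
  cc <- hap$pc$centroids[ancestry, ]
  centro[seq_along(cc)] <- cc
  pcs <- matrix(stats::rnorm(n * npc, sd = hap$pc$sd), n, npc, byrow = FALSE)
  pcs <- sweep(pcs, 2L, centro, `+`)
  colnames(pcs) <- paste0("PC", seq_len(npc))
  list(core = core, cn = cn, ka1 = ka1, ka2 = ka2, pcs = pcs)
}

.raw_take <- function(raw, idx) {
  list(core = raw$core[idx, , drop = FALSE],
       cn = raw$cn[idx, , drop = FALSE],
       ka1 = raw$ka1[idx, , drop = FALSE],
       ka2 = raw$ka2[idx, , drop = FALSE],
       pcs = raw$pcs[idx, , drop = FALSE])
}

.raw_bind <- function(raws) {
  list(core = do.call(rbind, lapply(raws, `[[`, "core")),
       cn = do.call(rbind, lapply(raws, `[[`, "cn")),
       ka1 = do.call(rbind, lapply(raws, `[[`, "ka1")),
       ka2 = do.call(rbind, lapply(raws, `[[`, "ka2")),
       pcs = do.call(rbind, lapply(raws, `[[`, "pcs")))
}

# marker value on a raw batch: carrier indicator or copy number
.raw_marker <- function(raw, marker, coding) {
  cn_of <- function(locus) {
    if (locus %in% names(.kir_union_loci))
      rowSums(raw$cn[, .kir_union_loci[[locus]], drop = FALSE])
    else raw$cn[, locus]
  }
  if (!grepl("*", marker, fixed = TRUE)) {
    hit <- match(toupper(marker), toupper(.presence_loci()))
    if (is.na(hit)) stop("unknown marker '", marker, "'")
    k <- cn_of(.presence_loci()[hit])
    return(if (coding == "additive_copy") as.numeric(k) else as.numeric(k >= 1))
  }
  if (coding == "additive_copy")
    stop("additive coding requires a KIR copy-number locus, got '", marker, "'")
  parts <- strsplit(toupper(marker), "*", fixed = TRUE)[[1]]
  locus_tok <- sub("^HLA-", "", parts[1])
  code <- parts[2]
  if (locus_tok == .hlag14_locus)
    return(as.numeric(grepl(tolower(code), raw$core$hlag_14bp, fixed = TRUE)))
  if (locus_tok %in% .kir_allele_loci) {
    cols <- names(.kir_cnv_allele_locus)[.kir_cnv_allele_locus == locus_tok]
    if (locus_tok == "KIR2DL5") cols <- c("KIR2DL5A", "KIR2DL5B")
    is_group <- nchar(code) == 3L
    hit <- rep(FALSE, nrow(raw$cn))
    for (cl in cols) {
      a1 <- raw$ka1[, cl]; a2 <- raw$ka2[, cl]; k <- raw$cn[, cl]
      if (is_group) {
        hit <- hit | (k >= 1L & substr(a1, 1, 3) %in% code) |
                     (k >= 2L & substr(a2, 1, 3) %in% code)
      } else {
        hit <- hit | (k >= 1L & a1 %in% code) | (k >= 2L & a2 %in% code)
      }
    }
    return(as.numeric(hit))
  }
  if (locus_tok %in% .hla_loci) {
    slot <- .hla_slot_for(locus_tok)
    target <- paste0(locus_tok, "*", code)
    a1 <- raw$core[[paste0(slot, ".1")]]
    a2 <- raw$core[[paste0(slot, ".2")]]
    return(as.numeric(a1 %in% target | a2 %in% target))
  }
  stop("unknown marker '", marker, "'")
}

# linear predictor of the disease model on a raw batch
.raw_lp <- function(raw, eff) {
  lp <- rep(eff$intercept, nrow(raw$core))
  if (nrow(eff$effects)) {
    for (i in seq_len(nrow(eff$effects))) {
      e <- eff$effects[i, ]
      lp <- lp + e$log_or * .raw_marker(raw, e$marker, e$coding)
    }
  }
  lp
}

# stringify a raw block into the cohort data layout
.raw_to_data <- function(raw) {
  d <- raw$core
  for (loc in colnames(raw$cn)) {
    k <- raw$cn[, loc]
    a1 <- raw$ka1[, loc]; a2 <- raw$ka2[, loc]
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    d[[loc]] <- ifelse(k == 0L, "0:",
                ifelse(k == 1L, paste0("1:", a1), paste0("2:", lo, ",", hi)))
  }
  d[, c("individual_id", "phenotype", "subgroup", "ancestry", "platform",
        "hlag_14bp", .hla_cols(), colnames(raw$cn))]
}

#' Simulate a case-control cohort
#'
#' Generates genotypes under `hap`, assigns disease status from the
#' logistic model in `eff` by rejection sampling, and fills the case and
#' control quotas per stratum. Fully reproducible from `seed`. Teratoma /
#' other-tumor / non-paraneoplastic subgroup labels are assigned to cases
#' at fixed proportions (0.22 / 0.04 / 0.74), mirroring the tumour
#' composition typical of anti-NMDAR encephalitis case series.
#'
#' @param hap A `haplotype_config` (default [default_haplotype_config()]).
#' @param eff An `effect_config` (default: intercept -2, no planted effects).
#' @param n_cases,n_controls Quotas (>= 1).
#' @param strata Data frame `ancestry`, `platform`, `prop` (default
#'   [default_strata()]); proportions apply to cases and controls alike.
#' @param seed Integer seed (required).
#' @param max_batches Cap on rejection-sampling rounds per stratum before
#'   the quota is declared unreachable.
#' @return A `kir_cohort`.
#' @export
simulate_cohort <- function(hap = default_haplotype_config(),
                            eff = effect_config(),
                            n_cases, n_controls,
                            strata = default_strata(),
                            seed, max_batches = 1000L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L)
  if (missing(seed)) stop("a seed is required for reproducibility")
  validate_haplotype_config(hap)
  set.seed(seed)
  Mc <- .segment_membership(hap$cen$segments, .kir_cnv_loci)
  Mt <- .segment_membership(hap$tel$segments, .kir_cnv_loci)
  case_q <- .quota(n_cases, strata$prop)
  ctrl_q <- .quota(n_controls, strata$prop)
  blocks <- list()
  for (s in seq_len(nrow(strata))) {
    need_case <- case_q[s]; need_ctrl <- ctrl_q[s]
    if (need_case + need_ctrl == 0L) next
    got_case <- list(); got_ctrl <- list()
    n_case_have <- 0L; n_ctrl_have <- 0L
    batch_size <- max(500L, need_case + need_ctrl)
    rounds <- 0L
    while (n_case_have < need_case || n_ctrl_have < need_ctrl) {
      rounds <- rounds + 1L
      if (rounds > max_batches)
        stop("case/control quota unreachable in stratum ", strata$ancestry[s],
             "|", strata$platform[s], " after ", max_batches,
             " sampling rounds; intercept too extreme?")
      b <- .sim_batch(hap, batch_size, strata$ancestry[s], strata$platform[s],
                      Mc, Mt)
      p <- stats::plogis(.raw_lp(b, eff))
      is_case <- stats::runif(batch_size) < p
      take_case <- which(is_case)[seq_len(min(sum(is_case), need_case - n_case_have))]
      take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case), need_ctrl - n_ctrl_have))]
      if (length(take_case)) {
        got_case[[length(got_case) + 1L]] <- .raw_take(b, take_case)
        n_case_have <- n_case_have + length(take_case)
      }
      if (length(take_ctrl)) {
        got_ctrl[[length(got_ctrl) + 1L]] <- .raw_take(b, take_ctrl)
        n_ctrl_have <- n_ctrl_have + length(take_ctrl)
      }
      # adapt batch size to the observed acceptance rate of the scarcer arm
      still_case <- need_case - n_case_have
      still_ctrl <- need_ctrl - n_ctrl_have
      rate_case <- max(mean(is_case), 1e-3)
      rate_ctrl <- max(1 - mean(is_case), 1e-3)
      batch_size <- min(200000L, max(500L, as.integer(
        1.2 * max(still_case / rate_case, still_ctrl / rate_ctrl))))
    }
    ca <- .raw_bind(got_case); co <- .raw_bind(got_ctrl)
    ca$core$phenotype <- "case"
    # tumour subgroup labels for cases
    u <- stats::runif(nrow(ca$core))
    ca$core$subgroup <- ifelse(u < 0.22, "teratoma",
                        ifelse(u < 0.26, "other_tumor", "non_paraneoplastic"))
    blocks[[length(blocks) + 1L]] <- .raw_bind(list(ca, co))
  }
  raw <- .raw_bind(blocks)
  d <- .raw_to_data(raw)
  pcs <- raw$pcs
  d$individual_id <- sprintf("IND%06d", seq_len(nrow(d)))
  rownames(pcs) <- d$individual_id
  rownames(d) <- NULL
  new_cohort(d, pcs, metadata = list(
    source = "simulate_cohort", seed = seed,
    n_cases = n_cases, n_controls = n_controls))
}

#' Expected copy number of a KIR locus under a haplotype configuration
#'
#' Exact value: twice the summed frequency of the segments carrying the
#' locus on its side of the cluster (union loci sum over their parts);
#' framework genes therefore always return 2.
#'
#' @param hap A `haplotype_config`.
#' @param locus KIR copy-number or union locus.
#' @param ancestry Ancestry label present in the configuration.
#' @return Expected copies per individual (numeric scalar).
#' @export
expected_copy_number <- function(hap, locus, ancestry) {
  if (locus %in% names(.kir_union_loci))
    return(sum(vapply(.kir_union_loci[[locus]], expected_copy_number,
                      numeric(1), hap = hap, ancestry = ancestry)))
  if (!locus %in% .kir_cnv_loci) stop("unknown KIR copy-number locus '", locus, "'")
  tot <- 0
  for (side in c("cen", "tel")) {
    has <- vapply(hap[[side]]$segments, function(s) locus %in% s, logical(1))
    tot <- tot + 2 * sum(hap[[side]]$freq[ancestry, names(has)[has]])
  }
  tot
}
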