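# Fixed-effect (inverse-variance) meta-analysis across ancestry strata,
# in the METAL SE-weighted scheme: w_i = 1/se_i^2, combined effect
# sum(w b)/sum(w), SE sqrt(1/sum(w)), two-sided z test, and Cochran's
# Q = sum(w (b - effect)^2) on k-1 df for heterogeneity. Strata whose fit
# was unestimable are excluded from weighting and rendered as "?" in the
# per-stratum direction string.

#' Fixed-effect inverse-variance meta-analysis
#'
#' @param beta Per-stratum effect estimates (log-OR scale); NA marks a
#'   stratum not examined (excluded from weighting, "?" in direction).
#' @param se Per-stratum standard errors (positive where beta is finite).
#' @param labels Optional stratum labels, stored in `per_stratum` and
#'   defining the direction-string order.
#' @param freqs Optional per-stratum carrier frequencies, summarized by
#'   [stratum_frequency_summary()].
#' @return Object of class `kir_meta`: list with `effect`, `se`, `z`, `p`,
#'   `k` (strata weighted), `het_q`, `het_p`, `direction`, `per_stratum`
#'   (data frame) and `freq_summary` (or NULL).
#' @export
meta_fixed <- function(beta, se, labels = NULL, freqs = NULL) {
  stopifnot(length(beta) == length(se))
  if (is.null(labels)) labels <- paste0("stratum", seq_along(beta))
  use <- is.finite(beta) & is.finite(se) & se > 0
  if (!any(use)) stop("all strata unestimable; nothing to combine")
  w <- 1 / se[use]^2
  effect <- sum(w * beta[use]) / sum(w)
  se_comb <- sqrt(1 / sum(w))
  z <- effect / se_comb
  p <- 2 * stats::pnorm(-abs(z))
  q <- sum(w * (beta[use] - effect)^2)
  k <- sum(use)
  het_p <- if (k >= 2L) stats::pchisq(q, df = k - 1L, lower.tail = FALSE) else NA_real_
  structure(list(
    effect = effect, se = se_comb, z = z, p = p, k = k,
    het_q = q, het_p = het_p,
    direction = direction_string(ifelse(use, beta, NA_real_)),
    per_stratum = data.frame(stratum = labels, beta = beta, se = se,
                             weighted = use, stringsAsFactors = FALSE),
    freq_summary = if (is.null(freqs)) NULL else stratum_frequency_summary(freqs)
  ), class = "kir_meta")
}

#' @export
print.kir_meta <- function(x, ...) {
  cat("<kir_meta> effect ", signif(x$effect, 4), " (SE ", signif(x$se, 4),
      "), p = ", format(x$p, digits = 3), ", direction ", x$direction,
      ", het p = ", format(x$het_p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Per-stratum direction string
#'
#' One character per stratum in the declared order: `"+"` for a
#' non-negative effect (a zero effect renders `"+"` by convention), `"-"`
#' for a negative effect, `"?"` for a stratum not examined.
#'
#' @param beta Per-stratum effects; NA renders `"?"`.
#' @param order Optional permutation/selection of strata (indices into
#'   `beta`) declaring the cohort order; errors if it does not match.
#' @return Single string, one character per stratum.
#' @export
direction_string <- function(beta, order = NULL) {
  if (!is.null(order)) {
    if (length(order) != length(beta) || anyNA(match(order, seq_along(beta))))
      stop("cohort order does not match the per-stratum results")
    beta <- beta[order]
  }
  paste(ifelse(is.na(beta), "?", ifelse(beta < 0, "-", "+")), collapse = "")
}

#' Cross-stratum frequency summary
#'
#' Arithmetic mean, standard error of the mean, minimum and maximum of a
#' carrier frequency across strata — the per-cohort frequency spread
#' printed alongside meta-analytic effects.
#'
#' @param freqs Per-stratum frequencies (non-empty numeric; NA dropped).
#' @return List with `mean`, `se`, `min`, `max`.
#' @export
stratum_frequency_summary <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  if (!length(freqs)) stop("no stratum frequencies to summarize")
  k <- length(freqs)
  list(mean = mean(freqs),
       se = if (k > 1L) stats::sd(freqs) / sqrt(k) else 0,
       min = min(freqs), max = max(freqs))
}

#' Meta-analytic scan over markers
#'
#' For each marker: per-stratum PC-adjusted fits via [assoc_by_stratum()],
#' inverse-variance combination via [meta_fixed()], and BH-FDR adjustment
#' of the combined p-values over the marker family (markers reaching the
#' carrier-frequency threshold in either phenotype group overall).
#'
#' @param x A `kir_cohort`.
#' @param markers Character vector of markers.
#' @param coding `"carrier"` or `"additive_copy"`.
#' @param freq_threshold Carrier-frequency threshold for the FDR family.
#' @param n_pcs Intra-stratum PCs per fit.
#' @return Data frame with one row per marker: `marker`, `effect`, `se`,
#'   `p`, `p_adj`, `direction`, `het_p`, `freq_mean`, `freq_min`,
#'   `freq_max`, `k`.
#' @export
meta_scan <- function(x, markers, coding = "carrier", freq_threshold = 0.05,
                      n_pcs = 3L) {
  rows <- lapply(markers, function(m) {
    per <- assoc_by_stratum(x, m, coding = coding, n_pcs = n_pcs)
    row <- data.frame(marker = m, effect = NA_real_, se = NA_real_,
                      p = NA_real_, p_adj = NA_real_, direction = NA_character_,
                      het_p = NA_real_, freq_mean = NA_real_, freq_min = NA_real_,
                      freq_max = NA_real_, k = 0L,
                      case_freq = NA_real_, control_freq = NA_real_,
                      estimable = FALSE, stringsAsFactors = FALSE)
    cf <- tryCatch(carrier_frequency(x, m, "case")$freq, error = function(e) NA)
    gf <- tryCatch(carrier_frequency(x, m, "control")$freq, error = function(e) NA)
    row$case_freq <- cf; row$control_freq <- gf
    mm <- tryCatch(
      meta_fixed(per$beta, per$se, labels = per$stratum,
                 freqs = ifelse(is.na(per$case_freq), per$control_freq,
                                per$case_freq)),
      error = function(e) NULL)
    if (!is.null(mm)) {
      row$effect <- mm$effect; row$se <- mm$se; row$p <- mm$p
      row$direction <- mm$direction; row$het_p <- mm$het_p; row$k <- mm$k
      row$freq_mean <- mm$freq_summary$mean
      row$freq_min <- mm$freq_summary$min
      row$freq_max <- mm$freq_summary$max
      row$estimable <- TRUE
    }
    row
  })
  out <- do.call(rbind, rows)
  fam <- adjust_pvalues(
    data.frame(marker = out$marker, p = out$p, estimable = out$estimable,
               case_freq = out$case_freq, control_freq = out$control_freq),
    method = "bh_fdr", freq_threshold = freq_threshold)
  out$p_adj <- fam$p_adj
  out
}
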