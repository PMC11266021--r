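# Carrier-frequency, copy-number and score association testing.
#
# The workhorse is a maximum-likelihood logistic regression of case status
# on a coded marker (carrier indicator, integer copy number, or an
# interaction score) adjusted for the first three principal components,
# with Wald tests per marker. Markers below the carrier-frequency
# reporting threshold in both cases and controls are excluded from the
# multiple-testing family (reported unadjusted, flagged exploratory), and
# unestimable fits (complete separation, zero variance) are dropped from
# the family rather than assigned p = 1. Independent signals are separated
# from linkage by iterative conditioning: the most significant marker is
# added to the covariates and the scan repeated until nothing remains
# significant.

.empty_result <- function(marker, coding) {
  data.frame(marker = marker, coding = coding, beta = NA_real_, se = NA_real_,
             or_value = NA_real_, p = NA_real_, p_adj = NA_real_,
             case_count = NA_integer_, case_n = NA_integer_, case_freq = NA_real_,
             control_count = NA_integer_, control_n = NA_integer_,
             control_freq = NA_real_, estimable = FALSE, exploratory = FALSE,
             covariates = "", stringsAsFactors = FALSE)
}

# logistic fit of y on x with covariate matrix; returns beta/se/p for x.
# Built on glm.fit with an explicit rank check: a marker collinear with
# the covariates (e.g. a conditioning indicator in perfect LD with it) is
# unestimable, and aliased covariate columns are dropped before fitting.
.unestimable <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
                     estimable = FALSE)

.fit_logistic <- function(y, x, covars = NULL) {
  ok <- !is.na(x)
  if (!is.null(covars) && ncol(covars)) ok <- ok & stats::complete.cases(covars)
  y <- y[ok]; x <- as.numeric(x[ok])
  if (!is.null(covars)) covars <- covars[ok, , drop = FALSE]
  if (length(unique(y)) < 2L || length(unique(x)) < 2L) return(.unestimable)
  base <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(covars) && ncol(covars)) {
    # greedily keep covariate columns that add rank
    for (j in seq_len(ncol(covars))) {
      cand <- cbind(base, covars[, j, drop = FALSE])
      if (qr(cand)$rank > qr(base)$rank) base <- cand
    }
  }
  if (qr(cbind(base, x))$rank == qr(base)$rank) return(.unestimable)
  X <- cbind(base, .x = x)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  p1 <- seq_len(fit$rank)
  covmat <- tryCatch(chol2inv(fit$qr$qr[p1, p1, drop = FALSE]),
                     error = function(e) NULL)
  if (is.null(covmat)) return(.unestimable)
  coefs <- fit$coefficients
  se_all <- rep(NA_real_, length(coefs))
  se_all[fit$qr$pivot[p1]] <- sqrt(diag(covmat))
  i <- match(".x", names(coefs))
  beta <- coefs[i]; se <- se_all[i]
  if (is.na(beta) || is.na(se)) return(.unestimable)
  z <- beta / se
  estimable <- is.finite(beta) && is.finite(se) && abs(beta) < 15 && se < 50 &&
    fit$converged
  list(beta = unname(beta), se = unname(se), p = 2 * stats::pnorm(-abs(z)),
       estimable = estimable)
}

.pc_covars <- function(x, n_pcs = 3L) {
  n_pcs <- min(n_pcs, ncol(x$pcs))
  if (n_pcs == 0L)
    return(matrix(numeric(0), nrow = cohort_size(x), ncol = 0L))
  m <- x$pcs[, seq_len(n_pcs), drop = FALSE]
  colnames(m) <- paste0("PC", seq_len(n_pcs))
  m
}

.marker_values <- function(x, marker, coding) {
  switch(coding,
    carrier = carrier_indicator(x, marker),
    additive_copy = kir_copy_number(x, marker),
    stop("unknown coding '", coding, "'"))
}

.freq_fields <- function(res, x, marker) {
  cf <- tryCatch(carrier_frequency(x, marker, "case"), error = function(e) NULL)
  gf <- tryCatch(carrier_frequency(x, marker, "control"), error = function(e) NULL)
  if (!is.null(cf)) {
    res$case_count <- cf$count; res$case_n <- cf$n; res$case_freq <- cf$freq
  }
  if (!is.null(gf)) {
    res$control_count <- gf$count; res$control_n <- gf$n; res$control_freq <- gf$freq
  }
  res
}

#' PC-adjusted logistic association for one marker
#'
#' Fits case status on the coded marker plus the first `n_pcs` principal
#' components and any conditioning markers, and reports the Wald test with
#' carrier counts per phenotype group. Fits with complete separation or a
#' constant predictor are flagged `estimable = FALSE`.
#'
#' @param x A `kir_cohort`.
#' @param marker Marker string (see [carrier_indicator()]).
#' @param coding `"carrier"` (>= 1 copy) or `"additive_copy"` (integer
#'   copies; KIR loci only).
#' @param extra_covariates Character vector of markers to condition on
#'   (entered as carrier indicators), or a numeric matrix of covariates.
#' @param n_pcs Leading PCs to adjust for (default 3).
#' @param pcs Optional covariate matrix overriding the cohort PCs (e.g.
#'   intra-stratum PCs).
#' @return One-row data frame (`AssociationResult`): `marker`, `coding`,
#'   `beta`, `se`, `or_value` (= exp(beta)), `p`, `p_adj` (NA until
#'   [adjust_pvalues()]), carrier counts/frequencies per group,
#'   `estimable`, `covariates`.
#' @export
assoc_logistic <- function(x, marker, coding = "carrier",
                           extra_covariates = character(0), n_pcs = 3L,
                           pcs = NULL) {
  stopifnot(inherits(x, "kir_cohort"))
  y <- as.integer(x$data$phenotype == "case")
  xv <- .marker_values(x, marker, coding)
  covars <- if (is.null(pcs)) .pc_covars(x, n_pcs) else pcs
  cov_names <- colnames(covars)
  if (is.character(extra_covariates) && length(extra_covariates)) {
    extra <- vapply(extra_covariates, function(m) carrier_indicator(x, m),
                    integer(cohort_size(x)))
    colnames(extra) <- paste0("cond_", seq_along(extra_covariates))
    covars <- cbind(covars, extra)
    cov_names <- c(cov_names, extra_covariates)
  } else if (is.matrix(extra_covariates)) {
    covars <- cbind(covars, extra_covariates)
    cov_names <- c(cov_names, colnames(extra_covariates))
  }
  f <- .fit_logistic(y, xv, covars)
  res <- .empty_result(marker, coding)
  res$beta <- f$beta; res$se <- f$se; res$p <- f$p
  res$or_value <- exp(f$beta)
  res$estimable <- f$estimable
  res$covariates <- paste(cov_names, collapse = "+")
  .freq_fields(res, x, marker)
}

#' Crude odds ratio from a 2x2 carrier table
#'
#' Diagnostic closed form against which the unadjusted logistic fit can be
#' checked: OR = ad/bc with the Haldane-Anscombe 0.5 continuity correction
#' applied to every cell iff any cell is zero, and
#' SE(log OR) = sqrt(sum of reciprocal cells).
#'
#' @param a,b,c,d Carrier cases, non-carrier cases, carrier controls,
#'   non-carrier controls.
#' @return List with `or`, `log_or`, `se`.
#' @export
crude_or <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(or = or, log_or = log(or), se = sqrt(sum(1 / cells)))
}

#' Presence and additive copy-number association for a KIR locus
#'
#' Runs the carrier (gene presence) and additive (integer copy) codings
#' through [assoc_logistic()]. A locus with constant copy number (the
#' framework genes KIR3DL3 and KIR3DL2 in typical data) yields
#' not-applicable results flagged unestimable.
#'
#' @param x A `kir_cohort`.
#' @param locus KIR copy-number or union locus.
#' @param ... Passed to [assoc_logistic()].
#' @return List with elements `presence` and `additive`.
#' @export
assoc_cnv <- function(x, locus, ...) {
  cn <- kir_copy_number(x, locus)
  presence <- if (length(unique(cn >= 1L)) < 2L) {
    r <- .empty_result(locus, "carrier"); r$covariates <- "n/a (no presence variation)"
    .freq_fields(r, x, locus)
  } else assoc_logistic(x, locus, coding = "carrier", ...)
  additive <- if (length(unique(cn)) < 2L) {
    r <- .empty_result(locus, "additive_copy"); r$covariates <- "n/a (constant copy number)"
    .freq_fields(r, x, locus)
  } else assoc_logistic(x, locus, coding = "additive_copy", ...)
  list(presence = presence, additive = additive)
}

#' Multiple-testing adjustment over a marker family
#'
#' The adjustment family contains the estimable markers whose carrier
#' frequency reaches `freq_threshold` in cases or in controls; the rest
#' keep their raw p (flagged `exploratory = TRUE`, `p_adj = NA`).
#'
#' @param results Data frame of stacked `AssociationResult` rows.
#' @param method `"bh_fdr"` (Benjamini-Hochberg step-up) or `"bonferroni"`.
#' @param freq_threshold Carrier-frequency threshold (default 0.05).
#' @return `results` with `p_adj` and `exploratory` filled in.
#' @export
adjust_pvalues <- function(results, method = c("bh_fdr", "bonferroni"),
                           freq_threshold = 0.05) {
  method <- match.arg(method)
  in_family <- results$estimable & !is.na(results$p) &
    (pmax(results$case_freq, results$control_freq, na.rm = TRUE) >= freq_threshold)
  in_family[is.na(in_family)] <- FALSE
  results$exploratory <- !in_family
  results$p_adj <- NA_real_
  if (!any(in_family)) {
    warning("empty adjustment family; no p-values adjusted")
    return(results)
  }
  results$p_adj[in_family] <- stats::p.adjust(
    results$p[in_family], method = if (method == "bh_fdr") "BH" else "bonferroni")
  results
}

#' Iterative conditional association scan
#'
#' Repeatedly fits every remaining marker with the previously selected
#' markers as covariates, adjusts p-values over the family, and moves the
#' most significant marker into the conditioning set, stopping when no
#' adjusted (or raw, see `use_adjusted`) p-value is below `alpha`. This
#' separates independent association signals from linkage shadows.
#'
#' @param x A `kir_cohort`.
#' @param markers Character vector of candidate markers.
#' @param alpha Stopping threshold (default 0.05).
#' @param coding Marker coding for all candidates (default `"carrier"`).
#' @param method,freq_threshold Passed to [adjust_pvalues()].
#' @param use_adjusted Condition on adjusted (default) or raw p-values.
#' @param n_pcs Leading PCs adjusted for in every fit.
#' @return Data frame of class `conditioning_trace`: one row per
#'   iteration (`iteration`, `marker`, `p`, `p_adj`, `conditioned_on`);
#'   zero rows if nothing is significant.
#' @export
conditional_scan <- function(x, markers, alpha = 0.05, coding = "carrier",
                             method = "bh_fdr", freq_threshold = 0.05,
                             use_adjusted = TRUE, n_pcs = 3L) {
  stopifnot(length(markers) >= 1L)
  trace <- list()
  selected <- character(0)
  remaining <- markers
  repeat {
    if (!length(remaining)) break
    fits <- do.call(rbind, lapply(remaining, function(m)
      assoc_logistic(x, m, coding = coding, extra_covariates = selected,
                     n_pcs = n_pcs)))
    # an all-unestimable (or all-exploratory) round simply ends the scan
    fits <- suppressWarnings(
      adjust_pvalues(fits, method = method, freq_threshold = freq_threshold))
    crit <- if (use_adjusted) fits$p_adj else fits$p
    crit[!fits$estimable] <- NA_real_
    if (all(is.na(crit)) || min(crit, na.rm = TRUE) >= alpha) break
    best <- order(crit, fits$marker)[1L]
    trace[[length(trace) + 1L]] <- data.frame(
      iteration = length(trace) + 1L, marker = fits$marker[best],
      beta = fits$beta[best], or_value = fits$or_value[best],
      p = fits$p[best], p_adj = fits$p_adj[best],
      conditioned_on = paste(selected, collapse = "+"),
      stringsAsFactors = FALSE)
    selected <- c(selected, fits$marker[best])
    remaining <- setdiff(remaining, selected)
  }
  out <- if (length(trace)) do.call(rbind, trace) else
    data.frame(iteration = integer(0), marker = character(0),
               beta = numeric(0), or_value = numeric(0), p = numeric(0),
               p_adj = numeric(0), conditioned_on = character(0))
  class(out) <- c("conditioning_trace", "data.frame")
  out
}

#' Association of an effective receptor-ligand pair
#'
#' Logistic fit of case status on the presence of one effective pair
#' (receptor carried and ligand state satisfied) plus the leading PCs.
#'
#' @param x A `kir_cohort`.
#' @param pair Pair name `"LOCUS_PATTERN"` (e.g. `"KIR2DL1_C2"`) or a
#'   length-2 vector `c(locus, pattern)`.
#' @param motif_table A `motif_table`.
#' @param n_pcs Leading PCs to adjust for.
#' @return One-row `AssociationResult` data frame (carrier fields report
#'   pair presence).
#' @export
pair_presence_assoc <- function(x, pair, motif_table = load_motif_table(),
                                n_pcs = 3L) {
  if (length(pair) == 2L) pair <- paste(pair, collapse = "_")
  us <- regexpr("_", pair, fixed = TRUE)
  locus <- substr(pair, 1L, us - 1L)
  pattern <- substr(pair, us + 1L, nchar(pair))
  pm <- enumerate_pairs(x, motif_table, loci = locus, patterns = pattern)
  ind <- as.integer(pm[, 1L])
  y <- as.integer(x$data$phenotype == "case")
  f <- .fit_logistic(y, ind, .pc_covars(x, n_pcs))
  res <- .empty_result(pair, "carrier")
  res$beta <- f$beta; res$se <- f$se; res$p <- f$p
  res$or_value <- exp(f$beta); res$estimable <- f$estimable
  res$covariates <- paste(colnames(.pc_covars(x, n_pcs)), collapse = "+")
  is_case <- x$data$phenotype == "case"
  res$case_count <- sum(ind[is_case]); res$case_n <- sum(is_case)
  res$case_freq <- res$case_count / res$case_n
  res$control_count <- sum(ind[!is_case]); res$control_n <- sum(!is_case)
  res$control_freq <- res$control_count / res$control_n
  res
}

#' Association of the signed interaction scores
#'
#' Two complementary fits of one score component: a logistic GLM of case
#' status on the score (+ leading PCs), and a proportional-odds ordinal
#' regression of the integer score on case status (+ leading PCs).
#'
#' @param x A `kir_cohort`.
#' @param component `"inhibitory"`, `"activating"` or `"net"`.
#' @param score_table,motif_table Score and motif configuration.
#' @param scores Optional precomputed [score_cohort()] table.
#' @param n_pcs Leading PCs to adjust for.
#' @return List with `glm` (one-row `AssociationResult`, coding
#'   `"score"`) and `ordinal` (data frame `beta`, `se`, `p` for the case
#'   coefficient; NA row if the score is constant).
#' @export
score_assoc <- function(x, component = c("inhibitory", "activating", "net"),
                        score_table = load_score_table(),
                        motif_table = load_motif_table(),
                        scores = NULL, n_pcs = 3L) {
  component <- match.arg(component)
  if (is.null(scores)) scores <- score_cohort(x, score_table, motif_table)
  s <- scores[[component]]
  y <- as.integer(x$data$phenotype == "case")
  covars <- .pc_covars(x, n_pcs)
  f <- .fit_logistic(y, s, covars)
  res <- .empty_result(paste0("score_", component), "score")
  res$beta <- f$beta; res$se <- f$se; res$p <- f$p
  res$or_value <- exp(f$beta); res$estimable <- f$estimable
  res$covariates <- paste(colnames(covars), collapse = "+")

  ord <- data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                    estimable = FALSE)
  n_levels <- length(unique(s))
  if (n_levels == 2L) {
    # a two-level outcome makes the proportional-odds model a plain
    # logistic regression of the high score level
    f2 <- .fit_logistic(as.integer(s == max(s)), y, covars)
    ord <- data.frame(beta = f2$beta, se = f2$se, p = f2$p,
                      estimable = f2$estimable)
  } else if (n_levels >= 3L) {
    df <- data.frame(.s = factor(s, ordered = TRUE), .case = y,
                     as.data.frame(covars))
    fit <- tryCatch(
      suppressWarnings(MASS::polr(.s ~ ., data = df, Hess = TRUE,
                                  method = "logistic")),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- summary(fit)$coefficients
      if (".case" %in% rownames(co)) {
        z <- co[".case", "t value"]
        ord <- data.frame(beta = co[".case", "Value"],
                          se = co[".case", "Std. Error"],
                          p = 2 * stats::pnorm(-abs(z)),
                          estimable = is.finite(z))
      }
    }
  }
  list(glm = res, ordinal = ord)
}

#' Intra-stratum principal components
#'
#' Re-derives PCs within one stratum by singular value decomposition of
#' the stratum's (centred) PC coordinates, so that regression adjustment
#' inside an ancestry group uses axes of variation specific to that group.
#'
#' @param x A `kir_cohort` (already subset to one stratum).
#' @param n_pcs Number of components to return.
#' @return Matrix of intra-stratum PC scores (`iPC1..`).
#' @export
intra_stratum_pcs <- function(x, n_pcs = 3L) {
  p <- stats::prcomp(x$pcs, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(p$x))
  m <- p$x[, seq_len(k), drop = FALSE]
  colnames(m) <- paste0("iPC", seq_len(k))
  m
}

#' Per-stratum association fits for one marker
#'
#' Splits the cohort by ancestry-by-platform stratum, recomputes PCs
#' within each stratum, and fits the marker there; strata where the fit is
#' unestimable (e.g. the marker is absent) return NA effect rows that a
#' downstream meta-analysis renders as "?" in the direction string.
#'
#' @param x A `kir_cohort`.
#' @param marker Marker string.
#' @param coding `"carrier"` or `"additive_copy"`.
#' @param n_pcs Intra-stratum PCs to adjust for.
#' @param min_n Minimum stratum size to attempt a fit.
#' @return Data frame: `stratum`, `beta`, `se`, `p`, `n`, `case_freq`,
#'   `control_freq`, `estimable`.
#' @export
assoc_by_stratum <- function(x, marker, coding = "carrier", n_pcs = 3L,
                             min_n = 30L) {
  strata <- cohort_strata(x)
  out <- lapply(sort(unique(strata)), function(s) {
    sub <- subset_cohort(x, strata == s)
    row <- data.frame(stratum = s, beta = NA_real_, se = NA_real_,
                      p = NA_real_, n = cohort_size(sub),
                      case_freq = NA_real_, control_freq = NA_real_,
                      estimable = FALSE, stringsAsFactors = FALSE)
    cf <- tryCatch(carrier_frequency(sub, marker, "case"), error = function(e) NULL)
    gf <- tryCatch(carrier_frequency(sub, marker, "control"), error = function(e) NULL)
    if (!is.null(cf)) row$case_freq <- cf$freq
    if (!is.null(gf)) row$control_freq <- gf$freq
    if (cohort_size(sub) >= min_n &&
        length(unique(sub$data$phenotype)) == 2L) {
      r <- assoc_logistic(sub, marker, coding = coding,
                          pcs = intra_stratum_pcs(sub, n_pcs))
      if (r$estimable) {
        row$beta <- r$beta; row$se <- r$se; row$p <- r$p; row$estimable <- TRUE
      }
    }
    row
  })
  do.call(rbind, out)
}
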