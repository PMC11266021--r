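# Nearest-neighbour control matching in principal-component space.
#
# Reproduces the control-selection step of PC-matched case-control designs:
# each case is matched to its k closest controls by Euclidean distance on
# the leading PCs, restricted to controls from the same ancestry-by-platform
# stratum. Matching is without replacement by default (each control serves
# one case), with cases processed in a seeded random order so that no case
# systematically gets first pick; ties in distance are broken by control id.

#' Match cases to their nearest controls in PC space
#'
#' @param cases,controls Either `kir_cohort` objects (cases/controls taken
#'   from their rows; `cases` may contain controls and vice versa — rows
#'   are used as given) or data frames with columns `individual_id`,
#'   `stratum`, and numeric `PC1..PCk`.
#' @param k Number of controls per case (default 10).
#' @param pcs_used Number of leading PCs in the distance (default 10,
#'   capped at the available number).
#' @param with_replacement If `FALSE` (default) each control is used at
#'   most once; cases that cannot receive their full `k` are reported in
#'   `unmatched_cases`. If `TRUE`, every case independently gets its k
#'   nearest controls and the result does not depend on case order.
#' @param seed Seed for the case processing order (ignored with
#'   replacement).
#' @return An object of class `kir_match`: list with `matches` (data frame
#'   `case_id`, `control_id`, `rank`, `distance`, distances non-decreasing
#'   within case), `unmatched_cases`, and the matching parameters.
#' @export
match_controls <- function(cases, controls, k = 10L, pcs_used = 10L,
                           with_replacement = FALSE, seed = 1L) {
  as_tbl <- function(x, phen) {
    if (inherits(x, "kir_cohort")) {
      i <- x$data$phenotype == phen
      data.frame(individual_id = x$data$individual_id[i],
                 stratum = cohort_strata(x)[i],
                 x$pcs[i, , drop = FALSE],
                 stringsAsFactors = FALSE, check.names = FALSE)
    } else x
  }
  ca <- as_tbl(cases, "case")
  co <- as_tbl(controls, "control")
  if (nrow(ca) == 0L) stop("no cases to match")
  pc_cols <- grep("^PC", names(ca), value = TRUE)
  pcs_used <- min(pcs_used, length(pc_cols))
  pc_cols <- pc_cols[seq_len(pcs_used)]
  stopifnot(k >= 1L, pcs_used >= 1L)

  matches <- vector("list", nrow(ca))
  unmatched <- character(0)
  # seeded random processing order (only consequential without replacement)
  order_idx <- if (with_replacement) seq_len(nrow(ca)) else {
    withr_seed <- seed
    local({ set.seed(withr_seed); sample.int(nrow(ca)) })
  }
  used <- new.env(parent = emptyenv())
  for (ci in order_idx) {
    strat <- ca$stratum[ci]
    pool <- co[co$stratum == strat, , drop = FALSE]
    if (!with_replacement && nrow(pool)) {
      taken <- vapply(pool$individual_id, function(id)
        !is.null(used[[id]]), logical(1))
      pool <- pool[!taken, , drop = FALSE]
    }
    if (nrow(pool) == 0L) {
      unmatched <- c(unmatched, ca$individual_id[ci])
      next
    }
    dx <- sweep(as.matrix(pool[, pc_cols, drop = FALSE]), 2L,
                as.numeric(ca[ci, pc_cols]), `-`)
    dist <- sqrt(rowSums(dx^2))
    ord <- order(dist, pool$individual_id)
    take <- ord[seq_len(min(k, length(ord)))]
    matches[[ci]] <- data.frame(case_id = ca$individual_id[ci],
                                control_id = pool$individual_id[take],
                                rank = seq_along(take),
                                distance = dist[take],
                                stringsAsFactors = FALSE)
    if (!with_replacement)
      for (id in pool$individual_id[take]) used[[id]] <- TRUE
    if (length(take) < k) unmatched <- c(unmatched, ca$individual_id[ci])
  }
  got <- !vapply(matches, is.null, logical(1))
  res <- if (any(got)) do.call(rbind, matches[got]) else
    data.frame(case_id = character(0), control_id = character(0),
               rank = integer(0), distance = numeric(0))
  # stable output order: by case as given, then rank
  res <- res[order(match(res$case_id, ca$individual_id), res$rank), , drop = FALSE]
  rownames(res) <- NULL
  if (length(unmatched))
    warning(length(unmatched), " case(s) could not receive their full k=",
            k, " matched controls")
  structure(list(matches = res, unmatched_cases = sort(unique(unmatched)),
                 k = k, pcs_used = pcs_used,
                 with_replacement = with_replacement, seed = seed),
            class = "kir_match")
}

#' @export
print.kir_match <- function(x, ...) {
  cat("<kir_match> ", length(unique(x$matches$case_id)), " matched case(s), k=",
      x$k, ", ", x$pcs_used, " PCs, ",
      if (x$with_replacement) "with" else "without", " replacement\n", sep = "")
  if (length(x$unmatched_cases))
    cat("  incompletely matched cases: ", length(x$unmatched_cases), "\n", sep = "")
  invisible(x)
}

#' Restrict a cohort to matched cases and their matched controls
#'
#' @param x A `kir_cohort` containing the cases and the control pool.
#' @param match A `kir_match` from [match_controls()].
#' @return A `kir_cohort` with the fully matched cases and every control
#'   they were matched to.
#' @export
apply_match <- function(x, match) {
  full <- setdiff(unique(match$matches$case_id), match$unmatched_cases)
  ctrl <- unique(match$matches$control_id[match$matches$case_id %in% full])
  keep <- x$data$individual_id %in% c(full, ctrl)
  subset_cohort(x, keep)
}
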