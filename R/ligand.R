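# KIR-ligand motif classification and signed interaction scoring.
#
# Subsets of HLA class I allotypes serve as KIR ligands: the A3 and A11
# motifs (HLA-A*03/*11 groups, ligands of KIR3DL2), the Bw4 epitope at
# residues 77-83 of HLA-B and a few HLA-A allotypes (ligand of
# KIR3DL1/3DS1, split by residue 80 into 80I and 80T forms), and the
# HLA-C residue-80 dimorphism that partitions every HLA-C allotype into
# C1 (Asn80; also carried by B*46:01 and B*73:01) or C2 (Lys80). Per
# individual, each carried receptor facing a satisfied ligand state forms
# an "effective pair"; a signed weight table (magnitude 1-3, inhibitory or
# activating) turns the pair set into a total inhibitory score, a total
# activating score, and their difference (activating minus inhibitory).

.motif_levels <- c("A3", "A11", "Bw4-80I", "Bw4-80T", "C1", "C2", "none")
.pattern_levels <- c("A3", "A11", "Bw4", "Bw4-80I", "Bw4-80T",
                     "C1", "C2", "C1_C1", "C1_C2", "C2_C2")

#' Load an HLA to KIR-ligand motif table
#'
#' CSV with columns `locus` (e.g. `HLA-C`), `allele` (two-field code) and
#' `motif` (one of A3, A11, Bw4-80I, Bw4-80T, C1, C2, none). The bundled
#' default covers the allotypes produced by the synthetic-cohort generator
#' plus common reference assignments; replace it with a fuller table for
#' real data.
#'
#' @param path CSV path; `NULL` loads the bundled table.
#' @return Data frame of class `motif_table`.
#' @export
load_motif_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hla_kir_motifs.csv", package = "kirhla",
                        mustWork = TRUE)
  mt <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "allele", "motif") %in% names(mt)))
  mt$locus <- toupper(mt$locus)
  mt$allele <- toupper(mt$allele)
  if (!all(mt$motif %in% .motif_levels))
    stop("unknown motif label(s): ",
         paste(setdiff(mt$motif, .motif_levels), collapse = ", "))
  key <- paste(mt$locus, mt$allele)
  if (anyDuplicated(key))
    stop("allele assigned to more than one motif: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  bad_c <- mt$locus == "HLA-C" & !mt$motif %in% c("C1", "C2")
  if (any(bad_c))
    stop("every HLA-C allele must map to C1 or C2; offending: ",
         paste(mt$allele[bad_c], collapse = ", "))
  if (any(mt$motif == "A3" & !startsWith(mt$allele, "03")))
    stop("A3 motif is restricted to the A*03 group")
  if (any(mt$motif == "A11" & !startsWith(mt$allele, "11")))
    stop("A11 motif is restricted to the A*11 group")
  class(mt) <- c("motif_table", "data.frame")
  mt
}

#' Classify one HLA allele into its KIR-ligand motif
#'
#' Input is truncated to two fields before lookup. Class II alleles are
#' never KIR ligands and return `"none"` without requiring a table entry.
#' HLA-A/B/C alleles absent from the table return `"unknown"` (for HLA-C a
#' `residue80` column in the table, if present, is used as a fallback:
#' N -> C1, K -> C2).
#'
#' @param allele Allele string or `allele_name` (must be HLA).
#' @param table A `motif_table` (default: bundled).
#' @return Motif string.
#' @export
classify_motif <- function(allele, table = load_motif_table()) {
  a <- if (is.character(allele)) parse_allele(allele) else allele
  if (!startsWith(a$locus, "HLA-"))
    stop("classify_motif expects an HLA allele, got ", format_allele(a))
  locus_tok <- sub("^HLA-", "", a$locus)
  if (!locus_tok %in% c("A", "B", "C")) return("none")
  code <- .truncate_two_field(a$code)
  hit <- which(table$locus == a$locus & table$allele == code)
  if (length(hit)) return(table$motif[hit[1]])
  if (locus_tok == "C" && "residue80" %in% names(table)) {
    r <- table$residue80[match(code, table$allele[table$locus == "HLA-C"])]
    if (!is.na(r)) return(if (toupper(r) == "N") "C1" else "C2")
  }
  "unknown"
}

#' Per-individual KIR-ligand states
#'
#' Motif carriage flags are ORs over the individual's class I alleles; the
#' composite C-state summarizes the two HLA-C motifs (`C1_C1`, `C1_C2`,
#' `C2_C2`; NA when an HLA-C call is missing or unclassifiable).
#'
#' @param x A `kir_cohort`.
#' @param table A `motif_table`.
#' @return Data frame: `individual_id`, logical `has_A3`, `has_A11`,
#'   `has_Bw4_80I`, `has_Bw4_80T`, `has_C1`, `has_C2`, and `c_state`.
#' @export
ligand_state <- function(x, table = load_motif_table()) {
  stopifnot(inherits(x, "kir_cohort"))
  n <- cohort_size(x)
  lookup <- function(locus, calls) {
    # calls: canonical "LOC*code" or NA; returns motif or NA
    out <- rep(NA_character_, length(calls))
    ok <- !is.na(calls)
    if (any(ok)) {
      code <- sub("^[^*]+\\*", "", calls[ok])
      m <- table$motif[match(paste(locus, code),
                             paste(table$locus, table$allele))]
      m[is.na(m)] <- "unknown"
      out[ok] <- m
    }
    out
  }
  motifs <- list()
  for (loc in c("A", "B", "C")) {
    calls <- .hla_calls(x, loc)
    motifs[[paste0(loc, "1")]] <- lookup(paste0("HLA-", loc), calls[, 1])
    motifs[[paste0(loc, "2")]] <- lookup(paste0("HLA-", loc), calls[, 2])
  }
  has <- function(motif) {
    Reduce(`|`, lapply(motifs, function(m) !is.na(m) & m == motif))
  }
  c1 <- motifs$C1; c2 <- motifs$C2
  c_state <- rep(NA_character_, n)
  known <- !is.na(c1) & !is.na(c2) & c1 %in% c("C1", "C2") & c2 %in% c("C1", "C2")
  n2 <- (c1 == "C2") + (c2 == "C2")
  c_state[known] <- c("C1_C1", "C1_C2", "C2_C2")[n2[known] + 1L]
  data.frame(individual_id = x$data$individual_id,
             has_A3 = has("A3"), has_A11 = has("A11"),
             has_Bw4_80I = has("Bw4-80I"), has_Bw4_80T = has("Bw4-80T"),
             has_C1 = has("C1"), has_C2 = has("C2"),
             c_state = c_state, stringsAsFactors = FALSE)
}

# does each individual's ligand state satisfy a pattern?
.pattern_satisfied <- function(state, pattern) {
  switch(pattern,
    A3  = state$has_A3,
    A11 = state$has_A11,
    "Bw4-80I" = state$has_Bw4_80I,
    "Bw4-80T" = state$has_Bw4_80T,
    Bw4 = state$has_Bw4_80I | state$has_Bw4_80T,
    C1  = state$has_C1,
    C2  = state$has_C2,
    C1_C1 = !is.na(state$c_state) & state$c_state == "C1_C1",
    C1_C2 = !is.na(state$c_state) & state$c_state == "C1_C2",
    C2_C2 = !is.na(state$c_state) & state$c_state == "C2_C2",
    stop("unknown ligand-state pattern '", pattern, "'"))
}

#' Enumerate effective receptor-ligand pairs
#'
#' A pair `(kir_locus, pattern)` is effective for an individual iff the
#' receptor gene is carried (copy number >= 1) and the individual's ligand
#' state satisfies the pattern. Patterns cover single motifs (A3, A11,
#' Bw4 and its 80I/80T split, C1, C2) and composite C-states (C1_C1,
#' C1_C2, C2_C2).
#'
#' @param x A `kir_cohort`.
#' @param table A `motif_table`.
#' @param loci KIR loci to enumerate (default: union loci KIR2DL5, KIR2DS3,
#'   KIR2DS5, KIR2DS4 plus all measured loci).
#' @param patterns Ligand-state patterns to enumerate.
#' @param state Optional precomputed [ligand_state()] table.
#' @return Logical matrix, individuals x pairs, with `"LOCUS_PATTERN"`
#'   column names (e.g. `"KIR2DL1_C2"`).
#' @export
enumerate_pairs <- function(x, table = load_motif_table(),
                            loci = c(names(kir_union_loci()), kir_cnv_loci()),
                            patterns = .pattern_levels,
                            state = NULL) {
  stopifnot(inherits(x, "kir_cohort"))
  if (is.null(state)) state <- ligand_state(x, table)
  carried <- vapply(loci, function(l) kir_copy_number(x, l) >= 1L,
                    logical(cohort_size(x)))
  if (is.null(dim(carried))) carried <- matrix(carried, nrow = 1L,
                                               dimnames = list(NULL, loci))
  sat <- vapply(patterns, function(p) {
    s <- .pattern_satisfied(state, p)
    !is.na(s) & s
  }, logical(cohort_size(x)))
  if (is.null(dim(sat))) sat <- matrix(sat, nrow = 1L,
                                       dimnames = list(NULL, patterns))
  out <- matrix(FALSE, cohort_size(x), length(loci) * length(patterns))
  cn <- character(ncol(out))
  j <- 0L
  for (l in loci) for (p in patterns) {
    j <- j + 1L
    out[, j] <- carried[, l] & sat[, p]
    cn[j] <- paste(l, p, sep = "_")
  }
  colnames(out) <- cn
  rownames(out) <- x$data$individual_id
  out
}

#' Load a signed interaction score table
#'
#' CSV with columns `kir_locus`, `pattern`, `class`
#' (`inhibitory`/`activating`) and integer `weight` in 1..3. The bundled
#' default encodes the canonical receptor-ligand pairs (e.g. KIR2DL1-C2
#' inhibitory weight 3, KIR2DS1-C2 activating weight 2); it is a
#' configuration, not a fitted model, and can be replaced file-for-file.
#'
#' @param path CSV path; `NULL` loads the bundled table.
#' @param collapse_bw4 If `TRUE`, rows for Bw4-80I and Bw4-80T are merged
#'   onto the plain `Bw4` pattern (keeping the maximum weight), for
#'   analyses that do not split the Bw4 epitope.
#' @return Data frame of class `score_table`.
#' @export
load_score_table <- function(path = NULL, collapse_bw4 = FALSE) {
  if (is.null(path))
    path <- system.file("extdata", "kir_hla_scores.csv", package = "kirhla",
                        mustWork = TRUE)
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("kir_locus", "pattern", "class", "weight") %in% names(st)))
  if (!all(st$class %in% c("inhibitory", "activating")))
    stop("score class must be inhibitory or activating")
  if (!all(st$weight %in% 1:3))
    stop("score weights must be integers in 1..3")
  if (!all(st$pattern %in% .pattern_levels))
    stop("unknown pattern(s) in score table: ",
         paste(setdiff(st$pattern, .pattern_levels), collapse = ", "))
  ok_loci <- c(.kir_cnv_loci, names(.kir_union_loci))
  if (!all(st$kir_locus %in% ok_loci))
    stop("unknown KIR locus in score table: ",
         paste(setdiff(st$kir_locus, ok_loci), collapse = ", "))
  if (collapse_bw4) {
    st$pattern[st$pattern %in% c("Bw4-80I", "Bw4-80T")] <- "Bw4"
    st <- stats::aggregate(weight ~ kir_locus + pattern + class, data = st, FUN = max)
  }
  if (anyDuplicated(st[, c("kir_locus", "pattern")]))
    stop("duplicate (kir_locus, pattern) rows in score table")
  class(st) <- c("score_table", "data.frame")
  st
}

#' Signed interaction scores per individual
#'
#' Sums the weights of the effective pairs listed in the score table:
#' `inhibitory` and `activating` totals plus `net = activating -
#' inhibitory`. Pairs not listed in the table contribute nothing.
#'
#' @param x A `kir_cohort`.
#' @param score_table A `score_table`.
#' @param motif_table A `motif_table`.
#' @param pairs Optional precomputed [enumerate_pairs()] matrix.
#' @return Data frame: `individual_id`, `inhibitory`, `activating`, `net`.
#' @export
score_cohort <- function(x, score_table = load_score_table(),
                         motif_table = load_motif_table(), pairs = NULL) {
  if (is.null(pairs))
    pairs <- enumerate_pairs(x, motif_table,
                             loci = unique(score_table$kir_locus),
                             patterns = unique(score_table$pattern))
  key <- paste(score_table$kir_locus, score_table$pattern, sep = "_")
  missing_cols <- setdiff(key, colnames(pairs))
  if (length(missing_cols))
    stop("pairs matrix lacks scored pair(s): ", paste(missing_cols, collapse = ", "))
  w <- ifelse(score_table$class == "inhibitory", score_table$weight, 0L)
  inh <- as.integer(pairs[, key, drop = FALSE] %*% w)
  w <- ifelse(score_table$class == "activating", score_table$weight, 0L)
  act <- as.integer(pairs[, key, drop = FALSE] %*% w)
  data.frame(individual_id = x$data$individual_id,
             inhibitory = inh, activating = act, net = act - inh,
             stringsAsFactors = FALSE)
}

#' Score a single pair set
#'
#' Convenience scalar form of [score_cohort()] for an explicit set of
#' effective pairs (names `"LOCUS_PATTERN"`).
#'
#' @param pairs Character vector of effective pair names.
#' @param score_table A `score_table`.
#' @return List with `inhibitory`, `activating`, `net`.
#' @export
score_individual <- function(pairs, score_table = load_score_table()) {
  key <- paste(score_table$kir_locus, score_table$pattern, sep = "_")
  present <- key %in% pairs
  inh <- sum(score_table$weight[present & score_table$class == "inhibitory"])
  act <- sum(score_table$weight[present & score_table$class == "activating"])
  list(inhibitory = as.integer(inh), activating = as.integer(act),
       net = as.integer(act - inh))
}
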