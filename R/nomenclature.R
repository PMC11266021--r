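# IPD-IMGT/HLA and IPD-KIR allele nomenclature.
#
# HLA alleles are written LOCUS*FF:FF[...] with colon-separated numeric
# fields (two-field protein-level resolution at minimum); KIR alleles are
# written LOCUS*DDDDD with a plain digit string whose first three digits
# identify the protein. Names are stored uppercase and compared
# case-insensitively.

.hla_code_re <- "^[0-9]{2,4}(:[0-9]{2,4})+$"
.kir_code_re <- "^[0-9]{3,}$"

#' Parse an HLA or KIR allele name
#'
#' Splits a name such as `"KIR2DL4*00103"` or `"DRB1*01:01"` (an optional
#' `"HLA-"` prefix is accepted and normalized away) into its locus and
#' allele code. HLA codes must have at least two colon-separated numeric
#' fields; KIR codes at least three digits.
#'
#' @param raw Allele name string.
#' @return An object of class `allele_name` with fields `locus` (e.g.
#'   `"HLA-DRB1"` or `"KIR2DL4"`), `code` (e.g. `"01:01"`, `"00103"`) and
#'   `raw` (the input).
#' @examples
#' parse_allele("KIR2DL4*00103")
#' parse_allele("HLA-DRB1*01:01")
#' @export
parse_allele <- function(raw) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("allele name must be a single non-empty string")
  x <- toupper(trimws(raw))
  parts <- strsplit(x, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("malformed allele name '", raw,
         "': expected LOCUS*code with a single '*' separator")
  locus_tok <- sub("^HLA-", "", parts[1])
  code <- parts[2]
  if (locus_tok %in% .kir_allele_loci) {
    if (!grepl(.kir_code_re, code))
      stop("malformed KIR allele code '", code, "' in '", raw,
           "': expected at least 3 digits")
    locus <- locus_tok
  } else if (locus_tok %in% .hla_loci) {
    if (!grepl(.hla_code_re, code))
      stop("malformed HLA allele code '", code, "' in '", raw,
           "': expected colon-separated numeric fields (two-field minimum)")
    locus <- paste0("HLA-", locus_tok)
  } else if (locus_tok == .hlag14_locus) {
    if (!code %in% .hlag14_alleles)
      stop("HLAG14BP allele must be INS or DEL, got '", code, "'")
    locus <- locus_tok
  } else {
    stop("unknown locus '", parts[1], "' in allele name '", raw, "'")
  }
  structure(list(locus = locus, code = code, raw = raw),
            class = "allele_name")
}

#' Format an allele name in canonical form
#'
#' The canonical form drops the `"HLA-"` prefix (matching how association
#' tables print alleles): `"DRB1*01:01"`, `"KIR2DL4*00103"`.
#'
#' @param a An `allele_name` or a string (parsed first).
#' @return Canonical allele string.
#' @export
format_allele <- function(a) {
  if (is.character(a)) a <- parse_allele(a)
  stopifnot(inherits(a, "allele_name"))
  paste0(sub("^HLA-", "", a$locus), "*", a$code)
}

#' @export
print.allele_name <- function(x, ...) {
  cat("<allele>", format_allele(x), "\n")
  invisible(x)
}

#' @export
format.allele_name <- function(x, ...) format_allele(x)

#' Protein-level group of an allele
#'
#' KIR alleles sharing their first three code digits encode the same
#' protein sequence (so e.g. KIR2DL4*00103 and KIR2DL4*00102 are one
#' protein group); a two-field HLA code already names the protein, so HLA
#' grouping is the identity.
#'
#' @param a An `allele_name` or allele string.
#' @return An object of class `protein_group` with fields `locus` and
#'   `group_code` (3 digits for KIR; the two-field code for HLA).
#' @examples
#' protein_group("KIR2DL4*00103")  # group 001, shared with *00102
#' @export
protein_group <- function(a) {
  if (is.character(a)) a <- parse_allele(a)
  stopifnot(inherits(a, "allele_name"))
  if (startsWith(a$locus, "KIR")) {
    if (nchar(a$code) < 3L)
      stop("KIR allele code '", a$code, "' shorter than 3 digits")
    group <- substr(a$code, 1L, 3L)
  } else {
    # two-field truncation: higher-resolution codes collapse to the protein
    fields <- strsplit(a$code, ":", fixed = TRUE)[[1]]
    group <- paste(fields[1:2], collapse = ":")
  }
  structure(list(locus = a$locus, group_code = group),
            class = "protein_group")
}

#' @export
print.protein_group <- function(x, ...) {
  cat("<protein group>", paste0(sub("^HLA-", "", x$locus), "*", x$group_code), "\n")
  invisible(x)
}

#' Read an allele frequency table
#'
#' CSV with columns `locus`, `allele`, `population`, `frequency`. Per-locus,
#' per-population frequency sums may be below 1 (partial tables are common
#' for KIR) but must not exceed 1 by more than a small tolerance.
#'
#' @param path CSV file path.
#' @param tol Tolerance on per-locus frequency sums exceeding 1.
#' @return Data frame of class `allele_freq_table`.
#' @export
read_freq_table <- function(path, tol = 0.01) {
  ft <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(allele = "character"))
  required <- c("locus", "allele", "population", "frequency")
  if (!all(required %in% names(ft)))
    stop("frequency table must have columns ", paste(required, collapse = ", "))
  as_freq_table(ft, tol = tol)
}

#' @rdname read_freq_table
#' @param ft Data frame with the frequency-table columns.
#' @export
as_freq_table <- function(ft, tol = 0.01) {
  if (any(ft$frequency < 0)) stop("negative allele frequency")
  sums <- tapply(ft$frequency, interaction(ft$locus, ft$population, drop = TRUE), sum)
  if (any(sums > 1 + tol))
    stop("per-locus frequency sum exceeds 1 + ", tol, ": ",
         paste(names(sums)[sums > 1 + tol], collapse = ", "))
  ft$locus <- toupper(ft$locus)
  ft$allele <- toupper(ft$allele)
  class(ft) <- c("allele_freq_table", "data.frame")
  ft
}

.lookup_freq <- function(freqs, alleles, population = NULL, floor = 1e-6) {
  tab <- freqs
  if (!is.null(population)) tab <- tab[tab$population == population, , drop = FALSE]
  key <- paste(sub("^HLA-", "", tab$locus), tab$allele, sep = "*")
  vapply(alleles, function(al) {
    can <- format_allele(al)
    hit <- match(can, key)
    if (is.na(hit)) floor else max(tab$frequency[hit], floor)
  }, numeric(1))
}

#' Resolve a genotype ambiguity by population frequency
#'
#' Sequencing-based KIR (and HLA) genotyping can leave several candidate
#' allele sets consistent with the reads; the conventional resolution keeps
#' the candidate whose alleles are jointly most frequent in a reference
#' population. This implementation maximizes the product of the member
#' alleles' frequencies; alleles absent from the reference table contribute
#' a small floor frequency so that unlisted sets lose to listed ones but
#' still compare deterministically among themselves. Exact ties are broken
#' lexicographically on the sorted canonical allele strings.
#'
#' @param candidates List of character vectors, each a candidate allele set.
#' @param freqs An `allele_freq_table`.
#' @param population Optional population label to restrict the table.
#' @param floor Frequency assigned to unlisted alleles (default `1e-6`).
#' @return The winning candidate as a character vector of canonical names.
#' @export
resolve_ambiguity <- function(candidates, freqs, population = NULL, floor = 1e-6) {
  if (length(candidates) == 0L) stop("empty candidate list")
  canon <- lapply(candidates, function(set)
    sort(unname(vapply(set, format_allele, character(1)))))
  scores <- vapply(canon, function(set) {
    prod(.lookup_freq(freqs, set, population = population, floor = floor))
  }, numeric(1))
  best <- max(scores)
  # tolerance-free tie handling: exact equality only
  winners <- which(scores == best)
  if (length(winners) > 1L) {
    keys <- vapply(canon[winners], paste, character(1), collapse = "|")
    winners <- winners[order(keys)][1L]
  }
  canon[[winners]]
}
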