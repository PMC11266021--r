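# Cohort data model: one row per individual holding phenotype, subgroup,
# stratum labels (ancestry x genotyping platform), diploid HLA genotypes,
# per-locus KIR copy numbers with allele multisets, the HLA-G 14-bp
# insertion/deletion genotype, and principal-component coordinates.
#
# On-disk dialect (see read_cohort/write_cohort): a genotype TSV with two
# columns per HLA locus (canonical "LOCUS*code" strings, NA for a missing
# call or an absent DRB3/4/5 gene) and one token column per KIR
# copy-number locus formatted "cn:allele1,allele2,..."; plus a
# whitespace-delimited PC table in PLINK .eigenvec layout (FID IID PC1..).

.kir_token <- function(cn, alleles) {
  paste0(cn, ":", vapply(alleles, paste, character(1), collapse = ","))
}

# vectorized: returns list(cn = integer vector, alleles = list of chr)
.parse_kir_token <- function(tok) {
  has_colon <- !is.na(tok) & grepl(":", tok, fixed = TRUE)
  cn <- rep(NA_integer_, length(tok))
  cn[has_colon] <- suppressWarnings(as.integer(sub(":.*$", "", tok[has_colon])))
  rest <- character(length(tok))
  rest[has_colon] <- sub("^[^:]*:", "", tok[has_colon])
  alleles <- strsplit(rest, ",", fixed = TRUE)
  list(cn = cn, alleles = alleles)
}

.hla_cols <- function() {
  as.vector(t(outer(.hla_cohort_loci, c("1", "2"), paste, sep = ".")))
}

#' Construct a cohort object
#'
#' @param data Data frame, one row per individual, with columns
#'   `individual_id`, `phenotype` (`"case"`/`"control"`), `subgroup`
#'   (`"teratoma"`, `"other_tumor"`, `"non_paraneoplastic"`, `"unknown"`),
#'   `ancestry`, `platform`, `hlag_14bp` (`"ins/ins"`, `"ins/del"`,
#'   `"del/del"` or NA), two columns `<locus>.1`/`<locus>.2` per HLA locus
#'   and one `"cn:alleles"` token column per KIR copy-number locus.
#' @param pcs Numeric matrix of principal-component coordinates, one row
#'   per individual (rownames = `individual_id`), columns `PC1..PCk`.
#' @param metadata Optional list (source, seed, notes).
#' @return An object of class `kir_cohort`.
#' @export
new_cohort <- function(data, pcs, metadata = list()) {
  obj <- structure(list(data = data, pcs = pcs, metadata = metadata),
                   class = "kir_cohort")
  validate_cohort(obj)
}

#' @rdname new_cohort
#' @param x A `kir_cohort`.
#' @export
validate_cohort <- function(x) {
  d <- x$data
  if (anyDuplicated(d$individual_id))
    stop("duplicate individual_id: ",
         paste(unique(d$individual_id[duplicated(d$individual_id)]), collapse = ", "))
  if (!all(d$phenotype %in% c("case", "control")))
    stop("phenotype must be 'case' or 'control'")
  need <- c("individual_id", "phenotype", "subgroup", "ancestry", "platform",
            "hlag_14bp", .hla_cols(), .kir_cnv_loci)
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cohort data missing columns: ", paste(miss, collapse = ", "))
  if (!is.matrix(x$pcs) || nrow(x$pcs) != nrow(d))
    stop("pcs must be a matrix with one row per individual")
  if (ncol(x$pcs) < 3L) stop("at least 3 principal components required")
  if (any(!is.finite(x$pcs))) stop("non-finite PC coordinates")
  if (nrow(d) > 0L && !identical(rownames(x$pcs), d$individual_id))
    stop("pcs rownames must equal data$individual_id in order")
  for (loc in .kir_cnv_loci) {
    parsed <- .parse_kir_token(d[[loc]])
    cn <- parsed$cn
    nal <- lengths(parsed$alleles)
    bad <- which(is.na(cn) | cn < 0L | cn > 4L | nal != cn)
    if (length(bad))
      stop("copy-number/allele-multiset mismatch at ", loc,
           " for individual(s) ", paste(d$individual_id[bad], collapse = ", "))
  }
  x
}

#' @export
print.kir_cohort <- function(x, ...) {
  d <- x$data
  cat("<kir_cohort> ", nrow(d), " individuals (",
      sum(d$phenotype == "case"), " cases, ",
      sum(d$phenotype == "control"), " controls), ",
      ncol(x$pcs), " PCs\n", sep = "")
  strat <- table(paste(d$ancestry, d$platform, sep = "|"), d$phenotype)
  print(strat)
  invisible(x)
}

#' Number of individuals in a cohort
#' @param x A `kir_cohort`.
#' @export
cohort_size <- function(x) nrow(x$data)

#' Stratum labels (ancestry x platform) per individual
#' @param x A `kir_cohort`.
#' @export
cohort_strata <- function(x) paste(x$data$ancestry, x$data$platform, sep = "|")

#' Subset a cohort by row index or logical mask
#' @param x A `kir_cohort`.
#' @param i Integer or logical index.
#' @export
subset_cohort <- function(x, i) {
  d <- x$data[i, , drop = FALSE]
  p <- x$pcs[i, , drop = FALSE]
  rownames(d) <- NULL
  new_cohort(d, p, x$metadata)
}

#' KIR copy number per individual
#'
#' @param x A `kir_cohort`.
#' @param locus A measured copy-number locus (e.g. `"KIR2DL5B"`,
#'   `"KIR2DS4wt"`) or a union locus (`"KIR2DL5"`, `"KIR2DS3"`,
#'   `"KIR2DS5"`, `"KIR2DS4"`) whose copies are the sum of its parts.
#' @return Integer vector, one entry per individual.
#' @export
kir_copy_number <- function(x, locus) {
  if (locus %in% names(.kir_union_loci)) {
    parts <- .kir_union_loci[[locus]]
    return(Reduce(`+`, lapply(parts, function(p) kir_copy_number(x, p))))
  }
  if (!locus %in% .kir_cnv_loci) stop("unknown KIR copy-number locus '", locus, "'")
  .parse_kir_token(x$data[[locus]])$cn
}

#' KIR allele multisets per individual
#'
#' @inheritParams kir_copy_number
#' @return List of character vectors of allele codes (bare digit strings).
#' @export
kir_alleles <- function(x, locus) {
  if (locus %in% names(.kir_union_loci)) {
    parts <- lapply(.kir_union_loci[[locus]], function(p) kir_alleles(x, p))
    return(do.call(Map, c(list(c), parts)))
  }
  if (!locus %in% .kir_cnv_loci) stop("unknown KIR copy-number locus '", locus, "'")
  .parse_kir_token(x$data[[locus]])$alleles
}

.hla_slot_for <- function(locus_tok) {
  if (locus_tok %in% c("DRB3", "DRB4", "DRB5", "DRB345")) "DRB345" else locus_tok
}

.truncate_two_field <- function(code) {
  vapply(strsplit(code, ":", fixed = TRUE), function(f) {
    if (length(f) < 2L || anyNA(f)) NA_character_ else paste(f[1:2], collapse = ":")
  }, character(1))
}

# two-field canonical forms of the stored diploid HLA calls at a slot
.hla_calls <- function(x, slot) {
  a1 <- x$data[[paste0(slot, ".1")]]
  a2 <- x$data[[paste0(slot, ".2")]]
  norm <- function(v) {
    out <- rep(NA_character_, length(v))
    ok <- !is.na(v)
    if (any(ok)) {
      sp <- strsplit(toupper(v[ok]), "*", fixed = TRUE)
      loc <- vapply(sp, `[`, character(1), 1)
      code <- .truncate_two_field(vapply(sp, `[`, character(1), 2))
      out[ok] <- paste0(sub("^HLA-", "", loc), "*", code)
    }
    out
  }
  cbind(norm(a1), norm(a2))
}

#' Carrier indicator for a marker
#'
#' Returns, per individual, whether at least one copy of the marker is
#' carried. Markers are given as strings:
#' \itemize{
#'   \item a bare KIR locus name (`"KIR2DL5B"`, union `"KIR2DL5"`):
#'     gene presence, i.e. copy number >= 1;
#'   \item a KIR allele (`"KIR2DL4*00103"`): exact allele carriage;
#'   \item a KIR protein group — a 3-digit code (`"KIR2DL4*001"`): carriage
#'     of any allele in that protein group;
#'   \item an HLA allele (`"DRB1*01:01"`, optionally `"HLA-"`-prefixed):
#'     carriage at two-field resolution;
#'   \item `"HLAG14BP*INS"` / `"HLAG14BP*DEL"`: carriage of the HLA-G
#'     14-bp insertion or deletion allele.
#' }
#'
#' @param x A `kir_cohort`.
#' @param marker Marker string (see Details).
#' @return Integer vector of 0/1 (NA where the call is missing), one entry
#'   per individual, in cohort order.
#' @export
carrier_indicator <- function(x, marker) {
  stopifnot(inherits(x, "kir_cohort"), is.character(marker), length(marker) == 1L)
  marker <- trimws(marker)
  if (!grepl("*", marker, fixed = TRUE)) {
    hit <- match(toupper(marker), toupper(.presence_loci()))
    if (is.na(hit)) stop("unknown marker '", marker, "'")
    return(as.integer(kir_copy_number(x, .presence_loci()[hit]) >= 1L))
  }
  parts <- strsplit(toupper(marker), "*", fixed = TRUE)[[1]]
  locus_tok <- sub("^HLA-", "", parts[1])
  code <- parts[2]
  if (locus_tok == .hlag14_locus) {
    if (!code %in% .hlag14_alleles) stop("unknown HLAG14BP allele '", code, "'")
    g <- x$data$hlag_14bp
    return(ifelse(is.na(g), NA_integer_,
                  as.integer(grepl(tolower(code), g, fixed = TRUE))))
  }
  if (locus_tok %in% .kir_allele_loci) {
    is_group <- nchar(code) == 3L
    if (!is_group) parse_allele(marker)  # validates
    cols <- names(.kir_cnv_allele_locus)[.kir_cnv_allele_locus == locus_tok]
    if (locus_tok == "KIR2DL5") cols <- c("KIR2DL5A", "KIR2DL5B")
    if (!length(cols)) stop("KIR locus '", locus_tok, "' has no copy-number column")
    hit <- rep(FALSE, cohort_size(x))
    for (cl in cols) {
      als <- kir_alleles(x, cl)
      hit <- hit | vapply(als, function(a) {
        if (is_group) any(substr(a, 1L, 3L) == code) else any(a == code)
      }, logical(1))
    }
    return(as.integer(hit))
  }
  if (locus_tok %in% .hla_loci) {
    a <- parse_allele(marker)
    target <- paste0(sub("^HLA-", "", a$locus), "*", .truncate_two_field(a$code))
    calls <- .hla_calls(x, .hla_slot_for(locus_tok))
    miss <- is.na(calls[, 1]) & is.na(calls[, 2])
    out <- as.integer(calls[, 1] %in% target | calls[, 2] %in% target)
    out[miss] <- NA_integer_
    return(out)
  }
  stop("unknown marker '", marker, "'")
}

#' Carrier count and frequency in a phenotype group
#'
#' @param x A `kir_cohort`.
#' @param marker Marker string as in [carrier_indicator()].
#' @param group One of `"case"`, `"control"`, `"teratoma"`,
#'   `"non_teratoma"` (non-teratoma cases) or `"all"`.
#' @return List with `count` (carriers), `n` (individuals with a
#'   non-missing call) and `freq` (= count/n).
#' @export
carrier_frequency <- function(x, marker, group = c("case", "control",
                                                   "teratoma", "non_teratoma", "all")) {
  group <- match.arg(group)
  d <- x$data
  sel <- switch(group,
    case = d$phenotype == "case",
    control = d$phenotype == "control",
    teratoma = d$phenotype == "case" & d$subgroup == "teratoma",
    non_teratoma = d$phenotype == "case" & d$subgroup != "teratoma",
    all = rep(TRUE, nrow(d)))
  ind <- carrier_indicator(x, marker)[sel]
  n <- sum(!is.na(ind))
  if (n == 0L) stop("no individuals with a non-missing call for '", marker,
                    "' in group '", group, "'")
  count <- sum(ind, na.rm = TRUE)
  list(count = count, n = n, freq = count / n)
}

#' Read a cohort from a genotype TSV and a PLINK-style eigenvector file
#'
#' Individuals present in the genotype table but absent from the PC table
#' are dropped with a warning that reports the count; duplicate ids or a
#' copy-number/allele-multiset mismatch are errors.
#'
#' @param genotype_path Genotype TSV path (dialect as written by
#'   [write_cohort()]).
#' @param pc_path Whitespace-delimited PC table: FID IID PC1..PCk, no header
#'   or a header line starting with FID.
#' @return A `kir_cohort`.
#' @export
read_cohort <- function(genotype_path, pc_path) {
  d <- utils::read.delim(genotype_path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "NA",
                         comment.char = "#", check.names = FALSE)
  first <- readLines(pc_path, n = 10L)
  first <- first[!startsWith(first, "#")]
  has_header <- grepl("^\\s*FID\\b", first[1])
  pc <- utils::read.table(pc_path, header = has_header, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!has_header)
    names(pc) <- c("FID", "IID", paste0("PC", seq_len(ncol(pc) - 2L)))
  if (anyDuplicated(d$individual_id))
    stop("duplicate individual_id in ", genotype_path)
  keep <- d$individual_id %in% pc$IID
  if (!all(keep)) {
    warning(sum(!keep), " individual(s) missing from PC table dropped: ",
            paste(utils::head(d$individual_id[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")
    d <- d[keep, , drop = FALSE]
  }
  m <- as.matrix(pc[match(d$individual_id, pc$IID), grep("^PC", names(pc)), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d$individual_id
  rownames(d) <- NULL
  new_cohort(d, m, metadata = list(source = c(genotype_path, pc_path)))
}

#' Write a cohort to a genotype TSV and PC table
#'
#' Inverse of [read_cohort()]: `read_cohort()` on the written files
#' reproduces the cohort.
#'
#' @param x A `kir_cohort`.
#' @param genotype_path,pc_path Output paths.
#' @param header_comment Optional comment lines (written prefixed with `#`).
#' @export
write_cohort <- function(x, genotype_path, pc_path, header_comment = NULL) {
  con <- file(genotype_path, "w")
  on.exit(close(con), add = TRUE)
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(x$data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  pc <- data.frame(FID = x$data$individual_id, IID = x$data$individual_id,
                   x$pcs, check.names = FALSE)
  con2 <- file(pc_path, "w")
  on.exit(close(con2), add = TRUE)
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con2)
  utils::write.table(pc, con2, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(x)
}
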