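# End-to-end orchestration: simulate (or read) -> PC-match -> carrier /
# CNV / pair / score association -> iterative conditioning -> per-stratum
# meta-analysis -> TSV report bundle with a manifest. Every output file
# carries the seed and a hash of the resolved configuration, and a rerun
# with the same configuration reproduces the bundle bit-for-bit.

#' Enumerate observed allele-carrier markers
#'
#' @param x A `kir_cohort`.
#' @param min_carriers Minimum carrier count for a marker to be listed.
#' @return Character vector of `"LOCUS*code"` markers.
#' @export
kir_allele_markers <- function(x, min_carriers = 1L) {
  out <- character(0)
  for (loc in kir_cnv_loci()) {
    als <- kir_alleles(x, loc)
    nomen <- .kir_cnv_allele_locus[[loc]]
    tab <- table(unlist(lapply(als, unique)))
    keep <- names(tab)[tab >= min_carriers]
    if (length(keep)) out <- c(out, paste0(nomen, "*", keep))
  }
  sort(unique(out))
}

#' @rdname kir_allele_markers
#' @export
hla_allele_markers <- function(x, min_carriers = 1L) {
  out <- character(0)
  for (loc in hla_cohort_loci()) {
    calls <- .hla_calls(x, loc)
    tab <- table(c(calls[, 1], calls[, 2]))
    keep <- names(tab)[tab >= min_carriers]
    out <- c(out, keep)
  }
  sort(unique(out))
}

#' Default pipeline configuration
#'
#' @param seed Master seed for the run.
#' @param out_dir Output directory for the report bundle.
#' @return Named list understood by [run_pipeline()]: cohort source
#'   (simulator settings or genotype/PC paths), matching, association and
#'   reporting parameters.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("kirhla_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    n_cases = 300L, n_controls = 3000L,
    intercept = -2,
    effects = list(),          # list of list(marker=, coding=, log_or=)
    haplotype_config = NULL,   # path to YAML; NULL = bundled default
    genotype_path = NULL, pc_path = NULL,  # read instead of simulate
    match_k = 10L, match_pcs = 10L, with_replacement = FALSE,
    n_pcs = 3L, alpha = 0.05, freq_threshold = 0.05,
    min_carriers = 10L,
    motif_table = NULL, score_table = NULL
  )
}

.resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  base[names(config)] <- config
  base$seed <- as.integer(base$seed)
  base
}

.config_hash <- function(config) {
  config$out_dir <- NULL  # hash the analysis, not the output location
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

.write_report <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seed: ", seed), paste0("# config_hash: ", hash)), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> match -> associate -> condition -> meta
#' and writes a report bundle to `config$out_dir`: the cohort
#' (`cohort.tsv`, `cohort_pcs.txt`), the matching (`matching.tsv`), the
#' association tables (`assoc_kir_alleles.tsv`, `assoc_cnv.tsv`,
#' `assoc_hla.tsv`, `assoc_pairs.tsv`, `assoc_scores.tsv`), the
#' conditioning trace (`conditioning.tsv`), the per-stratum meta-analysis
#' of copy-number effects (`meta_cnv.tsv`) and a `manifest.yaml` recording
#' the seed, configuration hash and row counts. Stage failures abort with
#' the stage name.
#'
#' @param config A config list (see [default_run_config()]) or path to a
#'   YAML file of overrides.
#' @return Invisible list with the in-memory results (`cohort`, `match`,
#'   `matched`, `kir_alleles`, `cnv`, `hla`, `pairs`, `scores`,
#'   `conditioning`, `meta_cnv`, `manifest`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- .resolve_config(config)
  hash <- .config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$genotype_path)) {
      read_cohort(cfg$genotype_path, cfg$pc_path)
    } else {
      hap <- if (is.null(cfg$haplotype_config)) default_haplotype_config()
             else read_haplotype_config(cfg$haplotype_config)
      eff <- if (length(cfg$effects)) {
        e <- do.call(rbind, lapply(cfg$effects, as.data.frame))
        effect_config(cfg$intercept, e$marker, e$coding, e$log_or)
      } else effect_config(cfg$intercept)
      simulate_cohort(hap, eff, cfg$n_cases, cfg$n_controls, seed = cfg$seed)
    }
  })
  write_cohort(cohort, file.path(cfg$out_dir, "cohort.tsv"),
               file.path(cfg$out_dir, "cohort_pcs.txt"),
               header_comment = c(paste0("seed: ", cfg$seed),
                                  paste0("config_hash: ", hash)))

  mres <- stage("match", match_controls(cohort, cohort, k = cfg$match_k,
                                        pcs_used = cfg$match_pcs,
                                        with_replacement = cfg$with_replacement,
                                        seed = cfg$seed))
  matched <- stage("match", apply_match(cohort, mres))
  .write_report(mres$matches, file.path(cfg$out_dir, "matching.tsv"),
                cfg$seed, hash)

  motif <- if (is.null(cfg$motif_table)) load_motif_table()
           else load_motif_table(cfg$motif_table)
  score_tab <- if (is.null(cfg$score_table)) load_score_table()
               else load_score_table(cfg$score_table)

  kir_markers <- kir_allele_markers(matched, cfg$min_carriers)
  kir_res <- stage("assoc_kir_alleles", {
    r <- do.call(rbind, lapply(kir_markers, function(m)
      assoc_logistic(matched, m, coding = "carrier", n_pcs = cfg$n_pcs)))
    adjust_pvalues(r, "bh_fdr", cfg$freq_threshold)
  })
  .write_report(kir_res, file.path(cfg$out_dir, "assoc_kir_alleles.tsv"),
                cfg$seed, hash)

  cnv_loci <- c(kir_cnv_loci(), names(kir_union_loci()))
  cnv_res <- stage("assoc_cnv", {
    rows <- lapply(cnv_loci, function(l) {
      r <- assoc_cnv(matched, l, n_pcs = cfg$n_pcs)
      rbind(r$presence, r$additive)
    })
    adjust_pvalues(do.call(rbind, rows), "bh_fdr", cfg$freq_threshold)
  })
  .write_report(cnv_res, file.path(cfg$out_dir, "assoc_cnv.tsv"), cfg$seed, hash)

  hla_res <- stage("assoc_hla", {
    r <- do.call(rbind, lapply(hla_allele_markers(matched, cfg$min_carriers),
      function(m) assoc_logistic(matched, m, coding = "carrier",
                                 n_pcs = cfg$n_pcs)))
    adjust_pvalues(r, "bonferroni", cfg$freq_threshold)
  })
  .write_report(hla_res, file.path(cfg$out_dir, "assoc_hla.tsv"), cfg$seed, hash)

  pair_res <- stage("assoc_pairs", {
    keys <- paste(score_tab$kir_locus, score_tab$pattern, sep = "_")
    r <- do.call(rbind, lapply(keys, function(k)
      pair_presence_assoc(matched, k, motif, n_pcs = cfg$n_pcs)))
    adjust_pvalues(r, "bh_fdr", cfg$freq_threshold)
  })
  .write_report(pair_res, file.path(cfg$out_dir, "assoc_pairs.tsv"),
                cfg$seed, hash)

  score_res <- stage("assoc_scores", {
    scores <- score_cohort(matched, score_tab, motif)
    rows <- lapply(c("inhibitory", "activating", "net"), function(comp) {
      sa <- score_assoc(matched, comp, score_tab, motif, scores = scores,
                        n_pcs = cfg$n_pcs)
      g <- sa$glm
      g$ordinal_beta <- sa$ordinal$beta
      g$ordinal_p <- sa$ordinal$p
      g
    })
    do.call(rbind, rows)
  })
  .write_report(score_res, file.path(cfg$out_dir, "assoc_scores.tsv"),
                cfg$seed, hash)

  cond <- stage("conditioning", {
    fam <- kir_res[!kir_res$exploratory & kir_res$estimable, , drop = FALSE]
    cand <- fam$marker[order(fam$p)]
    cand <- utils::head(cand, 25L)  # scan the strongest family members
    if (length(cand))
      conditional_scan(matched, cand, alpha = cfg$alpha,
                       freq_threshold = cfg$freq_threshold, n_pcs = cfg$n_pcs)
    else conditional_scan(matched, kir_markers[1], alpha = cfg$alpha)
  })
  .write_report(cond, file.path(cfg$out_dir, "conditioning.tsv"), cfg$seed, hash)

  meta_cnv <- stage("meta_cnv", {
    variable <- cnv_loci[vapply(cnv_loci, function(l)
      length(unique(kir_copy_number(matched, l))) > 1L, logical(1))]
    meta_scan(matched, variable, coding = "additive_copy",
              freq_threshold = cfg$freq_threshold, n_pcs = cfg$n_pcs)
  })
  .write_report(meta_cnv, file.path(cfg$out_dir, "meta_cnv.tsv"), cfg$seed, hash)

  manifest <- list(
    package = "kirhla",
    version = as.character(utils::packageVersion("kirhla")),
    seed = cfg$seed, config_hash = hash,
    n_individuals = cohort_size(cohort),
    n_matched = cohort_size(matched),
    tables = list(kir_alleles = nrow(kir_res), cnv = nrow(cnv_res),
                  hla = nrow(hla_res), pairs = nrow(pair_res),
                  scores = nrow(score_res), conditioning = nrow(cond),
                  meta_cnv = nrow(meta_cnv)))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(cohort = cohort, match = mres, matched = matched,
                 kir_alleles = kir_res, cnv = cnv_res, hla = hla_res,
                 pairs = pair_res, scores = score_res, conditioning = cond,
                 meta_cnv = meta_cnv, manifest = manifest, config = cfg))
}
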