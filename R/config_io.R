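# Plain-text (YAML) serialization of the simulator configuration, so that
# haplotype structure and planted effects can be edited without touching
# code and a pipeline run can record the exact configuration it used.

.mat_to_yaml <- function(m) {
  out <- lapply(rownames(m), function(r) as.list(m[r, , drop = TRUE]))
  names(out) <- rownames(m)
  out
}

.yaml_to_mat <- function(lst) {
  rows <- names(lst)
  cols <- names(lst[[1]])
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  for (r in rows) m[r, ] <- unlist(lst[[r]])[cols]
  m
}

.pool_to_yaml <- function(p) as.list(stats::setNames(p$freq, p$allele))

.yaml_to_pool <- function(lst) {
  data.frame(allele = names(lst), freq = unname(unlist(lst)),
             stringsAsFactors = FALSE)
}

#' Write a haplotype configuration to YAML
#'
#' @param hap A `haplotype_config`.
#' @param path Output file path.
#' @export
write_haplotype_config <- function(hap, path) {
  obj <- list(
    ancestries = hap$ancestries,
    pc = list(n_pcs = hap$pc$n_pcs, sd = hap$pc$sd,
              centroids = .mat_to_yaml(hap$pc$centroids)),
    cen = list(segments = hap$cen$segments, freq = .mat_to_yaml(hap$cen$freq)),
    tel = list(segments = hap$tel$segments, freq = .mat_to_yaml(hap$tel$freq)),
    kir_alleles = lapply(hap$kir_alleles, .pool_to_yaml),
    hla_haplotypes = lapply(seq_len(nrow(hap$hla_haplotypes)), function(i)
      as.list(hap$hla_haplotypes[i, , drop = TRUE])),
    hla_hap_freq = .mat_to_yaml(hap$hla_hap_freq),
    hla_pools = lapply(hap$hla_pools, .pool_to_yaml),
    hlag_del_freq = as.list(hap$hlag_del_freq)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a haplotype configuration from YAML
#'
#' @param path YAML file written by [write_haplotype_config()] (or edited
#'   by hand in the same layout).
#' @return A validated `haplotype_config`.
#' @export
read_haplotype_config <- function(path) {
  obj <- yaml::read_yaml(path)
  hap <- structure(list(
    ancestries = unlist(obj$ancestries),
    pc = list(n_pcs = as.integer(obj$pc$n_pcs), sd = as.numeric(obj$pc$sd),
              centroids = .yaml_to_mat(obj$pc$centroids)),
    cen = list(segments = lapply(obj$cen$segments, unlist),
               freq = .yaml_to_mat(obj$cen$freq)),
    tel = list(segments = lapply(obj$tel$segments, unlist),
               freq = .yaml_to_mat(obj$tel$freq)),
    kir_alleles = lapply(obj$kir_alleles, .yaml_to_pool),
    hla_haplotypes = do.call(rbind, lapply(obj$hla_haplotypes, function(h)
      data.frame(h, stringsAsFactors = FALSE))),
    hla_hap_freq = .yaml_to_mat(obj$hla_hap_freq),
    hla_pools = lapply(obj$hla_pools, .yaml_to_pool),
    hlag_del_freq = unlist(obj$hlag_del_freq)
  ), class = "haplotype_config")
  validate_haplotype_config(hap)
  hap
}

#' Write / read an effect configuration
#'
#' @param eff An `effect_config`.
#' @param path YAML file path.
#' @export
write_effect_config <- function(eff, path) {
  obj <- list(intercept = eff$intercept,
              effects = lapply(seq_len(nrow(eff$effects)), function(i)
                as.list(eff$effects[i, , drop = TRUE])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_effect_config
#' @export
read_effect_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (length(obj$effects) == 0L) return(effect_config(intercept = obj$intercept))
  eff <- do.call(rbind, lapply(obj$effects, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
  effect_config(intercept = obj$intercept, marker = eff$marker,
                coding = eff$coding, log_or = eff$log_or)
}
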