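#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a genotype panel into long format
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `variant_id`, `dosage`.
#' @export
tidy.genotype_panel <- function(x, ...) {
  tibble(sample_id = rep(x$samples, times = nrow(x$variants)),
         variant_id = rep(x$variants$variant_id, each = length(x$samples)),
         dosage = as.vector(x$dosages))
}

#' @export
glance.genotype_panel <- function(x, ...) {
  tibble(n_samples = length(x$samples), n_variants = nrow(x$variants),
         phased = !is.null(x$haplotypes),
         missing_rate = mean(is.na(x$dosages)))
}

#' @export
tidy.gene_assoc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gene_assoc")
  out
}

#' @export
glance.gene_assoc <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_snps_total = sum(x$n_snps),
         min_p_gene = if (nrow(x)) min(x$p_gene) else NA_real_,
         n_sims = attr(x, "params")$n_sims)
}

#' @export
tidy.module_search <- function(x, ...) {
  dplyr::mutate(x$modules, genes = vapply(.data$genes, paste, "",
                                          collapse = ","))
}

#' @export
glance.module_search <- function(x, ...) {
  sel <- x$modules[x$modules$selected, ]
  tibble(n_modules = nrow(x$modules), n_selected = nrow(sel),
         n_network_genes = length(x$network_genes),
         best_z_n = if (nrow(sel)) max(sel$z_n) else NA_real_)
}

#' @export
tidy.ld_scan <- function(x, ...) as_tibble(x$pairs)

#' @export
glance.ld_scan <- function(x, ...) {
  tibble(n_pruned_variants = nrow(x$pruned_variants),
         n_tested_pairs = sum(!x$pairs$untestable %||% logical()),
         n_significant = nrow(x$significant),
         q_threshold = x$params$q_threshold)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- dplyr::mutate(as_tibble(x),
                       overlap_genes = vapply(.data$overlap_genes, paste, "",
                                              collapse = ","))
  out
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms_tested = nrow(x),
         n_significant = sum(x$p_bonferroni < 0.05),
         min_p_bonferroni = if (nrow(x)) min(x$p_bonferroni) else NA_real_)
}

#' @export
tidy.polyadapt_run <- function(x, ...) as_tibble(x$ld$pairs %||% empty_pairs())

#' @export
glance.polyadapt_run <- function(x, ...) as_tibble(x$manifest$counts)
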