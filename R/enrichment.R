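#' One-sided hypergeometric term enrichment test
#'
#' Upper-tail probability `P(X >= a)` with
#' `X ~ Hypergeometric(N, K, n)`: `N` background genes, `K` of them in the
#' term, `n` study genes, `a` the observed overlap. Equivalent to the
#' one-sided Fisher exact test on the 2 x 2 table.
#'
#' @param study_genes Character vector (must be a subset of the background).
#' @param term_genes Character vector (intersected with the background
#'   before testing).
#' @param background_genes Character vector of the gene universe.
#' @return The enrichment p-value.
#' @export
fisher_term_test <- function(study_genes, term_genes, background_genes) {
  study <- unique(study_genes); bg <- unique(background_genes)
  if (length(study) == 0 || length(bg) == 0) abort("empty study or background set")
  if (!all(study %in% bg)) abort("study genes must be a subset of the background")
  term <- intersect(unique(term_genes), bg)
  a <- length(intersect(study, term))
  stats::phyper(a - 1, length(term), length(bg) - length(term),
                length(study), lower.tail = FALSE)
}

#' Term enrichment of a gene set with Bonferroni adjustment
#'
#' Tests every term whose overlap with the study set reaches `min_overlap`;
#' the Bonferroni multiplier is the number of terms actually tested. Results
#' are sorted by adjusted p ascending with a deterministic term-id
#' tie-break.
#'
#' @param study_genes Character vector of study genes.
#' @param gene_sets Gene-set tibble from [read_gmt()].
#' @param background_genes Character vector of the gene universe.
#' @param min_overlap Minimum overlap to test a term (default 2).
#' @return An `enrichment_result` tibble: `term_id`, `description`,
#'   `overlap_genes` (list), `a`, `n`, `K`, `N`, `p_fisher`, `p_bonferroni`.
#' @export
enrich_gene_set <- function(study_genes, gene_sets, background_genes,
                            min_overlap = 2L) {
  stopifnot(min_overlap >= 1)
  study <- intersect(unique(study_genes), unique(background_genes))
  bg <- unique(background_genes)
  rows <- lapply(seq_len(nrow(gene_sets)), function(i) {
    term <- intersect(unique(gene_sets$genes[[i]]), bg)
    ov <- intersect(study, term)
    if (length(ov) < min_overlap) return(NULL)
    tibble(term_id = gene_sets$term_id[i],
           description = gene_sets$description[i],
           overlap_genes = list(sort(ov)),
           a = length(ov), n = length(study), K = length(term), N = length(bg),
           p_fisher = fisher_term_test(study, term, bg))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(term_id = character(), description = character(),
                  overlap_genes = list(), a = integer(), n = integer(),
                  K = integer(), N = integer(), p_fisher = numeric(),
                  p_bonferroni = numeric())
  } else {
    out$p_bonferroni <- pmin(1, out$p_fisher * nrow(out))
    out <- dplyr::arrange(out, .data$p_bonferroni, .data$p_fisher,
                          .data$term_id)
  }
  class(out) <- c("enrichment_result", class(out))
  attr(out, "params") <- list(min_overlap = min_overlap,
                              n_tested = nrow(out))
  out
}
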