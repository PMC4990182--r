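#' Manhattan-style plot of |iHS| along the genome
#'
#' @param scores Tibble with `variant_id`, `ihs` and, if available, `chrom`
#'   and `pos` (e.g. summary statistics joined with [ihs_score()] output).
#' @param threshold Screening threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_ihs <- function(scores, threshold = 1.5) {
  df <- dplyr::filter(scores, !is.na(.data$ihs))
  if (!"chrom" %in% names(df)) df$chrom <- "1"
  if (!"pos" %in% names(df)) df$pos <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = abs(.data$ihs),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "|iHS|") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gene_assoc <- function(object, n_label = 10, ...) {
  df <- as_tibble(object)
  df$rank <- seq_len(nrow(df))
  df$expected <- -log10(stats::ppoints(nrow(df)))[rank(df$p_gene,
                                                       ties.method = "first")]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected,
                                   y = -log10(.data$p_gene))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "expected -log10 p", y = "observed -log10 p",
                  title = "Gene-based association QQ") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.module_search <- function(object, ...) {
  df <- object$modules
  df$label <- sprintf("%s (k=%d)", df$seed_gene, df$k)
  df <- utils::head(df, max(sum(df$selected), 20))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$z_n),
                                   y = .data$z_n,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Z[N]),
                  title = "Dense-module normalized scores") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ld_scan <- function(object, ...) {
  df <- object$pairs[!object$pairs$untestable, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_ld)) +
    ggplot2::geom_histogram(boundary = 0, bins = 30,
                            fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "genotypic-LD permutation p",
                  y = "pairs",
                  title = sprintf("%d tested pairs, %d significant at q < %g",
                                  nrow(df), nrow(object$significant),
                                  object$params$q_threshold)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_result <- function(object, n_terms = 15, ...) {
  df <- utils::head(as_tibble(object), n_terms)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$term_id, -.data$p_bonferroni),
    y = -log10(.data$p_bonferroni))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 Bonferroni-adjusted p",
                  title = "Term enrichment of the adaptation gene set") +
    ggplot2::theme_minimal()
}
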