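#' Greedy LD pruning of variants by r-squared
#'
#' Variants are visited in order of ascending GWAS p (ties by chromosome and
#' position); each is kept unless its squared dosage correlation with an
#' already-kept variant on the same chromosome is strictly greater than the
#' threshold, so the most informative variant of each LD clump survives.
#'
#' @param variants Variant tibble with `p_gwas`.
#' @param panel Reference `genotype_panel`.
#' @param r2_threshold Pruning threshold (default 0.8; r-squared equal to
#'   the threshold is retained).
#' @return The retained variants, in scan order.
#' @export
prune_r2 <- function(variants, panel, r2_threshold = 0.8) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  absent <- !variants$variant_id %in% colnames(panel$dosages)
  count_warn(sum(absent), "variant(s) absent from panel dropped before pruning")
  v <- variants[!absent, ]
  v <- dplyr::arrange(v, .data$p_gwas, .data$chrom, .data$pos)
  keep <- logical(nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    D <- panel$dosages[, v$variant_id[idx], drop = FALSE]
    kept_cols <- integer()
    for (j in seq_along(idx)) {
      ok <- TRUE
      if (length(kept_cols) > 0) {
        r <- suppressWarnings(
          stats::cor(D[, j], D[, kept_cols, drop = FALSE],
                     use = "pairwise.complete.obs"))
        r[is.na(r)] <- 0
        # strict > with a guard so r^2 numerically at the threshold is kept
        if (any(r^2 > r2_threshold + 1e-12)) ok <- FALSE
      }
      if (ok) { keep[idx[j]] <- TRUE; kept_cols <- c(kept_cols, j) }
    }
  }
  v[keep, ]
}

#' Enumerate long-distance candidate pairs
#'
#' All unordered variant pairs that are (a) on different chromosomes or
#' (b) on the same chromosome separated by at least `min_distance_bp`
#' (default 10 Mb, boundary included), that lie in two *different* genes of
#' the trait network, and where at least one member is nominally associated
#' (`min(p_a, p_b) < nominal_alpha`).
#'
#' @param pruned_variants Pruned variant tibble with `p_gwas`.
#' @param gene_map Tibble (`variant_id`, `gene_id`) restricted to network
#'   genes; a variant assigned to several genes uses its first assignment.
#' @param nominal_alpha Nominal significance level (default 0.05).
#' @param min_distance_bp Same-chromosome distance floor (default 1e7).
#' @return Tibble of candidate pairs with `variant_a/b`, `gene_a/b`,
#'   `pair_class`, `distance_bp`.
#' @export
candidate_pairs <- function(pruned_variants, gene_map, nominal_alpha = 0.05,
                            min_distance_bp = 1e7) {
  gm <- gene_map[!duplicated(gene_map$variant_id), ]
  v <- dplyr::inner_join(pruned_variants, gm[, c("variant_id", "gene_id")],
                         by = "variant_id")
  v <- dplyr::arrange(v, .data$chrom, .data$pos, .data$variant_id)
  n <- nrow(v)
  if (n < 2) return(empty_pairs())
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  diff_chrom <- v$chrom[i] != v$chrom[j]
  dist <- ifelse(diff_chrom, NA_integer_, abs(v$pos[i] - v$pos[j]))
  long <- diff_chrom | dist >= min_distance_bp
  nominal <- pmin(v$p_gwas[i], v$p_gwas[j]) < nominal_alpha
  diff_gene <- v$gene_id[i] != v$gene_id[j]
  sel <- long & nominal & diff_gene
  tibble(variant_a = v$variant_id[i[sel]], gene_a = v$gene_id[i[sel]],
         variant_b = v$variant_id[j[sel]], gene_b = v$gene_id[j[sel]],
         pair_class = ifelse(diff_chrom[sel], "inter_chromosomal",
                             "long_range_cis"),
         distance_bp = dist[sel])
}

empty_pairs <- function() {
  tibble(variant_a = character(), gene_a = character(),
         variant_b = character(), gene_b = character(),
         pair_class = character(), distance_bp = integer())
}

#' Permutation G-test of genotypic linkage disequilibrium
#'
#' Tests independence of unphased genotypes at two loci on the joint (up to
#' 3 x 3) genotype contingency table with the log-likelihood-ratio statistic
#' `G = 2 sum o log(o / e)` over non-zero observed cells. The p-value comes
#' from permuting one locus's genotype labels across samples: the add-one
#' Monte-Carlo estimator for large n, or exact enumeration over all `n!`
#' label permutations for `n <= 7` samples.
#'
#' @param dosages_a,dosages_b Integer dosage vectors in {0, 1, 2} (NA
#'   allowed; pairwise-complete samples are used; at least 10 required for
#'   the Monte-Carlo path).
#' @param n_perm Permutations (default 1e4, min 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `g_stat`, `p_ld`, `n_used`, `untestable`.
#' @export
genotypic_ld_test <- function(dosages_a, dosages_b, n_perm = 1e4, seed = 1L) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- as.integer(dosages_a[ok]); b <- as.integer(dosages_b[ok])
  n <- length(a)
  stopifnot(all(a %in% 0:2), all(b %in% 0:2))
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    return(tibble(g_stat = 0, p_ld = 1, n_used = n, untestable = TRUE))
  }
  if (n <= 7) {
    res <- g_test_exact(a, b)
    return(tibble(g_stat = res$g_obs, p_ld = res$p, n_used = n,
                  untestable = FALSE))
  }
  if (n < 10) abort("genotypic LD test needs >= 10 pairwise-complete samples")
  stopifnot(n_perm >= 1000)
  set.seed(derive_seed(seed, 9L))
  res <- g_test_perm_cpp(a, b, as.integer(n_perm))
  tibble(g_stat = res$g_obs, p_ld = (1 + res$count) / (1 + n_perm),
         n_used = n, untestable = FALSE)
}

g_stat_table <- function(a, b) {
  n <- length(a)
  ra <- tabulate(a + 1L, 3L); cb <- tabulate(b + 1L, 3L)
  e <- outer(ra, cb) / n
  o <- matrix(tabulate(3L * a + b + 1L, 9L), nrow = 3, byrow = TRUE)
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}

# exact permutation null: all n! label permutations of b (identity included)
g_test_exact <- function(a, b) {
  g_obs <- g_stat_table(a, b)
  perms <- all_perms(length(b))
  gs <- apply(perms, 1, function(p) g_stat_table(a, b[p]))
  list(g_obs = g_obs, p = mean(gs >= g_obs - 1e-9))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Keep significant pairs at the q-value threshold
#'
#' @param pairs Pair tibble with a `q_ld` column.
#' @param q_threshold Threshold (default 0.05; q equal to the threshold is
#'   excluded).
#' @return The significant subset.
#' @export
significant_pairs <- function(pairs, q_threshold = 0.05) {
  pairs[!is.na(pairs$q_ld) & pairs$q_ld < q_threshold, ]
}

#' Long-distance genotypic LD scan
#'
#' Runs the full epistasis screen over a set of network-gene variants:
#' r-squared pruning, long-distance candidate enumeration with the nominal
#' association filter, per-pair permutation G-tests, Storey q-values, and
#' the significance cut.
#'
#' @param variants Screened variant tibble restricted to network genes.
#' @param gene_map Tibble (`variant_id`, `gene_id`) for network genes.
#' @param panel Reference `genotype_panel`.
#' @param r2_threshold,nominal_alpha,min_distance_bp,q_threshold Screen
#'   parameters (defaults 0.8, 0.05, 1e7, 0.05).
#' @param n_perm Permutations per pair (default 1e4).
#' @param seed Integer seed.
#' @return An `ld_scan` object: list with `pairs` (all tested pairs with
#'   `g_stat`, `p_ld`, `q_ld`), `significant`, `pruned_variants`.
#' @export
ld_scan <- function(variants, gene_map, panel, r2_threshold = 0.8,
                    nominal_alpha = 0.05, min_distance_bp = 1e7,
                    q_threshold = 0.05, n_perm = 1e4, seed = 1L) {
  pruned <- prune_r2(variants, panel, r2_threshold)
  cand <- candidate_pairs(pruned, gene_map, nominal_alpha, min_distance_bp)
  if (nrow(cand) > 0) {
    tests <- lapply(seq_len(nrow(cand)), function(i) {
      genotypic_ld_test(panel$dosages[, cand$variant_a[i]],
                        panel$dosages[, cand$variant_b[i]],
                        n_perm = n_perm, seed = derive_seed(seed, i))
    })
    cand <- dplyr::bind_cols(cand, dplyr::bind_rows(tests))
    testable <- !cand$untestable
    cand$q_ld <- NA_real_
    if (any(testable)) {
      cand$q_ld[testable] <- qvalue_estimate(cand$p_ld[testable])
    }
  } else {
    cand$g_stat <- numeric(); cand$p_ld <- numeric()
    cand$n_used <- integer(); cand$untestable <- logical()
    cand$q_ld <- numeric()
  }
  structure(list(pairs = cand,
                 significant = significant_pairs(cand, q_threshold),
                 pruned_variants = pruned,
                 params = list(r2_threshold = r2_threshold,
                               nominal_alpha = nominal_alpha,
                               min_distance_bp = min_distance_bp,
                               q_threshold = q_threshold, n_perm = n_perm,
                               seed = seed)),
            class = "ld_scan")
}

#' @export
print.ld_scan <- function(x, ...) {
  cat(sprintf("<ld_scan> %d pruned variants, %d tested pairs, %d significant (q < %g)\n",
              nrow(x$pruned_variants), nrow(x$pairs), nrow(x$significant),
              x$params$q_threshold))
  invisible(x)
}

#' Build the adaptation gene set graph
#'
#' Nodes are genes carrying at least one variant of a significant
#' long-distance LD pair; edges are (i) the significant LD pairs, labeled by
#' the analysis of origin, and (ii) protein-interaction edges among those
#' genes, labeled as interaction evidence. Gene-level association p-values
#' are attached as node attributes when available.
#'
#' @param sig_pairs Significant pair tibble (`gene_a`, `gene_b`, ...).
#' @param ppi The PPI `igraph` graph.
#' @param gene_scores Optional `gene_assoc` tibble for node `p_gene`.
#' @param label Evidence label for LD edges (e.g. the trait/sub-phenotype
#'   analysed; default "ld").
#' @return An `igraph` graph with edge attribute `evidence` and node
#'   attribute `p_gene`.
#' @export
build_adaptation_gene_set <- function(sig_pairs, ppi, gene_scores = NULL,
                                      label = "ld") {
  genes <- sort(unique(c(sig_pairs$gene_a, sig_pairs$gene_b)))
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(g)$name <- genes
  if (length(genes) > 0) {
    for (i in seq_len(nrow(sig_pairs))) {
      g <- igraph::add_edges(g, c(sig_pairs$gene_a[i], sig_pairs$gene_b[i]),
                             evidence = label)
    }
    in_ppi <- intersect(genes, igraph::V(ppi)$name)
    pe <- igraph::as_edgelist(igraph::induced_subgraph(ppi, in_ppi))
    for (i in seq_len(nrow(pe))) {
      g <- igraph::add_edges(g, c(pe[i, 1], pe[i, 2]), evidence = "ppi")
    }
    if (!is.null(gene_scores)) {
      igraph::V(g)$p_gene <-
        gene_scores$p_gene[match(genes, gene_scores$gene_id)]
    }
  }
  g
}
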