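#' Assign variants to genes
#'
#' A variant is assigned to every gene whose interval (optionally extended by
#' `flank_bp` on both sides) contains its position; overlapping genes each
#' receive the variant. Unassigned variants are counted.
#'
#' @param variants Variant tibble (`variant_id`, `chrom`, `pos`, ...).
#' @param annotation Annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param flank_bp Flank added to both gene ends (default 0).
#' @return Tibble with one row per (gene_id, variant_id) assignment.
#' @export
map_snps_to_genes <- function(variants, annotation, flank_bp = 0) {
  stopifnot(flank_bp >= 0)
  hits <- dplyr::inner_join(
    variants[, c("variant_id", "chrom", "pos")],
    annotation[, c("gene_id", "chrom", "start", "end")],
    by = "chrom", relationship = "many-to-many")
  hits <- hits[hits$pos >= hits$start - flank_bp &
                 hits$pos <= hits$end + flank_bp, ]
  n_un <- sum(!variants$variant_id %in% hits$variant_id)
  if (n_un > 0) inform(sprintf("%d variant(s) not assigned to any gene", n_un))
  tibble(gene_id = hits$gene_id, variant_id = hits$variant_id,
         chrom = hits$chrom, pos = hits$pos)
}

#' LD correlation matrix for a set of SNPs
#'
#' Pairwise-complete Pearson correlation of dosage vectors from the reference
#' panel, repaired to positive semidefiniteness by clipping negative
#' eigenvalues at zero and re-normalizing to unit diagonal. Monomorphic SNPs
#' (undefined correlation) are dropped with a warning.
#'
#' @param panel A `genotype_panel`.
#' @param snp_ids Variant ids (must be panel columns).
#' @return Correlation matrix with `dimnames` = retained SNP ids and
#'   attribute `dropped` (monomorphic ids).
#' @export
ld_correlation_matrix <- function(panel, snp_ids) {
  missing_ids <- setdiff(snp_ids, colnames(panel$dosages))
  if (length(missing_ids) > 0) {
    abort(sprintf("SNP(s) absent from panel: %s",
                  paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  D <- panel$dosages[, snp_ids, drop = FALSE]
  sds <- apply(D, 2, stats::sd, na.rm = TRUE)
  mono <- is.na(sds) | sds == 0
  count_warn(sum(mono), "monomorphic SNP(s) dropped from LD matrix")
  D <- D[, !mono, drop = FALSE]
  if (ncol(D) == 0) abort("no polymorphic SNPs left for LD matrix")
  sigma <- stats::cor(D, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0; diag(sigma) <- 1
  sigma <- repair_psd(sigma)
  dimnames(sigma) <- list(colnames(D), colnames(D))
  attr(sigma, "dropped") <- snp_ids[mono]
  sigma
}

repair_psd <- function(sigma) {
  eg <- eigen(sigma, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    warn("LD matrix strongly non-PSD before repair")
  }
  if (min(eg$values) < 0) {
    vals <- pmax(eg$values, 0)
    sigma <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(sigma)); d[d == 0] <- 1
    sigma <- sigma / outer(d, d)
    sigma <- (sigma + t(sigma)) / 2
    diag(sigma) <- 1
  }
  sigma
}

#' Monte-Carlo gene-based association test
#'
#' The observed statistic is the sum of 1-df chi-square quantiles of the SNP
#' p-values, `T_obs = sum_j Q_chisq1(1 - p_j)`. The null distribution draws
#' z ~ MVN(0, Sigma) with Sigma the reference-panel LD correlation matrix and
#' uses `T* = sum_j z_j^2`; the p-value is the add-one estimator
#' `(1 + #[T* >= T_obs]) / (1 + n_sims)`. Simulation is staged adaptively
#' (10^3, then 10^4, then the ceiling) and escalates only while the current
#' estimate is below ten times the current resolution. Single-SNP genes
#' short-circuit to `p_gene = p_snp` exactly.
#'
#' @param snp_ps SNP p-values in (0, 1].
#' @param sigma LD correlation matrix (same dimension).
#' @param n_sims Simulation ceiling (default 1e6; must be >= 1000).
#' @param seed Integer seed.
#' @param adaptive Stage the simulations (default `TRUE`); `FALSE` runs the
#'   full `n_sims` in one pass.
#' @return One-row tibble: `n_snps`, `t_obs`, `p_gene`, `z_weight`.
#' @export
gene_test_mc <- function(snp_ps, sigma, n_sims = 1e6, seed = 1L,
                         adaptive = TRUE) {
  k <- length(snp_ps)
  stopifnot(k >= 1, n_sims >= 1000)
  assert_prob(snp_ps, "snp p-values")
  if (k != nrow(sigma)) abort("length(snp_ps) must equal dim(sigma)")
  t_obs <- sum(stats::qchisq(snp_ps, df = 1, lower.tail = FALSE))
  if (k == 1) {
    p <- snp_ps[1]
    return(tibble(n_snps = 1L, t_obs = t_obs, p_gene = p,
                  z_weight = probit_weight(p)))
  }
  sigma <- repair_psd(sigma)
  L <- tryCatch(chol(sigma, pivot = TRUE),
                error = function(e) abort("LD matrix not PSD after repair"))
  piv <- attr(L, "pivot")
  set.seed(derive_seed(seed, 7L))
  stages <- unique(pmin(c(1e3, 1e4, n_sims), n_sims))
  if (!adaptive) stages <- n_sims
  done <- 0; exceed <- 0
  for (target in stages) {
    todo <- target - done
    while (todo > 0) {
      b <- min(todo, 5e4)
      Z <- matrix(stats::rnorm(b * k), nrow = k)
      X <- t(L) %*% Z  # columns ~ MVN(0, sigma[piv, piv]); sum of squares is pivot-invariant
      exceed <- exceed + sum(colSums(X^2) >= t_obs)
      done <- done + b; todo <- todo - b
    }
    p <- (1 + exceed) / (1 + done)
    if (p >= 10 / done) break
  }
  tibble(n_snps = k, t_obs = t_obs, p_gene = p,
         z_weight = probit_weight(p))
}

#' Probit gene weight
#'
#' `z = qnorm(1 - p)` with p clipped into `[1e-16, 1 - 1e-16]` so the weight
#' is always finite (required by the module search).
#'
#' @param p_gene Gene p-value(s) in (0, 1].
#' @return Numeric weight(s).
#' @export
probit_weight <- function(p_gene) {
  assert_prob(p_gene, "gene p-values")
  p <- pmin(pmax(p_gene, 1e-16), 1 - 1e-16)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Gene-based association over all genes
#'
#' Maps screened variants to genes and runs the Monte-Carlo gene test per
#' gene, with the LD matrix estimated from the reference panel. Genes with
#' no screened SNPs are absent from the output (they are ineligible module
#' seeds downstream).
#'
#' @param variants Screened variant tibble (with `p_gwas`).
#' @param annotation Annotation tibble.
#' @param panel Reference `genotype_panel`.
#' @param flank_bp SNP-to-gene flank (default 0).
#' @param n_sims Simulation ceiling per gene (default 1e5).
#' @param seed Integer seed.
#' @return A `gene_assoc` tibble: `gene_id`, `n_snps`, `t_obs`, `p_gene`,
#'   `z_weight`, sorted by `p_gene`.
#' @export
gene_assoc <- function(variants, annotation, panel, flank_bp = 0,
                       n_sims = 1e5, seed = 1L) {
  gmap <- map_snps_to_genes(variants, annotation, flank_bp = flank_bp)
  genes <- sort(unique(gmap$gene_id))
  rows <- lapply(seq_along(genes), function(gi) {
    g <- genes[gi]
    ids <- gmap$variant_id[gmap$gene_id == g]
    ids <- ids[ids %in% colnames(panel$dosages)]
    if (length(ids) == 0) return(NULL)
    sigma <- withCallingHandlers(
      tryCatch(ld_correlation_matrix(panel, ids), error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(sigma)) return(NULL)
    keep <- setdiff(ids, attr(sigma, "dropped"))
    ps <- variants$p_gwas[match(keep, variants$variant_id)]
    res <- gene_test_mc(ps, sigma, n_sims = n_sims,
                        seed = derive_seed(seed, gi))
    dplyr::bind_cols(tibble(gene_id = g), res)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), n_snps = integer(),
                  t_obs = numeric(), p_gene = numeric(), z_weight = numeric())
  }
  out <- dplyr::arrange(out, .data$p_gene, .data$gene_id)
  class(out) <- c("gene_assoc", class(out))
  attr(out, "params") <- list(flank_bp = flank_bp, n_sims = n_sims, seed = seed)
  out
}
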