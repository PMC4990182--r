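test_that("SNP-to-gene assignment respects inclusive boundaries and flanks", {
  ann <- tibble::tibble(gene_id = c("G1", "G2"), chrom = c("1", "1"),
                        start = c(1000L, 1400L), end = c(1500L, 2000L))
  v <- tibble::tibble(variant_id = c("a", "b", "c", "d"),
                      chrom = "1", pos = c(1000L, 1450L, 2500L, 100L))
  gm <- suppressMessages(map_snps_to_genes(v, ann))
  expect_equal(sort(gm$gene_id[gm$variant_id == "a"]), "G1")  # pos == start
  expect_equal(sort(gm$gene_id[gm$variant_id == "b"]), c("G1", "G2"))  # overlap
  expect_false("c" %in% gm$variant_id)

  # flank boundary arithmetic at 50 kb
  ann2 <- tibble::tibble(gene_id = "G", chrom = "1",
                         start = 100000L, end = 110000L)
  v2 <- tibble::tibble(variant_id = c("near", "far"), chrom = "1",
                       pos = c(100000L - 49999L, 100000L - 50001L))
  gm2 <- suppressMessages(map_snps_to_genes(v2, ann2, flank_bp = 50000))
  expect_equal(gm2$variant_id, "near")
})

test_that("LD matrix is a repaired Pearson correlation of dosages", {
  D <- cbind(v1 = c(0, 1, 2, 1), v2 = c(2, 1, 0, 1), v3 = c(0, 1, 2, 1))
  p <- make_panel(D)
  sigma <- ld_correlation_matrix(p, c("v1", "v2", "v3"))
  expect_equal(sigma["v1", "v2"], -1)       # hand Pearson computation
  expect_equal(sigma["v1", "v3"], 1)        # duplicated column
  expect_true(all(eigen(sigma, symmetric = TRUE)$values >= -1e-10))

  # monomorphic SNP dropped
  D2 <- cbind(v1 = c(0, 1, 2, 1), v2 = c(1, 1, 1, 1))
  expect_warning(s2 <- ld_correlation_matrix(make_panel(D2), c("v1", "v2")),
                 "monomorphic")
  expect_equal(colnames(s2), "v1")

  # independent columns at large n have near-zero correlation
  set.seed(7)
  D3 <- cbind(a = rbinom(10000, 2, 0.3), b = rbinom(10000, 2, 0.4))
  s3 <- ld_correlation_matrix(make_panel(D3), c("a", "b"))
  expect_lt(abs(s3["a", "b"]), 0.05)
})

test_that("gene test short-circuits single SNPs and matches chi-square closed forms", {
  # k = 1: exact shortcut
  r1 <- gene_test_mc(0.01, matrix(1, 1, 1), n_sims = 1000)
  expect_equal(r1$p_gene, 0.01)
  # k = 2, independent SNPs at p = 0.05: T = 7.6829, survival chi2_2
  sig <- diag(2)
  r2 <- gene_test_mc(c(0.05, 0.05), sig, n_sims = 1e5, seed = 3,
                     adaptive = FALSE)
  expect_equal(r2$t_obs, 2 * qchisq(0.05, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  p_exact <- pchisq(r2$t_obs, df = 2, lower.tail = FALSE)  # ~0.0215
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(r2$p_gene - p_exact), 3 * se)
  # all p = 1 gives T = 0 and p_gene = 1
  r3 <- gene_test_mc(c(1, 1), diag(2), n_sims = 1000, seed = 1)
  expect_equal(r3$t_obs, 0)
  expect_equal(r3$p_gene, 1)
})

test_that("T_obs is monotone: decreasing any SNP p never decreases it", {
  set.seed(11)
  ps <- runif(5)
  t0 <- sum(qchisq(ps, 1, lower.tail = FALSE))
  for (j in 1:5) {
    ps2 <- ps
    ps2[j] <- ps[j] / 2
    expect_gte(sum(qchisq(ps2, 1, lower.tail = FALSE)), t0)
  }
})

test_that("probit weights transform gene p-values with clipping", {
  expect_equal(probit_weight(0.5), 0)
  expect_equal(probit_weight(0.0228), qnorm(0.0228, lower.tail = FALSE))
  expect_equal(probit_weight(0.0228), 2.0, tolerance = 0.01)
  w1 <- probit_weight(1)
  expect_true(is.finite(w1) && w1 < -5)
  expect_true(is.finite(probit_weight(1e-300)))
})

test_that("gene-level pipeline scores only genes with screened SNPs", {
  set.seed(21)
  D <- matrix(rbinom(50 * 6, 2, 0.4), nrow = 50)
  colnames(D) <- sprintf("v%d", 1:6)
  p <- make_panel(D, pos = c(100L, 200L, 300L, 5000L, 5100L, 9000L))
  ann <- tibble::tibble(gene_id = c("G1", "G2", "G3"), chrom = "1",
                        start = c(50L, 4500L, 20000L),
                        end = c(400L, 6000L, 30000L))
  v <- tibble::tibble(variant_id = sprintf("v%d", 1:6), chrom = "1",
                      pos = c(100L, 200L, 300L, 5000L, 5100L, 9000L),
                      p_gwas = c(0.01, 0.2, 0.5, 0.03, 0.4, 0.9))
  gs <- suppressMessages(gene_assoc(v, ann, p, n_sims = 1000, seed = 2))
  expect_setequal(gs$gene_id, c("G1", "G2"))  # G3 has no SNPs; v6 unassigned
  expect_equal(gs$n_snps[gs$gene_id == "G1"], 3L)
  expect_equal(gs$z_weight, probit_weight(gs$p_gene))
})
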