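test_that("r-squared pruning keeps the most associated variant of each clump", {
  # identical dosage columns: only the smaller-p variant survives
  D <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(0, 1, 2, 1, 0, 2))
  p <- make_panel(D)
  v <- tibble::tibble(variant_id = c("a", "b"), chrom = "1",
                      pos = c(1000L, 2000L), p_gwas = c(0.01, 0.5))
  kept <- prune_r2(v, p, 0.8)
  expect_equal(kept$variant_id, "a")

  # r^2 exactly at the threshold is retained (strict >)
  n <- 8
  e1 <- c(1, -1, 1, -1, 1, -1, 1, -1) / sqrt(8)
  e2 <- c(1, 1, -1, -1, 1, 1, -1, -1) / sqrt(8)
  r <- sqrt(0.8)
  D2 <- cbind(a = e1, b = r * e1 + sqrt(1 - r^2) * e2)
  p2 <- make_panel(D2)
  v2 <- tibble::tibble(variant_id = c("a", "b"), chrom = "1",
                       pos = c(1L, 2L), p_gwas = c(0.01, 0.5))
  expect_equal(cor(D2)[1, 2]^2, 0.8, tolerance = 1e-12)
  expect_equal(prune_r2(v2, p2, 0.8)$variant_id, c("a", "b"))

  # greedy chain: b pruned against a; c checked only against kept a
  th1 <- acos(sqrt(0.9)); th2 <- th1 + acos(sqrt(0.9))
  D3 <- cbind(a = e1,
              b = cos(th1) * e1 + sin(th1) * e2,
              c = cos(th2) * e1 + sin(th2) * e2)
  r2 <- cor(D3)^2
  expect_gt(r2["a", "b"], 0.8); expect_gt(r2["b", "c"], 0.8)
  expect_lte(r2["a", "c"], 0.8)
  v3 <- tibble::tibble(variant_id = c("a", "b", "c"), chrom = "1",
                       pos = 1:3, p_gwas = c(0.01, 0.02, 0.03))
  expect_equal(prune_r2(v3, make_panel(D3), 0.8)$variant_id, c("a", "c"))

  # variant absent from the panel is dropped with a warning
  v4 <- tibble::tibble(variant_id = c("a", "zz"), chrom = "1",
                       pos = c(1L, 2L), p_gwas = c(0.1, 0.2))
  expect_warning(out4 <- prune_r2(v4, p, 0.8), "absent")
  expect_equal(out4$variant_id, "a")
})

test_that("long-distance pair enumeration honors the 10 Mb and nominal filters", {
  v <- tibble::tibble(
    variant_id = c("a", "b", "c", "d", "e"),
    chrom = c("1", "1", "1", "2", "2"),
    pos = c(1L, 10000001L, 9999999L, 5L, 10L),
    p_gwas = c(0.01, 0.5, 0.5, 0.2, 0.2))
  gm <- tibble::tibble(variant_id = c("a", "b", "c", "d", "e"),
                       gene_id = c("G1", "G2", "G3", "G4", "G5"))
  pr <- candidate_pairs(v, gm, nominal_alpha = 0.05)
  key <- paste(pr$variant_a, pr$variant_b)
  expect_true("a b" %in% key)        # exactly 10 Mb apart: included
  expect_false("a c" %in% key)       # 9,999,998 bp: excluded
  expect_false("d e" %in% key)       # neither nominally associated
  expect_true(all(pr$pair_class %in% c("inter_chromosomal", "long_range_cis")))
  # different chromosomes with one associated member
  expect_true("a d" %in% key)
  # within-gene pairs never tested
  gm2 <- tibble::tibble(variant_id = c("a", "b"), gene_id = c("G1", "G1"))
  expect_equal(nrow(candidate_pairs(v[1:2, ], gm2)), 0)
})

test_that("genotypic LD G-test detects perfect dependence and handles degeneracy", {
  set.seed(13)
  a <- rbinom(50, 2, 0.4)
  while (length(unique(a)) < 2) a <- rbinom(50, 2, 0.4)
  res <- genotypic_ld_test(a, a, n_perm = 2000, seed = 1)
  expect_equal(res$p_ld, 1 / 2001, tolerance = 5e-3)
  expect_gt(res$g_stat, 0)

  # monomorphic locus: untestable, p = 1
  res2 <- genotypic_ld_test(a, rep(1L, 50), n_perm = 2000)
  expect_true(res2$untestable)
  expect_equal(res2$p_ld, 1)
})

test_that("Monte-Carlo G-test p agrees with the exact enumeration oracle", {
  a <- c(0L, 1L, 2L, 0L, 1L, 2L)
  b <- c(0L, 1L, 2L, 1L, 0L, 2L)
  exact <- genotypic_ld_test(a, b)  # n = 6: exact path
  # Monte-Carlo on the same table via the compiled kernel
  set.seed(99)
  mc <- polyadapt:::g_test_perm_cpp(a, b, 20000L)
  p_mc <- (1 + mc$count) / (1 + 20000)
  se <- sqrt(exact$p_ld * (1 - exact$p_ld) / 20000)
  expect_equal(mc$g_obs, exact$g_stat, tolerance = 1e-9)
  expect_lt(abs(p_mc - exact$p_ld), 3 * se + 1e-4)
})

test_that("G statistic is invariant under consistent genotype relabeling", {
  set.seed(17)
  a <- rbinom(40, 2, 0.5); b <- rbinom(40, 2, 0.5)
  g1 <- polyadapt:::g_stat_table(a, b)
  # swap categories 0 <-> 2 at both loci
  g2 <- polyadapt:::g_stat_table(2L - a, 2L - b)
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 = 1", {
  p <- c(0.01, 0.02, 0.03, 0.9)
  expect_equal(qvalue_estimate(p), c(0.04, 0.04, 0.04, 0.9))  # hand BH
  # agreement with the independent BH implementation
  set.seed(23)
  p2 <- runif(60)
  expect_equal(qvalue_estimate(p2), p.adjust(p2, "BH"), tolerance = 1e-12)
  expect_equal(qvalue_estimate(rep(1, 5)), rep(1, 5))
  expect_equal(qvalue_estimate(numeric(0)), numeric(0))
  # monotone non-decreasing in p
  p3 <- sort(runif(50))
  q3 <- qvalue_estimate(p3)
  expect_true(all(diff(q3) >= -1e-12))
})

test_that("pi0 estimation shrinks q-values on signal-rich large inputs", {
  set.seed(29)
  p <- c(runif(150), rbeta(150, 0.2, 8))
  q <- qvalue_estimate(p)
  pi0 <- polyadapt:::estimate_pi0(p)
  expect_lt(pi0, 1)
  expect_gt(pi0, 0)
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
})

test_that("significance cut on q is strict at the threshold", {
  pr <- tibble::tibble(variant_a = c("a", "b", "c"), q_ld = c(0.05, 0.049, NA))
  out <- significant_pairs(pr)
  expect_equal(out$variant_a, "b")
})

test_that("the adaptation gene set carries labeled LD and PPI evidence", {
  sig <- tibble::tibble(gene_a = "G1", gene_b = "G2")
  ppi <- toy_graph(c("G1", "G2", "G2", "G3"))
  gs <- build_adaptation_gene_set(sig, ppi, label = "bmi")
  expect_setequal(igraph::V(gs)$name, c("G1", "G2"))
  expect_equal(igraph::ecount(gs), 2)  # parallel LD + PPI edges
  expect_setequal(igraph::E(gs)$evidence, c("bmi", "ppi"))
  # no significant pairs: empty graph
  empty <- build_adaptation_gene_set(sig[0, ], ppi)
  expect_equal(igraph::vcount(empty), 0)
})
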