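small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_samples = 40, n_chrom = 2, variants_per_chrom = 60,
             chrom_length_bp = 3e7, n_genes = 60, n_background_terms = 5, ...)
}

test_that("panel simulation is deterministic in the seed and respects shape", {
  cfg <- small_cfg(3)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  p3 <- simulate_panel(small_cfg(4))
  expect_false(identical(p1$dosages, p3$dosages))

  expect_equal(dim(p1$dosages), c(40, 120))
  expect_equal(dim(p1$haplotypes), c(80, 120))
  # haplotype pairs sum to the dosage
  n <- length(p1$samples)
  expect_equal(unname(p1$haplotypes[seq(1, 2 * n, 2), ] +
                        p1$haplotypes[seq(2, 2 * n, 2), ]),
               unname(p1$dosages))
  # variants sorted by (chrom, pos)
  v <- p1$variants
  expect_true(all(diff(order(v$chrom, v$pos)) == 1))
  # sweep needs at least two carrier haplotypes
  expect_error(simulate_panel(
    sim_config(seed = 1, n_samples = 1, n_chrom = 1, variants_per_chrom = 10,
               sweep = list(chrom = "1", derived_freq = 0.2,
                            recomb_rate_per_bp = 1e-6,
                            mutation_rate_per_site = 0))),
    "carrier")
})

test_that("summary statistics are null-uniform except in planted genes", {
  # mu_alt = 0 reduces planted genes to the background
  ks_ps <- vapply(1:10, function(s) {
    cfg <- small_cfg(s, alt_effect = 0)
    p <- simulate_panel(cfg)
    ann <- simulate_annotation(cfg)
    ss <- suppressMessages(
      simulate_summary_stats(cfg, p, ann, planted_genes = ann$gene_id[1:5]))
    suppressWarnings(ks.test(ss$p_gwas, "punif")$p.value)
  }, 0)
  expect_gte(sum(ks_ps > 0.01), 9)

  # mu_alt = 4 drives planted-gene p-values far down
  medians <- vapply(1:10, function(s) {
    cfg <- small_cfg(s, alt_effect = 4)
    p <- simulate_panel(cfg)
    ann <- simulate_annotation(cfg)
    planted <- ann$gene_id[1:5]
    ss <- suppressMessages(
      simulate_summary_stats(cfg, p, ann, planted_genes = planted))
    gm <- suppressMessages(map_snps_to_genes(ss, ann))
    median(ss$p_gwas[ss$variant_id %in%
                       gm$variant_id[gm$gene_id %in% planted]])
  }, 0)
  expect_true(all(medians < 1e-3))

  # empty planted set: all uniform
  cfg <- small_cfg(2)
  p <- simulate_panel(cfg)
  ann <- simulate_annotation(cfg)
  ss <- simulate_summary_stats(cfg, p, ann, planted_genes = character())
  expect_gt(suppressWarnings(ks.test(ss$p_gwas, "punif")$p.value), 0.01)
})

test_that("PPI simulation wires the planted module at q_in and stays scale-free", {
  cfg <- small_cfg(7, q_in = 1)
  genes <- sprintf("g%04d", 1:60)
  mod <- genes[1:6]
  g1 <- simulate_ppi(cfg, genes, planted_module = mod)
  sub <- igraph::induced_subgraph(g1, mod)
  expect_equal(igraph::ecount(sub), choose(6, 2))  # clique at q_in = 1

  cfg0 <- small_cfg(7, q_in = 0)
  g0 <- simulate_ppi(cfg0, genes, planted_module = mod)
  gbg <- simulate_ppi(cfg0, genes, planted_module = character())
  expect_equal(igraph::ecount(g0), igraph::ecount(gbg))  # background only

  # heavy-tailed degrees on a large graph, over seeds
  hits <- 0L
  for (s in 1:10) {
    cfg2 <- sim_config(seed = s, n_genes = 600)
    gg <- simulate_ppi(cfg2, sprintf("g%04d", 1:600),
                       planted_module = character())
    deg <- igraph::degree(gg)
    if (max(deg) > 3 * median(deg)) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("epistasis planting creates the specified dosage dependence", {
  # eps = 0: dependent column becomes an exact copy
  set.seed(51)
  D <- cbind(a = rbinom(80, 2, 0.4), b = rbinom(80, 2, 0.3))
  p <- make_panel(D, chrom = c("1", "2"), pos = c(1000L, 1000L))
  pp <- plant_epistasis(p, tibble::tibble(variant_a = "a", variant_b = "b",
                                          eps = 0), seed = 1)
  expect_equal(unname(pp$dosages[, "b"]), unname(pp$dosages[, "a"]))

  # eps = 0.5 at n = 10,000: correlation ~ (1 - eps) by the mixture argument
  set.seed(52)
  D2 <- cbind(a = rbinom(10000, 2, 0.3), b = rbinom(10000, 2, 0.3))
  p2 <- make_panel(D2, chrom = c("1", "2"), pos = c(1L, 1L))
  pp2 <- plant_epistasis(p2, tibble::tibble(variant_a = "a", variant_b = "b",
                                            eps = 0.5), seed = 2)
  expect_equal(cor(pp2$dosages[, "a"], pp2$dosages[, "b"]), 0.5,
               tolerance = 0.04)

  # same-chromosome pair under 10 Mb is rejected
  p3 <- make_panel(cbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 0)),
                   chrom = c("1", "1"), pos = c(1000L, 2000L))
  expect_error(plant_epistasis(p3, tibble::tibble(variant_a = "a",
                                                  variant_b = "b", eps = 0.1)),
               "10 Mb")

  # haplotypes remain consistent with dosages after planting
  cfg <- small_cfg(9)
  pan <- simulate_panel(cfg)
  v <- pan$variants
  pair <- tibble::tibble(variant_a = v$variant_id[v$chrom == "1"][1],
                         variant_b = v$variant_id[v$chrom == "2"][1],
                         eps = 0.1)
  pl <- plant_epistasis(pan, pair, seed = 3)
  n <- length(pl$samples)
  expect_equal(unname(pl$haplotypes[seq(1, 2 * n, 2), ] +
                        pl$haplotypes[seq(2, 2 * n, 2), ]),
               unname(pl$dosages))
})

test_that("bundle truth manifests exactly the planted entities", {
  cfg <- small_cfg(13, n_planted_genes = 3, n_planted_pairs = 1)
  b <- suppressWarnings(suppressMessages(simulate_bundle(cfg)))
  expect_length(b$truth$planted_genes, 3)
  expect_true(all(b$truth$planted_genes %in% b$annotation$gene_id))
  expect_true(all(unlist(b$truth$planted_pairs[, c("variant_a", "variant_b")]) %in%
                    b$panel$variants$variant_id))
  expect_equal(b$gene_sets$term_id[1], "term_true")
  expect_setequal(b$gene_sets$genes[[1]], b$truth$planted_genes)
  # two runs with different seeds differ
  b2 <- suppressWarnings(suppressMessages(simulate_bundle(small_cfg(14,
    n_planted_genes = 3, n_planted_pairs = 1))))
  expect_false(identical(b$panel$dosages, b2$panel$dosages))
})
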