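test_that("EHH matches hand-enumerated and degenerate cases", {
  # 4 carriers spanning core + flank with strings {00, 00, 01, 10}:
  # one identical pair out of six
  H <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 0L))
  expect_equal(ehh(H, 1, 2), 1 / 6)
  # all carriers identical over the span
  H2 <- matrix(1L, nrow = 5, ncol = 3)
  expect_equal(ehh(H2, 1, 3), 1)
  # target = core: the span is the shared core allele
  expect_equal(ehh(H, 1, 1), 1)
  expect_error(ehh(H[1, , drop = FALSE], 1, 2), "2 carrier")
})

test_that("EHH equals the brute-force all-pairs identity count", {
  set.seed(41)
  reps <- 0
  while (reps < 100) {
    n <- sample(6:20, 1)
    m <- sample(5:50, 1)
    H <- random_hap_matrix(n, m)
    core <- sample(seq_len(m), 1)
    H <- H[H[, core] == 1L, , drop = FALSE]  # carriers of the core allele
    if (nrow(H) < 2) next
    target <- sample(seq_len(m), 1)
    expect_equal(ehh(H, core, target), brute_ehh(H, core, target),
                 tolerance = 1e-12)
    reps <- reps + 1
  }
})

test_that("EHH decay curves are non-increasing in distance", {
  set.seed(42)
  for (rep in 1:25) {
    H <- random_hap_matrix(sample(4:16, 1), 30)
    pos <- sort(sample.int(1e6, 30))
    cv <- polyadapt:::ehh_curve_side(H, 10, pos, "right", cutoff = 0)
    expect_true(all(diff(cv$ehh) <= 1e-12))
  }
})

test_that("iHH trapezoid integration truncates at the cutoff", {
  # hand trapezoid: (1+0.5)/2*1000 + (0.5+0.04)/2*1000 = 750 + 270
  c1 <- tibble::tibble(distance_bp = c(0, 1000, 2000), ehh = c(1, 0.5, 0.04))
  expect_equal(as.numeric(ihh(c1)), 1020)
  expect_false(attr(ihh(c1), "edge_truncated"))
  # EHH = 1 over [0, D], then 0 at the next marker: D + gap/2
  c2 <- tibble::tibble(distance_bp = c(0, 4000, 4400), ehh = c(1, 1, 0))
  expect_equal(as.numeric(ihh(c2)), 4000 + 400 / 2)
  # curve that never reaches the cutoff is flagged
  c3 <- tibble::tibble(distance_bp = c(0, 1000), ehh = c(1, 0.6))
  expect_true(attr(ihh(c3), "edge_truncated"))
  # empty far side (core at chromosome edge)
  c4 <- tibble::tibble(distance_bp = 0, ehh = 1)
  res <- ihh(list(c4))
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "edge_truncated"))
})

test_that("iHH matches an independent trapezoid oracle on random curves", {
  set.seed(43)
  for (rep in 1:100) {
    k <- sample(3:12, 1)
    d <- c(0, sort(sample.int(1e5, k - 1)))
    e <- c(1, sort(runif(k - 1), decreasing = TRUE))
    expect_equal(as.numeric(ihh(tibble::tibble(distance_bp = d, ehh = e))),
                 trapezoid_oracle(d, e), tolerance = 1e-9)
  }
})

test_that("iHS standardization centers and scales within frequency bins", {
  sc <- tibble::tibble(derived_freq = c(0.12, 0.13, 0.14),
                       ihs_unstandardized = c(0.6, 0.8, 1.0))
  out <- ihs_standardize(sc)
  expect_equal(out$ihs, c(-1, 0, 1))  # mean 0.8, sample SD 0.2

  # all values equal in a bin: flagged, not infinite
  sc2 <- tibble::tibble(derived_freq = rep(0.3, 4),
                        ihs_unstandardized = rep(0.5, 4))
  expect_warning(out2 <- ihs_standardize(sc2), "unstandardizable")
  expect_true(all(is.na(out2$ihs)))

  # a bin with < 3 scores is flagged
  sc3 <- tibble::tibble(derived_freq = c(0.1, 0.12),
                        ihs_unstandardized = c(0.1, 0.9))
  expect_warning(out3 <- ihs_standardize(sc3), "unstandardizable")
  expect_true(all(is.na(out3$ihs)))

  # two populated bins are standardized independently
  sc4 <- tibble::tibble(derived_freq = c(0.11, 0.12, 0.13, 0.61, 0.62, 0.63),
                        ihs_unstandardized = c(1, 2, 3, 10, 20, 60))
  out4 <- ihs_standardize(sc4)
  for (half in list(1:3, 4:6)) {
    expect_equal(mean(out4$ihs[half]), 0, tolerance = 1e-12)
    expect_equal(sd(out4$ihs[half]), 1, tolerance = 1e-12)
  }
})

test_that("the |iHS| screen applies a strict threshold and drops missing scores", {
  v <- tibble::tibble(variant_id = c("a", "b", "c", "d"),
                      ihs = c(1.5, -1.6, 2.0, NA))
  expect_warning(out <- filter_by_ihs(v, 1.5), "without iHS")
  expect_equal(out$variant_id, c("b", "c"))  # 1.5 excluded, |-1.6| included
  v2 <- tibble::tibble(variant_id = "a", ihs = NA_real_)
  expect_warning(
    expect_warning(out2 <- filter_by_ihs(v2, 1.5), "no variants pass"),
    "without iHS")
  expect_equal(nrow(out2), 0)
})

test_that("a no-recombination sweep yields identical carrier haplotypes and EHH 1", {
  cfg <- sim_config(seed = 9, n_samples = 25, n_chrom = 1,
                    variants_per_chrom = 60, chrom_length_bp = 1e7,
                    sweep = list(chrom = "1", derived_freq = 0.4,
                                 recomb_rate_per_bp = 1e-300,
                                 mutation_rate_per_site = 0))
  p <- simulate_panel(cfg)
  core <- polyadapt:::sweep_core_index(cfg)
  carriers <- p$haplotypes[, core] == 1L
  Hc <- p$haplotypes[carriers, ]
  expect_true(all(apply(Hc, 2, function(x) length(unique(x)) == 1)))
  expect_equal(ehh(Hc, core, 1), 1)
  expect_equal(ehh(Hc, core, ncol(Hc)), 1)
})

test_that("sweep panels show elevated standardized |iHS| at the core", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_samples = 100, n_chrom = 2,
                      variants_per_chrom = 150, chrom_length_bp = 3e7,
                      sweep = list(chrom = "1", derived_freq = 0.5,
                                   recomb_rate_per_bp = 1e-6,
                                   mutation_rate_per_site = 1e-3))
    p <- simulate_panel(cfg)
    sc <- suppressWarnings(ihs_score(p))
    core_id <- sprintf("snp_1_%03d", polyadapt:::sweep_core_index(cfg))
    core_ihs <- abs(sc$ihs[sc$variant_id == core_id])
    bg <- abs(sc$ihs[sc$variant_id != core_id &
                       !grepl("^snp_1", sc$variant_id)])
    q95 <- quantile(bg, 0.95, na.rm = TRUE)
    if (!is.na(core_ihs) && core_ihs > q95) hits <- hits + 1L
  }
  expect_gte(hits, 8)
})
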