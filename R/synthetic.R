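#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the package's reference study condition: 200 diploid samples, 5 chromosomes
#' of 50 Mb with 400 variants each, 1,000 genes, a scale-free protein
#' interaction network of ~3,000 edges, one partial selective sweep (derived
#' frequency 0.5), ten planted trait genes that double as a densely wired
#' network module, and five planted cross-chromosome epistatic pairs.
#'
#' @param seed Integer seed; every random draw in the generator descends
#'   from it.
#' @param n_samples Number of diploid samples in the reference panel.
#' @param n_chrom,variants_per_chrom,chrom_length_bp Genome shape.
#' @param maf_range Allele-frequency range (uniform draw per variant).
#' @param n_genes Size of the gene universe (tiled across chromosomes).
#' @param sweep `NULL` for no sweep, or a list with `chrom` (label),
#'   `derived_freq` (carrier fraction f of haplotypes, 0 < f < 1),
#'   `recomb_rate_per_bp` (rate of the exponential distance from the core to
#'   the founder-copy breakpoint) and `mutation_rate_per_site` (per-site copy
#'   error). The core variant is the middle variant of the sweep chromosome.
#' @param n_planted_genes,planted_genes Trait genes whose SNPs receive
#'   non-null association z-scores; either an explicit character vector or a
#'   count to auto-select (genes holding at least one selection-screened
#'   variant are preferred so the planted signal survives the iHS screen).
#' @param alt_effect Mean of |z| for SNPs in planted genes.
#' @param planted_module Gene set to wire densely (defaults to the planted
#'   trait genes); `q_in` is the within-module Erdos-Renyi edge probability.
#' @param q_in Within-module edge probability.
#' @param ppi_m Attachment edges per node of the preferential-attachment
#'   background graph.
#' @param n_planted_pairs,planted_pairs Cross-chromosome (or >= 10 Mb
#'   long-range cis) genotype-dependence pairs; explicit tibble with columns
#'   `variant_a`, `variant_b`, `eps`, or a count to auto-select.
#' @param copy_error Per-sample probability `eps` that the dependent variant
#'   receives a fresh Hardy-Weinberg draw instead of copying its partner.
#' @param n_background_terms Number of random gene sets written next to the
#'   planted "true" term in the GMT output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 200L,
                       n_chrom = 5L,
                       variants_per_chrom = 400L,
                       chrom_length_bp = 5e7,
                       maf_range = c(0.05, 0.5),
                       n_genes = 1000L,
                       sweep = list(chrom = "1", derived_freq = 0.5,
                                    recomb_rate_per_bp = 1e-6,
                                    mutation_rate_per_site = 1e-3),
                       n_planted_genes = 10L, planted_genes = NULL,
                       alt_effect = 4,
                       planted_module = NULL, q_in = 0.8, ppi_m = 3L,
                       n_planted_pairs = 5L, planted_pairs = NULL,
                       copy_error = 0.1,
                       n_background_terms = 50L) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            copy_error >= 0, copy_error <= 0.5)
  if (!is.null(sweep)) {
    stopifnot(sweep$derived_freq > 0, sweep$derived_freq < 1)
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_chrom = as.integer(n_chrom),
                 variants_per_chrom = as.integer(variants_per_chrom),
                 chrom_length_bp = chrom_length_bp, maf_range = maf_range,
                 n_genes = as.integer(n_genes), sweep = sweep,
                 n_planted_genes = n_planted_genes,
                 planted_genes = planted_genes, alt_effect = alt_effect,
                 planted_module = planted_module, q_in = q_in,
                 ppi_m = as.integer(ppi_m),
                 n_planted_pairs = n_planted_pairs,
                 planted_pairs = planted_pairs, copy_error = copy_error,
                 n_background_terms = n_background_terms),
            class = "sim_config")
}

#' Null configuration: no sweep, no planted genes, module or pairs
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @export
null_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, sweep = NULL, n_planted_genes = 0L,
             n_planted_pairs = 0L, ...)
}

sweep_core_index <- function(config) config$variants_per_chrom %/% 2L + 1L

#' Simulate a phased reference genotype panel
#'
#' Haplotype alleles are i.i.d. Bernoulli draws at per-variant frequencies
#' uniform in `maf_range`, except on the sweep chromosome: a fraction f of
#' haplotypes carry the derived core allele and copy a single founder
#' haplotype outward from the core, switching back to independent frequency
#' draws beyond a per-haplotype recombination breakpoint at exponential
#' distance (rate `recomb_rate_per_bp`) on each side, with per-site copy
#' errors at `mutation_rate_per_site`. Dosages are derived from the two
#' haplotypes of each sample, so the panel is in Hardy-Weinberg proportions
#' by construction.
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel` with phased haplotypes.
#' @export
simulate_panel <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  n_hap <- 2L * config$n_samples
  chroms <- as.character(seq_len(config$n_chrom))
  var_list <- list(); hap_list <- list()
  for (ci in seq_along(chroms)) {
    m <- config$variants_per_chrom
    pos <- sort(sample.int(config$chrom_length_bp, m))
    freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    H <- matrix(stats::rbinom(n_hap * m, 1L, rep(freq, each = n_hap)),
                nrow = n_hap)
    if (!is.null(config$sweep) && chroms[ci] == norm_chrom(config$sweep$chrom)) {
      H <- apply_sweep(H, pos, config, n_hap)
    }
    var_list[[ci]] <- tibble(
      variant_id = sprintf("snp_%s_%03d", chroms[ci], seq_len(m)),
      chrom = chroms[ci], pos = as.integer(pos),
      ref_allele = "A", alt_allele = "G")
    hap_list[[ci]] <- H
  }
  variants <- dplyr::bind_rows(var_list)
  haps <- do.call(cbind, hap_list)
  dos <- haps[seq(1, n_hap, by = 2), , drop = FALSE] +
    haps[seq(2, n_hap, by = 2), , drop = FALSE]
  new_genotype_panel(sprintf("s%03d", seq_len(config$n_samples)),
                     variants, dos, haps)
}

apply_sweep <- function(H, pos, config, n_hap) {
  sw <- config$sweep
  core <- sweep_core_index(config)
  n_car <- round(sw$derived_freq * n_hap)
  if (n_car < 2) abort("sweep needs >= 2 carrier haplotypes (f * 2n < 2)")
  carriers <- sample.int(n_hap, n_car)
  founder <- H[carriers[1], ]
  founder[core] <- 1L
  rho <- sw$recomb_rate_per_bp; mu <- sw$mutation_rate_per_site
  for (h in carriers) {
    d_left <- stats::rexp(1, rho); d_right <- stats::rexp(1, rho)
    span <- pos >= pos[core] - d_left & pos <= pos[core] + d_right
    copied <- founder[span]
    flip <- stats::runif(length(copied)) < mu
    H[h, span] <- ifelse(flip, 1L - copied, copied)
    H[h, core] <- 1L
  }
  H[-carriers, core] <- 0L
  H
}

#' Tile a synthetic gene annotation across the simulated genome
#'
#' Genes are non-overlapping: each chromosome is split into equal windows and
#' a gene occupies the central 80% of its window, so most uniformly placed
#' variants fall inside a gene.
#'
#' @param config A [sim_config()].
#' @return Annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @export
simulate_annotation <- function(config) {
  per_chrom <- ceiling(config$n_genes / config$n_chrom)
  rows <- list()
  g <- 0L
  for (ci in seq_len(config$n_chrom)) {
    k <- min(per_chrom, config$n_genes - g)
    if (k <= 0) break
    win <- config$chrom_length_bp / k
    i <- seq_len(k)
    rows[[ci]] <- tibble(
      gene_id = sprintf("g%04d", g + i),
      chrom = as.character(ci),
      start = as.integer(floor((i - 1) * win + 0.1 * win)) + 1L,
      end = as.integer(floor((i - 1) * win + 0.9 * win)))
    g <- g + k
  }
  dplyr::bind_rows(rows)
}

#' Simulate GWAS summary statistics with planted trait genes
#'
#' SNPs inside planted genes receive two-sided p-values from
#' z ~ Normal(`alt_effect`, 1); all other SNPs are null with p ~ Uniform(0,1).
#'
#' @param config A [sim_config()] (uses `alt_effect` and the seed).
#' @param panel Panel from [simulate_panel()].
#' @param annotation Annotation tibble.
#' @param planted_genes Character vector of trait genes; defaults to
#'   `config$planted_genes`.
#' @return Variant tibble in the [read_summary_stats()] shape (`ihs` is `NA`;
#'   scores come from [ihs_score()]).
#' @export
simulate_summary_stats <- function(config, panel, annotation,
                                   planted_genes = config$planted_genes) {
  set.seed(derive_seed(config$seed, 2L))
  v <- panel$variants
  p <- stats::runif(nrow(v))
  if (length(planted_genes) > 0) {
    gmap <- map_snps_to_genes(v, annotation, flank_bp = 0)
    hit <- unique(gmap$variant_id[gmap$gene_id %in% planted_genes])
    idx <- match(hit, v$variant_id)
    z <- stats::rnorm(length(idx), mean = config$alt_effect, sd = 1)
    p[idx] <- 2 * stats::pnorm(-abs(z))
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  tibble(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
         ref_allele = v$ref_allele, alt_allele = v$alt_allele,
         p_gwas = p, ihs = NA_real_)
}

#' Simulate a scale-free protein-interaction network with a planted module
#'
#' Background topology is a preferential-attachment graph (`ppi_m` attachment
#' edges per node, vertex names assigned by a random permutation of the gene
#' universe); the planted module is additionally wired as Erdos-Renyi(`q_in`)
#' among its members.
#'
#' @param config A [sim_config()].
#' @param gene_universe Character vector of gene ids (typically
#'   `annotation$gene_id`).
#' @param planted_module Gene subset to wire densely.
#' @return An undirected simple `igraph` graph.
#' @export
simulate_ppi <- function(config, gene_universe,
                         planted_module = config$planted_module) {
  set.seed(derive_seed(config$seed, 3L))
  n <- length(gene_universe)
  g <- igraph::sample_pa(n, m = config$ppi_m, directed = FALSE)
  igraph::V(g)$name <- sample(gene_universe)
  if (length(planted_module) > 1) {
    stopifnot(all(planted_module %in% gene_universe))
    pairs <- utils::combn(planted_module, 2)
    keep <- stats::runif(ncol(pairs)) < config$q_in
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
    }
  }
  igraph::simplify(g)
}

#' Plant cross-locus genotype dependence (epistasis truth)
#'
#' For each planted pair, variant b's dosage is replaced per sample by
#' variant a's dosage with probability 1 - eps, else by a fresh
#' Hardy-Weinberg draw at b's allele frequency. Haplotypes (if present) are
#' rewritten at b so the two alleles per sample still sum to the dosage.
#' Pairs must be long-distance (different chromosomes or >= 10 Mb apart);
#' closer pairs are rejected because the screen never tests them.
#'
#' @param panel A `genotype_panel`.
#' @param planted_pairs Tibble with columns `variant_a`, `variant_b`, `eps`.
#' @param seed Integer seed.
#' @return The modified `genotype_panel`.
#' @export
plant_epistasis <- function(panel, planted_pairs, seed = 1L) {
  if (is.null(planted_pairs) || nrow(planted_pairs) == 0) return(panel)
  set.seed(derive_seed(seed, 4L))
  v <- panel$variants
  n <- length(panel$samples)
  for (i in seq_len(nrow(planted_pairs))) {
    a <- planted_pairs$variant_a[i]; b <- planted_pairs$variant_b[i]
    eps <- planted_pairs$eps[i]
    ia <- match(a, v$variant_id); ib <- match(b, v$variant_id)
    if (is.na(ia) || is.na(ib)) abort(sprintf("planted pair variant not in panel: %s/%s", a, b))
    if (v$chrom[ia] == v$chrom[ib] && abs(v$pos[ia] - v$pos[ib]) < 1e7) {
      abort(sprintf("planted pair %s-%s is same-chromosome and < 10 Mb apart; the long-distance screen would never test it", a, b))
    }
    freq_b <- mean(panel$dosages[, ib]) / 2
    copy <- stats::runif(n) >= eps
    fresh <- stats::rbinom(n, 2L, freq_b)
    newdos <- ifelse(copy, panel$dosages[, ia], fresh)
    panel$dosages[, ib] <- newdos
    if (!is.null(panel$haplotypes)) {
      h1 <- as.integer(newdos >= 1); h2 <- as.integer(newdos == 2)
      swap <- newdos == 1L & stats::runif(n) < 0.5
      tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
      panel$haplotypes[seq(1, 2 * n, by = 2), ib] <- h1
      panel$haplotypes[seq(2, 2 * n, by = 2), ib] <- h2
    }
  }
  panel
}

#' Simulate a complete input bundle with planted truth
#'
#' Runs every generator, auto-selecting planted trait genes among genes that
#' hold at least one iHS-screened variant and planted epistatic pairs among
#' screened, nominally associated variants in different planted genes, so
#' that planted signal is visible to every later pipeline stage. The iHS
#' table is recomputed after epistasis planting so the bundle is internally
#' consistent (planting rewrites haplotypes at the dependent variant, which
#' can move that variant's own iHS; the truth manifest records the screen
#' status of every planted pair member).
#'
#' @param config A [sim_config()].
#' @param ihs_threshold Screening threshold used for auto-selection.
#' @return A list: `panel`, `annotation`, `summary_stats`, `ihs`, `ppi`,
#'   `gene_sets`, `truth` (planted genes, module, pairs, sweep core).
#' @export
simulate_bundle <- function(config, ihs_threshold = 1.5) {
  panel <- simulate_panel(config)
  annotation <- simulate_annotation(config)
  ihs0 <- ihs_score(panel)
  screened0 <- ihs0$variant_id[!is.na(ihs0$ihs) & abs(ihs0$ihs) > ihs_threshold]

  set.seed(derive_seed(config$seed, 5L))
  planted_genes <- config$planted_genes
  if (is.null(planted_genes) && config$n_planted_genes > 0) {
    gmap <- map_snps_to_genes(panel$variants, annotation, flank_bp = 0)
    with_screen <- sort(unique(gmap$gene_id[gmap$variant_id %in% screened0]))
    planted_genes <- sample(with_screen,
                            min(config$n_planted_genes, length(with_screen)))
  }
  planted_module <- config$planted_module %||% planted_genes

  summary_stats <- simulate_summary_stats(config, panel, annotation,
                                          planted_genes = planted_genes)

  pairs <- config$planted_pairs
  if (is.null(pairs) && config$n_planted_pairs > 0 && length(planted_genes) > 1) {
    gmap <- map_snps_to_genes(panel$variants, annotation, flank_bp = 0)
    cand <- gmap[gmap$gene_id %in% planted_genes &
                   gmap$variant_id %in% screened0, ]
    cand <- dplyr::distinct(cand, .data$variant_id, .keep_all = TRUE)
    sel <- auto_plant_pairs(panel, cand, ihs0, config, ihs_threshold)
    panel <- sel$panel
    pairs <- sel$pairs
  } else if (!is.null(pairs) && nrow(pairs) > 0) {
    panel <- plant_epistasis(panel, pairs, seed = config$seed)
  }
  ihs <- ihs_score(panel)
  screened <- ihs$variant_id[!is.na(ihs$ihs) & abs(ihs$ihs) > ihs_threshold]
  summary_stats$ihs <- ihs$ihs[match(summary_stats$variant_id, ihs$variant_id)]

  ppi <- simulate_ppi(config, annotation$gene_id, planted_module = planted_module)
  gene_sets <- simulate_gene_sets(config, annotation$gene_id, planted_genes)

  truth <- list(
    planted_genes = planted_genes %||% character(),
    planted_module = planted_module %||% character(),
    planted_pairs = if (is.null(pairs)) tibble(variant_a = character(),
                                               variant_b = character(),
                                               eps = numeric())
                    else dplyr::mutate(pairs,
                           a_screened = .data$variant_a %in% screened,
                           b_screened = .data$variant_b %in% screened),
    sweep_core = if (is.null(config$sweep)) NA_character_ else
      sprintf("snp_%s_%03d", norm_chrom(config$sweep$chrom),
              sweep_core_index(config)),
    true_term = if (length(planted_genes %||% character()) > 0) "term_true" else NA_character_)

  list(panel = panel, annotation = annotation, summary_stats = summary_stats,
       ihs = ihs, ppi = ppi, gene_sets = gene_sets, truth = truth)
}

# Auto-select and plant epistatic pairs so that the dependent variant b
# still passes the |iHS| screen after planting (planting rewrites b's
# haplotypes, which perturbs b's own haplotype-homozygosity signal).
# Candidate b's are tried in random order; b's post-planting score is
# re-standardized against the pre-planting bin statistics.
auto_plant_pairs <- function(panel, cand, ihs0, config, ihs_threshold,
                             max_tries = 20L) {
  if (nrow(cand) < 2) return(list(panel = panel, pairs = NULL))
  binref <- ihs_bin_stats(ihs0)
  eps <- config$copy_error
  out <- list(); used <- character()
  for (k in seq_len(config$n_planted_pairs)) {
    avail <- cand[!cand$variant_id %in% used, ]
    if (length(unique(avail$gene_id)) < 2) break
    ga <- sample(unique(avail$gene_id), 1)
    a <- avail[avail$gene_id == ga, ][1, ]
    rest <- avail[avail$gene_id != ga, ]
    av <- panel$variants[match(a$variant_id, panel$variants$variant_id), ]
    rv <- panel$variants[match(rest$variant_id, panel$variants$variant_id), ]
    rest <- rest[rv$chrom != av$chrom | abs(rv$pos - av$pos) >= 1e7, ]
    if (nrow(rest) == 0) next
    rest <- rest[sample.int(nrow(rest)), ]
    for (t in seq_len(min(nrow(rest), max_tries))) {
      b <- rest[t, ]
      pr <- tibble(variant_a = a$variant_id, variant_b = b$variant_id,
                   eps = eps)
      trial <- plant_epistasis(panel, pr,
                               seed = derive_seed(config$seed, 100L + 37L * k + t))
      std <- standardized_ihs_single(trial, b$variant_id, binref)
      if (!is.na(std) && abs(std) > ihs_threshold) {
        panel <- trial
        out[[length(out) + 1]] <- pr
        used <- c(used, a$variant_id, b$variant_id)
        break
      }
    }
  }
  list(panel = panel,
       pairs = if (length(out) == 0) NULL else dplyr::bind_rows(out))
}

# per-bin mean/sd of unstandardized iHS (frozen reference for cheap
# single-variant re-standardization)
ihs_bin_stats <- function(ihs_tbl, n_bins = 20L) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(ihs_tbl$derived_freq, breaks, include.lowest = TRUE)
  ok <- !is.na(ihs_tbl$ihs_unstandardized)
  list(breaks = breaks,
       mean = tapply(ihs_tbl$ihs_unstandardized[ok], bin[ok], mean),
       sd = tapply(ihs_tbl$ihs_unstandardized[ok], bin[ok], stats::sd),
       n = tapply(ihs_tbl$ihs_unstandardized[ok], bin[ok], length),
       levels = levels(bin))
}

standardized_ihs_single <- function(panel, variant_id, binref) {
  v <- panel$variants
  i <- match(variant_id, v$variant_id)
  cols <- which(v$chrom == v$chrom[i])
  Hc <- panel$haplotypes[, cols, drop = FALSE]
  j <- match(i, cols)
  one <- ihs_one(Hc, j, v$pos[cols])
  if (is.null(one) || is.na(one$unstandardized)) return(NA_real_)
  freq <- mean(Hc[, j])
  b <- as.character(cut(freq, binref$breaks, include.lowest = TRUE))
  m <- binref$mean[b]; s <- binref$sd[b]; n <- binref$n[b]
  if (is.na(m) || is.na(s) || s == 0 || n < 3) return(NA_real_)
  (one$unstandardized - m) / s
}

simulate_gene_sets <- function(config, gene_universe, planted_genes) {
  set.seed(derive_seed(config$seed, 6L))
  terms <- list(); ids <- character(); desc <- character()
  if (length(planted_genes %||% character()) > 0) {
    terms <- list(unique(planted_genes))
    ids <- "term_true"; desc <- "planted adaptation term"
  }
  for (i in seq_len(config$n_background_terms)) {
    sz <- sample(10:30, 1)
    terms[[length(terms) + 1]] <- sample(gene_universe, sz)
    ids <- c(ids, sprintf("term_bg%03d", i))
    desc <- c(desc, "random background term")
  }
  tibble(term_id = ids, description = desc, genes = terms)
}

#' Write a complete fixture bundle to disk
#'
#' Emits a phased VCF, summary-statistics TSV, iHS TSV, BED annotation, PPI
#' edge list, GMT gene sets and a JSON truth manifest, in exactly the
#' dialects the package's readers consume.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  b <- simulate_bundle(config)
  paths <- c(
    vcf = file.path(out_dir, "panel.vcf"),
    summary = file.path(out_dir, "summary_stats.tsv"),
    ihs = file.path(out_dir, "ihs.tsv"),
    bed = file.path(out_dir, "genes.bed"),
    ppi = file.path(out_dir, "ppi_edges.tsv"),
    gmt = file.path(out_dir, "terms.gmt"),
    truth = file.path(out_dir, "truth.json"))
  write_genotypes_vcf(b$panel, paths[["vcf"]])
  write_table(b$summary_stats, paths[["summary"]])
  write_table(b$ihs[, c("variant_id", "derived_freq", "ihs")], paths[["ihs"]])
  write_gene_bed(b$annotation, paths[["bed"]])
  write_ppi_edges(b$ppi, paths[["ppi"]])
  write_gmt(b$gene_sets, paths[["gmt"]])
  jsonlite::write_json(b$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
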