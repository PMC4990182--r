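#' Pipeline configuration
#'
#' One configuration object per trait/sub-phenotype analysis, holding the
#' input paths and every tunable threshold. The defaults are the screen's
#' canonical settings: |iHS| > 1.5, 0 bp gene flank, adaptive gene-test
#' simulations, module growth r = 0.1 with the top 10 modules, r-squared
#' pruning at 0.8, a 10 Mb long-range floor, nominal alpha 0.05, 10,000 LD
#' permutations, q < 0.05 significance and enrichment min overlap 2.
#'
#' @param summary_stats,genotypes_vcf,ihs_table,gene_bed,ppi_edges,gmt Input
#'   file paths (`ihs_table` may be `NULL` when the VCF is phased, in which
#'   case iHS is computed from the haplotypes).
#' @param label Analysis label (trait/sub-phenotype) carried into outputs.
#' @param ihs_threshold,flank_bp,gene_test_sims,module_r,n_top,module_n_perm
#'   Stage parameters (see module-level functions).
#' @param r2_prune,long_range_mb,nominal_alpha,ld_n_perm,q_threshold
#'   Epistasis-screen parameters.
#' @param min_overlap Enrichment minimum overlap.
#' @param match_by Join key between summary statistics and the iHS table:
#'   `"id"` (rsID; default) or `"position"` (chrom + pos).
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(summary_stats, genotypes_vcf, ihs_table = NULL,
                            gene_bed, ppi_edges, gmt, label = "trait",
                            ihs_threshold = 1.5, flank_bp = 0,
                            gene_test_sims = 1e6, module_r = 0.1,
                            n_top = 10L, module_n_perm = 1e5,
                            r2_prune = 0.8, long_range_mb = 10,
                            nominal_alpha = 0.05, ld_n_perm = 1e4,
                            q_threshold = 0.05, min_overlap = 2L,
                            match_by = c("id", "position"), seed = 1L) {
  match_by <- match.arg(match_by)
  stopifnot(ihs_threshold > 0, flank_bp >= 0, gene_test_sims >= 1000,
            module_r >= 0, n_top >= 1, r2_prune > 0, r2_prune <= 1,
            long_range_mb > 0, nominal_alpha > 0, nominal_alpha < 1,
            ld_n_perm >= 1000, q_threshold > 0, q_threshold < 1,
            min_overlap >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_abort <- function(stage, parent) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage,
                conditionMessage(parent)),
        class = c(paste0("polyadapt_stage_", stage), "polyadapt_stage_error"))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "polyadapt_stage_error")) stop(e)
    stage_abort(stage, e)
  })
}

#' Run the full polygenic-adaptation pipeline
#'
#' Executes, for one trait/sub-phenotype input bundle: the |iHS| selection
#' screen, the Monte-Carlo gene-based association test, the dense-module
#' search, the long-distance genotypic-LD epistasis screen with q-value FDR
#' control, the adaptation gene-set construction and the term-enrichment
#' analysis. Per-stage tables, the gene-set graph and a run manifest are
#' written to `out_dir`; the run is a pure function of (inputs, config,
#' seed).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return A `polyadapt_run` object: list with `screened`, `gene_scores`,
#'   `modules`, `ld`, `gene_set` (igraph), `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  inputs <- run_stage("read_inputs", {
    panel <- read_genotypes_vcf(config$genotypes_vcf)
    ss <- read_summary_stats(config$summary_stats)
    list(panel = panel, summary_stats = ss,
         annotation = read_gene_bed(config$gene_bed),
         ppi = read_ppi_edges(config$ppi_edges),
         gene_sets = read_gmt(config$gmt))
  })

  screened <- run_stage("selection_screen", {
    ss <- inputs$summary_stats
    if (!is.null(config$ihs_table)) {
      it <- read_ihs_table(config$ihs_table)
      if (config$match_by == "id") {
        ss$ihs <- it$ihs[match(ss$variant_id, it$variant_id)]
      } else {
        # match through the panel's (chrom, pos) -> id map: the iHS table's
        # ids refer to panel variants
        pv <- inputs$panel$variants
        pid <- pv$variant_id[match(paste(ss$chrom, ss$pos),
                                   paste(pv$chrom, pv$pos))]
        ss$ihs <- it$ihs[match(pid, it$variant_id)]
      }
    } else if (all(is.na(ss$ihs))) {
      if (is.null(inputs$panel$haplotypes)) {
        abort("no iHS table and the panel is unphased: cannot screen")
      }
      sc <- ihs_score(inputs$panel)
      ss$ihs <- sc$ihs[match(ss$variant_id, sc$variant_id)]
    }
    filter_by_ihs(ss, config$ihs_threshold)
  })

  gene_scores <- run_stage("gene_association", {
    gene_assoc(screened, inputs$annotation, inputs$panel,
               flank_bp = config$flank_bp, n_sims = config$gene_test_sims,
               seed = derive_seed(config$seed, 20L))
  })

  modules <- run_stage("network_modules", {
    if (nrow(gene_scores) == 0 ||
        length(intersect(gene_scores$gene_id, igraph::V(inputs$ppi)$name)) == 0) {
      NULL
    } else {
      search_and_select(inputs$ppi, gene_scores, r = config$module_r,
                        n_top = config$n_top, n_perm = config$module_n_perm,
                        seed = derive_seed(config$seed, 30L))
    }
  })

  ld <- run_stage("epistasis_ld", {
    if (is.null(modules)) {
      NULL
    } else {
      gmap <- map_snps_to_genes(screened, inputs$annotation,
                                flank_bp = config$flank_bp)
      gmap <- gmap[gmap$gene_id %in% modules$network_genes, ]
      net_variants <- screened[screened$variant_id %in% gmap$variant_id, ]
      ld_scan(net_variants, gmap, inputs$panel,
              r2_threshold = config$r2_prune,
              nominal_alpha = config$nominal_alpha,
              min_distance_bp = config$long_range_mb * 1e6,
              q_threshold = config$q_threshold,
              n_perm = config$ld_n_perm,
              seed = derive_seed(config$seed, 40L))
    }
  })

  sig <- if (is.null(ld)) empty_pairs() else ld$significant
  gene_set <- run_stage("gene_set", {
    build_adaptation_gene_set(sig, inputs$ppi, gene_scores,
                              label = config$label)
  })

  enrichment <- run_stage("enrichment", {
    bg <- intersect(inputs$annotation$gene_id,
                    unique(unlist(inputs$gene_sets$genes)))
    enrich_gene_set(igraph::V(gene_set)$name, inputs$gene_sets, bg,
                    min_overlap = config$min_overlap)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("polyadapt")),
    label = config$label, seed = config$seed,
    config = config[!vapply(config, is.null, TRUE)],
    counts = list(
      n_variants_input = nrow(inputs$summary_stats),
      n_variants_screened = nrow(screened),
      n_genes_scored = nrow(gene_scores),
      n_modules = if (is.null(modules)) 0L else nrow(modules$modules),
      n_genes_network = if (is.null(modules)) 0L else
        length(modules$network_genes),
      n_pruned_variants = if (is.null(ld)) 0L else nrow(ld$pruned_variants),
      n_tested_pairs = if (is.null(ld)) 0L else nrow(ld$pairs),
      n_significant_pairs = nrow(sig),
      n_gene_set_genes = length(igraph::V(gene_set)),
      n_enriched_terms = sum(enrichment$p_bonferroni < 0.05)))

  res <- structure(list(screened = screened, gene_scores = gene_scores,
                        modules = modules, ld = ld, gene_set = gene_set,
                        enrichment = enrichment, manifest = manifest),
                   class = "polyadapt_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(res$screened, file.path(out_dir, "screened_variants.tsv"))
  write_table(res$gene_scores, file.path(out_dir, "gene_scores.tsv"))
  if (!is.null(res$modules)) {
    write_table(res$modules$modules, file.path(out_dir, "modules.tsv"))
    writeLines(res$modules$network_genes,
               file.path(out_dir, "network_genes.txt"))
  }
  if (!is.null(res$ld)) {
    write_table(res$ld$pairs, file.path(out_dir, "ld_pairs.tsv"))
    write_table(res$ld$significant,
                file.path(out_dir, "significant_pairs.tsv"))
  }
  el <- igraph::as_edgelist(res$gene_set)
  ev <- if (igraph::ecount(res$gene_set) > 0)
    igraph::E(res$gene_set)$evidence else character()
  write_table(tibble(gene_a = el[, 1], gene_b = el[, 2], evidence = ev),
              file.path(out_dir, "gene_set_edges.tsv"))
  write_table(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.polyadapt_run <- function(x, ...) {
  co <- x$manifest$counts
  cat("<polyadapt_run>", x$manifest$label, "\n")
  cat(sprintf("  screened variants : %d / %d\n", co$n_variants_screened,
              co$n_variants_input))
  cat(sprintf("  scored genes      : %d\n", co$n_genes_scored))
  cat(sprintf("  trait network     : %d genes (top %d modules)\n",
              co$n_genes_network, if (is.null(x$modules)) 0L else
                sum(x$modules$modules$selected)))
  cat(sprintf("  pruned variants   : %d\n", co$n_pruned_variants))
  cat(sprintf("  LD pairs          : %d tested, %d significant\n",
              co$n_tested_pairs, co$n_significant_pairs))
  cat(sprintf("  gene set          : %d genes; %d enriched term(s)\n",
              co$n_gene_set_genes, co$n_enriched_terms))
  invisible(x)
}
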