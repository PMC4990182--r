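#' Read GWAS summary statistics
#'
#' Parses a tab- or whitespace-delimited per-variant summary-statistics table.
#' Column names are configurable via `cols`; the defaults expect
#' `variant_id`, `chrom`, `pos`, `p_gwas` and optionally `ref`, `alt`, `ihs`.
#' Rows with p-values outside the half-open interval (0, 1] or non-numeric
#' fields are rejected with a warning that reports the offending line numbers.
#'
#' @param path Path to the summary-statistics file (header required).
#' @param cols Named list mapping internal field names (`id`, `chrom`, `pos`,
#'   `p`, and optionally `ref`, `alt`, `ihs`) to column names in the file.
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `p_gwas`, `ihs`, sorted by `(chrom, pos)`. Missing iHS is
#'   `NA` and is tolerated until the selection screen.
#' @export
read_summary_stats <- function(path,
                               cols = list(id = "variant_id", chrom = "chrom",
                                           pos = "pos", p = "p_gwas",
                                           ref = "ref_allele", alt = "alt_allele",
                                           ihs = "ihs")) {
  raw <- read_any_delim(path)
  for (req in c("id", "chrom", "pos", "p")) {
    nm <- cols[[req]]
    if (is.null(nm) || !nm %in% names(raw)) {
      abort(sprintf("summary-statistics file lacks required column '%s'",
                    cols[[req]] %||% req), class = "polyadapt_format_error")
    }
  }
  out <- tibble(
    variant_id = as.character(raw[[cols$id]]),
    chrom      = norm_chrom(raw[[cols$chrom]]),
    pos        = suppressWarnings(as.integer(raw[[cols$pos]])),
    ref_allele = opt_col(raw, cols$ref, NA_character_),
    alt_allele = opt_col(raw, cols$alt, NA_character_),
    p_gwas     = suppressWarnings(as.numeric(raw[[cols$p]])),
    ihs        = suppressWarnings(as.numeric(opt_col(raw, cols$ihs, NA_character_)))
  )
  line <- seq_len(nrow(out)) + 1L  # header is line 1
  bad_pos <- is.na(out$pos) | out$pos < 1L
  bad_p <- is.na(out$p_gwas) | out$p_gwas <= 0 | out$p_gwas > 1
  bad <- bad_pos | bad_p
  if (any(bad)) {
    warn(sprintf(
      "rejected %d row(s) with invalid pos or p (must have pos >= 1, 0 < p <= 1); lines: %s",
      sum(bad), paste(utils::head(line[bad], 10), collapse = ", ")))
    out <- out[!bad, ]
  }
  if (anyDuplicated(out$variant_id)) {
    abort("duplicate variant_id in summary statistics",
          class = "polyadapt_format_error")
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

opt_col <- function(raw, nm, default) {
  if (!is.null(nm) && nm %in% names(raw)) as.character(raw[[nm]]) else default
}

read_any_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) abort("empty file", class = "polyadapt_format_error")
  if (grepl("\t", first)) {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
  } else {
    readr::read_table(path, col_types = readr::cols(.default = "c"),
                      progress = FALSE, show_col_types = FALSE)
  }
}

#' Read a genotype reference panel from VCF
#'
#' Ingests a VCF (v4.x) using only the GT field. Only biallelic SNPs are
#' retained; multiallelic or indel records are skipped with a logged count.
#' Dosage is the count of ALT alleles per sample. If every genotype in the
#' file is phased (`|` separator), a haplotype matrix is populated alongside
#' the dosages; otherwise haplotypes are absent.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @return A `genotype_panel` object: list with `samples` (character),
#'   `variants` (tibble: variant_id, chrom, pos, ref_allele, alt_allele),
#'   `dosages` (n_samples x n_variants integer matrix, NA for missing) and
#'   `haplotypes` (2 n_samples x n_variants 0/1 matrix or NULL).
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ok <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$REF %in% c("A", "C", "G", "T")
  ok[is.na(ok)] <- FALSE
  count_warn(sum(!ok), "non-biallelic-SNP record(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(gt), dimnames = list(names(gt), NULL))
  gt <- gt[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  samples <- colnames(gt)

  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  sep_ok <- substr(gt, 2, 2) %in% c("|", "/")
  bad_gt <- !sep_ok | is.na(a1) | is.na(a2) | a1 > 1 | a2 > 1
  a1[bad_gt] <- NA_integer_; a2[bad_gt] <- NA_integer_
  dos <- matrix(a1 + a2, nrow = nrow(gt))  # variants x samples

  all_missing <- rowSums(!is.na(dos)) == 0
  count_warn(sum(all_missing), "all-missing variant(s) dropped")
  keep <- !all_missing
  dos <- dos[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  a1 <- matrix(a1, nrow = length(all_missing))[keep, , drop = FALSE]
  a2 <- matrix(a2, nrow = length(all_missing))[keep, , drop = FALSE]

  variants <- tibble(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = norm_chrom(fix$CHROM),
    pos = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT
  )

  haps <- NULL
  if (nrow(gt) > 0 && all(substr(gt, 2, 2) == "|", na.rm = TRUE) && !anyNA(dos)) {
    # rows = haplotypes interleaved per sample (sample1.a, sample1.b, ...)
    haps <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(variants))
    haps[seq(1, by = 2, length.out = length(samples)), ] <- t(a1)
    haps[seq(2, by = 2, length.out = length(samples)), ] <- t(a2)
  }

  new_genotype_panel(samples, variants, t(dos), haps)
}

new_genotype_panel <- function(samples, variants, dosages, haplotypes = NULL) {
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  dosages <- dosages[, ord, drop = FALSE]
  if (!is.null(haplotypes)) haplotypes <- haplotypes[, ord, drop = FALSE]
  dimnames(dosages) <- list(samples, variants$variant_id)
  if (!is.null(haplotypes)) colnames(haplotypes) <- variants$variant_id
  structure(list(samples = samples, variants = variants,
                 dosages = dosages, haplotypes = haplotypes),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants (%s haplotypes)\n",
              length(x$samples), nrow(x$variants),
              if (is.null(x$haplotypes)) "no" else "phased"))
  invisible(x)
}

#' Read an undirected protein-interaction edge list
#'
#' Two whitespace- or tab-separated gene identifiers per line (no header, or a
#' header starting with `#`). Self-loops and duplicate undirected edges are
#' dropped with logged counts.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph` graph whose vertex names are gene ids.
#' @export
read_ppi_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- lengths(parts) < 2
  if (any(bad)) abort(sprintf("edge list line(s) with < 2 fields: %d", sum(bad)),
                      class = "polyadapt_format_error")
  edges <- do.call(rbind, lapply(parts, function(p) p[1:2]))
  loops <- edges[, 1] == edges[, 2]
  count_warn(sum(loops), "self-loop(s) dropped from PPI edge list")
  edges <- edges[!loops, , drop = FALSE]
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  count_warn(sum(duplicated(key)), "duplicate edge(s) dropped from PPI edge list")
  edges <- edges[!duplicated(key), , drop = FALSE]
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Write a PPI network as an edge list
#' @param network An `igraph` graph.
#' @param path Output path.
#' @export
write_ppi_edges <- function(network, path) {
  el <- igraph::as_edgelist(network)
  readr::write_tsv(tibble(gene_a = el[, 1], gene_b = el[, 2]), path,
                   col_names = FALSE)
  invisible(path)
}

#' Read gene annotations from BED
#'
#' BED intervals (0-based half-open on disk) are converted to the package's
#' 1-based inclusive convention: `start = start0 + 1`, `end = end0`.
#'
#' @param path Path to a BED file with at least 4 columns
#'   (chrom, start, end, gene id).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 4) abort("BED file needs >= 4 columns (chrom,start,end,name)",
                           class = "polyadapt_format_error")
  start0 <- as.integer(raw$X2); end0 <- as.integer(raw$X3)
  if (anyNA(start0) || anyNA(end0) || any(start0 >= end0)) {
    abort("BED intervals must satisfy start < end (0-based half-open)",
          class = "polyadapt_format_error")
  }
  out <- tibble(gene_id = as.character(raw$X4), chrom = norm_chrom(raw$X1),
                start = start0 + 1L, end = end0)
  if (anyDuplicated(out$gene_id)) abort("duplicate gene_id in BED",
                                        class = "polyadapt_format_error")
  out
}

#' Write gene annotations to BED (1-based inclusive -> 0-based half-open)
#' @param annotation Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_gene_bed <- function(annotation, path) {
  readr::write_tsv(tibble(annotation$chrom, annotation$start - 1L,
                          annotation$end, annotation$gene_id),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then tab-separated gene ids.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `description` and list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  parts <- parts[lengths(parts) > 0]
  if (any(lengths(parts) < 3)) {
    abort("GMT term with no genes", class = "polyadapt_format_error")
  }
  out <- tibble(
    term_id = vapply(parts, `[[`, "", 1L),
    description = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (any(lengths(out$genes) < 1)) abort("GMT term with no genes",
                                         class = "polyadapt_format_error")
  out
}

#' Write gene sets in GMT format
#' @param gene_sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(c(gene_sets$term_id[i], gene_sets$description[i],
            gene_sets$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular result as TSV with a header
#' @param records A data frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  listcols <- vapply(df, is.list, TRUE)
  df[listcols] <- lapply(df[listcols], vapply, paste, "", collapse = ",")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an iHS score table
#'
#' Tab-delimited with header columns `variant_id`, `derived_freq`, `ihs`.
#' @param path Path to the table.
#' @return Tibble with those columns.
#' @export
read_ihs_table <- function(path) {
  raw <- read_any_delim(path)
  for (nm in c("variant_id", "ihs")) {
    if (!nm %in% names(raw)) abort(sprintf("iHS table lacks column '%s'", nm),
                                   class = "polyadapt_format_error")
  }
  tibble(variant_id = as.character(raw$variant_id),
         derived_freq = if ("derived_freq" %in% names(raw))
           as.numeric(raw$derived_freq) else NA_real_,
         ihs = suppressWarnings(as.numeric(raw$ihs)))
}

# minimal phased/unphased VCF v4.2 text writer for fixture bundles
write_genotypes_vcf <- function(panel, path) {
  v <- panel$variants
  n <- length(panel$samples)
  gt <- if (!is.null(panel$haplotypes)) {
    a1 <- t(panel$haplotypes[seq(1, by = 2, length.out = n), , drop = FALSE])
    a2 <- t(panel$haplotypes[seq(2, by = 2, length.out = n), , drop = FALSE])
    matrix(paste0(a1, "|", a2), nrow = nrow(v))
  } else {
    d <- t(panel$dosages)
    out <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id,
                ifelse(is.na(v$ref_allele), "A", v$ref_allele),
                ifelse(is.na(v$alt_allele), "G", v$alt_allele),
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
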