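# Independent oracles and small fixture builders used across tests.

# brute-force EHH: count identical haplotype pairs over the span directly
brute_ehh <- function(haps, core, target) {
  span <- seq(min(core, target), max(core, target))
  n <- nrow(haps)
  idpairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (all(haps[i, span] == haps[j, span])) idpairs <- idpairs + 1L
    }
  }
  idpairs / (n * (n - 1) / 2)
}

# independent straight-line trapezoid integrator with the truncation rule:
# stop at (and include) the first point below the cutoff
trapezoid_oracle <- function(dist, e, cutoff = 0.05) {
  stop_at <- length(dist)
  below <- which(e < cutoff)
  if (length(below) > 0) stop_at <- below[1]
  total <- 0
  for (i in seq_len(stop_at - 1)) {
    total <- total + (dist[i + 1] - dist[i]) * (e[i] + e[i + 1]) / 2
  }
  total
}

# closed-form upper-tail hypergeometric via binomial coefficients
hyper_oracle <- function(N, K, n, a) {
  sum(vapply(a:min(n, K), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, 0))
}

# construct a genotype_panel directly from a dosage matrix
make_panel <- function(dosages, chrom = NULL, pos = NULL, haplotypes = NULL) {
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  ids <- colnames(dosages)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  variants <- tibble::tibble(variant_id = ids, chrom = as.character(chrom),
                             pos = as.integer(pos),
                             ref_allele = "A", alt_allele = "G")
  polyadapt:::new_genotype_panel(sprintf("s%03d", seq_len(nrow(dosages))),
                                 variants, unname(dosages), haplotypes)
}

# random small haplotype panel for oracle-equivalence checks
random_hap_matrix <- function(n_hap, n_site) {
  matrix(sample(0:1, n_hap * n_site, replace = TRUE), nrow = n_hap)
}

# tiny star-free toy graph from an edge list given as c("A","B", "B","C", ...)
toy_graph <- function(edges) {
  igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                              directed = FALSE)
}
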