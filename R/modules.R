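#' Module score
#'
#' `Z_m = sum(z_i) / sqrt(k)` for a module of k gene weights.
#'
#' @param weights Numeric gene weights (length >= 1).
#' @return The module score.
#' @export
module_score <- function(weights) {
  stopifnot(length(weights) >= 1)
  sum(weights) / sqrt(length(weights))
}

#' Greedy dense-module growth from a seed gene
#'
#' Starting from the seed, repeatedly evaluates all scored candidate genes
#' within graph distance `d` of the current module (through scored genes for
#' d > 1, attached together with their connecting path), adds the candidate
#' maximizing the new score, and accepts only if
#' `Z_new > Z_current * (1 + r)`. Ties break deterministically by higher
#' weight then lexicographic gene id. Unscored interactors are invisible to
#' the search.
#'
#' @param network Undirected `igraph` PPI graph with named vertices.
#' @param weights Named numeric vector of gene weights (scored genes).
#' @param seed_gene Seed gene id (must be scored and on the network).
#' @param r Minimum proportional score improvement (default 0.1).
#' @param d Candidate neighborhood distance (default 1).
#' @return A `module` object: list with `seed_gene`, `genes` (insertion
#'   order), `z_m`, and the growth `trace` of accepted scores.
#' @export
grow_module <- function(network, weights, seed_gene, r = 0.1, d = 1L) {
  stopifnot(r >= 0, d >= 1)
  if (!seed_gene %in% names(weights)) abort("seed gene has no score")
  if (!seed_gene %in% igraph::V(network)$name) abort("seed gene not on network")
  ctx <- scored_graph(network, weights)
  grow_core(ctx, weights, seed_gene, r, d)
}

# induced subgraph over scored genes plus its adjacency list; computed once
# per search and shared across seeds
scored_graph <- function(network, weights) {
  scored <- intersect(igraph::V(network)$name, names(weights))
  sg <- igraph::induced_subgraph(network, scored)
  adj <- lapply(igraph::adjacent_vertices(sg, igraph::V(sg)), names)
  names(adj) <- igraph::V(sg)$name
  list(sg = sg, adj = adj)
}

grow_core <- function(ctx, weights, seed_gene, r, d) {
  sg <- ctx$sg; adj <- ctx$adj
  genes <- seed_gene
  z_cur <- module_score(weights[genes])
  trace <- z_cur
  repeat {
    if (d == 1L) {
      cand <- setdiff(unique(unlist(adj[genes], use.names = FALSE)), genes)
      additions <- as.list(cand)
    } else {
      dist <- igraph::distances(sg, v = genes)
      dmin <- apply(dist, 2, min)
      cand <- setdiff(colnames(dist)[is.finite(dmin) & dmin <= d], genes)
      additions <- lapply(cand, function(cc) {
        from <- genes[which.min(dist[, cc])]
        path <- names(igraph::shortest_paths(sg, from = from, to = cc)$vpath[[1]])
        setdiff(path, genes)
      })
    }
    if (length(additions) == 0) break
    z_new <- vapply(additions, function(add) {
      module_score(weights[c(genes, add)])
    }, 0)
    tip <- vapply(additions, function(add) add[length(add)], "")
    ord <- order(-z_new, -weights[tip], tip)
    best <- ord[1]
    if (z_new[best] > z_cur * (1 + r)) {
      genes <- c(genes, additions[[best]])
      z_cur <- z_new[best]
      trace <- c(trace, z_cur)
    } else break
  }
  structure(list(seed_gene = seed_gene, genes = genes, z_m = z_cur,
                 trace = trace),
            class = "module")
}

#' @export
print.module <- function(x, ...) {
  cat(sprintf("<module> seed %s: %d gene(s), Z_m = %.4f\n",
              x$seed_gene, length(x$genes), x$z_m))
  invisible(x)
}

# Null mean/sd of Z* over uniform random k-subsets of the scored-gene
# universe. Depends only on k, so callers cache per module size.
# Exhaustive enumeration replaces sampling when C(universe, k) <= max_exhaustive.
null_score_moments <- function(all_weights, k, n_perm = 1e5,
                               max_exhaustive = 1e4) {
  n <- length(all_weights)
  if (length(unique(all_weights)) < 2) abort("degenerate weight universe: < 2 distinct weights")
  if (k >= n) abort("module spans the whole scored universe: null score is degenerate")
  if (choose(n, k) <= max_exhaustive) {
    sums <- utils::combn(all_weights, k, sum)
  } else {
    stopifnot(n_perm >= 1000)
    sums <- subset_sums_cpp(all_weights, as.integer(k), as.integer(n_perm))
  }
  zs <- sums / sqrt(k)
  s <- stats::sd(zs)
  if (s == 0) abort("degenerate null score distribution (sd = 0)")
  list(mean = mean(zs), sd = s)
}

#' Permutation-normalized module score
#'
#' `Z_N = (Z_m - mean(Z*)) / sd(Z*)`, where `Z*` are module scores of
#' uniform random k-subsets of all scored genes (connectivity is not imposed
#' in the null). Exhaustive enumeration replaces sampling when
#' `C(universe, k) <= 10,000`; the standard deviation uses denominator n - 1.
#'
#' @param module A `module` object (or list with `genes` and `z_m`).
#' @param all_weights Named numeric vector over all scored genes.
#' @param n_perm Number of random subsets (default 1e5, min 1000).
#' @param seed Integer seed.
#' @return The normalized score `Z_N`.
#' @export
normalize_score <- function(module, all_weights, n_perm = 1e5, seed = 1L) {
  set.seed(derive_seed(seed, 8L))
  mom <- null_score_moments(all_weights, length(module$genes), n_perm)
  (module$z_m - mom$mean) / mom$sd
}

#' Search dense modules from every seed and select the top set
#'
#' Grows a module from every scored gene present on the network, removes
#' duplicate gene sets (first seed in sorted order wins), normalizes scores
#' against the random-set null (cached per module size), and ranks by `Z_N`
#' descending with ties broken by `Z_m` then seed id. The union of the genes
#' of the top `n_top` modules is the trait gene network.
#'
#' @param network Undirected `igraph` PPI graph.
#' @param gene_scores A `gene_assoc` tibble (or any tibble with `gene_id`
#'   and `z_weight`).
#' @param r Growth threshold (default 0.1).
#' @param n_top Number of modules to keep (default 10).
#' @param n_perm Null subsets per module size (default 1e5).
#' @param seed Integer seed.
#' @param d Candidate neighborhood distance (default 1).
#' @return A `module_search` object: list with `modules` (tibble: seed_gene,
#'   k, genes list-column, z_m, z_n, selected), `network_genes` (union of
#'   top-module genes) and `subgraph` (induced PPI subgraph).
#' @export
search_and_select <- function(network, gene_scores, r = 0.1, n_top = 10L,
                              n_perm = 1e5, seed = 1L, d = 1L) {
  stopifnot(n_top >= 1)
  weights <- stats::setNames(gene_scores$z_weight, gene_scores$gene_id)
  weights <- weights[!duplicated(names(weights))]
  seeds <- sort(intersect(names(weights), igraph::V(network)$name))
  if (length(seeds) == 0) abort("no scored genes present on the network")
  ctx <- scored_graph(network, weights)
  mods <- lapply(seeds, function(s) grow_core(ctx, weights, s, r = r, d = d))
  key <- vapply(mods, function(m) paste(sort(m$genes), collapse = "|"), "")
  mods <- mods[!duplicated(key)]

  ks <- vapply(mods, function(m) length(m$genes), 0L)
  mom_cache <- new.env(parent = emptyenv())
  z_n <- vapply(seq_along(mods), function(i) {
    kk <- as.character(ks[i])
    if (is.null(mom_cache[[kk]])) {
      set.seed(derive_seed(seed, 8L + ks[i]))
      mom_cache[[kk]] <- null_score_moments(weights, ks[i], n_perm)
    }
    (mods[[i]]$z_m - mom_cache[[kk]]$mean) / mom_cache[[kk]]$sd
  }, 0)

  tab <- tibble(
    seed_gene = vapply(mods, `[[`, "", "seed_gene"),
    k = ks,
    genes = lapply(mods, `[[`, "genes"),
    z_m = vapply(mods, `[[`, 0, "z_m"),
    z_n = z_n)
  tab <- dplyr::arrange(tab, dplyr::desc(.data$z_n), dplyr::desc(.data$z_m),
                        .data$seed_gene)
  tab$selected <- seq_len(nrow(tab)) <= n_top
  union_genes <- sort(unique(unlist(tab$genes[tab$selected])))
  structure(list(modules = tab, network_genes = union_genes,
                 subgraph = igraph::induced_subgraph(network, union_genes),
                 params = list(r = r, n_top = n_top, n_perm = n_perm,
                               seed = seed, d = d)),
            class = "module_search")
}

#' @export
print.module_search <- function(x, ...) {
  cat(sprintf("<module_search> %d unique modules; top %d span %d genes\n",
              nrow(x$modules), sum(x$modules$selected),
              length(x$network_genes)))
  invisible(x)
}
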