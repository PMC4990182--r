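#' Extended haplotype homozygosity at a flanking marker
#'
#' EHH is the probability that two random haplotypes carrying the core allele
#' are identical over the span from the core to the target marker
#' (inclusive): `sum_g C(n_g, 2) / C(n, 2)` over distinct haplotype strings
#' `g` in the span.
#'
#' @param haplotypes Binary matrix (rows = carrier haplotypes of one core
#'   allele, columns = markers).
#' @param core_index,target_index Column indices; the target must lie on one
#'   side of (or at) the core.
#' @return EHH in `[0, 1]`.
#' @export
ehh <- function(haplotypes, core_index, target_index) {
  n <- nrow(haplotypes)
  if (is.null(n) || n < 2) abort("EHH needs >= 2 carrier haplotypes")
  # at the core the span is the shared core allele itself
  if (core_index == target_index) return(1)
  span <- seq(min(core_index, target_index), max(core_index, target_index))
  key <- apply(haplotypes[, span, drop = FALSE], 1, paste, collapse = "")
  ng <- tabulate(match(key, unique(key)))
  sum(choose(ng, 2)) / choose(n, 2)
}

#' Integrated EHH (iHH) from EHH decay curves
#'
#' Trapezoid integral of EHH over physical distance, summed over the sides
#' supplied, truncated at the first marker where EHH drops below `cutoff`
#' (the final trapezoid down to that first sub-cutoff marker is included).
#' A side whose curve never reaches the cutoff before the chromosome end is
#' integrated in full and flagged as edge-truncated.
#'
#' @param ehh_curves A single data frame or a list of data frames (one per
#'   side) with columns `distance_bp` (starting at 0) and `ehh` (starting
#'   at 1).
#' @param cutoff EHH truncation cutoff (default 0.05).
#' @return iHH in bp x EHH units, with attribute `edge_truncated` (logical).
#' @export
ihh <- function(ehh_curves, cutoff = 0.05) {
  if (is.data.frame(ehh_curves)) ehh_curves <- list(ehh_curves)
  total <- 0; edge <- FALSE
  for (curve in ehh_curves) {
    d <- curve$distance_bp; e <- curve$ehh
    if (length(d) == 0 || d[1] != 0 || abs(e[1] - 1) > 1e-12) {
      abort("EHH curve must start at (0, 1)")
    }
    if (length(d) > 1 && any(diff(d) <= 0)) abort("distances must be strictly increasing")
    below <- which(e < cutoff)
    if (length(below) == 0) {
      last <- length(d)
      edge <- TRUE
      if (last == 1) next  # core at chromosome edge: empty side
    } else {
      last <- below[1]
    }
    if (last > 1) {
      total <- total + sum((e[1:(last - 1)] + e[2:last]) / 2 * diff(d[1:last]))
    }
  }
  structure(total, edge_truncated = edge)
}

# EHH decay curve for one allele class on one side of the core.
# Incremental refinement: groups of identical haplotype strings can only
# split as the span widens, which also guarantees EHH is non-increasing.
ehh_curve_side <- function(H, core, positions, side = c("right", "left"),
                           cutoff = 0.05) {
  side <- match.arg(side)
  n <- nrow(H)
  idx <- if (side == "right") seq(core, ncol(H)) else rev(seq(1, core))
  grp <- rep(1L, n)
  denom <- choose(n, 2)
  dist <- numeric(length(idx)); ehh_v <- numeric(length(idx))
  edge <- TRUE
  kept <- 0L
  for (j in seq_along(idx)) {
    # refine identity groups by the new marker's allele (integer relabeling)
    key <- grp * 2L + H[, idx[j]]
    grp <- match(key, unique.default(key))
    cnt <- tabulate(grp)
    val <- sum(cnt * (cnt - 1L)) / 2 / denom
    kept <- j
    dist[j] <- abs(positions[idx[j]] - positions[core])
    ehh_v[j] <- val
    if (val < cutoff) { edge <- FALSE; break }
  }
  curve <- tibble(distance_bp = dist[seq_len(kept)], ehh = ehh_v[seq_len(kept)])
  # the span at the core itself is the shared core allele: EHH = 1 by definition
  curve$ehh[1] <- 1
  attr(curve, "edge_truncated") <- edge
  curve
}

#' Compute iHS from a phased panel
#'
#' For every variant with at least `min_carriers` haplotypes in each allele
#' class, computes EHH decay curves on both sides for derived (allele 1) and
#' ancestral (allele 0) carriers, integrates them to iHH, forms the
#' unstandardized score `ln(iHH_A / iHH_D)`, and standardizes within
#' equal-width derived-allele-frequency bins.
#'
#' @param panel A phased `genotype_panel`.
#' @param cutoff EHH truncation cutoff (default 0.05).
#' @param n_bins Number of derived-frequency bins for standardization
#'   (default 20).
#' @param min_carriers Minimum haplotypes per allele class (default 2).
#' @param keep_edge_truncated Keep scores whose EHH curve ran off the
#'   chromosome end before reaching the cutoff (default `TRUE`; set `FALSE`
#'   to drop them).
#' @return Tibble: `variant_id`, `derived_freq`, `ihh_ancestral`,
#'   `ihh_derived`, `ihs_unstandardized`, `ihs`, `edge_truncated`.
#' @export
ihs_score <- function(panel, cutoff = 0.05, n_bins = 20L, min_carriers = 2L,
                      keep_edge_truncated = TRUE) {
  if (is.null(panel$haplotypes)) abort("iHS requires phased haplotypes")
  v <- panel$variants
  H <- panel$haplotypes
  out <- tibble(variant_id = v$variant_id,
                derived_freq = colMeans(H),
                ihh_ancestral = NA_real_, ihh_derived = NA_real_,
                ihs_unstandardized = NA_real_, edge_truncated = FALSE)
  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    Hc <- H[, cols, drop = FALSE]
    pos <- v$pos[cols]
    for (j in seq_along(cols)) {
      one <- ihs_one(Hc, j, pos, cutoff, min_carriers)
      if (is.null(one)) next
      i <- cols[j]
      out$ihh_derived[i] <- one$ihh_derived
      out$ihh_ancestral[i] <- one$ihh_ancestral
      out$edge_truncated[i] <- one$edge_truncated
      out$ihs_unstandardized[i] <- one$unstandardized
    }
  }
  if (!keep_edge_truncated) {
    out$ihs_unstandardized[out$edge_truncated] <- NA_real_
  }
  std <- ihs_standardize(out[, c("derived_freq", "ihs_unstandardized")],
                         n_bins = n_bins)
  out$ihs <- std$ihs
  out[, c("variant_id", "derived_freq", "ihh_ancestral", "ihh_derived",
          "ihs_unstandardized", "ihs", "edge_truncated")]
}

# unstandardized iHS for one variant (column j of chromosome haplotype
# matrix Hc with positions pos); NULL when an allele class is too small
ihs_one <- function(Hc, j, pos, cutoff = 0.05, min_carriers = 2L) {
  der <- Hc[, j] == 1L
  if (sum(der) < min_carriers || sum(!der) < min_carriers) return(NULL)
  res <- lapply(list(derived = Hc[der, , drop = FALSE],
                     ancestral = Hc[!der, , drop = FALSE]), function(Hk) {
    cr <- ehh_curve_side(Hk, j, pos, "right", cutoff)
    cl <- ehh_curve_side(Hk, j, pos, "left", cutoff)
    val <- ihh(list(cr, cl), cutoff)
    list(ihh = as.numeric(val),
         edge = attr(cr, "edge_truncated") || attr(cl, "edge_truncated"))
  })
  list(ihh_derived = res$derived$ihh, ihh_ancestral = res$ancestral$ihh,
       edge_truncated = res$derived$edge || res$ancestral$edge,
       unstandardized = if (res$derived$ihh > 0 && res$ancestral$ihh > 0)
         log(res$ancestral$ihh / res$derived$ihh) else NA_real_)
}

#' Standardize unstandardized iHS within derived-frequency bins
#'
#' Scores are partitioned into `n_bins` equal-width derived-frequency bins
#' over `[0, 1]`; within each bin the mean is subtracted and the sample
#' standard deviation (denominator n - 1) divided out. Bins with fewer than
#' 3 scores, or zero spread, leave their scores unstandardizable (`NA`, with
#' a logged count).
#'
#' @param scores Data frame with columns `derived_freq` and
#'   `ihs_unstandardized`.
#' @param n_bins Number of bins (default 20).
#' @return The input with an added `ihs` column.
#' @export
ihs_standardize <- function(scores, n_bins = 20L) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scores$derived_freq, breaks, include.lowest = TRUE)
  ihs <- rep(NA_real_, nrow(scores))
  n_flagged <- 0L
  for (b in levels(bin)) {
    in_bin <- which(bin == b & !is.na(scores$ihs_unstandardized))
    if (length(in_bin) == 0) next
    if (length(in_bin) < 3) { n_flagged <- n_flagged + length(in_bin); next }
    x <- scores$ihs_unstandardized[in_bin]
    s <- stats::sd(x)
    if (s == 0) { n_flagged <- n_flagged + length(in_bin); next }
    ihs[in_bin] <- (x - mean(x)) / s
  }
  count_warn(n_flagged, "iHS score(s) unstandardizable (bin with < 3 scores or zero spread)")
  out <- as_tibble(scores)
  out$ihs <- ihs
  out
}

#' Screen variants by |iHS|
#'
#' Keeps exactly the variants with `|ihs|` strictly greater than the
#' threshold. Variants with missing iHS are dropped with a logged count
#' (not every GWAS variant carries a haplotype score).
#'
#' @param variants Variant tibble with an `ihs` column.
#' @param threshold Screening threshold (default 1.5).
#' @return The filtered tibble.
#' @export
filter_by_ihs <- function(variants, threshold = 1.5) {
  stopifnot(threshold > 0)
  missing <- is.na(variants$ihs)
  count_warn(sum(missing), "variant(s) without iHS dropped at the selection screen")
  out <- variants[!missing & abs(variants$ihs) > threshold, ]
  if (nrow(out) == 0) warn("no variants pass the |iHS| screen")
  out
}
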