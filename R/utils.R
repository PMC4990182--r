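# shared internal helpers

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Chromosome labels are stored without a "chr" prefix so mixed-source inputs
# (VCF, BED, summary tables) agree.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

# single place to derive reproducible sub-seeds (kept < 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483647L
}

assert_prob <- function(x, name, open_left = TRUE) {
  bad <- !is.finite(x) | x > 1 | (if (open_left) x <= 0 else x < 0)
  if (any(bad)) {
    abort(sprintf("%s must lie in %s0,1]: %d offending value(s)",
                  name, if (open_left) "(" else "[", sum(bad)))
  }
  invisible(x)
}

count_warn <- function(n, what) {
  if (n > 0) warn(sprintf("%d %s", n, what))
  invisible(n)
}
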