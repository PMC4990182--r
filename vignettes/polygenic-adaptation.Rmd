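---
title: "Detecting polygenic adaptation in trait-associated protein networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polygenic adaptation in trait-associated protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyadapt)
```

## The problem

Single-locus selection scans find sweeps, but most adaptation of complex
traits is thought to be polygenic: many trait-associated alleles shift
frequency together, each too weakly to stand out on its own. `polyadapt`
looks for such coordinated signals by intersecting three layers of evidence:
per-variant signatures of recent positive selection (the integrated
haplotype score, iHS), gene- and network-level association with the trait
(GWAS summary statistics aggregated over a protein-interaction network), and
statistical dependence between distant loci (long-distance genotypic LD,
a signature of epistatic co-selection). Genes that sit in
selection-enriched, trait-associated network modules *and* participate in
long-range genotype dependence form the "adaptation gene set", which is then
summarised by term enrichment.

## The five stages

### 1. Selection screen (iHS)

For a core SNP, the extended haplotype homozygosity at a flanking marker is
the probability that two random haplotypes carrying the same core allele are
identical over the intervening span:

$$EHH(t) = \sum_g \binom{n_g}{2} \Big/ \binom{n}{2},$$

where $g$ runs over distinct haplotype strings between core and target.
Because groups can only split as the span widens, $EHH$ is non-increasing in
distance — an invariant asserted on every computed curve. Each side's decay
curve is integrated by the trapezoid rule (`ihh()`), truncated at the first
marker where $EHH$ drops below 0.05 (that final trapezoid is included); the
unstandardized score is $\ln(iHH_A/iHH_D)$ and is standardized to mean 0,
SD 1 within 20 equal-width derived-allele-frequency bins, so a score is
comparable across frequencies. Variants with $|iHS| > 1.5$ (strictly) pass
the screen; the threshold, cutoff and bin count are configurable. Scores
whose curves run off the chromosome end are flagged `edge_truncated` and
kept by default — on short simulated chromosomes dropping them would
systematically discard near-edge variants; set `keep_edge_truncated = FALSE`
for the stricter convention. When an iHS table is supplied instead of phased
haplotypes, variants absent from the table are dropped with a logged count,
and matching is by variant id by default (`match_by = "position"` joins
through chromosome and position instead).

In "ingest" mode the derived allele is taken to be the VCF ALT allele; true
ancestral-state inference from outgroups is out of scope, and only
$|iHS|$ is consumed downstream, so the sign convention is immaterial there.

### 2. Gene-based association

Screened SNP p-values are combined per gene (SNPs are assigned to every
gene whose interval contains them; flank configurable, default 0 bp) into

$$T_{obs} = \sum_j Q_{\chi^2_1}(1 - p_j),$$

whose null distribution is calibrated by reference-panel LD: draw
$z \sim MVN(0, \Sigma)$ with $\Sigma$ the dosage correlation matrix
(repaired to positive semidefiniteness by eigenvalue clipping and
re-normalization), and compare $T^* = \sum_j z_j^2$. The add-one Monte-Carlo
estimator $p = (1 + \#\{T^* \ge T_{obs}\})/(1 + n_{sims})$ can never return
zero, which the probit transform requires. Simulation is staged
($10^3 \to 10^4 \to$ ceiling) and escalates only while the estimate is
below ten times the current resolution; single-SNP genes short-circuit to
the SNP p-value exactly. The gene weight is $z = \Phi^{-1}(1-p)$ with $p$
clipped into $[10^{-16}, 1-10^{-16}]$. Genes with no screened SNPs are
absent from the output rather than given $p = 1$: an unscored gene is not
evidence of no association, and it must not become a module seed.

### 3. Dense-module search

On the PPI graph with gene weights $z_i$, a module scores
$Z_m = \sum_i z_i / \sqrt{k}$. From every scored seed, the greedy search
evaluates scored direct neighbours of the current module and accepts the
best addition only if $Z_{new} > Z_{current}(1 + r)$, with $r = 0.1$ by
default; ties break deterministically (higher weight, then lexicographic
id). A neighbourhood distance $d > 1$ is available, attaching a candidate
together with its connecting path of scored genes; the default $d = 1$
guarantees connectivity trivially. Unscored interactors are invisible to
the search — there is no principled imputation for them. Raw scores are
normalized against uniformly random $k$-subsets of all scored genes
(connectivity deliberately *not* imposed in the null):
$Z_N = (Z_m - \mu_{Z^*})/\sigma_{Z^*}$, by exhaustive enumeration when
$\binom{n}{k} \le 10^4$ and by sampling otherwise. Because the null depends
only on $k$, the search caches one null per module size. Duplicate gene
sets are collapsed, modules rank by $Z_N$ (then $Z_m$, then seed id) —
both scores are reported so either convention can be inspected — and the
union of the top 10 modules is the trait gene network.

### 4. Long-distance genotypic LD (epistasis screen)

Variants mapping to network genes are pruned greedily in order of ascending
GWAS p: a variant is kept unless its squared dosage correlation with an
already-kept same-chromosome variant strictly exceeds 0.8, so each LD clump
keeps its most associated representative. Candidate pairs are variants in
*different* network genes, on different chromosomes or $\ge$ 10 Mb apart on
the same chromosome (measured between variant positions), with at least one
member nominally associated ($\min(p_a, p_b) < 0.05$; the conventional
reading of "nominal significance", configurable). Each pair is tested for
independence of unphased genotypes on the joint $\le 3 \times 3$ table with
the log-likelihood-ratio statistic $G = 2\sum o \ln(o/e)$; the p-value comes
from permuting one locus's genotype labels (add-one estimator; exact
enumeration over all $n!$ permutations replaces sampling for $n \le 7$).
Monomorphic loci are untestable and reported with $p = 1$ and a flag. FDR
control uses Storey q-values: $\hat\pi_0(\lambda)$ over
$\lambda = 0.05, \dots, 0.95$, smoothed by a natural cubic smoothing spline
with 3 df and read at $\lambda = 0.95$, capped into $(0,1]$; with fewer
than 100 p-values the smoother is unstable and $\pi_0$ defaults to 1,
reducing the procedure to Benjamini–Hochberg. Pairs with $q < 0.05$
(strictly) are significant.

### 5. Gene set and enrichment

Genes carrying a significant-pair variant form the adaptation gene set,
drawn as a graph whose edges are the significant LD pairs (labelled by the
analysis of origin) and the PPI edges among those genes. Terms from a GMT
collection are tested by the one-sided hypergeometric (Fisher exact) upper
tail, testing only terms overlapping the study set in $\ge 2$ genes, with a
Bonferroni multiplier equal to the number of terms actually tested — the
hypotheses actually evaluated, not the whole collection. The default
background is the annotated genes that appear in the GMT universe.

## The synthetic-data generator

`sim_config()` fixes the reference study condition: 200 diploid samples,
5 chromosomes of 50 Mb with 400 variants each (allele frequencies uniform
in [0.05, 0.5]), 1,000 genes tiled without overlap, a scale-free PPI
background of ~3,000 edges (preferential attachment, $m = 3$), one partial
sweep at derived frequency 0.5 with founder-copy breakpoints at exponential
distance (rate $10^{-6}$ per bp, i.e. mean 1 Mb) and per-site copy errors
at $10^{-3}$, ten planted trait genes with SNP effects $|z| \sim N(4, 1)$
that double as a densely wired module ($q_{in} = 0.8$), and up to five
cross-chromosome epistatic pairs with copy error $\varepsilon = 0.1$. These
scales keep a full end-to-end run in the minutes range on one CPU while
leaving every stage's planted signal recoverable.

The sweep is a founder-copy approximation, not a coalescent simulation: it
produces the elevated-EHH core that iHS detects, but no realistic
demography, mutation spectrum or background LD structure. Genotypes are in
Hardy–Weinberg proportions by construction, which matches the panel's role
(the pipeline never tests HWE). Planting an epistatic pair rewrites the
dependent variant's haplotypes, which perturbs that variant's own iHS; the
bundle generator therefore retries candidate partners until the planted
pair remains visible to the selection screen, recomputes the final iHS
table after planting, and records each pair's screen status in the truth
manifest. Consequently, passing tests demonstrate recovery of signals *of
the planted form* under HWE and free recombination between chromosomes —
not performance on real LD structure, real selection, or real annotation
databases.

## Numerical choices and degenerate inputs

- Add-one Monte-Carlo estimators everywhere a permutation p feeds a
  transform or an FDR step, so p = 0 cannot occur; the exact enumeration
  path divides by $n!$ with the identity included.
- LD matrices are repaired by eigenvalue clipping at 0 followed by
  re-normalization to unit diagonal; monomorphic SNPs are dropped with a
  warning before correlation.
- Frequency bins with fewer than 3 scores, or zero spread, leave their iHS
  unstandardizable (`NA`, logged) rather than $\pm\infty$.
- The r² pruning comparison uses a $10^{-12}$ guard so a correlation
  numerically at the threshold is retained, as the strict inequality
  intends.
- Degenerate module nulls (module spanning the whole scored universe, or
  all weights equal) are errors, not silent zeros.
- All stage seeds derive deterministically from one global seed; permuting
  input row order does not change any output (seeds are canonicalized by
  sorted gene id).

## Problem sizes used by the tests

The test-suite calibration checks use 2,000 null genes (5 SNPs,
exchangeable $r = 0.5$) for gene-test type-I error; 10,000 null
Hardy–Weinberg pairs (n = 100, 2,000 permutations) for the G-test rejection
rate; 20 mixture seeds (10 planted $\varepsilon = 0.1$ pairs among 200
nulls, n = 200) for FDR/power; and ten 1,000-gene planted-module searches.
These sizes were chosen to give stable empirical rates while keeping the
default test run in the minutes range.

## Known limitations

- iHS polarization in VCF-ingest mode trusts the ALT allele as derived.
- The genotypic-LD test is a permutation G-test on the joint genotype
  table; it targets the same null as the classical Markov-chain exact test
  of genotypic differentiation but is not numerically identical to it.
- The random-set module null ignores connectivity (by design, matching the
  method it follows); a connectivity-preserving null is left as a config
  extension point.
- Sex-stratified analyses are handled simply as separate summary-statistic
  files, one pipeline run each; merging across sub-phenotypes is limited to
  the evidence labels on gene-set edges.
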