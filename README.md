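# haplogic

Genome-wide discovery of **genic 3-SNP haplotype associations** in phased
case-control cohorts, for statistical geneticists who want to go beyond
single-SNP GWAS without exhaustively testing every contiguous SNP window.

A haplotype pattern is a Boolean logic tree over `(SNP = allele)` literals
evaluated on one chromosome copy, e.g.
`(rs_a = C) or ((rs_b = A) and (rs_c = G))`. Within each *gene analytic
window* — a gene's span plus 500-kb flanks, LD-pruned to tagging SNPs
(pairwise r² ≤ 0.8) — a simulated-annealing logic-regression search finds
the tree minimizing the logistic deviance over all 2N chromosome copies.
Windows are ranked by a permutation-based evaluation statistic

    (D_obs − D_med) / MAD,

where `D_med` and the MAD come from re-running the full search under 20
phenotype permutations; the top 1% of unique trees (structural
deduplication across overlapping windows) go to replication. A reported
haplotype is fit at the subject level with the additive copy-count model

    logit P(case) = β0 + β1·L,   L ∈ {0, 1, 2},

and replicates when its replication p-value beats the Bonferroni per-test
threshold with an odds ratio in the same direction as discovery. The
package also provides the standard sliding-window benchmark (EM haplotype
frequencies with a phase-uncertainty-aware global score test), Fisher-exact
annotation/eQTL enrichment, SHAPEIT HAPS/SAMPLE and phased-VCF input with
the usual QC filters, and a phased-cohort simulator with an embedded
Boolean-tree risk effect.

## Worked example

Simulate a cohort carrying a 3-SNP risk haplotype, search its window, and
fit the additive model:

```r
library(haplogic)

causal <- lt_or(lt_leaf(10, 1), lt_and(lt_leaf(25, 1), lt_leaf(40, 1)))
sim <- simulate_phased_cohort(sim_config(
  n_subjects = 2000, n_snps = 50, rho = 0.3,
  causal_tree = causal, beta0 = -1, beta1 = log(3), seed = 101))
co <- sim$cohort

w <- structure(list(window_id = "w", gene_ids = "w", chrom = "1",
                    start = 1, end = 1e9, snp_indices_all = 1:50,
                    snp_indices_pruned = 1:50), class = "gene_window")
fit <- search_window(co, w, search_config(n_restarts = 100,
                                          n_iter = 3000, seed = 7))
format_tree(fit$tree, co$variants)
#> [1] "((snp00040 = G) and (snp00025 = G)) or (snp00010 = G)"
fit$deviance
#> [1] 5363.114

fit_additive(copy_count(fit$tree, co), co$subjects$phenotype)
#> hap_assoc: OR 2.587 (beta1 0.9504), p 4.17e-39, n 2000
```

The search recovers the generating tree (up to commutativity). The fitted
per-copy odds ratio 2.59 estimates the simulated `exp(β1) = 3` within
sampling error (Wald standard error ≈ 0.073 on the log scale); the
p-value tests `β1 = 0`.

Reproducing published grouped-count odds ratios from printed group sizes
and case percentages:

```r
run_table1_check()[, c("chr", "or_fitted", "or_printed", "match")]
#>   chr or_fitted or_printed match
#> 1   6     3.665      3.665  TRUE
#> 2   6     3.075      3.075  TRUE
#> 3   6     0.365      0.365  TRUE
#> 4   7     0.066      0.066  TRUE
#> 5   9     1.672      1.672  TRUE
```

A thin command-line wrapper for full runs over HAPS/SAMPLE inputs lives in
`inst/scripts/discover.R` (YAML config; see its header).

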