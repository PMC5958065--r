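---
title: "Genic haplotype discovery with logic-regression trees: models and methods"
author: "haplogic authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genic haplotype discovery with logic-regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplogic)
```

## The problem

Single-SNP association scans miss risk patterns that live on haplotypes:
particular combinations of alleles carried on the *same* chromosome copy,
possibly far apart within a gene region. haplogic searches phased
case-control data for such patterns, restricted to three SNPs per pattern
and to gene-centered "analytic windows", so that discovered combinations are
plausible models of cis-regulatory interaction rather than arbitrary
genome-wide triples.

A haplotype pattern is a Boolean **logic tree** over literals
`(SNP = allele)` evaluated per chromosome copy, e.g.

```
(rs_a = C) or ((rs_b = A) and (rs_c = G))
```

Each subject carries two copies, so a tree induces a per-subject copy count
`L` in {0, 1, 2}. Discovery works at the chromosome level (2N observations);
inference for a reported haplotype works at the subject level through the
additive logistic model

```
logit P(case) = beta0 + beta1 * L
```

whose `exp(beta1)` is the reported per-copy odds ratio. Because biallelic
SNPs make `(SNP = ref)` the exact complement of `(SNP = alt)`, negation
nodes are unnecessary and not represented; a tree and its De Morgan
complement produce complementary indicators and identical deviances, and
either form is a valid report of the same association.

## Gene analytic windows

Windows are a gene's merged transcript span extended by `flank` (default
500 kb) on both sides; SNPs are mapped by inclusive position, and windows
with fewer than two mapped SNPs are dropped. Within a window, SNPs are
LD-pruned by a greedy sweep in ascending position: a SNP is kept when its
haplotypic r² with every already-kept SNP is at most `r2_max` (default
0.8). Sweep order matters only for ties in LD structure; ascending position
makes the result deterministic. r² is computed on phased chromosomes, not
on genotypic dosage correlation, because phase is known downstream.
Monomorphic columns (r² undefined, no haplotype information) are dropped
during pruning.

## The search

Per window, the best tree is sought by simulated annealing over tree space,
scored by the residual deviance of the logistic regression of phenotype on
the binary tree indicator over all 2N chromosome copies (each subject's
status duplicated onto both copies). With a binary predictor the ML fit is
the pair of group proportions, so the deviance is closed-form and cheap; the
inner loop is compiled. A constant indicator scores the null deviance, and
perfect separation scores zero.

States are trees with one to three leaves over distinct SNPs. Proposals
draw from six moves: replace a leaf's SNP, flip a leaf's allele, toggle an
operator, grow a leaf (capped at three), prune a leaf, and **reshape** —
for a three-leaf tree, re-draw which leaf sits outside the inner pair
together with both operators. Reshape exists because the first five moves
can only re-associate `((a ? b) ? c)` into `((b ? c) ? a)` by passing
through one- and two-leaf states whose deviance is far worse whenever the
window carries real signal; those barriers scale with the effect size and
are practically uncrossable at useful temperatures. Reshape makes
re-association a single, frequently downhill step; in our development
simulations it raised causal-tree recovery from roughly two-thirds of
replicates to all of them at a fixed budget.

A proposal changing the deviance by `delta` at temperature `T` is accepted
with probability `min(1, exp(-delta / T))`; `T` follows a geometric
schedule (defaults 10 down to 0.01 over 25,000 iterations). The search is
restarted from `n_restarts` random one-leaf trees (default 100, mirroring
the 100-initialization protocol of the analysis this package implements;
the schedule itself is our choice — no published schedule exists for this
problem). Empirically, the restart count is what drives global-optimum
attainment; hotter or longer chains at a fixed total budget perform worse.
Restart seeds derive deterministically from (master seed, window id,
restart index), so results are bit-reproducible and restart budgets are
nested. Ties in deviance break by canonical-key order. With the default
`min_leaves = 3` the reported best is the best tree over three distinct
SNPs — the search still traverses smaller states, they are simply not
reported.

For windows of up to about six pruned SNPs, `search_window_exhaustive()`
enumerates all structurally distinct trees and is the reference the
annealer is expected to attain.

## The permutation evaluation statistic

Deviance is not comparable across windows (it depends on window content and
the attainable fit), so candidate windows are ranked by a permutation-
calibrated statistic. Phenotypes are permuted at the subject level (both
chromosome copies move together) 20 times, the full multi-restart search is
re-run per permutation — the statistic compares best-achievable fits, not
re-scores of a fixed tree — and from the permutation deviances
`D_1..D_20` we form leave-one-out deviations `d_i = D_i - median(D_-i)`.
The statistic is

```
(D_obs - D_med) / MAD(d)
```

with `D_med` the median of all 20 permutation deviances and `MAD` the
median absolute deviation of the deviations (scaled by 1.4826 by default;
a raw-MAD switch is provided since either convention appears in practice).
More negative means the observed best fit sits farther below its own
permutation null. Windows where all permutation deviances coincide give a
zero MAD; they return a degenerate sentinel and are excluded from ranking.

Trees found in several overlapping windows are deduplicated by
**structural** canonical identity (commutativity and associativity
normalized — not truth-table equivalence), keeping the most negative
statistic; the lowest `ceiling(fraction * n_unique)` statistics (default
top 1%) become replication candidates. The realized cutoff is
data-dependent and is reported, not assumed.

## Replication and the grouped-count check

Each candidate is refit in the replication cohort with the additive model.
Replication requires a p-value strictly below the Bonferroni per-test
threshold `alpha / m` (`m` = number of candidates) *and* a replication odds
ratio on the same side of 1 as discovery. Combined-cohort fits pool both
cohorts without a cohort covariate; this choice reproduces the published
combined odds ratios exactly when refit from grouped counts (see below),
which is the empirical justification for not adding a covariate. P-values
are two-sided Wald; the model is fit on grouped binomial counts, so
subject-level and grouped input agree to machine precision by construction.

`run_table1_check()` inverts the published display "group size (% cases)"
— one-decimal percentages rounded half-up, constrained to the known total
case count (1,381 of 2,886) — to unique integer counts, refits the model,
and compares the fitted odds ratio with the printed one. All five published
example rows reproduce to three decimals; half-up rounding is the only
rounding model under which all reconstructions are unique.

## The sliding-window benchmark

The standard alternative tests all contiguous 3-SNP windows. Genotypes are
obtained by collapsing the phased data (the benchmark models unphased
input), haplotype frequencies are estimated by EM over compatible
diplotypes from a uniform start (the observed-data log-likelihood is
non-decreasing every iteration and is asserted as such in the tests), and
association is a global score test. With posterior expected haplotype
dosages `e_i` (the E-step quantities at convergence), the score vector is
`U = sum_i (y_i - ybar) e_i` and the variance is

```
V = ybar (1 - ybar) * sum_i (e_i - ebar)(e_i - ebar)'
```

after dropping haplotypes with estimated count below 20 (excluded by
default; pooling into a pseudo-haplotype is available, as the original
tool's rare-haplotype handling is not documented) and the most common
haplotype as reference. The statistic is `U' V^- U` with a Moore-Penrose
inverse (rank from a 1e-10 relative eigenvalue tolerance), chi-square on
`df = rank(V) <= h - 1`. This `V` is the score variance of the subject-
level marginalized likelihood: it accounts for phase uncertainty through
the posterior dosages, equals the subject-level Pearson contingency
statistic when phase is certain, and gives uniform permutation-null
p-values — a chromosome-level variance would be conservative under phase
ambiguity.

## Enrichment

Annotation enrichment compares the haplotype SNP set against a disjoint
comparison set (in practice, window-mapped SNPs with nominal univariate
association; `single_snp_assoc()` provides the screen) over interval
tracks, one two-sided Fisher exact test (probability-mass criterion) per
track, Bonferroni-corrected within each assay family. Intervals keep their
on-disk half-open convention and a SNP position `p` counts when
`start <= p < end`; a SNP exactly at `end` does not count. eQTL enrichment
consumes per-SNP significant-eQTL counts, either as summed SNP-gene pairs
(requires the number tested) or collapsed to a per-SNP indicator.

## The simulator

`simulate_phased_cohort()` draws each chromosome copy independently:
per-SNP MAF uniform in `maf_range` (default 0.05-0.5, the post-QC floor),
and adjacent-SNP LD from a first-order copying chain — each allele copies
its left neighbour with probability `rho` (default 0.3, chosen once to give
adjacent r² around 0.1, a realistic tag-SNP scale that exercises pruning
without saturating it). Subjects are two independent copies; case status is
Bernoulli with `logit p = beta0 + beta1 * L` for the causal tree's copy
count. Defaults mirror the study design this package targets: 2,886
subjects split a priori 1,937/949 into discovery and replication cohorts.

The simulator deliberately matches the inference model, so parameter
recovery is a clean check of the machinery. What it does **not** emulate:
recombination-map structure, demography and coalescent genealogies, allele
frequency spectra, phasing error, genotyping artifacts, or population
stratification. Passing tests therefore demonstrate correctness of the
algorithms under their own assumptions, not robustness to real-data
pathologies.

## Numerical and design choices

* QC order: variant call rate ≥ 0.95, then MAF ≥ 0.05, then exact HWE
  p ≥ 0.001 in controls (plain conditional exact test, no mid-p), then
  sample call rate ≥ 0.97 over retained variants.
* Missing phased alleles are tolerated defensively (phasing output is
  normally complete): a chromosome missing a tree SNP is excluded from the
  chromosome-level deviance, and a subject missing either copy is excluded
  from the subject-level model.
* Pruned windows need at least two SNPs; windows with two pruned SNPs
  cannot form 3-SNP trees and simply report no candidate under the default
  `min_leaves = 3` (this is configurable, since whether sub-3-SNP best
  trees were discarded or never produced in the original analysis is
  unknowable from the publication).
* The boundary r² = 0.8 is kept (removal only when r² strictly exceeds the
  threshold).
* Deviance ties break by canonical key; eigenvalues below 1e-10 of the
  largest are treated as null space; reconstruction of printed percentages
  uses half-up rounding.

## Problem sizes used in the automated checks

The test suite and `scripts/acceptance.R` run reduced but non-trivial
problem sizes, chosen as the smallest that make the stochastic properties
sharp: annealing-vs-enumeration on 100 windows of 4-6 SNPs at N = 500
(40 restarts x 1,000 iterations); null selection calibration over 300
8-SNP windows at N = 300 with 20 permutations each (6 restarts x 300
iterations, 3 restarts within permutations); causal-tree recovery on 20
replicates of a 50-SNP window at N = 2,000 with `beta1 = ln 3`
(100 restarts x 3,000 iterations); score-test calibration over 500
3-SNP windows at N = 250; and 1,000 random Fisher tables with margins up
to 200.

## Known limitations

* Three-leaf trees only; no NOT nodes (redundant for biallelic SNPs), no
  model-size selection.
* Binary traits only; no covariates in the association model.
* The evaluation statistic is a ranking device without an analytic null;
  selection is by quantile, not by p-value.
* Simulated annealing is stochastic: the exhaustive optimum is guaranteed
  only on windows small enough to enumerate.
* The benchmark's EM treats subjects as unrelated and in HWE within the
  window, as the standard method does.
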