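# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written without reusing the implementation path they check.

# A tiny handmade cohort: explicit haplotype matrix, 1-based variant grid.
toy_cohort <- function(haps, phenotype, cohort = NULL, pos = NULL) {
  haps <- as.matrix(haps)
  m <- ncol(haps)
  n <- nrow(haps) / 2
  variants <- data.frame(id = paste0("rs", seq_len(m)), chrom = "1",
                         pos = pos %||% as.integer(seq_len(m) * 1000L),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  subjects <- data.frame(id = paste0("s", seq_len(n)),
                         phenotype = as.integer(phenotype),
                         cohort = cohort %||% rep("discovery", n),
                         stringsAsFactors = FALSE)
  phased_cohort(variants, haps, subjects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A gene_window over explicit SNP indices (already "pruned").
make_window <- function(snps, id = "w1") {
  structure(list(window_id = id, gene_ids = id, chrom = "1",
                 start = 1, end = 1e9,
                 snp_indices_all = snps, snp_indices_pruned = snps),
            class = "gene_window")
}

# Oracle: chromosome-level logistic deviance via glm (generic IRLS path,
# independent of the closed-form implementation).
oracle_glm_deviance <- function(x, y) {
  as.numeric(stats::glm(y ~ x, family = stats::binomial())$deviance)
}

# Oracle: brute-force best 3-leaf tree deviance by direct enumeration over
# flat shapes, with indicators and deviance computed from first principles.
oracle_best3_deviance <- function(cohort, snps) {
  haps <- cohort$haps[, snps, drop = FALSE]
  y <- rep(cohort$subjects$phenotype, each = 2)
  dev_of <- function(x) {
    d <- 0
    for (v in c(TRUE, FALSE)) {
      n <- sum(x == v)
      k <- sum(y[x == v])
      if (n == 0) next
      p <- k / n
      if (k > 0) d <- d + k * log(p)
      if (n - k > 0) d <- d + (n - k) * log(1 - p)
    }
    x0 <- sum(x); if (x0 == 0 || x0 == length(x)) {
      p <- mean(y)
      return(-2 * (sum(y) * log(p) + sum(1 - y) * log(1 - p)))
    }
    -2 * d
  }
  best <- Inf
  k <- length(snps)
  idx <- utils::combn(k, 3)
  for (ci in seq_len(ncol(idx))) {
    trip <- idx[, ci]
    for (a1 in 0:1) for (a2 in 0:1) for (a3 in 0:1) {
      l1 <- haps[, trip[1]] == a1
      l2 <- haps[, trip[2]] == a2
      l3 <- haps[, trip[3]] == a3
      cands <- list(l1 & l2 & l3, l1 | l2 | l3,
                    (l1 & l2) | l3, (l1 | l2) & l3,
                    (l1 & l3) | l2, (l1 | l3) & l2,
                    (l2 & l3) | l1, (l2 | l3) & l1)
      for (x in cands) best <- min(best, dev_of(x))
    }
  }
  best
}

# Oracle: exact HWE p-value from the explicit combinatorial formula
# P(n_ab) = n! 2^n_ab / (n_aa! n_ab! n_bb!) * (na! nb! / (2n)!).
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- sapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- (nb - h) / 2
    lfactorial(n) + h * log(2) - lfactorial(aa) - lfactorial(h) -
      lfactorial(bb) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  })
  p <- exp(logp)
  sum(p[p <= p[match(n_ab, hets)] * (1 + 1e-9)])
}
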