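# Benchmark method: EM haplotype-frequency estimation from unphased
# genotypes and a global score test over 3-SNP sliding windows. Genotypes are
# obtained by collapsing the phased input, reproducing the unphased setting
# the benchmark models.

hap_label <- function(code, k) {
  vapply(code, function(h)
    paste(rev(as.integer(intToBits(h))[seq_len(k)]), collapse = ""),
    character(1))
}

# All ordered-pair-free diplotype expansions compatible with genotype g
# (complete, values 0/1/2). Haplotypes are bit codes, bit j (from the left,
# i.e. site order) set when the alternative allele is carried.
compatible_pairs <- function(g) {
  k <- length(g)
  bit <- 2^((k - 1):0)
  base <- sum(bit[g == 2])
  het <- which(g == 1)
  if (!length(het))
    return(matrix(c(base, base), ncol = 2))
  nh <- length(het)
  # fix the first het site on haplotype 1 to 0: each unordered pair once
  combos <- as.matrix(expand.grid(rep(list(0:1), nh - 1)))
  if (nh == 1) combos <- matrix(numeric(0), nrow = 1, ncol = 0)
  h1 <- base + if (nh > 1) as.vector(combos %*% bit[het[-1]]) else 0
  h2 <- base + sum(bit[het]) - (h1 - base)
  cbind(h1, h2)
}

#' EM haplotype-frequency estimation for a genotype window
#'
#' Standard EM over the haplotypes compatible with the observed (complete)
#' genotypes, starting from uniform frequencies. The observed-data
#' log-likelihood is non-decreasing at every iteration; the trace is
#' returned so this can be asserted. Posterior expected haplotype dosages
#' per subject are retained for the score test.
#'
#' @param geno integer matrix of allele-count genotypes (subjects by k SNPs,
#'   values 0/1/2/`NA`); subjects with any missing genotype are excluded.
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @return a `hap_freqs` list: `haplotypes` (0/1 strings), `freq`, `dosage`
#'   (subjects-by-haplotypes posterior expected counts), `loglik_trace`,
#'   `converged`, `subjects_used` (row indices of complete subjects).
#' @export
em_hap_freqs <- function(geno, tol = 1e-8, max_iter = 500L) {
  geno <- as.matrix(geno)
  k <- ncol(geno)
  complete <- which(rowSums(is.na(geno)) == 0L)
  if (!length(complete)) stop("all genotypes missing in this window")
  pairs <- lapply(complete, function(i) compatible_pairs(geno[i, ]))
  codes <- sort(unique(unlist(lapply(pairs, as.vector))))
  H <- length(codes)
  idx <- lapply(pairs, function(pm)
    cbind(match(pm[, 1], codes), match(pm[, 2], codes)))
  p <- rep(1 / H, H)
  n <- length(complete)
  ll_trace <- numeric(0)
  converged <- FALSE
  dosage <- NULL
  for (it in seq_len(max_iter)) {
    counts <- numeric(H)
    dosage <- matrix(0, n, H)
    ll <- 0
    for (i in seq_len(n)) {
      pm <- idx[[i]]
      w <- p[pm[, 1]] * p[pm[, 2]] * ifelse(pm[, 1] == pm[, 2], 1, 2)
      tot <- sum(w)
      ll <- ll + log(tot)
      w <- w / tot
      for (r in seq_len(nrow(pm))) {
        dosage[i, pm[r, 1]] <- dosage[i, pm[r, 1]] + w[r]
        dosage[i, pm[r, 2]] <- dosage[i, pm[r, 2]] + w[r]
      }
    }
    counts <- colSums(dosage)
    ll_trace <- c(ll_trace, ll)
    p_new <- counts / (2 * n)
    if (it > 1 && ll - ll_trace[it - 1] < tol) {
      converged <- TRUE
      break
    }
    p <- p_new
  }
  colnames(dosage) <- hap_label(codes, k)
  structure(list(haplotypes = hap_label(codes, k), freq = p,
                 dosage = dosage, loglik_trace = ll_trace,
                 converged = converged, subjects_used = complete),
            class = "hap_freqs")
}

#' @exportS3Method base::print
print.hap_freqs <- function(x, ...) {
  cat("hap_freqs over", length(x$haplotypes), "haplotypes;",
      length(x$subjects_used), "subjects;",
      if (x$converged) "converged" else "NOT converged",
      "at loglik", formatC(utils::tail(x$loglik_trace, 1), digits = 6), "\n")
  print(stats::setNames(round(x$freq, 4), x$haplotypes))
  invisible(x)
}

# Symmetric pseudo-inverse quadratic form U' V^- U with rank from a relative
# eigenvalue tolerance.
ginv_quad <- function(V, U, rel_tol = 1e-10) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * rel_tol
  if (!any(pos)) return(list(stat = NA_real_, df = 0L))
  z <- crossprod(eg$vectors[, pos, drop = FALSE], U)
  list(stat = sum(z^2 / eg$values[pos]), df = sum(pos))
}

#' Global haplotype score test with phase uncertainty
#'
#' Score test of the null of no haplotype effect on a binary phenotype.
#' Haplotype frequencies come from [em_hap_freqs()]; haplotypes with
#' estimated count (`2N x frequency`) below `min_count` are excluded from
#' scoring (or pooled, with `rare = "pool"`), and the most common retained
#' haplotype is the reference. The score vector uses posterior expected
#' haplotype dosages centered at the phenotype-pooled mean,
#' `U = sum_i (y_i - ybar) e_i`, and the variance is the phase-uncertainty-
#' aware score variance `V = ybar (1 - ybar) sum_i (e_i - ebar)(e_i - ebar)'`.
#' The statistic is `U' V^- U` (Moore-Penrose inverse), chi-square with
#' `df = rank(V) <= h - 1`. With phase-unambiguous data the statistic
#' coincides with the Pearson contingency statistic on the subject-level
#' haplotype-by-phenotype count table.
#'
#' @param geno genotype matrix for the window (subjects by k SNPs).
#' @param phenotype 0/1 per subject.
#' @param min_count minimum estimated haplotype count to score (default 20).
#' @param rare `"exclude"` (default) drops rare haplotypes from the score
#'   vector; `"pool"` merges them into one pseudo-haplotype.
#' @param rel_tol relative eigenvalue tolerance for the generalized inverse.
#' @return a `score_test` list: `statistic`, `df`, `p`, `h` (retained
#'   haplotype count), `reference`, `est_counts`, `freqs` (the `hap_freqs`),
#'   `untestable` flag with `reason`.
#' @export
global_score_test <- function(geno, phenotype, min_count = 20,
                              rare = c("exclude", "pool"), rel_tol = 1e-10) {
  rare <- match.arg(rare)
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == length(phenotype))
  untestable <- function(reason, em = NULL)
    structure(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                   h = NA_integer_, reference = NA_character_,
                   est_counts = NULL, freqs = em,
                   untestable = TRUE, reason = reason),
              class = "score_test")
  em <- em_hap_freqs(geno)
  use <- em$subjects_used
  y <- as.integer(phenotype[use])
  if (length(unique(y)) < 2L) return(untestable("single phenotype class", em))
  n <- length(use)
  est_counts <- 2 * n * em$freq
  keep <- est_counts >= min_count
  e <- em$dosage
  labels <- em$haplotypes
  if (rare == "pool" && any(!keep)) {
    e <- cbind(e[, keep, drop = FALSE],
               pooled = rowSums(e[, !keep, drop = FALSE]))
    est_counts <- c(est_counts[keep], sum(est_counts[!keep]))
    labels <- c(labels[keep], "pooled")
  } else {
    e <- e[, keep, drop = FALSE]
    est_counts <- est_counts[keep]
    labels <- labels[keep]
  }
  h <- length(labels)
  if (h < 2L) return(untestable("fewer than 2 scorable haplotypes", em))
  ref <- which.max(est_counts)
  e <- e[, -ref, drop = FALSE]
  ybar <- mean(y)
  U <- crossprod(e, y - ybar)
  ec <- sweep(e, 2, colMeans(e))
  V <- ybar * (1 - ybar) * crossprod(ec)
  q <- ginv_quad(V, U, rel_tol)
  if (q$df == 0L) return(untestable("degenerate score variance", em))
  structure(list(statistic = q$stat, df = q$df,
                 p = stats::pchisq(q$stat, q$df, lower.tail = FALSE),
                 h = h, reference = labels[ref],
                 est_counts = stats::setNames(est_counts, labels),
                 freqs = em, untestable = FALSE, reason = NULL),
            class = "score_test")
}

#' @exportS3Method base::print
print.score_test <- function(x, ...) {
  if (x$untestable) {
    cat("score_test: untestable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("score_test: X2 %.4f, df %d, p %s (h = %d, ref %s)\n",
                x$statistic, x$df, format(x$p, digits = 3), x$h,
                x$reference))
  }
  invisible(x)
}

#' Overlap between two sets of flagged gene windows
#'
#' Set-intersection summary used to compare methods: how many of the gene
#' windows flagged by one method (e.g. carrying a replicated logic tree)
#' were also flagged by another (e.g. containing a Bonferroni-significant
#' sliding-window haplotype).
#'
#' @param ids_a,ids_b character vectors of window ids flagged by each method.
#' @return list with `n_a`, `n_b`, `n_shared`, and `fraction_a_in_b`
#'   (`n_shared / n_a`).
#' @export
method_overlap <- function(ids_a, ids_b) {
  a <- unique(ids_a)
  b <- unique(ids_b)
  shared <- intersect(a, b)
  list(n_a = length(a), n_b = length(b), n_shared = length(shared),
       fraction_a_in_b = if (length(a)) length(shared) / length(a)
                         else NA_real_)
}

#' Contiguous sliding windows over an ordered SNP index list
#'
#' @param snp_indices variant indices ordered by position.
#' @param size window size in SNPs (default 3).
#' @param skip skip length between starts (default 1).
#' @return list of index vectors; empty when fewer than `size` SNPs.
#' @export
sliding_windows <- function(snp_indices, size = 3L, skip = 1L) {
  n <- length(snp_indices)
  if (n < size) return(list())
  lapply(seq(1L, n - size + 1L, by = skip), function(i)
    snp_indices[i:(i + size - 1L)])
}

#' Exhaustive sliding-window benchmark scan
#'
#' Runs the global score test on every contiguous 3-SNP sliding window of
#' every gene analytic window (using all mapped SNPs, not the LD-pruned tag
#' set) and reports the total test count and the Bonferroni threshold over
#' it.
#'
#' @param cohort a [phased_cohort()]; genotypes are derived by collapsing
#'   the phased alleles.
#' @param windows list of `gene_window` objects.
#' @param alpha family-wise error rate (default 0.05).
#' @param min_count rare-haplotype cutoff passed to [global_score_test()].
#' @param size,skip sliding-window geometry (defaults 3 and 1).
#' @return list with `results` (one row per test: window id, SNP triple,
#'   `h`, `statistic`, `df`, `p`), `best` (best p per gene window),
#'   `n_tests`, `threshold`.
#' @export
benchmark_scan <- function(cohort, windows, alpha = 0.05, min_count = 20,
                           size = 3L, skip = 1L) {
  geno <- cohort_genotypes(cohort)
  y <- cohort$subjects$phenotype
  rows <- list()
  for (w in windows) {
    for (trip in sliding_windows(w$snp_indices_all, size, skip)) {
      st <- global_score_test(geno[, trip, drop = FALSE], y,
                              min_count = min_count)
      rows[[length(rows) + 1L]] <- data.frame(
        window_id = w$window_id,
        snps = paste(cohort$variants$id[trip], collapse = ","),
        h = st$h, statistic = st$statistic, df = st$df, p = st$p,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  n_tests <- nrow(results)
  thr <- if (n_tests > 0) bonferroni_threshold(alpha, n_tests) else NA_real_
  best <- if (n_tests > 0) {
    do.call(rbind, lapply(split(results, results$window_id), function(df) {
      df[which.min(replace(df$p, is.na(df$p), Inf)), , drop = FALSE]
    }))
  } else data.frame()
  list(results = results, best = best, n_tests = n_tests, threshold = thr)
}
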