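# Subject-level additive haplotype association model
#   logit(p) = beta0 + beta1 * L,   L in {0, 1, 2}
# with grouped-count fitting, printed-table count reconstruction, Bonferroni
# thresholds, and the replication protocol.

#' Fit the additive haplotype logistic model
#'
#' Maximum-likelihood logistic regression of case status on the haplotype
#' copy count `L`, treating each subject as one observation. Subject-level
#' input is aggregated to grouped binomial counts before fitting, so grouped
#' and ungrouped inputs give identical estimates by construction. The p-value
#' is a two-sided Wald test.
#'
#' @param L per-subject copy counts in `{0, 1, 2}` (`NA` dropped), or `NULL`
#'   when `grouped` is given.
#' @param phenotype per-subject 0/1 status, aligned with `L`.
#' @param grouped alternatively, a data frame with columns `L`, `n`
#'   (group size) and `cases`.
#' @return a `hap_assoc` list: `beta0`, `beta1`, `or` (= `exp(beta1)`),
#'   `se`, `p`, `direction` (`sign(beta1)`), `n` (subjects used), `grouped`,
#'   `flag` (`"ok"` or `"separation"`, in which case `p` is omitted).
#' @export
fit_additive <- function(L = NULL, phenotype = NULL, grouped = NULL) {
  if (is.null(grouped)) {
    stopifnot(length(L) == length(phenotype))
    ok <- !is.na(L) & !is.na(phenotype)
    L <- L[ok]
    phenotype <- as.integer(phenotype[ok])
    grouped <- do.call(rbind, lapply(sort(unique(L)), function(l)
      data.frame(L = l, n = sum(L == l),
                 cases = sum(phenotype[L == l]))))
  }
  grouped <- as.data.frame(grouped)
  stopifnot(all(c("L", "n", "cases") %in% names(grouped)),
            all(grouped$cases >= 0), all(grouped$cases <= grouped$n))
  grouped <- grouped[grouped$n > 0, , drop = FALSE]
  if (length(unique(grouped$L)) < 2L)
    stop("no haplotype variation: a single copy-count group carries no slope")
  if (sum(grouped$cases) == 0 || sum(grouped$n - grouped$cases) == 0)
    stop("both outcome classes must be present")
  fit <- suppressWarnings(stats::glm(
    cbind(cases, n - cases) ~ L, family = stats::binomial(),
    data = grouped, control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 200)))
  beta <- stats::coef(fit)
  mu <- stats::fitted(fit)
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8) || abs(beta[2]) > 20
  se <- sqrt(diag(stats::vcov(fit)))[2]
  p <- if (separated) NA_real_ else unname(2 * stats::pnorm(-abs(beta[2] / se)))
  structure(list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 or = unname(exp(beta[2])), se = unname(se), p = p,
                 direction = sign(unname(beta[2])), n = sum(grouped$n),
                 grouped = grouped,
                 flag = if (separated) "separation" else "ok"),
            class = "hap_assoc")
}

#' @exportS3Method base::print
print.hap_assoc <- function(x, ...) {
  cat(sprintf("hap_assoc: OR %.3f (beta1 %.4f), p %s, n %d%s\n",
              x$or, x$beta1,
              if (is.na(x$p)) "NA" else format(x$p, digits = 3), x$n,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Reconstruct integer grouped counts from printed percentages
#'
#' Inverts the published display "`# with k haplotype copies (% cases)`":
#' for each group, the admissible case counts are the integers whose exact
#' percentage rounds (half-up, one decimal) to the printed value; the unique
#' combination summing to the known total case count is returned.
#'
#' @param group_sizes integer group sizes (one per copy-count group).
#' @param pct_cases printed one-decimal percentages of cases per group.
#' @param total_cases total number of cases across the groups.
#' @return data frame with `L` (0, 1, 2 in input order), `n`, `cases`.
#' @export
reconstruct_group_counts <- function(group_sizes, pct_cases, total_cases) {
  stopifnot(length(group_sizes) == length(pct_cases), length(group_sizes) >= 1)
  cand <- lapply(seq_along(group_sizes), function(i) {
    n <- group_sizes[i]
    c0 <- 0:n
    c0[abs(round_half_up(100 * c0 / n, 1) - pct_cases[i]) < 1e-9]
  })
  if (any(lengths(cand) == 0))
    stop("no consistent solution: a printed percentage matches no integer count")
  grid <- do.call(expand.grid, cand)
  hit <- which(rowSums(grid) == total_cases)
  if (length(hit) == 0)
    stop("no consistent solution: no candidate combination sums to ",
         total_cases)
  if (length(hit) > 1)
    stop("ambiguous reconstruction: ", length(hit),
         " combinations sum to the total (",
         paste(apply(grid[hit, , drop = FALSE], 1, paste, collapse = "/"),
               collapse = "; "), ")")
  data.frame(L = seq_along(group_sizes) - 1L, n = as.integer(group_sizes),
             cases = as.integer(unlist(grid[hit, ])), row.names = NULL)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests (at least 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(length(m) == 1, m >= 1)
  alpha / m
}

#' Replication protocol for selected haplotypes
#'
#' Each candidate tree is refit with the additive model in the replication
#' cohort. A candidate replicates iff its replication p-value is strictly
#' below the Bonferroni-corrected per-test threshold `alpha / m` (m = number
#' of candidates) AND the replication odds ratio lies on the same side of 1
#' as in discovery. A combined-cohort fit (all subjects pooled, no cohort
#' covariate) is also reported. Candidates whose copy counts cannot be
#' formed or show no variation in replication are verdict `"untestable"`.
#'
#' @param trees list of candidate logic trees.
#' @param cohort a [phased_cohort()] containing both cohorts.
#' @param alpha family-wise error rate for replication (default 0.05).
#' @param discovery_label,replication_label cohort labels.
#' @return data frame with per-candidate discovery/replication/combined OR
#'   and p, the verdict, and the threshold as attribute `"threshold"`.
#' @export
replicate_candidates <- function(trees, cohort, alpha = 0.05,
                                 discovery_label = "discovery",
                                 replication_label = "replication") {
  stopifnot(length(trees) >= 1)
  m <- length(trees)
  thr <- bonferroni_threshold(alpha, m)
  disc <- split_cohort(cohort, discovery_label)
  repl <- split_cohort(cohort, replication_label)
  safe_fit <- function(tree, coh) {
    tryCatch({
      if (max(tree_snps(tree)) > nrow(coh$variants))
        stop("tree SNP absent from cohort")
      fit_additive(copy_count(tree, coh), coh$subjects$phenotype)
    }, error = function(e) NULL)
  }
  rows <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    fd <- safe_fit(tr, disc)
    fr <- safe_fit(tr, repl)
    fc <- safe_fit(tr, cohort)
    untestable <- is.null(fd) || is.null(fr) ||
      is.na(fr$p %||% NA_real_) || is.na(fd$p %||% NA_real_)
    replicated <- !untestable && fr$p < thr && fr$direction == fd$direction
    data.frame(
      tree_text = format_tree(tr, cohort$variants),
      or_disc = if (is.null(fd)) NA_real_ else fd$or,
      p_disc = if (is.null(fd)) NA_real_ else fd$p,
      or_rep = if (is.null(fr)) NA_real_ else fr$or,
      p_rep = if (is.null(fr)) NA_real_ else fr$p,
      or_comb = if (is.null(fc)) NA_real_ else fc$or,
      p_comb = if (is.null(fc)) NA_real_ else fc$p,
      verdict = if (untestable) "untestable"
                else if (replicated) "replicated" else "not_replicated",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}

#' Single-SNP additive association
#'
#' Additive (allele-dosage) logistic test for one variant; the nominal
#' univariate screen used to build enrichment comparison SNP sets.
#'
#' @param cohort a [phased_cohort()].
#' @param snp variant column index.
#' @return a `hap_assoc` (dosage plays the role of `L`).
#' @export
single_snp_assoc <- function(cohort, snp) {
  geno <- cohort_genotypes(cohort)[, snp]
  fit_additive(geno, cohort$subjects$phenotype)
}
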