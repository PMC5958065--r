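# Variant and sample quality control.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional-on-allele-counts exact test: the p-value is the summed
#' probability of all heterozygote counts whose conditional probability does
#' not exceed that of the observed count (plain p, no mid-p correction).
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote; the labelling is symmetric).
#' @return the exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na <- 2 * n_aa + n_ab          # allele A count
  nb <- 2 * n_bb + n_ab
  nmin <- min(na, nb)
  if (nmin == 0) return(1)
  hets <- seq(nmin %% 2, nmin, by = 2)
  # log P(n_ab = h | n, na) up to a constant:
  #   n! 2^h / (n_aa! h! n_bb!)  with n_aa, n_bb determined by h
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- (nb - h) / 2
    h * log(2) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Apply variant and sample quality-control filters
#'
#' Variants are filtered first, sequentially: genotype call rate, then minor
#' allele frequency, then an exact Hardy-Weinberg test computed in controls
#' from subject-level genotypes. Samples failing the call-rate threshold over
#' the retained variants are then removed.
#'
#' @param cohort a [phased_cohort()] with at least one control.
#' @param min_call minimum variant genotype call rate (default 0.95).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param min_hwe_p minimum exact HWE p-value in controls (default 0.001).
#' @param min_sample_call minimum per-sample call rate over retained variants
#'   (default 0.97); samples strictly below it are excluded.
#' @return a list with the filtered `cohort` and a `report` of class
#'   `qc_report` with per-filter removal counts.
#' @export
qc_filter <- function(cohort, min_call = 0.95, min_maf = 0.05,
                      min_hwe_p = 0.001, min_sample_call = 0.97) {
  if (!any(cohort$subjects$phenotype == 0))
    stop("HWE filtering requires at least one control subject")
  geno <- cohort_genotypes(cohort)
  n_var_in <- nrow(cohort$variants)
  n_sub_in <- n_subjects(cohort)

  call_rate <- colMeans(!is.na(geno))
  fail_call <- call_rate < min_call
  keep <- !fail_call

  af <- colMeans(cohort$haps, na.rm = TRUE)
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  fail_maf <- keep & (maf < min_maf)
  keep <- keep & !fail_maf

  ctrl <- which(cohort$subjects$phenotype == 0)
  fail_hwe <- rep(FALSE, n_var_in)
  for (j in which(keep)) {
    g <- geno[ctrl, j]
    g <- g[!is.na(g)]
    p <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    if (p < min_hwe_p) fail_hwe[j] <- TRUE
  }
  keep <- keep & !fail_hwe

  if (!any(keep)) {
    report <- qc_report(n_var_in, 0L, n_sub_in, n_sub_in,
                        sum(fail_call), sum(fail_maf), sum(fail_hwe), 0L)
    cond <- structure(
      class = c("haplogic_qc_error", "error", "condition"),
      list(message = "all variants removed by QC filters",
           call = sys.call(-1), report = report))
    stop(cond)
  }

  out <- subset_variants(cohort, which(keep))
  sample_call <- rowMeans(!is.na(cohort_genotypes(out)))
  keep_sub <- sample_call >= min_sample_call
  n_sub_removed <- sum(!keep_sub)
  if (n_sub_removed > 0) out <- subset_subjects(out, which(keep_sub))

  report <- qc_report(n_var_in, sum(keep), n_sub_in, sum(keep_sub),
                      sum(fail_call), sum(fail_maf), sum(fail_hwe),
                      n_sub_removed)
  list(cohort = out, report = report)
}

qc_report <- function(n_var_in, n_var_out, n_sub_in, n_sub_out,
                      rm_call, rm_maf, rm_hwe, rm_sample) {
  structure(list(
    n_variants_in = n_var_in, n_variants_out = n_var_out,
    n_subjects_in = n_sub_in, n_subjects_out = n_sub_out,
    removed = c(call_rate = rm_call, maf = rm_maf, hwe = rm_hwe,
                sample_call = rm_sample)),
    class = "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC: variants", x$n_variants_in, "->", x$n_variants_out,
      sprintf("(call_rate -%d, maf -%d, hwe -%d)",
              x$removed[["call_rate"]], x$removed[["maf"]],
              x$removed[["hwe"]]), "\n")
  cat("    subjects", x$n_subjects_in, "->", x$n_subjects_out,
      sprintf("(sample_call -%d)", x$removed[["sample_call"]]), "\n")
  invisible(x)
}
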