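#' Phased case-control cohort container
#'
#' Bundles biallelic variant metadata, a phased allele matrix with one row per
#' chromosome copy (rows `2i - 1` and `2i` belong to subject `i`), and the
#' subject table with case/control status and cohort label.
#'
#' @param variants data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per biallelic SNP.
#' @param haps integer matrix of 0/1/`NA` phased alleles, `2 * nrow(subjects)`
#'   rows (chromosome copies) by `nrow(variants)` columns.
#' @param subjects data frame with columns `id`, `phenotype` (0 control /
#'   1 case) and `cohort` (e.g. `"discovery"` / `"replication"`).
#' @return an object of class `phased_cohort`.
#' @export
phased_cohort <- function(variants, haps, subjects) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            all(c("id", "phenotype") %in% names(subjects)))
  if (is.null(subjects$cohort)) subjects$cohort <- "discovery"
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (nrow(haps) != 2L * nrow(subjects))
    stop("haplotype rows (", nrow(haps), ") must equal 2 x subjects (",
         2L * nrow(subjects), ")")
  if (ncol(haps) != nrow(variants))
    stop("haplotype columns must match the variant table")
  bad <- haps[!is.na(haps)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("non-biallelic encoding: phased alleles must be 0, 1 or missing")
  if (anyNA(subjects$phenotype) || !all(subjects$phenotype %in% c(0L, 1L)))
    stop("phenotype must be 0 (control) or 1 (case) for every subject")
  if (any(variants$pos < 1)) stop("variant positions are 1-based (pos >= 1)")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ (biallelic SNPs only)")
  structure(list(variants = variants, haps = haps, subjects = subjects),
            class = "phased_cohort")
}

#' @exportS3Method base::print
print.phased_cohort <- function(x, ...) {
  cat("phased_cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$phenotype == 1), "cases /",
      sum(x$subjects$phenotype == 0), "controls ),",
      nrow(x$variants), "variants\n")
  tab <- table(x$subjects$cohort)
  cat("  cohorts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#'
#' @param cohort a [phased_cohort()].
#' @return integer subject count.
#' @export
n_subjects <- function(cohort) nrow(cohort$subjects)

# Chromosome-level phenotype vector (each subject's status duplicated onto
# both chromosome copies).
chromosome_phenotype <- function(cohort) {
  rep(as.integer(cohort$subjects$phenotype), each = 2L)
}

#' Collapse phased haplotypes to unphased genotypes
#'
#' Sums the two chromosome copies of each subject to allele-count genotypes
#' in `{0, 1, 2}`; a genotype is missing when either copy is missing. This is
#' how the sliding-window benchmark, which models unphased data, consumes a
#' phased cohort.
#'
#' @param cohort a [phased_cohort()].
#' @return integer matrix, subjects by variants.
#' @export
cohort_genotypes <- function(cohort) {
  n <- n_subjects(cohort)
  odd <- cohort$haps[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  even <- cohort$haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  g <- odd + even
  rownames(g) <- cohort$subjects$id
  g
}

#' Subset a cohort by cohort label
#'
#' @param cohort a [phased_cohort()].
#' @param label a cohort label present in the subject table, or `"combined"`
#'   for all subjects.
#' @return a [phased_cohort()] with the matching subjects; the variant list is
#'   unchanged.
#' @export
split_cohort <- function(cohort, label) {
  stopifnot(length(label) == 1)
  if (identical(label, "combined")) return(cohort)
  if (!label %in% cohort$subjects$cohort)
    stop("unknown cohort label: ", label)
  keep <- which(cohort$subjects$cohort == label)
  if (!length(keep)) stop("no subjects with cohort label ", label)
  rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  phased_cohort(cohort$variants, cohort$haps[rows, , drop = FALSE],
                cohort$subjects[keep, , drop = FALSE])
}

# Subset a cohort by variant column indices (keeps subject table).
subset_variants <- function(cohort, cols) {
  phased_cohort(cohort$variants[cols, , drop = FALSE],
                cohort$haps[, cols, drop = FALSE],
                cohort$subjects)
}

# Subset a cohort by subject indices.
subset_subjects <- function(cohort, idx) {
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  phased_cohort(cohort$variants, cohort$haps[rows, , drop = FALSE],
                cohort$subjects[idx, , drop = FALSE])
}
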