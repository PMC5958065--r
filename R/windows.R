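# Gene analytic windows: gene span +/- flank, SNP mapping, LD pruning.

#' Build gene analytic windows
#'
#' Each gene's transcripts are merged to a single span (minimum start,
#' maximum end), extended by `flank` base pairs on both sides (clipped at
#' position 1), and all variants on the same chromosome falling inside the
#' span (boundaries inclusive) are mapped to the window. Windows with fewer
#' than two mapped SNPs are dropped. Because windows overlap, a window also
#' records every gene whose merged span intersects it.
#'
#' @param genes data frame with `gene_id`, `chrom`, `tx_start`, `tx_end`
#'   (1-based inclusive), `strand` (see [read_gene_table()]).
#' @param variants variant table (`id`, `chrom`, `pos`).
#' @param flank flanking distance in bp added to each side (default 500 kb).
#' @return list of `gene_window` objects, sorted by chromosome and start;
#'   empty (with a warning) when no window retains two SNPs.
#' @export
build_windows <- function(genes, variants, flank = 500000) {
  if (is.null(genes) || nrow(genes) == 0 ||
      is.null(variants) || nrow(variants) == 0) {
    warning("no genes or no variants: returning an empty window list")
    return(list())
  }
  stopifnot(all(genes$tx_start <= genes$tx_end))
  merged <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    if (length(unique(g$chrom)) != 1L)
      stop("gene ", g$gene_id[1], " maps to multiple chromosomes")
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               tx_start = min(g$tx_start), tx_end = max(g$tx_end),
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$tx_start, merged$gene_id), ]
  windows <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    g <- merged[i, ]
    start <- max(1, g$tx_start - flank)
    end <- g$tx_end + flank
    snps <- which(variants$chrom == g$chrom &
                    variants$pos >= start & variants$pos <= end)
    if (length(snps) < 2L) next
    covered <- merged$gene_id[merged$chrom == g$chrom &
                                merged$tx_start <= end &
                                merged$tx_end >= start]
    windows[[i]] <- structure(list(
      window_id = g$gene_id, gene_ids = covered, chrom = g$chrom,
      start = start, end = end,
      snp_indices_all = snps, snp_indices_pruned = snps),
      class = "gene_window")
  }
  windows <- windows[!vapply(windows, is.null, logical(1))]
  if (!length(windows)) warning("no window retained >= 2 mapped SNPs")
  windows
}

#' @exportS3Method base::print
print.gene_window <- function(x, ...) {
  cat("gene_window", x$window_id, sprintf("[%s:%d-%d]", x$chrom, x$start,
                                          x$end),
      length(x$snp_indices_all), "SNPs mapped,",
      length(x$snp_indices_pruned), "after pruning\n")
  invisible(x)
}

#' Haplotypic linkage-disequilibrium r-squared
#'
#' `r^2 = (p_ab - p_a p_b)^2 / (p_a (1 - p_a) p_b (1 - p_b))` computed on
#' phased chromosomes; chromosomes missing at either site are removed first.
#'
#' @param alleles_a,alleles_b 0/1 allele vectors over the same chromosomes.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(alleles_a, alleles_b) {
  stopifnot(length(alleles_a) == length(alleles_b),
            length(alleles_a) >= 2)
  ok <- !is.na(alleles_a) & !is.na(alleles_b)
  a <- alleles_a[ok]
  b <- alleles_b[ok]
  pa <- mean(a)
  pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("undefined r-squared: monomorphic input")
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' LD-prune a window to tagging SNPs
#'
#' Greedy sweep in ascending genomic position: a SNP is kept iff its
#' haplotypic r-squared with every already-kept SNP does not exceed
#' `r2_max`. Monomorphic SNPs (undefined r-squared; they carry no haplotype
#' information) are dropped. Windows falling below two kept SNPs are dropped
#' (`NULL` is returned).
#'
#' @param cohort a [phased_cohort()].
#' @param window a `gene_window` from [build_windows()].
#' @param r2_max maximum tolerated pairwise r-squared (default 0.8).
#' @return the window with `snp_indices_pruned` filled in, or `NULL`.
#' @export
prune_window <- function(cohort, window, r2_max = 0.8) {
  snps <- window$snp_indices_all
  stopifnot(length(snps) >= 2)
  ord <- snps[order(cohort$variants$pos[snps])]
  kept <- integer(0)
  for (s in ord) {
    col <- cohort$haps[, s]
    f <- mean(col, na.rm = TRUE)
    if (is.nan(f) || f %in% c(0, 1)) next
    ok <- TRUE
    for (k in kept) {
      if (ld_r2(col, cohort$haps[, k]) > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, s)
  }
  if (length(kept) < 2L) return(NULL)
  window$snp_indices_pruned <- kept
  window
}

#' Prune a list of windows, dropping those that fall below two SNPs
#'
#' @inheritParams prune_window
#' @param windows list of `gene_window` objects.
#' @return list of pruned windows.
#' @export
prune_windows <- function(cohort, windows, r2_max = 0.8) {
  out <- lapply(windows, prune_window, cohort = cohort, r2_max = r2_max)
  out[!vapply(out, is.null, logical(1))]
}
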