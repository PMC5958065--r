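# Fisher-exact enrichment of haplotype SNPs against a comparison SNP set
# over annotation interval tracks and eQTL indicator tables.

#' Annotation interval track
#'
#' Intervals are stored as on disk: 0-based half-open `[start, end)` per
#' chromosome. Degenerate intervals (`start >= end`) are rejected.
#'
#' @param id track identifier (cell type / assay).
#' @param intervals data frame with `chrom`, `start`, `end`.
#' @return an `annotation_track`.
#' @export
annotation_track <- function(id, intervals) {
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("degenerate interval: start must be < end")
  structure(list(id = id, intervals = intervals), class = "annotation_track")
}

#' Count SNPs overlapping a track
#'
#' A SNP counts once iff its position falls in at least one interval of the
#' track on the same chromosome. Positions are matched against the half-open
#' interval bounds as `start <= pos < end`, so a SNP exactly at an interval's
#' `end` does not count.
#'
#' @param snps variant table (`id`, `chrom`, `pos`).
#' @param track an [annotation_track()].
#' @return integer count.
#' @export
overlap_count <- function(snps, track) {
  sum(snp_overlaps(snps, track))
}

snp_overlaps <- function(snps, track) {
  iv <- track$intervals
  vapply(seq_len(nrow(snps)), function(i) {
    sel <- iv$chrom == snps$chrom[i]
    any(sel & iv$start <= snps$pos[i] & snps$pos[i] < iv$end)
  }, logical(1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass criterion: the p-value is the sum of hypergeometric
#' probabilities (margins fixed) of all tables at most as probable as the
#' observed one. A zero margin yields p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_two_sided <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[match(tab[1, 1], support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Enrichment scan over annotation tracks
#'
#' For each track, builds the 2x2 table of overlap / non-overlap counts for
#' the haplotype SNP set versus a disjoint comparison SNP set and computes a
#' two-sided Fisher exact p-value; the per-track significance threshold is
#' `alpha` divided by the number of tracks in the scan (one assay family per
#' call).
#'
#' @param hap_snps variant table of haplotype SNPs.
#' @param comparison_snps variant table of comparison SNPs (must not share
#'   ids with `hap_snps`).
#' @param tracks list of [annotation_track()] objects.
#' @param alpha family-wise error rate (default 0.05).
#' @return data frame with one row per track: the 2x2 cells, `p`,
#'   `threshold`, `significant`.
#' @export
enrichment_scan <- function(hap_snps, comparison_snps, tracks,
                            alpha = 0.05) {
  if (length(intersect(hap_snps$id, comparison_snps$id)))
    stop("haplotype and comparison SNP sets must be disjoint")
  thr <- bonferroni_threshold(alpha, length(tracks))
  rows <- lapply(tracks, function(tr) {
    a <- overlap_count(hap_snps, tr)
    c_ <- overlap_count(comparison_snps, tr)
    tab <- matrix(c(a, nrow(hap_snps) - a,
                    c_, nrow(comparison_snps) - c_), nrow = 2)
    data.frame(track = tr$id,
               hap_overlap = a, hap_non = nrow(hap_snps) - a,
               comp_overlap = c_, comp_non = nrow(comparison_snps) - c_,
               p = fisher_two_sided(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$threshold <- thr
  out$significant <- out$p < thr
  rownames(out) <- NULL
  out
}

#' eQTL-count enrichment
#'
#' Compares significant cis-eQTL counts between the haplotype SNP set and
#' the comparison set with a two-sided Fisher exact test. With
#' `unit = "pair"` the cells are (significant, non-significant) SNP-gene
#' pairs summed per set (requires `n_sig` and `n_tested` columns); with
#' `unit = "snp"` each SNP collapses to an indicator of carrying at least
#' one significant eQTL.
#'
#' @param hap_ids,comparison_ids SNP id vectors (disjoint).
#' @param eqtl data frame with `snp_id`, `n_sig` and (for `unit = "pair"`)
#'   `n_tested`; SNPs absent from the table count as zero.
#' @param unit `"pair"` (default) or `"snp"`.
#' @return list with the 2x2 `table` and the Fisher `p`.
#' @export
eqtl_enrichment <- function(hap_ids, comparison_ids, eqtl,
                            unit = c("pair", "snp")) {
  unit <- match.arg(unit)
  if (length(intersect(hap_ids, comparison_ids)))
    stop("haplotype and comparison SNP sets must be disjoint")
  get <- function(ids, col) {
    v <- eqtl[[col]][match(ids, eqtl$snp_id)]
    v[is.na(v)] <- 0
    v
  }
  cells <- function(ids) {
    n_sig <- get(ids, "n_sig")
    if (unit == "pair") {
      n_tested <- get(ids, "n_tested")
      c(sum(n_sig), sum(n_tested) - sum(n_sig))
    } else {
      c(sum(n_sig > 0), sum(n_sig == 0))
    }
  }
  tab <- cbind(hap = cells(hap_ids), comparison = cells(comparison_ids))
  rownames(tab) <- c("significant", "not_significant")
  list(table = tab, p = fisher_two_sided(t(tab)))
}
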