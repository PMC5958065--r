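# Synthetic phased case-control cohorts with configurable MAF, adjacent-SNP
# LD (first-order copying chain) and an embedded Boolean-tree risk effect
# acting through the additive copy-count logistic model.

#' Simulation configuration
#'
#' Defaults mirror the study conditions this package targets: 2,886 subjects
#' split a priori into 1,937 discovery and 949 replication, per-SNP minor
#' allele frequencies at or above the 5% QC floor, and a moderate
#' adjacent-SNP copying correlation. The phenotype is generated at the
#' subject level as `Bernoulli(logistic(beta0 + beta1 * L))` with `L` the
#' causal-tree copy count, exactly the model the association stage fits.
#'
#' @param n_subjects total subjects (default 2886).
#' @param n_snps number of biallelic SNPs (default 50).
#' @param maf_range per-SNP minor allele frequency range, drawn uniformly
#'   (default `c(0.05, 0.5)`).
#' @param rho adjacent-SNP copying probability in `[0, 1)`: each allele
#'   copies its left neighbour with probability `rho`, else is drawn fresh
#'   (default 0.3).
#' @param causal_tree optional logic tree over SNP indices `< n_snps`
#'   generating the risk effect; `NULL` for a null cohort.
#' @param beta0,beta1 intercept and per-copy log-odds of the generating
#'   model (defaults 0).
#' @param split named cohort-label fractions (default
#'   `c(discovery = 1937/2886, replication = 949/2886)`).
#' @param chrom chromosome name for the simulated variants.
#' @param pos_spacing mean spacing between adjacent SNPs in bp
#'   (default 5000).
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 2886L, n_snps = 50L,
                       maf_range = c(0.05, 0.5), rho = 0.3,
                       causal_tree = NULL, beta0 = 0, beta1 = 0,
                       split = c(discovery = 1937 / 2886,
                                 replication = 949 / 2886),
                       chrom = "1", pos_spacing = 5000, seed = 1L) {
  stopifnot(n_subjects >= 1, n_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            rho >= 0, rho < 1,
            abs(sum(split) - 1) < 1e-9)
  if (!is.null(causal_tree)) {
    stopifnot(max(tree_snps(causal_tree)) <= n_snps)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 rho = rho, causal_tree = causal_tree,
                 beta0 = beta0, beta1 = beta1, split = split,
                 chrom = chrom, pos_spacing = pos_spacing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a phased case-control cohort
#'
#' Haplotypes are drawn independently per chromosome copy: the first SNP is
#' Bernoulli(MAF), and each subsequent allele copies its left neighbour with
#' probability `rho` or is drawn fresh from its own MAF. Each subject is two
#' independent haplotypes; case status follows the additive copy-count
#' logistic model of the causal tree (or `Bernoulli(logistic(beta0))` for a
#' null cohort). Fixed seeds give bit-identical cohorts.
#'
#' @param config a [sim_config()].
#' @return list with the `cohort` (a [phased_cohort()]) and `truth` (a
#'   `truth_record` list: the causal tree, its realized per-haplotype
#'   satisfaction frequency, the realized case fraction, and a
#'   `monomorphic_tree` warning flag).
#' @export
simulate_phased_cohort <- function(config = sim_config()) {
  with_seed(config$seed, {
    n <- config$n_subjects
    m <- config$n_snps
    nh <- 2L * n
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    haps <- matrix(0L, nh, m)
    haps[, 1] <- stats::rbinom(nh, 1L, maf[1])
    if (m > 1) {
      fresh <- vapply(seq_len(m), function(j)
        stats::rbinom(nh, 1L, maf[j]), integer(nh))
      copy <- matrix(stats::runif(nh * m) < config$rho, nh, m)
      for (j in 2:m) {
        haps[, j] <- ifelse(copy[, j], haps[, j - 1L], fresh[, j])
      }
    }
    pos <- cumsum(1L + stats::rpois(m, config$pos_spacing))
    variants <- data.frame(
      id = sprintf("snp%05d", seq_len(m)), chrom = config$chrom,
      pos = as.integer(pos), ref = "A", alt = "G",
      stringsAsFactors = FALSE)
    if (!is.null(config$causal_tree)) {
      L <- copy_count(config$causal_tree, haps)
      sat_freq <- mean(tree_indicator(config$causal_tree, haps))
    } else {
      L <- rep(0L, n)
      sat_freq <- NA_real_
    }
    p <- stats::plogis(config$beta0 + config$beta1 * L)
    pheno <- stats::rbinom(n, 1L, p)
    n_per <- round(config$split * n)
    n_per[length(n_per)] <- n - sum(n_per[-length(n_per)])
    labels <- rep(names(config$split), times = n_per)
    subjects <- data.frame(id = sprintf("subj%05d", seq_len(n)),
                           phenotype = pheno, cohort = labels,
                           stringsAsFactors = FALSE)
    truth <- structure(list(
      causal_tree = config$causal_tree,
      satisfaction_frequency = sat_freq,
      case_fraction = mean(pheno),
      monomorphic_tree = !is.na(sat_freq) && sat_freq %in% c(0, 1)),
      class = "truth_record")
    if (isTRUE(truth$monomorphic_tree))
      warning("causal tree is monomorphic in the simulated haplotypes")
    list(cohort = phased_cohort(variants, haps, subjects), truth = truth)
  })
}

#' Simulate a gene annotation table
#'
#' Random non-nested gene spans on one chromosome, sorted by start.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param gene_length_range span length range in bp.
#' @param chrom chromosome name.
#' @param seed seed.
#' @return data frame with `gene_id`, `chrom`, `tx_start`, `tx_end`,
#'   `strand`.
#' @export
simulate_gene_table <- function(n_genes, chrom_length,
                                gene_length_range = c(1000, 100000),
                                chrom = "1", seed = 1L) {
  stopifnot(gene_length_range[2] <= chrom_length)
  if (n_genes == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      tx_start = integer(0), tx_end = integer(0),
                      strand = character(0)))
  with_seed(seed, {
    for (attempt in 1:20) {
      starts <- sort(sample.int(chrom_length, n_genes * 2))
      lens <- sample(gene_length_range[1]:gene_length_range[2],
                     n_genes * 2, replace = TRUE)
      ends <- pmin(starts + lens - 1L, chrom_length)
      keep <- integer(0)
      max_end <- 0
      for (i in seq_along(starts)) {   # drop nested spans
        if (ends[i] > max_end) {
          keep <- c(keep, i)
          max_end <- ends[i]
        }
      }
      if (length(keep) >= n_genes) {
        keep <- keep[seq_len(n_genes)]
        return(data.frame(
          gene_id = sprintf("gene%04d", seq_len(n_genes)),
          chrom = chrom, tx_start = as.integer(starts[keep]),
          tx_end = as.integer(ends[keep]),
          strand = sample(c("+", "-"), n_genes, replace = TRUE),
          stringsAsFactors = FALSE))
      }
    }
    stop("infeasible gene packing for the requested chromosome length")
  })
}

#' Simulate an annotation track covering a SNP subset
#'
#' One padded interval per covered SNP, so
#' `overlap_count(cover_set, track) == nrow(cover_set)` by construction.
#'
#' @param snps variant table.
#' @param cover_ids ids of the SNPs the track must cover (subset of
#'   `snps$id`).
#' @param padding bp added on each side of a covered position.
#' @param id track identifier.
#' @return an [annotation_track()].
#' @export
simulate_tracks <- function(snps, cover_ids, padding = 100,
                            id = "sim_track") {
  stopifnot(all(cover_ids %in% snps$id))
  cov <- snps[snps$id %in% cover_ids, , drop = FALSE]
  intervals <- data.frame(chrom = cov$chrom,
                          start = pmax(0, cov$pos - padding),
                          end = cov$pos + padding + 1)
  annotation_track(id, intervals[seq_len(nrow(cov)), , drop = FALSE])
}

#' Write a simulated cohort to disk
#'
#' Emits the HAPS/SAMPLE pair, a phenotype TSV, an optional gene BED and the
#' truth record as JSON.
#'
#' @param cohort a [phased_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param genes optional gene table to write as BED (0-based half-open).
#' @param truth optional `truth_record` to serialize.
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort", genes = NULL,
                         truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(haps = file.path(dir, paste0(prefix, ".haps")),
             sample = file.path(dir, paste0(prefix, ".sample")),
             pheno = file.path(dir, paste0(prefix, "_pheno.tsv")))
  write_haps_sample(cohort, paths[["haps"]], paths[["sample"]])
  utils::write.table(
    cohort$subjects[, c("id", "phenotype")], paths[["pheno"]],
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(genes)) {
    paths <- c(paths, genes = file.path(dir, paste0(prefix, "_genes.bed")))
    utils::write.table(
      data.frame(genes$chrom, genes$tx_start - 1L, genes$tx_end,
                 genes$gene_id, 0L, genes$strand),
      paths[["genes"]], sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, paste0(prefix, "_truth.json")))
    tr <- unclass(truth)
    if (!is.null(tr$causal_tree)) tr$causal_tree <- format_tree(tr$causal_tree)
    jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}
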