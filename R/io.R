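# Readers and writers for phased cohorts (SHAPEIT HAPS/SAMPLE, phased VCF)
# and small annotation tables.

#' Read a SHAPEIT HAPS/SAMPLE pair
#'
#' The HAPS file is space-delimited with five leading columns (chromosome,
#' variant id, position, reference allele, alternative allele) followed by
#' `2N` allele columns, two per subject in sample order. Alleles must be `0`,
#' `1` or `?` (missing). The SAMPLE file follows the SHAPEIT convention of two
#' header lines; a `pheno` column (0/1) and an optional `cohort` column are
#' read when present.
#'
#' @param haps_path path to the `.haps` file.
#' @param sample_path path to the `.sample` file.
#' @param phenotype optional two-column data frame or TSV path
#'   (`subject id`, `status`) overriding the SAMPLE phenotype column.
#' @return a [phased_cohort()] with variants in file order; column pair `j`
#'   maps to subject `j`.
#' @export
read_haps_sample <- function(haps_path, sample_path, phenotype = NULL) {
  stopifnot(file.exists(haps_path), file.exists(sample_path))
  lines <- readLines(haps_path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, " ", fixed = TRUE)
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop("ragged HAPS file: rows have differing column counts")
  n_hap <- ncols[1] - 5L
  if (n_hap < 2L || n_hap %% 2L != 0L)
    stop("HAPS allele columns must be an even count >= 2")
  m <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  variants <- data.frame(id = m[, 2], chrom = m[, 1],
                         pos = as.integer(m[, 3]),
                         ref = m[, 4], alt = m[, 5],
                         stringsAsFactors = FALSE)
  al <- m[, -(1:5), drop = FALSE]
  bad <- setdiff(unique(as.vector(al)), c("0", "1", "?"))
  if (length(bad))
    stop("non-biallelic encoding: unexpected allele token(s) ",
         paste(sQuote(bad), collapse = ", "))
  haps <- matrix(NA_integer_, nrow = n_hap, ncol = nrow(variants))
  haps[t(al == "1")] <- 1L
  haps[t(al == "0")] <- 0L

  samp <- read_sample_file(sample_path)
  if (nrow(samp) * 2L != n_hap)
    stop("SAMPLE file lists ", nrow(samp), " subjects but HAPS has ",
         n_hap, " allele columns")
  if (!is.null(phenotype)) {
    ph <- if (is.character(phenotype))
      utils::read.table(phenotype, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else as.data.frame(phenotype)
    names(ph)[1:2] <- c("id", "phenotype")
    samp$phenotype <- ph$phenotype[match(samp$id, ph$id)]
  }
  if (anyNA(samp$phenotype))
    stop("phenotype missing for ", sum(is.na(samp$phenotype)), " subject(s)")
  phased_cohort(variants, haps, samp)
}

read_sample_file <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), " ", fixed = TRUE)[[1]]
  tab <- utils::read.table(path, header = FALSE, skip = 2L,
                           stringsAsFactors = FALSE)
  names(tab) <- hdr[seq_len(ncol(tab))]
  data.frame(
    id = as.character(tab[[1]]),
    phenotype = if ("pheno" %in% names(tab))
      as.integer(tab[["pheno"]]) else NA_integer_,
    cohort = if ("cohort" %in% names(tab))
      as.character(tab[["cohort"]]) else "discovery",
    stringsAsFactors = FALSE)
}

#' Write a cohort as a SHAPEIT HAPS/SAMPLE pair
#'
#' Canonical output: missing alleles become `?`, and the SAMPLE file carries
#' `pheno` and `cohort` columns. `read_haps_sample()` followed by
#' `write_haps_sample()` reproduces a canonically written pair byte for byte.
#'
#' @param cohort a [phased_cohort()].
#' @param haps_path,sample_path output paths.
#' @return the two paths, invisibly.
#' @export
write_haps_sample <- function(cohort, haps_path, sample_path) {
  v <- cohort$variants
  al <- t(cohort$haps)
  al_chr <- matrix(as.character(al), nrow = nrow(al))
  al_chr[is.na(al)] <- "?"
  lines <- paste(v$chrom, v$id, v$pos, v$ref, v$alt,
                 apply(al_chr, 1, paste, collapse = " "))
  writeLines(lines, haps_path)
  s <- cohort$subjects
  writeLines(c("ID_1 ID_2 missing pheno cohort",
               "0 0 0 B D",
               paste(s$id, s$id, 0, s$phenotype, s$cohort)),
             sample_path)
  invisible(c(haps_path, sample_path))
}

#' Read a phased VCF
#'
#' Accepts a VCF 4.x with phased `GT` fields: `"0|1"` places alleles 0 and 1
#' on the subject's two chromosome rows, and `"."` components become missing.
#' Unphased separators (`"/"`) are rejected because phase is required input
#' for haplotype-tree evaluation.
#'
#' @param path path to a (possibly gzipped) VCF.
#' @param phenotype optional two-column data frame or TSV path
#'   (`subject id`, `status`); defaults to all-control phenotypes.
#' @return a [phased_cohort()].
#' @export
read_phased_vcf <- function(path, phenotype = NULL) {
  stopifnot(file.exists(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic records are not supported (biallelic SNPs only)")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  if (any(grepl("/", gt[!is.na(gt)], fixed = TRUE)))
    stop("unphased genotype: all GT fields must use the '|' separator")
  subjects_id <- colnames(gt)
  n <- length(subjects_id)
  split_gt <- function(part) {
    a <- sub("^([^|]*)\\|.*$", "\\1", gt)
    b <- sub("^[^|]*\\|(.*)$", "\\1", gt)
    if (part == 1) a else b
  }
  to_int <- function(x) {
    x[is.na(x) | x == "."] <- NA
    bad <- setdiff(unique(x[!is.na(x)]), c("0", "1"))
    if (length(bad))
      stop("non-biallelic encoding in GT: ", paste(bad, collapse = ", "))
    suppressWarnings(as.integer(x))
  }
  a1 <- matrix(to_int(split_gt(1)), ncol = n)
  a2 <- matrix(to_int(split_gt(2)), ncol = n)
  haps <- matrix(NA_integer_, nrow = 2L * n, ncol = nrow(fix))
  haps[seq(1L, 2L * n, 2L), ] <- t(a1)
  haps[seq(2L, 2L * n, 2L), ] <- t(a2)
  variants <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  subjects <- data.frame(id = subjects_id, phenotype = 0L,
                         cohort = "discovery", stringsAsFactors = FALSE)
  if (!is.null(phenotype)) {
    ph <- if (is.character(phenotype))
      utils::read.table(phenotype, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else as.data.frame(phenotype)
    names(ph)[1:2] <- c("id", "phenotype")
    subjects$phenotype <- as.integer(ph$phenotype[match(subjects$id, ph$id)])
  }
  phased_cohort(variants, haps, subjects)
}

#' Read a BED-like gene table
#'
#' Expects tab-separated `chrom, start, end, gene_id, strand`, 0-based
#' half-open on disk; spans are converted to 1-based inclusive coordinates.
#'
#' @param path TSV/BED path (no header).
#' @return data frame with `gene_id`, `chrom`, `tx_start`, `tx_end`, `strand`.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(gene_id = tab[[4]], chrom = as.character(tab[[1]]),
             tx_start = as.integer(tab[[2]]) + 1L,
             tx_end = as.integer(tab[[3]]),
             strand = if (ncol(tab) >= 5) tab[[5]] else "+",
             stringsAsFactors = FALSE)
}

#' Read a BED interval track
#'
#' Intervals stay in their on-disk 0-based half-open convention; see
#' [overlap_count()] for how SNP positions are matched against them.
#'
#' @param path BED path (chrom, start, end, ...).
#' @param id track identifier (defaults to the file name).
#' @return an [annotation_track()].
#' @export
read_bed_track <- function(path, id = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  annotation_track(id, data.frame(chrom = as.character(tab[[1]]),
                                  start = as.numeric(tab[[2]]),
                                  end = as.numeric(tab[[3]]),
                                  stringsAsFactors = FALSE))
}
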