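test_that("window spans: flank arithmetic, inclusive bounds, clipping", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                      tx_start = c(1000000L, 200000L),
                      tx_end = c(1010000L, 210000L), strand = "+")
  variants <- data.frame(id = paste0("v", 1:5), chrom = "1",
                         pos = c(499999L, 500000L, 1510000L, 1510001L,
                                 700000L),
                         ref = "A", alt = "G")
  w <- build_windows(genes, variants, flank = 500000)
  wa <- w[[which(vapply(w, `[[`, "", "window_id") == "gA")]]
  expect_equal(c(wa$start, wa$end), c(500000, 1510000))
  # boundary SNPs: 499999 out, 500000 in, 1510000 in, 1510001 out
  expect_setequal(variants$id[wa$snp_indices_all], c("v2", "v3", "v5"))
  wb <- w[[which(vapply(w, `[[`, "", "window_id") == "gB")]]
  expect_equal(wb$start, 1)  # clipped at chromosome start
})

test_that("window construction is order-independent and merges transcripts", {
  set.seed(2)
  genes <- simulate_gene_table(6, 2e6, c(5000, 50000), seed = 4)
  genes <- rbind(genes, within(genes[2, ], tx_end <- tx_end + 3000L))
  variants <- data.frame(id = paste0("v", 1:300), chrom = "1",
                         pos = sort(sample.int(2e6, 300)), ref = "A",
                         alt = "G")
  w1 <- build_windows(genes, variants, flank = 100000)
  w2 <- build_windows(genes[sample(nrow(genes)), ], variants,
                      flank = 100000)
  expect_identical(lapply(w1, unclass), lapply(w2, unclass))
  # merged transcript span: single window for the duplicated gene id
  ids <- vapply(w1, `[[`, "", "window_id")
  expect_equal(sum(ids == genes$gene_id[2]), 1)
  # overlapping windows may share variants
  if (length(w1) >= 2) {
    counts <- table(unlist(lapply(w1, `[[`, "snp_indices_all")))
    expect_gte(max(counts), 2)
  }
})

test_that("ld_r2 matches haplotype-count arithmetic", {
  expect_equal(ld_r2(c(0, 1, 0, 1, 1, 0), c(0, 1, 0, 1, 1, 0)), 1)
  a <- rep(c(1, 1, 0, 0), each = 2)
  b <- rep(c(1, 0, 1, 0), each = 2)   # AB=Ab=aB=ab=2: independence
  expect_equal(ld_r2(a, b), 0)
  # AB=3, Ab=1, aB=1, ab=3: D = 0.125, denominators 0.25 * 0.25
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(ld_r2(a, b), 0.25)
  expect_error(ld_r2(c(0, 0, 0), c(0, 1, 0)), "undefined r-squared")
})

test_that("greedy pruning keeps the position-first independent set", {
  n <- 40
  set.seed(8)
  s1 <- rbinom(2 * n, 1, 0.5)
  s3 <- rbinom(2 * n, 1, 0.5)
  haps <- cbind(s1, s1, s3)   # r2(1,2) = 1; r2(1,3), r2(2,3) small
  pheno <- rep(c(0, 1), length.out = n)
  co <- toy_cohort(haps, pheno)
  w <- prune_window(co, make_window(1:3), r2_max = 0.8)
  expect_equal(w$snp_indices_pruned, c(1L, 3L))
  # identical duplicated column always removed; orthogonal columns all kept
  co2 <- toy_cohort(cbind(s1, s3, rbinom(2 * n, 1, 0.5)), pheno)
  w2 <- prune_window(co2, make_window(1:3), r2_max = 0.8)
  expect_true(length(w2$snp_indices_pruned) >= 2)
})

test_that("pruned sets always satisfy the pairwise r2 bound", {
  for (seed in 1:8) {
    sim <- simulate_phased_cohort(sim_config(n_subjects = 120, n_snps = 12,
                                             rho = 0.8, seed = seed))
    co <- sim$cohort
    w <- prune_window(co, make_window(1:12), r2_max = 0.5)
    if (is.null(w)) next
    kept <- w$snp_indices_pruned
    prs <- utils::combn(kept, 2)
    for (i in seq_len(ncol(prs))) {
      expect_lte(ld_r2(co$haps[, prs[1, i]], co$haps[, prs[2, i]]), 0.5)
    }
  }
})
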