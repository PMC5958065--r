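test_that("simulated MAF and case fraction track the configuration", {
  sim <- simulate_phased_cohort(sim_config(n_subjects = 5000, n_snps = 12,
    rho = 0, maf_range = c(0.2, 0.2), beta0 = 0, beta1 = 0, seed = 1))
  co <- sim$cohort
  af <- colMeans(co$haps)
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_true(all(abs(pmin(af, 1 - af) - 0.2) < 3.5 * se + 0.002))
  # beta0 = beta1 = 0: case fraction near 0.5
  expect_lt(abs(sim$truth$case_fraction - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("cohorts are reproducible and rho = 0 leaves adjacent SNPs free", {
  c1 <- simulate_phased_cohort(sim_config(n_subjects = 50, n_snps = 6,
                                          seed = 5))$cohort
  c2 <- simulate_phased_cohort(sim_config(n_subjects = 50, n_snps = 6,
                                          seed = 5))$cohort
  expect_identical(c1$haps, c2$haps)
  expect_identical(c1$subjects, c2$subjects)
  sim <- simulate_phased_cohort(sim_config(n_subjects = 1000, n_snps = 10,
                                           rho = 0, seed = 6))
  co <- sim$cohort
  r2 <- vapply(1:9, function(j) ld_r2(co$haps[, j], co$haps[, j + 1]),
               numeric(1))
  expect_lt(mean(r2), 0.05)
  # and rho = 0.6 induces visible adjacent correlation
  sim2 <- simulate_phased_cohort(sim_config(n_subjects = 1000, n_snps = 10,
                                            rho = 0.6, seed = 6))
  r2h <- vapply(1:9, function(j)
    ld_r2(sim2$cohort$haps[, j], sim2$cohort$haps[, j + 1]), numeric(1))
  expect_gt(mean(r2h), mean(r2))
})

test_that("causal trees shift risk through the additive model", {
  tr <- lt_or(lt_leaf(2, 1), lt_and(lt_leaf(4, 1), lt_leaf(6, 1)))
  sim <- simulate_phased_cohort(sim_config(n_subjects = 3000, n_snps = 8,
    causal_tree = tr, beta0 = -1, beta1 = log(3), seed = 12))
  co <- sim$cohort
  L <- copy_count(tr, co)
  fit <- fit_additive(L, co$subjects$phenotype)
  expect_lt(abs(fit$beta1 - log(3)), 3 * fit$se)
  expect_gt(sim$truth$satisfaction_frequency, 0)
  expect_lt(sim$truth$satisfaction_frequency, 1)
  expect_false(sim$truth$monomorphic_tree)
})

test_that("gene tables are sorted, bounded, non-nested and reproducible", {
  g1 <- simulate_gene_table(12, 5e6, c(2000, 80000), seed = 9)
  g2 <- simulate_gene_table(12, 5e6, c(2000, 80000), seed = 9)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 12)
  expect_true(all(diff(g1$tx_start) > 0))
  expect_true(all(diff(g1$tx_end) > 0))   # non-nested
  expect_true(all(g1$tx_start >= 1 & g1$tx_end <= 5e6))
  expect_equal(nrow(simulate_gene_table(0, 1e6)), 0)
})

test_that("simulated tracks cover exactly the requested SNPs", {
  sim <- simulate_phased_cohort(sim_config(n_subjects = 10, n_snps = 20,
                                           seed = 3))
  v <- sim$cohort$variants
  cover <- v$id[c(2, 5, 9, 14, 18)]
  track <- simulate_tracks(v, cover, padding = 50)
  expect_equal(overlap_count(v[v$id %in% cover, ], track), 5)
  # non-covered SNPs are untouched when spacing exceeds the padding
  others <- v[!v$id %in% cover, ]
  expect_equal(overlap_count(others, track), 0)
  empty <- simulate_tracks(v, character(0))
  expect_equal(overlap_count(v, empty), 0)
})

test_that("write_cohort emits readable HAPS/SAMPLE plus sidecar files", {
  sim <- simulate_phased_cohort(sim_config(n_subjects = 12, n_snps = 4,
                                           seed = 8))
  genes <- simulate_gene_table(3, 1e6, c(1000, 5000), seed = 2)
  d <- tempfile()
  paths <- write_cohort(sim$cohort, d, "toy", genes = genes,
                        truth = sim$truth)
  expect_true(all(file.exists(paths)))
  back <- read_haps_sample(paths[["haps"]], paths[["sample"]])
  expect_identical(back$haps, sim$cohort$haps)
  genes_back <- read_gene_table(paths[["genes"]])
  expect_equal(genes_back$tx_start, genes$tx_start)
  expect_equal(genes_back$tx_end, genes$tx_end)
})
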