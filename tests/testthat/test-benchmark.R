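test_that("EM resolves unambiguous and toy windows to known frequencies", {
  # no ambiguity: (0,0) and (2,2) subjects
  em <- em_hap_freqs(rbind(c(0, 0), c(2, 2)))
  expect_equal(sort(stats::setNames(em$freq, em$haplotypes)[c("00", "11")]),
               sort(c("00" = 0.5, "11" = 0.5)))
  # single double-heterozygote: symmetric stationary point 0.25 each
  em2 <- em_hap_freqs(matrix(c(1, 1), nrow = 1))
  expect_equal(unname(em2$freq), rep(0.25, 4), tolerance = 1e-12)
  # five (0,0), four (2,2), one (1,1): het resolved as 00/11 -> 0.55/0.45
  g <- rbind(matrix(0, 5, 2), matrix(2, 4, 2), c(1, 1))
  em3 <- em_hap_freqs(g)
  freqs <- stats::setNames(em3$freq, em3$haplotypes)
  expect_equal(unname(freqs["00"]), 0.55, tolerance = 1e-6)
  expect_equal(unname(freqs["11"]), 0.45, tolerance = 1e-6)
  expect_error(em_hap_freqs(matrix(NA, 3, 2)), "missing")
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  set.seed(12)
  for (i in 1:6) {
    sim <- simulate_phased_cohort(sim_config(n_subjects = 60, n_snps = 3,
                                             rho = 0.4, seed = 700 + i))
    em <- em_hap_freqs(cohort_genotypes(sim$cohort))
    expect_true(all(diff(em$loglik_trace) > -1e-10))
    expect_true(em$converged)
  }
})

test_that("EM frequencies match true phased proportions at n = 2000", {
  sim <- simulate_phased_cohort(sim_config(n_subjects = 2000, n_snps = 3,
                                           rho = 0.4, seed = 81))
  co <- sim$cohort
  truth <- table(apply(co$haps, 1, paste, collapse = "")) / nrow(co$haps)
  em <- em_hap_freqs(cohort_genotypes(co))
  est <- stats::setNames(em$freq, em$haplotypes)
  for (h in names(truth)) {
    se <- sqrt(truth[[h]] * (1 - truth[[h]]) / nrow(co$haps))
    expect_lt(abs(est[[h]] - truth[[h]]), 4 * se + 0.01)
  }
})

test_that("phase-known score statistic equals the contingency oracle", {
  # 40 fully homozygous subjects: phase is certain
  set.seed(4)
  blocks <- list(c(0, 0, 0), c(2, 0, 0), c(0, 2, 2), c(2, 2, 2))
  g <- do.call(rbind, rep(lapply(blocks, rbind), times = c(12, 10, 10, 8)))
  y <- rbinom(40, 1, 0.5)
  st <- global_score_test(g, y, min_count = 2)
  hap <- apply(g / 2, 1, paste, collapse = "")
  oracle <- suppressWarnings(
    stats::chisq.test(table(hap, y), correct = FALSE)$statistic)
  expect_equal(st$statistic, unname(oracle), tolerance = 1e-8)
  expect_equal(st$df, 3)          # h = 4 retained -> h - 1
  expect_equal(st$h, 4)
})

test_that("rare haplotypes are excluded (or pooled) and df tracks rank", {
  set.seed(19)
  sim <- simulate_phased_cohort(sim_config(n_subjects = 150, n_snps = 3,
                                           rho = 0, seed = 44))
  co <- sim$cohort
  y <- co$subjects$phenotype
  g <- cohort_genotypes(co)
  st <- global_score_test(g, y, min_count = 20)
  expect_lte(st$df, st$h - 1)
  expect_true(all(st$est_counts >= 20))
  stp <- global_score_test(g, y, min_count = 20, rare = "pool")
  expect_gte(stp$h, st$h)
  # impossible scoring set -> untestable
  st2 <- global_score_test(g, y, min_count = 1e6)
  expect_true(st2$untestable)
})

test_that("sliding windows follow size/skip geometry", {
  expect_length(sliding_windows(1:5), 3)
  expect_length(sliding_windows(1:3), 1)
  expect_length(sliding_windows(1:2), 0)
  expect_equal(sliding_windows(c(4L, 9L, 11L, 20L))[[2]], c(9L, 11L, 20L))
})

test_that("method overlap is plain set arithmetic", {
  ov <- method_overlap(c("w1", "w2", "w3", "w3"), c("w2", "w3", "w9"))
  expect_equal(ov$n_a, 3)
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$fraction_a_in_b, 2 / 3)
  expect_true(is.na(method_overlap(character(0), "w1")$fraction_a_in_b))
})

test_that("benchmark_scan counts tests and applies the family threshold", {
  sim <- simulate_phased_cohort(sim_config(n_subjects = 120, n_snps = 10,
                                           rho = 0.2, seed = 66))
  co <- sim$cohort
  windows <- list(make_window(1:5, "wA"), make_window(6:10, "wB"))
  scan <- benchmark_scan(co, windows, min_count = 5)
  expect_equal(scan$n_tests, 6)     # 3 sliding windows per 5-SNP window
  expect_equal(scan$threshold, 0.05 / 6)
  expect_equal(nrow(scan$best), 2)
})
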