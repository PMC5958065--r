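test_that("grouped and subject-level fits agree with glm to 10 sig figs", {
  set.seed(14)
  for (i in 1:6) {
    n <- 400
    L <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    y <- rbinom(n, 1, plogis(-0.4 + 0.6 * L))
    if (length(unique(y)) < 2) next
    fit <- fit_additive(L, y)
    oracle <- stats::glm(y ~ L, family = binomial(),
                         control = glm.control(epsilon = 1e-12))
    expect_equal(fit$beta1, unname(coef(oracle)[2]), tolerance = 1e-10)
    expect_equal(fit$beta0, unname(coef(oracle)[1]), tolerance = 1e-10)
    grouped <- do.call(rbind, lapply(0:2, function(l)
      data.frame(L = l, n = sum(L == l), cases = sum(y[L == l]))))
    fitg <- fit_additive(grouped = grouped)
    expect_equal(fitg$beta1, fit$beta1, tolerance = 1e-12)
    expect_equal(fitg$p, fit$p, tolerance = 1e-12)
  }
})

test_that("symmetric counts give OR 1 and label inversion maps OR to 1/OR", {
  sym <- fit_additive(grouped = data.frame(L = 0:1, n = c(100, 100),
                                           cases = c(50, 50)))
  expect_equal(sym$or, 1, tolerance = 1e-12)
  set.seed(6)
  L <- sample(0:2, 300, replace = TRUE)
  y <- rbinom(300, 1, plogis(-0.2 + 0.5 * L))
  f1 <- fit_additive(L, y)
  f2 <- fit_additive(L, 1 - y)
  expect_equal(f2$or, 1 / f1$or, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(fit_additive(grouped = data.frame(L = 1, n = 50, cases = 20)),
               "no haplotype variation")
  expect_error(fit_additive(grouped = data.frame(L = 0:1, n = c(5, 5),
                                                 cases = c(0, 0))),
               "both outcome classes")
  sep <- fit_additive(grouped = data.frame(L = 0:1, n = c(40, 40),
                                           cases = c(0, 40)))
  expect_equal(sep$flag, "separation")
  expect_true(is.na(sep$p))
})

test_that("grouped counts reconstruct uniquely from printed percentages", {
  # three groups resolved jointly by the total: 698 vs 699 in the middle
  r1 <- reconstruct_group_counts(c(775, 1434, 677), c(35.4, 48.7, 60.4),
                                 1381)
  expect_equal(r1$cases, c(274, 698, 409))
  # 1,295-1,297 in the large group resolved by the total
  r2 <- reconstruct_group_counts(c(2571, 304, 11), c(50.4, 27.3, 9.1), 1381)
  expect_equal(r2$cases, c(1297, 83, 1))
  expect_error(reconstruct_group_counts(10, 33.3, 99), "no consistent")
})

test_that("beta1 is recovered from data generated under the additive model", {
  set.seed(20)
  b1 <- log(2)
  ests <- replicate(40, {
    L <- sample(0:2, 800, replace = TRUE, prob = c(0.45, 0.4, 0.15))
    y <- rbinom(800, 1, plogis(-0.5 + b1 * L))
    fit_additive(L, y)$beta1
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - b1), 3 * mc_se)
})

test_that("bonferroni thresholds and display rounding match convention", {
  expect_equal(bonferroni_threshold(0.05, 74), 0.05 / 74)
  expect_equal(format_signif_threshold(bonferroni_threshold(0.05, 74)),
               "6.8e-04")
  expect_equal(format_signif_threshold(bonferroni_threshold(0.05, 1567361)),
               "3.2e-08")
  expect_equal(format_signif_threshold(bonferroni_threshold(0.05, 29)),
               "1.7e-03")
  expect_equal(format_signif_threshold(bonferroni_threshold(0.05, 11)),
               "4.5e-03")
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, integer(0)))
})

test_that("replication requires threshold p AND same direction", {
  set.seed(33)
  sim <- simulate_phased_cohort(sim_config(n_subjects = 1200, n_snps = 6,
    rho = 0.1, causal_tree = lt_and(lt_leaf(2, 1), lt_leaf(4, 1)),
    beta0 = -0.4, beta1 = 1.2,
    split = c(discovery = 0.5, replication = 0.5), seed = 91))
  co <- sim$cohort
  trees <- list(lt_and(lt_leaf(2, 1), lt_leaf(4, 1)),  # true signal
                lt_or(lt_leaf(1, 1), lt_leaf(5, 0)))   # noise
  out <- replicate_candidates(trees, co, alpha = 0.05)
  expect_equal(attr(out, "threshold"), 0.025)
  expect_equal(out$verdict[1], "replicated")
  # direction flip blocks replication regardless of p: refit with inverted
  # discovery direction by swapping phenotype in the discovery half only
  flip <- co
  d <- flip$subjects$cohort == "discovery"
  flip$subjects$phenotype[d] <- 1L - flip$subjects$phenotype[d]
  out2 <- replicate_candidates(trees[1], flip)
  expect_true(out2$verdict[1] %in% c("not_replicated", "untestable"))
  # a tree over SNPs absent from the cohort is untestable
  out3 <- replicate_candidates(list(lt_leaf(99, 1)), co)
  expect_equal(out3$verdict[1], "untestable")
})
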