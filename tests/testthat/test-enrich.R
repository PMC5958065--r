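test_that("overlap counting follows the documented interval convention", {
  track <- annotation_track("t", data.frame(chrom = "1", start = 100,
                                            end = 200))
  snp_at <- function(p) data.frame(id = paste0("v", p), chrom = "1", pos = p,
                                   ref = "A", alt = "G")
  expect_equal(overlap_count(snp_at(150), track), 1)
  expect_equal(overlap_count(snp_at(200), track), 0)    # half-open end
  expect_equal(overlap_count(snp_at(100), track), 1)
  # a SNP inside two overlapping intervals counts once
  track2 <- annotation_track("t2", data.frame(chrom = "1",
                                              start = c(100, 140),
                                              end = c(200, 260)))
  expect_equal(overlap_count(snp_at(150), track2), 1)
  # chromosome mismatch never counts
  track3 <- annotation_track("t3", data.frame(chrom = "2", start = 100,
                                              end = 200))
  expect_equal(overlap_count(snp_at(150), track3), 0)
  expect_error(annotation_track("bad", data.frame(chrom = "1", start = 5,
                                                  end = 5)), "degenerate")
})

test_that("two-sided Fisher p matches hand enumeration and edge cases", {
  # [[2,8],[8,2]]: 2 x (1 + 100 + 2025) / C(20,10)
  expect_equal(fisher_two_sided(matrix(c(2, 8, 8, 2), 2)),
               2 * (1 + 100 + 2025) / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_two_sided(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_two_sided(matrix(c(0, 3, 0, 7), 2)), 1)  # zero margin
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(77)
  for (i in 1:150) {
    tab <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    expect_equal(fisher_two_sided(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("enrichment scan builds per-track tables with the family threshold", {
  sim <- simulate_phased_cohort(sim_config(n_subjects = 30, n_snps = 40,
                                           rho = 0, seed = 31))
  v <- sim$cohort$variants
  hap <- v[1:10, ]
  comp <- v[11:40, ]
  # a track covering only haplotype SNPs must enrich strongly
  cover <- simulate_tracks(v, hap$id, padding = 10, id = "cover_hap")
  empty <- annotation_track("empty", data.frame(chrom = character(0),
                                                start = numeric(0),
                                                end = numeric(0)))
  out <- enrichment_scan(hap, comp, list(cover, empty))
  expect_equal(out$threshold, rep(0.025, 2))
  expect_equal(out$hap_overlap[1], 10)
  expect_equal(out$comp_overlap[1], 0)
  expect_lt(out$p[1], 0.025)
  expect_equal(out$p[2], 1)
  expect_true(out$significant[1])
  # track order only permutes rows
  out2 <- enrichment_scan(hap, comp, list(empty, cover))
  expect_equal(out2$p, rev(out$p))
  expect_error(enrichment_scan(v[1:5, ], v[3:8, ], list(cover)), "disjoint")
})

test_that("eQTL enrichment supports per-pair and per-SNP units", {
  eqtl <- data.frame(snp_id = c("a1", "a2", "b1", "b2", "b3"),
                     n_sig = c(4, 0, 1, 0, 0),
                     n_tested = c(10, 10, 10, 10, 10))
  pair <- eqtl_enrichment(c("a1", "a2"), c("b1", "b2", "b3"), eqtl,
                          unit = "pair")
  expect_equal(unname(pair$table[, "hap"]), c(4, 16))
  expect_equal(unname(pair$table[, "comparison"]), c(1, 29))
  snp <- eqtl_enrichment(c("a1", "a2"), c("b1", "b2", "b3"), eqtl,
                         unit = "snp")
  expect_equal(unname(snp$table[, "hap"]), c(1, 1))
  expect_equal(unname(snp$table[, "comparison"]), c(1, 2))
  expect_error(eqtl_enrichment(c("a1"), c("a1", "b1"), eqtl), "disjoint")
})
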