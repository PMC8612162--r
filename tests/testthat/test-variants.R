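# Sequence-variant clustering, divergence estimation, and rarefaction.

test_that("pairwise identity handles identity, substitutions, and indels", {
  set.seed(1)
  s <- rand_seq(100)
  expect_equal(pairwise_identity(s, s), 1.0)
  # 3 substitutions in 100 nt, no indels
  expect_equal(pairwise_identity(s, sub_k(s, 3, offset = 10)), 0.97)
  # one internal 2-nt deletion: 98 matches over 100 columns
  deleted <- paste0(substr(s, 1, 40), substr(s, 43, 100))
  expect_equal(pairwise_identity(s, deleted), 0.98)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("variant pools validate, merge duplicates, and canonicalise order", {
  p <- variant_pool(c("acgt", "ACGT", "TTTT"), c(2, 3, 4))
  expect_equal(nrow(p$variants), 2L)
  expect_equal(p$variants$count, c(5L, 4L))  # ACGT merged to 5
  expect_error(variant_pool("ACGN", 1), "non-ACGT")
  expect_error(variant_pool("ACGT", 0), ">= 1")
  expect_error(variant_pool(character(0), integer(0)), "empty")
  expect_error(variant_pool("ACGT", 1, residual_error_rate = 0.2),
               "0.05")
})

test_that("greedy clustering obeys the threshold and the exact-match limit", {
  set.seed(2)
  base <- rand_seq(200)
  near <- sub_k(base, 6)    # 3% divergent
  pool <- make_pool(c(base, near), c(100, 10))
  # 3% divergence: together at 97%, apart at 98%
  expect_equal(greedy_cluster(pool, 0.97)$otu_count, 1L)
  expect_equal(greedy_cluster(pool, 0.98)$otu_count, 2L)
  # at 1.00 clusters are exact-sequence groups
  expect_equal(greedy_cluster(pool, 1.00)$otu_count, 2L)
  same <- make_pool(c(base, base), c(5, 7))
  expect_equal(greedy_cluster(same, 1.00)$otu_count, 1L)
  expect_error(greedy_cluster(pool, 0.5), "0.80")
})

test_that("clustering is invariant to input order", {
  set.seed(3)
  base <- rand_seq(150)
  seqs <- c(base, sub_k(base, 3), sub_k(base, 15), sub_k(base, 8, offset = 5))
  counts <- c(800, 400, 200, 200)
  perms <- list(1:4, 4:1, c(2, 4, 1, 3))
  results <- lapply(perms, function(p) {
    greedy_cluster(make_pool(seqs[p], counts[p]), 0.97)
  })
  for (r in results[-1]) {
    expect_equal(r$otu_count, results[[1]]$otu_count)
    expect_equal(r$clusters$centroid, results[[1]]$clusters$centroid)
    expect_equal(r$clusters$reads, results[[1]]$clusters$reads)
  }
})

test_that("threshold scans are monotone and step at the constructed divergences", {
  set.seed(4)
  base <- rand_seq(300)
  # variants at 2% and 8% divergence from the dominant
  pool <- make_pool(c(base, sub_k(base, 6), sub_k(base, 24, offset = 8)),
                    c(1000, 300, 300))
  scan <- threshold_scan(pool)
  # counts never increase as the threshold is lowered
  expect_true(all(diff(scan$otu_count) >= 0))  # scan ascends in threshold
  expect_equal(scan$otu_count[scan$threshold == 1.00], 3L)
  # 2% pair merges below 98%, 8% pair below 92%
  expect_equal(scan$otu_count[scan$threshold == 0.98], 2L)
  expect_equal(scan$otu_count[scan$threshold == 0.97], 2L)
  expect_equal(scan$otu_count[scan$threshold == 0.92], 1L)
  expect_equal(scan$otu_count[scan$threshold == 0.93], 2L)
  # single variant: 1 everywhere
  single <- make_pool(base, 1600)
  expect_true(all(threshold_scan(single)$otu_count == 1L))
})

test_that("leveling threshold and error correction give the published divergences", {
  set.seed(5)
  # C. steinii-like rDNA pool: max divergence 11% -> levels at 89%,
  # corrected divergence 10% at 1% residual error
  base <- rand_seq(373)
  pool_cs <- make_pool(c(base, sub_k(base, 41)), c(1500, 100), error = 0.01)
  lev_cs <- leveling_threshold(threshold_scan(pool_cs))
  expect_equal(as.numeric(lev_cs), 0.89)
  expect_equal(corrected_divergence(lev_cs, pool_cs$residual_error_rate),
               0.10)
  # C. inflata-like: levels at 95% -> 4% (18/373 = 4.8% divergence)
  pool_ci <- make_pool(c(base, sub_k(base, 18)), c(1500, 100),
                       error = 0.01)
  lev_ci <- leveling_threshold(threshold_scan(pool_ci))
  expect_equal(as.numeric(lev_ci), 0.95)
  expect_equal(corrected_divergence(lev_ci, 0.01), 0.04)
  # E. vannus-like rDNA: levels at 99%, no residual error -> 1%
  base_ev <- rand_seq(445)
  pool_ev <- make_pool(c(base_ev, sub_k(base_ev, 4)), c(1550, 50))
  lev_ev <- leveling_threshold(threshold_scan(pool_ev))
  expect_equal(as.numeric(lev_ev), 0.99)
  expect_equal(corrected_divergence(lev_ev, 0), 0.01)
  # single variant levels at 1.00
  expect_equal(as.numeric(leveling_threshold(threshold_scan(
    make_pool(base, 100)))), 1.00)
  expect_equal(corrected_divergence(1.00, 0), 0)
  # never leveling: flagged, lowest threshold returned
  scan_stub <- data.frame(threshold = seq(0.89, 1, 0.01),
                          otu_count = 2L)
  expect_warning(lev <- leveling_threshold(scan_stub), "never reached 1")
  expect_equal(as.numeric(lev), 0.89)
  expect_false(attr(lev, "leveled"))
})

test_that("generator-built pools round-trip their construction divergence", {
  # divergence d with zero error: corrected divergence within one grid step
  for (d in c(0.03, 0.07, 0.11)) {
    prof <- make_profile(divergences = d)
    pool <- gen_variant_pool(prof, seed = 17)
    lev <- leveling_threshold(threshold_scan(pool))
    expect_lte(abs(corrected_divergence(lev, 0) - d), 0.01)
  }
})

test_that("dominant proportion matches pool construction", {
  set.seed(6)
  base <- rand_seq(373)
  expect_equal(dominant_proportion(make_pool(base, 1600), 0.99), 1.0)
  # two equal clusters: deterministic 0.5
  far <- sub_k(base, 60)
  expect_equal(dominant_proportion(make_pool(c(base, far), c(800, 800)),
                                   0.99), 0.5)
  # generated pools reproduce the observed 0.87-1.00 range
  for (dom in c(0.87, 0.95, 1.0)) {
    prof <- make_profile(divergences = if (dom < 1) 0.05 else numeric(0),
                         dominant = dom)
    pool <- gen_variant_pool(prof, seed = 23)
    expect_equal(dominant_proportion(pool, 0.99), dom, tolerance = 1e-3)
  }
})

test_that("rarefied richness matches the hypergeometric expectation", {
  # 10 mutually distant variants with geometric abundances
  set.seed(7)
  seqs <- replicate(10, rand_seq(200))
  counts <- round(3200 * 0.5^(0:9))  # 3200 total-ish, geometric
  counts[counts < 1] <- 1
  pool <- make_pool(seqs, counts)
  total <- sum(counts)
  depth <- 1600L
  # E(S) = sum_i (1 - P(variant i absent from the subsample))
  expected <- sum(1 - exp(lchoose(total - counts, depth) -
                            lchoose(total, depth)))
  got <- rarefied_richness(pool, depth = depth, threshold = 1.0,
                           reps = 100, seed = 7)
  expect_lt(abs(got - expected), 0.2)
  # depth = total reads reproduces the full-pool count
  expect_equal(as.numeric(rarefied_richness(pool, depth = total,
                                            threshold = 1.0, reps = 3,
                                            seed = 1)), 10)
  # single-variant pool: 1 at any depth
  expect_equal(as.numeric(rarefied_richness(make_pool(seqs[1], 2000),
                                            depth = 500, reps = 3,
                                            seed = 1)), 1)
  expect_error(rarefied_richness(make_pool(seqs[1], 100), depth = 1600),
               "fewer than depth")
  # seeded reproducibility
  expect_identical(rarefied_richness(pool, 800, 1.0, 20, seed = 42),
                   rarefied_richness(pool, 800, 1.0, 20, seed = 42))
})

test_that("richness-vs-copy-number regression reports sign and fit quality", {
  set.seed(8)
  cns <- 10^runif(30, 3, 6)
  # negative dependence with noise
  otus <- pmax(1, round(6 - 1.2 * (log10(cns) - 3) + rnorm(30, 0, 0.7)))
  fit <- richness_vs_cn_regression(otus, cns)
  expect_lt(fit$slope, 0)
  expect_equal(attr(fit, "slope_sign"), -1)
  expect_false(fit$log_response)
  # independent richness: slope ~ 0
  flat <- richness_vs_cn_regression(rep(c(2, 3), 15), cns)
  expect_lt(abs(flat$slope), 0.5)
  # effect size tuned to the observed R2 band
  r2s <- vapply(1:50, function(i) {
    set.seed(300 + i)
    cn <- 10^runif(16, 3.5, 5.5)
    otu <- pmax(1, round(5 - 1.1 * (log10(cn) - 3.5) + rnorm(16, 0, 1.1)))
    richness_vs_cn_regression(otu, cn)$r_squared
  }, numeric(1))
  expect_gt(mean(r2s >= 0.1 & r2s <= 0.5), 0.5)
})
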