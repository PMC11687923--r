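test_that("hwe_test matches the chi-square oracle", {
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_lt(hwe_test(100, 0, 100), 1e-10)
  expect_error(hwe_test(0, 0, 0), "zero")
  # direct-formula oracle on random triples
  set.seed(3)
  for (i in 1:20) {
    cts <- rmultinom(1, 200, c(0.3, 0.45, 0.25))[, 1]
    n <- sum(cts)
    q <- (2 * cts[3] + cts[2]) / (2 * n)
    e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    chi2 <- sum((cts - e)^2 / e)
    expect_equal(hwe_test(cts[1], cts[2], cts[3]),
                 pchisq(chi2, 1, lower.tail = FALSE), tolerance = 1e-9)
  }
})

test_that("qc_filter removes the enumerated casualties in order", {
  # 20-variant toy panel with known per-filter casualties
  set.seed(8)
  n <- 200
  dos <- sapply(1:16, function(j) rbinom(n, 2, 0.3))
  dos <- cbind(dos, 0)                         # 17: monomorphic -> maf
  dos <- cbind(dos, rbinom(n, 2, 0.0015))      # 18: rare -> maf (freq ~0.001)
  miss <- rbinom(n, 2, 0.3); miss[1:40] <- NA  # 19: 20% missing
  dos <- cbind(dos, miss)
  dos <- cbind(dos, c(rep(0, 100), rep(2, 100)))  # 20: het deficit -> hwe
  dos[, 2] <- dos[, 1]                         # duplicate pair -> prune
  vm <- data.frame(chrom = "1", pos = seq(1000, by = 1000, length.out = 20),
                   id = paste0("v", 1:20), ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  panel <- genotype_panel(paste0("s", 1:n), vm, dos)
  res <- qc_filter(panel, maf_min = 0.01, hwe_alpha = 0.001,
                   miss_max = 0.1, prune_r2 = 0.8)
  expect_identical(unname(res$report$removed),
                   c(2L, 1L, 1L, 1L))  # maf, missingness, hwe, prune
  expect_identical(res$report$survivors, 15L)
  expect_false("v2" %in% res$panel$variant_map$id)  # later duplicate dropped
  expect_true("v1" %in% res$panel$variant_map$id)   # earlier one kept
})

test_that("qc_filter drops high-missingness samples", {
  p <- simulate_genotypes(50, 40, seed = 2)
  p$dosages[1, 1:20] <- NA   # sample 1 at 50% missing
  res <- qc_filter(p, miss_max = 0.1)
  expect_identical(res$report$samples_removed, 1L)
  expect_false("S0001" %in% res$panel$sample_ids)
})

test_that("association scan matches the per-variant lm oracle", {
  fx <- small_cohort(n = 120, seed = 9)
  traits <- cbind(t1 = rnorm(120), t2 = rnorm(120))
  set.seed(10)
  scans <- association_scan(fx$panel, traits, fx$cohort$covariates)
  cov <- fx$cohort$covariates
  for (j in sample(ncol(fx$panel$dosages), 10)) {
    g <- fx$panel$dosages[, j]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    fit <- summary(lm(traits[, 1] ~ g + age + sex + batch + pc1 + pc2 + pc3 +
                        pc4 + pc5 + pc6 + pc7 + pc8 + pc9 + pc10, data = cov))
    expect_equal(scans$t1$beta[j], fit$coefficients["g", 1], tolerance = 1e-8)
    expect_equal(scans$t1$se[j], fit$coefficients["g", 2], tolerance = 1e-8)
    expect_equal(scans$t1$p[j], fit$coefficients["g", 4], tolerance = 1e-8)
  }
})

test_that("a perfectly linear trait gives beta 2 and vanishing p", {
  p <- simulate_genotypes(60, 10, c(0.3, 0.5), block_corr = 0, seed = 5)
  trait <- 2 * p$dosages[, 4]
  s <- association_scan(p, trait)
  expect_equal(s$beta[4], 2, tolerance = 1e-8)
  expect_lt(s$p[4], 1e-100)
})

test_that("zero-variance dosages are flagged, not fatal", {
  vm <- data.frame(chrom = "1", pos = c(100L, 200L), id = c("a", "b"),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- genotype_panel(paste0("s", 1:20),
                          vm, cbind(rep(1, 20), rbinom(20, 2, 0.5)))
  s <- association_scan(panel, rnorm(20))
  expect_true(s$zero_variance[1])
  expect_identical(s$beta[1], 0)
  expect_identical(s$p[1], 1)
  expect_false(s$zero_variance[2])
})

test_that("null panels give calibrated type-I error", {
  p <- simulate_genotypes(800, 1500, c(0.1, 0.5), ld_block_size = 25,
                          block_corr = 0.6, seed = 14)
  set.seed(15)
  s <- association_scan(p, rnorm(800))
  expect_gt(mean(s$p < 0.05), 0.035)
  expect_lt(mean(s$p < 0.05), 0.065)
})

test_that("adding the confounder as covariate removes a spurious hit", {
  set.seed(16)
  n <- 400
  p <- simulate_genotypes(n, 20, c(0.3, 0.5), block_corr = 0, seed = 16)
  conf <- scale(p$dosages[, 7])[, 1] + rnorm(n, sd = 0.3)
  trait <- 2 * conf + rnorm(n, sd = 0.5)
  naive <- association_scan(p, trait)
  expect_lt(naive$p[7], 1e-6)
  adj <- association_scan(p, trait,
                          data.frame(sample_id = p$sample_ids, conf = conf))
  expect_gt(adj$p[7], 0.01)
})

test_that("bonferroni_threshold reproduces the published thresholds", {
  expect_identical(bonferroni_threshold(5e-8, 20), 2.5e-9)
  expect_identical(signif(bonferroni_threshold(0.05, 102 * 20), 2), 2.5e-5)
  expect_identical(bonferroni_threshold(0.01, 1), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("clumping follows the greedy hand-run oracle", {
  s <- make_stats(c(100000, 200000, 600000), c(1e-12, 1e-10, 1e-11))
  loci <- clump(s, window_bp = 250000, index_p = 1e-9, member_p = 5e-8)
  expect_identical(nrow(loci), 2L)
  expect_identical(loci$index_id, c("s1", "s3"))
  expect_setequal(loci$members[[1]], c("s1", "s2"))
  expect_identical(loci$members[[2]], "s3")

  # no index passes
  expect_identical(nrow(clump(make_stats(1:3 * 1e5, rep(1e-6, 3)))), 0L)
  # singleton
  one <- clump(make_stats(c(1e5, 9e5), c(1e-12, 0.5)))
  expect_identical(nrow(one), 1L)
  expect_identical(one$members[[1]], "s1")
})

test_that("clumping conserves variants and is monotone in index_p", {
  set.seed(21)
  pos <- sort(sample(1:5e6, 150))
  s <- make_stats(pos, runif(150)^8)
  loci <- clump(s, index_p = 1e-4, member_p = 1e-2)
  members <- unlist(loci$members)
  expect_identical(anyDuplicated(members), 0L)
  expect_true(all(members %in% s$id))
  for (k in seq_len(nrow(loci))) {
    mpos <- s$pos[s$id %in% loci$members[[k]]]
    expect_true(all(abs(mpos - loci$index_pos[k]) <= 250000))
    expect_identical(loci$min_p[k], min(s$p[s$id %in% loci$members[[k]]]))
  }
  counts <- sapply(c(1e-8, 1e-6, 1e-4, 1e-2),
                   function(ip) nrow(clump(s, index_p = ip, member_p = 1e-2)))
  expect_true(all(diff(counts) >= 0))
})

test_that("aggregate_traits takes the elementwise minimum p", {
  s1 <- make_stats(c(1e5, 2e5, 3e5), c(1e-4, 1e-2, 1e-6), trait = "A")
  s2 <- make_stats(c(1e5, 2e5, 3e5), c(1e-3, 1e-7, 1e-3), trait = "B")
  agg <- aggregate_traits(list(s1, s2))
  expect_equal(agg$p, pmin(s1$p, s2$p))
  expect_identical(agg$trait, c("A", "B", "A"))
  expect_true(all(agg$p <= s1$p) && all(agg$p <= s2$p))
  # single-trait aggregation is the identity on p
  expect_equal(aggregate_traits(list(s1))$p, s1$p)
})

test_that("merge_loci matches the enumeration oracle", {
  a <- clump(make_stats(c(1e5, 9e5), c(1e-12, 1e-12)))
  expect_identical(nrow(merge_loci(a, a)$shared), 2L)
  b <- clump(make_stats(c(1e5, 9e5), c(1e-12, 1e-12), chrom = "2"))
  m <- merge_loci(a, b)
  expect_identical(nrow(m$shared), 0L)
  expect_identical(nrow(m$a_only), 2L)
  # constructed overlap: a at 100k/900k, c at 180k (matches 100k) + 2.0M
  cc <- clump(make_stats(c(180000, 2000000), c(1e-12, 1e-12)))
  m2 <- merge_loci(a, cc)
  expect_identical(m2$shared$a_index, "s1")
  expect_identical(m2$shared$b_index, "s1")
  expect_identical(nrow(m2$a_only), 1L)
  expect_identical(nrow(m2$b_only), 1L)
})

test_that("strong planted effects replicate across a cohort split", {
  hits <- sapply(1:6, function(s) {
    p <- simulate_genotypes(1200, 60, c(0.3, 0.5), ld_block_size = 10,
                            block_corr = 0.5, seed = 100 + s)
    set.seed(200 + s)
    g <- p$dosages[, 30]
    trait <- scale(0.5 * g + rnorm(1200))[, 1]
    loci <- replicate_split(p, trait, frac = 0.65, index_p = 1e-7,
                            seed = s)
    nrow(loci) > 0 && any(loci$replicated)
  })
  expect_gte(sum(hits), 5)
})

test_that("null panels never replicate and degenerate splits error", {
  p <- simulate_genotypes(200, 50, seed = 31)
  set.seed(32)
  loci <- replicate_split(p, rnorm(200), frac = 0.6, index_p = 1e-9)
  expect_identical(nrow(loci), 0L)
  expect_error(replicate_split(p, rnorm(200), frac = 0), "frac")
  expect_error(replicate_split(p, rnorm(200), frac = 1), "frac")
})
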