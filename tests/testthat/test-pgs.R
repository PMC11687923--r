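test_that("pgs_score matches hand arithmetic and handles allele flips", {
  panel <- tiny_panel()
  w <- latentgwas:::as_pgs_weights(data.frame(
    id = c("v1", "v2", "v3"),
    effect_allele = c("G", "T", "A"),
    other_allele = c("A", "C", "G"),
    weight = c(0.5, -1, 2), stringsAsFactors = FALSE
  ))
  # hand-computed: 0.5*d1 - 1*d2 + 2*d3
  d <- panel$dosages
  expect_equal(as.numeric(pgs_score(panel, w)),
               unname(0.5 * d[, 1] - 1 * d[, 2] + 2 * d[, 3]))
  # flip the coding of v2 in the panel: scores must be unchanged
  flipped <- panel
  flipped$variant_map$ref[2] <- "T"; flipped$variant_map$alt[2] <- "C"
  flipped$dosages[, 2] <- 2 - flipped$dosages[, 2]
  expect_equal(as.numeric(pgs_score(flipped, w)),
               as.numeric(pgs_score(panel, w)))
  # empty weights give all-zero scores
  empty <- latentgwas:::as_pgs_weights(w[0, ])
  expect_equal(as.numeric(pgs_score(panel, empty)), rep(0, 4))
  # unmatched variant skipped and counted
  w2 <- w; w2$id[3] <- "nope"
  expect_identical(attr(pgs_score(panel, w2), "skipped"), 1L)
})

test_that("pgs_score is linear in the weights", {
  panel <- simulate_genotypes(50, 20, seed = 101)
  vm <- panel$variant_map
  mk <- function(wt) latentgwas:::as_pgs_weights(data.frame(
    id = vm$id[1:10], effect_allele = vm$alt[1:10],
    other_allele = vm$ref[1:10], weight = wt, stringsAsFactors = FALSE))
  set.seed(102)
  w1 <- rnorm(10); w2 <- rnorm(10)
  expect_equal(as.numeric(pgs_score(panel, mk(w1 + w2))),
               as.numeric(pgs_score(panel, mk(w1))) +
                 as.numeric(pgs_score(panel, mk(w2))),
               tolerance = 1e-10)
})

test_that("clumping+thresholding PGS recovers a planted causal variant", {
  hits <- sapply(1:10, function(s) {
    panel <- simulate_genotypes(600, 50, c(0.2, 0.5), ld_block_size = 10,
                                block_corr = 0.5, seed = 400 + s)
    set.seed(500 + s)
    g <- panel$dosages[, 25]
    y <- scale(0.5 * g + rnorm(600))[, 1]
    stats <- association_scan(panel, y)
    # ambiguous-allele warnings are expected on a random synthetic panel
    w <- suppressWarnings(fit_ct_pgs(stats, panel, y, seed = s))
    causal <- panel$variant_map$id[25]
    causal %in% w$id && w$weight[w$id == causal] > 0
  })
  expect_gte(sum(hits), 9)
})

test_that("fit_ct_pgs returns empty weights when nothing passes", {
  s <- make_stats(c(1e5, 2e5, 3e5), c(1, 1, 1))
  panel <- simulate_genotypes(30, 3, seed = 1)
  s$id <- panel$variant_map$id
  expect_warning(w <- fit_ct_pgs(s, panel, rnorm(30)), "empty")
  expect_identical(nrow(w), 0L)
})

test_that("threshold selection never leaks variants across thresholds", {
  panel <- simulate_genotypes(400, 40, c(0.2, 0.5), seed = 110)
  set.seed(111)
  y <- scale(0.4 * panel$dosages[, 20] + rnorm(400))[, 1]
  stats <- association_scan(panel, y)
  w <- fit_ct_pgs(stats, panel, y, p_thresholds = c(1e-6, 1e-3, 1e-1))
  thr <- attr(w, "p_threshold")
  expect_true(all(stats$p[match(w$id, stats$id)] <= thr))
})

test_that("multi_pgs_eval guards against noise and rewards real signal", {
  # pure-noise extra scores: mean delta stays near or below zero
  deltas <- sapply(1:20, function(s) {
    set.seed(600 + s)
    n <- 500
    base <- matrix(rnorm(n), ncol = 1)
    y <- base[, 1] + rnorm(n)
    extra <- matrix(rnorm(n * 5), n, 5)
    multi_pgs_eval(y, base, extra, n_perm = 10, seed = s)$delta
  })
  expect_lt(mean(deltas), 0.005)
  # duplicated base column adds nothing
  set.seed(620)
  n <- 300
  base <- matrix(rnorm(n), ncol = 1)
  y <- base[, 1] + rnorm(n)
  ev <- multi_pgs_eval(y, base, base, n_perm = 10, seed = 1)
  expect_equal(ev$delta, 0, tolerance = 1e-8)
  # independent planted signal detected
  wins <- sapply(1:20, function(s) {
    set.seed(640 + s)
    b <- rnorm(500); x <- rnorm(500)
    y <- b + sqrt(0.12) * x + rnorm(500, sd = 0.9)
    multi_pgs_eval(y, matrix(b), matrix(x), n_perm = 10, seed = s)$delta > 0.03
  })
  expect_gte(sum(wins), 18)
})

test_that("multi_pgs_eval never fits on test samples", {
  set.seed(660)
  n <- 200
  base <- matrix(rnorm(n), ncol = 1)
  extra <- matrix(rnorm(n), ncol = 1)
  y <- base[, 1] + rnorm(n)
  e1 <- multi_pgs_eval(y, base, extra, train_frac = 0.6, n_perm = 5, seed = 3)
  # mutate test-set outcomes: fitted models (hence test predictions) must
  # be identical because only training samples enter the fit
  y2 <- y
  y2[e1$test_index] <- rnorm(length(e1$test_index))
  e2 <- multi_pgs_eval(y2, base, extra, train_frac = 0.6, n_perm = 5, seed = 3)
  expect_identical(e1$test_index, e2$test_index)
  expect_identical(e1$pred_base, e2$pred_base)
  expect_identical(e1$pred_ext, e2$pred_ext)
  expect_error(multi_pgs_eval(y, base, extra, train_frac = 1), "train_frac")
})

test_that("pleiotropic image-derived PGS improve a trait-specific PGS", {
  # two traits share half their causal variants; each PGS is fit from an
  # independent GWAS sample and both are evaluated on a third cohort
  deltas <- sapply(1:10, function(s) {
    big <- simulate_genotypes(1600, 300, c(0.2, 0.5), ld_block_size = 10,
                              block_corr = 0.5, seed = 900 + s)
    g1 <- subset_panel(big, samples = 1:500)
    g2 <- subset_panel(big, samples = 501:1000)
    ev <- subset_panel(big, samples = 1001:1600)
    latentgwas:::with_seed(950 + s, {
      shared <- seq(15, 285, length.out = 6)
      cy <- c(shared, shared + 3)   # trait-specific causal set
      cd <- c(shared, shared + 6)   # image-trait causal set
      b <- rep(sqrt(0.025), 12)
      mk <- function(p, cs) as.numeric(scale(p$dosages[, cs] %*% b)) *
        sqrt(0.3) + rnorm(nrow(p$dosages), sd = sqrt(0.7))
      y1 <- mk(g1, cy); d2 <- mk(g2, cd); ye <- mk(ev, cy)
      NULL
    })
    wy <- suppressWarnings(fit_ct_pgs(association_scan(g1, y1), g1, y1,
                                      p_thresholds = c(1e-6, 1e-4, 1e-2),
                                      seed = s))
    wd <- suppressWarnings(fit_ct_pgs(association_scan(g2, d2), g2, d2,
                                      p_thresholds = c(1e-6, 1e-4, 1e-2),
                                      seed = s))
    multi_pgs_eval(ye, matrix(pgs_score(ev, wy)),
                   matrix(pgs_score(ev, wd)), n_perm = 10, seed = s)$delta
  })
  expect_gt(mean(deltas), 0)
})

test_that("the permutation test is exact on identical predictions and bounded", {
  set.seed(700)
  y <- rnorm(50); pred <- y + rnorm(50, sd = 0.5)
  expect_identical(permutation_test_r2(y, pred, pred, n_perm = 99, seed = 1), 1)
  p <- permutation_test_r2(y, pred, y + rnorm(50, sd = 0.4), n_perm = 99,
                           seed = 2)
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
  expect_error(permutation_test_r2(y, pred, pred, n_perm = 0), "n_perm")
})

test_that("the permutation test is calibrated under a matched null", {
  ps <- sapply(1:200, function(s) {
    set.seed(800 + s)
    n <- 60
    y <- rnorm(n)
    # two equally good independent predictors
    pa <- 0.5 * y + rnorm(n, sd = 0.8)
    pb <- 0.5 * y + rnorm(n, sd = 0.8)
    permutation_test_r2(y, pa, pb, n_perm = 200, seed = s)
  })
  # permutation p-values live on a discrete grid, so KS ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
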