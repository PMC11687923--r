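make_stack <- function(vols) {
  volume_stack(vols, array(0L, dim = dim(vols)[1:3]) + 1L,
               roi_dict = c(roi1 = 1L))
}

test_that("plain autoencoder training descends in reconstruction error", {
  fx <- small_cohort(n = 64, seed = 50, radius_noise_sd = 0.6,
                     shape = c(32, 32, 32))
  cfg <- cvae_config(lambda_kld = 0, lambda_pred = 0, epochs = 8, seed = 1)
  m <- train_cvae(fx$cohort$volumes, fx$cohort$covariates,
                  fx$cohort$dementia_score, cfg)
  h <- m$history
  expect_lt(h$recon[nrow(h)], h$recon[1])
})

test_that("the prediction head recovers the planted dementia signal", {
  fx <- small_cohort(n = 200, seed = 51, beta = 0.8, radius_noise_sd = 1.0,
                     noise_sd = 0.05, shape = c(32, 32, 32))
  train_ix <- 1:160; test_ix <- 161:200
  sub_stack <- function(ix) volume_stack(
    fx$cohort$volumes$volumes[, , , ix, drop = FALSE],
    fx$cohort$volumes$roi_labels, fx$cohort$volumes$voxel_size,
    fx$cohort$volumes$roi_dict, fx$cohort$volumes$sample_ids[ix])
  m <- train_cvae(sub_stack(train_ix),
                  fx$cohort$covariates[train_ix, ],
                  fx$cohort$dementia_score[train_ix],
                  cvae_config(epochs = 20, seed = 2))
  yhat <- predict_dementia(m, sub_stack(test_ix),
                           fx$cohort$covariates[test_ix, ])
  y <- fx$cohort$dementia_score[test_ix]
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0)
})

test_that("training is deterministic given config and seed", {
  fx <- small_cohort(n = 30, seed = 52)
  cfg <- cvae_config(epochs = 3, seed = 7, pool = 1)
  m1 <- train_cvae(fx$cohort$volumes, fx$cohort$covariates,
                   fx$cohort$dementia_score, cfg)
  m2 <- train_cvae(fx$cohort$volumes, fx$cohort$covariates,
                   fx$cohort$dementia_score, cfg)
  expect_identical(m1$history$total, m2$history$total)
  expect_identical(m1$params, m2$params)
})

test_that("the analytic gradients match finite differences", {
  cfg <- cvae_config(latent_dim = 3, hidden_dim = 5, head_hidden = 4,
                     lambda_kld = 1e-2, lambda_pred = 0.5, seed = 2, pool = 1)
  set.seed(11)
  X <- matrix(rnorm(60), 6, 10)
  Cov <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  par <- latentgwas:::cvae_init_params(10, cfg, 2)
  eps <- matrix(rnorm(18), 6, 3)
  fw <- latentgwas:::cvae_forward(par, X, Cov, y, cfg, eps)
  gr <- latentgwas:::cvae_backward(par, fw, X, Cov, y, cfg)
  for (nm in names(par)) {
    for (k in sample(seq_along(par[[nm]]), min(4, length(par[[nm]])))) {
      h <- 1e-6
      pp <- par; pp[[nm]][k] <- pp[[nm]][k] + h
      f1 <- latentgwas:::cvae_forward(pp, X, Cov, y, cfg, eps)$total
      pp[[nm]][k] <- pp[[nm]][k] - 2 * h
      f0 <- latentgwas:::cvae_forward(pp, X, Cov, y, cfg, eps)$total
      expect_equal(gr[[nm]][k], (f1 - f0) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("encoding is deterministic, order-equivariant, and non-degenerate", {
  fx <- small_cohort(n = 40, seed = 53, radius_noise_sd = 0.6)
  st <- fx$cohort$volumes
  m <- train_cvae(st, fx$cohort$covariates, fx$cohort$dementia_score,
                  cvae_config(epochs = 5, seed = 3))
  lat <- encode_volumes(m, st)
  # duplicated sample encodes identically
  dup <- volume_stack(st$volumes[, , , c(1, 1, 2), drop = FALSE],
                      st$roi_labels, st$voxel_size, st$roi_dict,
                      c("a", "b", "c"))
  lat_dup <- encode_volumes(m, dup)
  expect_identical(lat_dup[1, ], lat_dup[2, ])
  # permutation equivariance
  perm <- c(5, 1, 9, 2)
  permuted <- volume_stack(st$volumes[, , , perm, drop = FALSE],
                           st$roi_labels, st$voxel_size, st$roi_dict,
                           st$sample_ids[perm])
  expect_equal(unclass(encode_volumes(m, permuted)),
               unclass(lat)[perm, ], ignore_attr = TRUE)
  # no constant latent when inputs vary
  expect_true(all(apply(lat, 2, sd) > 0))
  # shape mismatch rejected
  bad <- volume_stack(array(0, c(8, 8, 8, 2)), array(0L, c(8, 8, 8)))
  expect_error(encode_volumes(m, bad), "shape")
})

test_that("conditioning lowers the latent-age correlation (majority of seeds)", {
  eff <- effect_spec(age_slope = 0.03, radius_noise_sd = 0.5, noise_sd = 0.05)
  wins <- 0L
  for (s in 1:5) {
    panel <- simulate_genotypes(150, 20, seed = 300 + s)
    co <- simulate_cohort(panel, eff, c(32, 32, 32), 4, seed = 300 + s)
    cond <- train_cvae(co$volumes, co$covariates, co$dementia_score,
                       cvae_config(epochs = 60, seed = s))
    uncond <- train_cvae(co$volumes, co$covariates, co$dementia_score,
                         cvae_config(epochs = 60, seed = s,
                                     conditioning = character(0)))
    cc <- max(abs(cor(encode_volumes(cond, co$volumes), co$covariates$age)))
    cu <- max(abs(cor(encode_volumes(uncond, co$volumes), co$covariates$age)))
    if (cc < cu) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("slice averaging equals the explicit slice-loop oracle", {
  set.seed(60)
  vols <- array(rnorm(12 * 10 * 8 * 3), c(12, 10, 8, 3))
  st <- make_stack(vols)
  f <- random_projection_features(c(12, 10), d = 7, seed = 4)
  enc <- slice_average_encode(st, f)
  for (i in 1:3) {
    acc <- rowMeans(sapply(1:8, function(k) f(vols[, , k, i])))
    expect_equal(unname(enc[i, ]), acc, tolerance = 1e-10)
  }
})

test_that("slice averaging collapses trivial cases and is linear", {
  one <- matrix(rnorm(64), 8, 8)
  vols <- array(rep(one, 8), c(8, 8, 8, 1))       # identical slices
  st <- make_stack(vols)
  f <- random_projection_features(c(8, 8), d = 5, seed = 1)
  expect_equal(unname(slice_average_encode(st, f)[1, ]), f(one),
               tolerance = 1e-10)
  # mean-intensity feature recovers the whole-volume mean
  expect_equal(unname(slice_average_encode(st, function(s) mean(s))[1, 1]),
               mean(vols), tolerance = 1e-12)
  # linearity in the feature function
  set.seed(61)
  vols2 <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  st2 <- make_stack(vols2)
  g <- random_projection_features(c(8, 8), d = 5, seed = 2)
  combo <- function(s) 2 * f(s) - 3 * g(s)
  expect_equal(unclass(slice_average_encode(st2, combo)),
               2 * unclass(slice_average_encode(st2, f)) -
                 3 * unclass(slice_average_encode(st2, g)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # inconsistent lengths rejected
  bad <- function(s) rnorm(sample(3:4, 1))
  expect_error(slice_average_encode(st2, bad), "inconsistent")
})

test_that("PCA recovers known spectra and satisfies projector identities", {
  # rank-1 data: first component explains everything
  set.seed(70)
  u <- rnorm(50); v <- rnorm(6)
  x <- outer(u, v)
  fp <- fit_pca(x, 2)
  expect_equal(fp$model$explained_variance_ratio[1], 1, tolerance = 1e-10)
  # known 2D Gaussian with covariance diag(4, 1): EVR (0.8, 0.2)
  x2 <- cbind(rnorm(10000, sd = 2), rnorm(10000, sd = 1))
  fp2 <- fit_pca(x2, 2)
  expect_equal(unname(fp2$model$explained_variance_ratio), c(0.8, 0.2),
               tolerance = 0.02)
  # orthonormal loadings, centred scores, idempotent projection
  x3 <- matrix(rnorm(200 * 8), 200, 8)
  fp3 <- fit_pca(x3, 4)
  L <- fp3$model$loadings
  expect_equal(crossprod(L), diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(colMeans(fp3$scores)) < 1e-8))
  expect_true(all(diff(fp3$model$explained_variance_ratio) <= 1e-12))
  recon <- sweep(fp3$scores %*% t(L), 2, fp3$model$center, "+")
  expect_equal(unname(predict(fp3$model, recon)), unname(fp3$scores),
               tolerance = 1e-8)
  expect_error(fit_pca(x3, 9), "k")
})
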