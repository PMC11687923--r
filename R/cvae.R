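#' Configuration for the conditional multi-task VAE
#'
#' The three loss weights follow the published objective (reconstruction 1,
#' KL divergence 1e-4, prediction 1e-2).  The latent dimension, epoch count,
#' and batch size default to desk-scale values; the reference analysis used
#' latent 128, 500 epochs, and batches of 128 on full-resolution cohorts.
#'
#' @param latent_dim Latent dimension (>= 1).
#' @param hidden_dim Width of the encoder/decoder hidden layer.
#' @param head_hidden Width of the prediction head's hidden layer.
#' @param lambda_recon,lambda_kld,lambda_pred Non-negative loss weights.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam step size.
#' @param seed Integer seed (weights, shuffling, reparameterisation noise).
#' @param conditioning Covariate names fed to the decoder and head
#'   (default `c("age", "sex")`; `character(0)` trains unconditioned).
#' @param pool Integer pooling factor of the fixed downsampling stem;
#'   `NULL` picks the factor bringing each axis to ~16 voxels.
#' @return An object of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim = 16, hidden_dim = 128, head_hidden = 32,
                        lambda_recon = 1, lambda_kld = 1e-4,
                        lambda_pred = 1e-2, epochs = 30, batch_size = 64,
                        lr = 2e-3, seed = 1,
                        conditioning = c("age", "sex"), pool = NULL) {
  check_count(latent_dim, "latent_dim")
  check_scalar(lambda_recon, "lambda_recon", lo = 0)
  check_scalar(lambda_kld, "lambda_kld", lo = 0)
  check_scalar(lambda_pred, "lambda_pred", lo = 0)
  check_count(epochs, "epochs", min = 0L)
  check_count(batch_size, "batch_size")
  structure(
    list(latent_dim = as.integer(latent_dim), hidden_dim = as.integer(hidden_dim),
         head_hidden = as.integer(head_hidden), lambda_recon = lambda_recon,
         lambda_kld = lambda_kld, lambda_pred = lambda_pred,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, seed = as.integer(seed), conditioning = conditioning,
         pool = pool),
    class = "cvae_config"
  )
}

# 3D average pooling of a 4D (x, y, z, n) array by integer factor f
avg_pool3d <- function(vols, f) {
  if (f == 1L) return(vols)
  d <- dim(vols)
  if (any(d[1:3] %% f != 0)) stop_arg("volume axes must be divisible by pool factor")
  out <- 0
  sel <- function(axis) lapply(seq_len(f), function(o) seq(o, d[axis], by = f))
  sx <- sel(1); sy <- sel(2); sz <- sel(3)
  for (i in seq_len(f)) for (j in seq_len(f)) for (k in seq_len(f)) {
    out <- out + vols[sx[[i]], sy[[j]], sz[[k]], , drop = FALSE]
  }
  out / f^3
}

# flatten pooled volumes into an n x d data matrix
volumes_to_matrix <- function(stack, f) {
  v <- avg_pool3d(stack$volumes, f)
  d <- prod(dim(v)[1:3])
  t(matrix(v, nrow = d))
}

relu <- function(x) x * (x > 0)

cvae_init_params <- function(d_in, cfg, n_cov) {
  L <- cfg$latent_dim; h <- cfg$hidden_dim; hh <- cfg$head_hidden
  zc <- L + n_cov
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  list(
    W1 = he(d_in, h), b1 = numeric(h),
    Wmu = he(h, L), bmu = numeric(L),
    Wlv = matrix(0, h, L), blv = numeric(L),
    Wd1 = he(zc, h), bd1 = numeric(h),
    Wd2 = he(h, d_in), bd2 = numeric(d_in),
    Wh1 = he(zc, hh), bh1 = numeric(hh),
    Wh2 = he(hh, 1), bh2 = numeric(1)
  )
}

# forward pass; eps = NULL encodes deterministically at the latent mean
cvae_forward <- function(par, X, Cov, y, cfg, eps = NULL) {
  B <- nrow(X)
  H1 <- relu(sweep(X %*% par$W1, 2, par$b1, "+"))
  mu <- sweep(H1 %*% par$Wmu, 2, par$bmu, "+")
  lv_raw <- sweep(H1 %*% par$Wlv, 2, par$blv, "+")
  lv <- pmin(pmax(lv_raw, -8), 8)
  z <- if (is.null(eps)) mu else mu + exp(lv / 2) * eps
  zc <- if (ncol(Cov)) cbind(z, Cov) else z
  H2 <- relu(sweep(zc %*% par$Wd1, 2, par$bd1, "+"))
  Xhat <- sweep(H2 %*% par$Wd2, 2, par$bd2, "+")
  H3 <- relu(sweep(zc %*% par$Wh1, 2, par$bh1, "+"))
  yhat <- (H3 %*% par$Wh2)[, 1] + par$bh2

  recon <- mean((Xhat - X)^2)
  kld <- mean(-0.5 * rowSums(1 + lv - mu^2 - exp(lv)))
  pred <- mean((yhat - y)^2)
  total <- cfg$lambda_recon * recon + cfg$lambda_kld * kld +
    cfg$lambda_pred * pred
  list(H1 = H1, mu = mu, lv = lv, lv_mask = abs(lv_raw) < 8, z = z, zc = zc,
       H2 = H2, Xhat = Xhat, H3 = H3, yhat = yhat, eps = eps, B = B,
       recon = recon, kld = kld, pred = pred, total = total)
}

cvae_backward <- function(par, fw, X, Cov, y, cfg) {
  B <- fw$B; d <- ncol(X); L <- cfg$latent_dim
  g <- list()
  dXhat <- 2 * cfg$lambda_recon * (fw$Xhat - X) / (B * d)
  g$Wd2 <- crossprod(fw$H2, dXhat); g$bd2 <- colSums(dXhat)
  dH2 <- (dXhat %*% t(par$Wd2)) * (fw$H2 > 0)
  g$Wd1 <- crossprod(fw$zc, dH2); g$bd1 <- colSums(dH2)
  dzc <- dH2 %*% t(par$Wd1)

  dyhat <- 2 * cfg$lambda_pred * (fw$yhat - y) / B
  g$Wh2 <- crossprod(fw$H3, matrix(dyhat)); g$bh2 <- sum(dyhat)
  dH3 <- (matrix(dyhat) %*% t(par$Wh2)) * (fw$H3 > 0)
  g$Wh1 <- crossprod(fw$zc, dH3); g$bh1 <- colSums(dH3)
  dzc <- dzc + dH3 %*% t(par$Wh1)

  dz <- dzc[, seq_len(L), drop = FALSE]
  dmu <- dz + cfg$lambda_kld * fw$mu / B
  dlv <- cfg$lambda_kld * 0.5 * (exp(fw$lv) - 1) / B
  if (!is.null(fw$eps)) dlv <- dlv + dz * fw$eps * exp(fw$lv / 2) * 0.5
  dlv <- dlv * fw$lv_mask
  dH1 <- (dmu %*% t(par$Wmu) + dlv %*% t(par$Wlv)) * (fw$H1 > 0)
  g$Wmu <- crossprod(fw$H1, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(fw$H1, dlv); g$blv <- colSums(dlv)
  g$W1 <- crossprod(X, dH1); g$b1 <- colSums(dH1)
  g[names(par)]
}

#' Train the conditional multi-task VAE
#'
#' Minimises `lambda_recon * MSE(x, xhat) + lambda_kld * KLD(q(z|x) || N(0, I))
#' + lambda_pred * MSE(y, yhat)` where the encoder maps a (pooled,
#' standardised) volume to a latent Gaussian, the decoder and prediction
#' head receive the sampled latent concatenated with the standardised
#' conditioning covariates, and sampling uses the reparameterisation trick.
#' The architecture is a fixed average-pooling stem followed by dense
#' encoder/decoder layers with a mirrored shape and a 2-layer head,
#' optimised with Adam.  Encoding at inference returns the latent mean (no
#' sampling).
#'
#' @param volumes A [volume_stack].
#' @param covariates Covariate data frame with at least the columns named in
#'   `config$conditioning`; ignored when training unconditioned.
#' @param dementia_score Per-sample continuous prediction target.
#' @param config A [cvae_config].
#' @return An object of class `cvae`: parameters, normalisation constants,
#'   and a per-epoch `history` of deterministic full-data loss components
#'   (row `epoch = 0` is the loss at the initial weights).
#' @export
train_cvae <- function(volumes, covariates, dementia_score,
                       config = cvae_config()) {
  stopifnot(inherits(volumes, "volume_stack"), inherits(config, "cvae_config"))
  n <- n_volumes(volumes)
  if (n < 2) stop_arg("at least 2 samples required")
  if (length(dementia_score) != n || !all(is.finite(dementia_score))) {
    stop_arg("dementia_score must be finite, one value per sample")
  }
  shape <- dim(volumes$volumes)[1:3]
  f <- config$pool %||% max(1L, floor(min(shape) / 16))
  while (any(shape %% f != 0) && f > 1L) f <- f - 1L

  X <- volumes_to_matrix(volumes, f)
  col_mean <- colMeans(X)
  sd_all <- stats::sd(X)
  if (!is.finite(sd_all) || sd_all == 0) sd_all <- 1
  X <- sweep(X, 2, col_mean) / sd_all

  cond <- config$conditioning
  if (length(cond)) {
    miss <- setdiff(cond, names(covariates))
    if (length(miss)) stop_arg("covariates missing: ", paste(miss, collapse = ", "))
    if (nrow(covariates) != n) stop_arg("covariates must match samples")
    Cov <- as.matrix(covariates[, cond, drop = FALSE])
    if (!all(is.finite(Cov))) stop_arg("conditioning covariates must be complete")
    cov_mean <- colMeans(Cov)
    cov_sd <- apply(Cov, 2, stats::sd); cov_sd[cov_sd == 0] <- 1
    Cov <- sweep(sweep(Cov, 2, cov_mean), 2, cov_sd, "/")
  } else {
    Cov <- matrix(0, n, 0); cov_mean <- numeric(0); cov_sd <- numeric(0)
  }
  y_mean <- mean(dementia_score)
  y_sd <- stats::sd(dementia_score); if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  y <- (dementia_score - y_mean) / y_sd

  with_seed(config$seed, {
    par <- cvae_init_params(ncol(X), config, ncol(Cov))
    m <- lapply(par, function(p) p * 0)
    v <- lapply(par, function(p) p * 0)
    b1t <- 1; b2t <- 1
    history <- data.frame(epoch = 0, cvae_forward(par, X, Cov, y, config)[
      c("total", "recon", "kld", "pred")])
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        ix <- ord[s:min(s + config$batch_size - 1L, n)]
        if (length(ix) < 2) next
        eps <- matrix(stats::rnorm(length(ix) * config$latent_dim),
                      length(ix), config$latent_dim)
        fw <- cvae_forward(par, X[ix, , drop = FALSE],
                           Cov[ix, , drop = FALSE], y[ix], config, eps)
        gr <- cvae_backward(par, fw, X[ix, , drop = FALSE],
                            Cov[ix, , drop = FALSE], y[ix], config)
        b1t <- b1t * 0.9; b2t <- b2t * 0.999
        for (nm in names(par)) {
          m[[nm]] <- 0.9 * m[[nm]] + 0.1 * gr[[nm]]
          v[[nm]] <- 0.999 * v[[nm]] + 0.001 * gr[[nm]]^2
          par[[nm]] <- par[[nm]] - config$lr * (m[[nm]] / (1 - b1t)) /
            (sqrt(v[[nm]] / (1 - b2t)) + 1e-8)
        }
      }
      ev <- cvae_forward(par, X, Cov, y, config)
      history <- rbind(history, data.frame(epoch = ep, ev[
        c("total", "recon", "kld", "pred")]))
    }
    structure(
      list(params = par, config = config, input_shape = shape, pool = f,
           col_mean = col_mean, sd_all = sd_all,
           cov_mean = cov_mean, cov_sd = cov_sd,
           y_mean = y_mean, y_sd = y_sd, history = history),
      class = "cvae"
    )
  })
}

#' @export
print.cvae <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "cvae: %s volumes (pool %d), latent %d, %d epochs; loss %.5g -> %.5g\n",
    paste(x$input_shape, collapse = "x"), x$pool, x$config$latent_dim,
    max(h$epoch), h$total[1], h$total[nrow(h)]))
  invisible(x)
}

cvae_prepare <- function(model, volumes, covariates = NULL,
                         need_cov = TRUE) {
  shape <- dim(volumes$volumes)[1:3]
  if (!identical(as.integer(shape), as.integer(model$input_shape))) {
    stop_arg("volume shape does not match the encoder's training shape")
  }
  X <- volumes_to_matrix(volumes, model$pool)
  X <- sweep(X, 2, model$col_mean) / model$sd_all
  cond <- model$config$conditioning
  if (length(cond) && need_cov) {
    if (is.null(covariates)) stop_arg("conditioned model needs covariates")
    Cov <- as.matrix(covariates[, cond, drop = FALSE])
    Cov <- sweep(sweep(Cov, 2, model$cov_mean), 2, model$cov_sd, "/")
  } else Cov <- matrix(0, nrow(X), 0)
  list(X = X, Cov = Cov)
}

#' Encode volumes to their latent means
#'
#' Deterministic inference-time encoding: each volume maps to the mean of
#' its approximate posterior (no sampling).
#'
#' @param model A trained [train_cvae] model.
#' @param volumes A [volume_stack] with the training shape.
#' @return A `latent_matrix`: n x latent_dim matrix with sample-id rownames
#'   and attribute `extractor = "cvae"`.
#' @export
encode_volumes <- function(model, volumes) {
  stopifnot(inherits(model, "cvae"))
  pr <- cvae_prepare(model, volumes, need_cov = FALSE)
  H1 <- relu(sweep(pr$X %*% model$params$W1, 2, model$params$b1, "+"))
  mu <- sweep(H1 %*% model$params$Wmu, 2, model$params$bmu, "+")
  rownames(mu) <- volumes$sample_ids
  colnames(mu) <- paste0("z", seq_len(ncol(mu)))
  structure(mu, extractor = "cvae")
}

#' Predict the dementia-like score from volumes
#'
#' Runs the trained prediction head on the latent means (plus conditioning
#' covariates), returning predictions on the original score scale.
#'
#' @inheritParams encode_volumes
#' @param covariates Covariate data frame (needed when conditioned).
#' @return Numeric vector of predicted scores.
#' @export
predict_dementia <- function(model, volumes, covariates = NULL) {
  stopifnot(inherits(model, "cvae"))
  pr <- cvae_prepare(model, volumes, covariates)
  mu <- encode_volumes(model, volumes)
  zc <- if (ncol(pr$Cov)) cbind(unclass(mu), pr$Cov) else unclass(mu)
  H3 <- relu(sweep(zc %*% model$params$Wh1, 2, model$params$bh1, "+"))
  yhat <- (H3 %*% model$params$Wh2)[, 1] + model$params$bh2
  yhat * model$y_sd + model$y_mean
}

#' Deterministic loss components of a trained model on a dataset
#'
#' Evaluates the multi-task objective at the latent mean (no sampling),
#' using the model's stored normalisation.
#'
#' @inheritParams predict_dementia
#' @param dementia_score Per-sample target.
#' @return Named list `total`, `recon`, `kld`, `pred`.
#' @export
cvae_loss <- function(model, volumes, covariates = NULL, dementia_score) {
  pr <- cvae_prepare(model, volumes, covariates)
  y <- (dementia_score - model$y_mean) / model$y_sd
  fw <- cvae_forward(model$params, pr$X, pr$Cov, y, model$config)
  fw[c("total", "recon", "kld", "pred")]
}
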