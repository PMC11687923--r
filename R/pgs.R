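#' Fit a clumping-and-thresholding polygenic score
#'
#' For each candidate p-value threshold, the summary statistics are clumped
#' (distance-based, index and member thresholds both at the candidate), the
#' index variants are retained with their marginal betas as weights, and a
#' score is computed on a held-out validation fold of the training samples;
#' the threshold maximising validation R-squared is selected.
#'
#' @param stats A [summary_stats] sharing variant ids with `panel`.
#' @param panel A [genotype_panel] of training samples.
#' @param y Per-sample trait used to validate the threshold choice.
#' @param p_thresholds Candidate thresholds (default
#'   `c(5e-8, 1e-6, 1e-4, 1e-2)`).
#' @param window_bp Clumping window (default 250 kb).
#' @param val_frac Validation fraction of the panel (default 0.3).
#' @param seed Fold-split seed.
#' @return A `pgs_weights` data frame (`id`, `effect_allele`,
#'   `other_allele`, `weight`) with attributes `p_threshold`, `window_bp`,
#'   and `validation_r2` (per candidate).  Empty (with a warning) when no
#'   variant passes any threshold.
#' @export
fit_ct_pgs <- function(stats, panel, y, p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-2),
                       window_bp = 250000, val_frac = 0.3, seed = 1) {
  stopifnot(inherits(stats, "summary_stats"), inherits(panel, "genotype_panel"))
  if (length(y) != nrow(panel$dosages)) stop_arg("y must match panel samples")
  n <- length(y)
  val <- with_seed(seed, sort(sample.int(n, max(2, round(val_frac * n)))))
  weights_at <- function(thr) {
    loci <- clump(stats, window_bp = window_bp, index_p = thr, member_p = thr)
    if (!nrow(loci)) return(NULL)
    m <- match(loci$index_id, stats$id)
    data.frame(id = stats$id[m], effect_allele = stats$a1[m],
               other_allele = stats$a2[m], weight = stats$beta[m],
               stringsAsFactors = FALSE)
  }
  r2s <- rep(NA_real_, length(p_thresholds))
  cands <- vector("list", length(p_thresholds))
  for (k in seq_along(p_thresholds)) {
    w <- weights_at(p_thresholds[k])
    cands[[k]] <- w
    if (is.null(w)) next
    s <- pgs_score(subset_panel(panel, samples = val), as_pgs_weights(w))
    r2s[k] <- if (stats::sd(s) == 0) 0 else stats::cor(s, y[val])^2
  }
  best <- which.max(r2s)
  if (!length(best) || all(is.na(r2s))) {
    warning("no variant passes any p threshold; empty PGS weights")
    out <- data.frame(id = character(), effect_allele = character(),
                      other_allele = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
    best_thr <- NA_real_
  } else {
    out <- cands[[best]]
    best_thr <- p_thresholds[best]
  }
  out <- as_pgs_weights(out)
  attr(out, "p_threshold") <- best_thr
  attr(out, "window_bp") <- window_bp
  attr(out, "validation_r2") <- stats::setNames(r2s, p_thresholds)
  out
}

as_pgs_weights <- function(df) {
  if (anyDuplicated(df$id)) stop_arg("PGS weight variant ids must be unique")
  if (nrow(df) && !all(is.finite(df$weight))) stop_arg("weights must be finite")
  class(df) <- c("pgs_weights", "data.frame")
  df
}

#' Score a cohort with polygenic-score weights
#'
#' `sum_j weight_j * (effect-allele dosage)_j` per sample.  When the
#' panel's alt allele is the weight's other allele (and the ref matches the
#' effect allele), the dosage is flipped to `2 - d`; variants absent from
#' the panel or with irreconcilable alleles are skipped and counted in the
#' `skipped` attribute.  Strand-ambiguous (A/T, C/G) variants are scored
#' as coded, with a warning.
#'
#' @param panel A [genotype_panel]; missing dosages mean-imputed.
#' @param weights A `pgs_weights` data frame.
#' @return Numeric per-sample score vector (attribute `skipped`).
#' @export
pgs_score <- function(panel, weights) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosages)
  score <- numeric(n)
  skipped <- 0L
  if (!nrow(weights)) {
    attr(score, "skipped") <- 0L
    return(score)
  }
  vm <- panel$variant_map
  m <- match(weights$id, vm$id)
  ambiguous <- 0L
  for (k in seq_len(nrow(weights))) {
    j <- m[k]
    if (is.na(j)) { skipped <- skipped + 1L; next }
    d <- panel$dosages[, j]
    if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
    pair <- sort(c(vm$ref[j], vm$alt[j]))
    if (identical(pair, c("A", "T")) || identical(pair, c("C", "G"))) {
      ambiguous <- ambiguous + 1L
    }
    if (vm$alt[j] == weights$effect_allele[k]) {
      score <- score + weights$weight[k] * d
    } else if (vm$alt[j] == weights$other_allele[k] &&
               vm$ref[j] == weights$effect_allele[k]) {
      score <- score + weights$weight[k] * (2 - d)
    } else {
      skipped <- skipped + 1L
    }
  }
  if (ambiguous) {
    warning(ambiguous, " strand-ambiguous variant(s) scored as coded")
  }
  attr(score, "skipped") <- skipped
  score
}

#' Compare nested multi-PGS prediction models
#'
#' Fits two linear models on a random train split — a baseline using the
#' base scores plus covariates, and an extended model adding the extra
#' scores — and compares their out-of-sample R-squared on the held-out
#' split, with a prediction-swap permutation test on the difference.
#'
#' @param y Per-sample outcome.
#' @param base_scores n x B matrix of baseline PGS columns.
#' @param extra_scores n x E matrix of additional PGS columns.
#' @param covariates Covariate data frame or `NULL`.
#' @param train_frac Training fraction (default 0.6, evaluation on the
#'   remaining 0.4).
#' @param n_perm Permutations for the swap test (default 1000).
#' @param seed Split and permutation seed.
#' @return An object of class `multi_pgs_eval`: `r2_base`, `r2_extended`,
#'   `delta`, `perm_p`, `n_train`, `n_test`, plus the held-out sample
#'   indices and both models' test-set predictions.
#' @export
multi_pgs_eval <- function(y, base_scores, extra_scores, covariates = NULL,
                           train_frac = 0.6, n_perm = 1000, seed = 1) {
  check_scalar(train_frac, "train_frac", lo = 0, hi = 1,
               lo_open = TRUE, hi_open = TRUE)
  base_scores <- as.matrix(base_scores)
  extra_scores <- as.matrix(extra_scores)
  n <- length(y)
  if (nrow(base_scores) != n || nrow(extra_scores) != n) {
    stop_arg("all inputs must share samples")
  }
  n_train <- round(train_frac * n)
  if (n_train < 2 || n - n_train < 3) stop_arg("degenerate split")
  C <- covariate_design(covariates, n)
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  test <- setdiff(seq_len(n), train)

  fit_predict <- function(X) {
    Xd <- cbind(C, X)
    fit <- stats::lm.fit(Xd[train, , drop = FALSE], y[train])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    drop(Xd[test, , drop = FALSE] %*% cf)
  }
  pred_base <- fit_predict(base_scores)
  pred_ext <- fit_predict(cbind(base_scores, extra_scores))
  r2 <- function(pred) 1 - sum((y[test] - pred)^2) / sum((y[test] - mean(y[test]))^2)
  r2b <- r2(pred_base); r2e <- r2(pred_ext)
  p <- permutation_test_r2(y[test], pred_base, pred_ext, n_perm = n_perm,
                           seed = child_seed(seed, "perm"))
  structure(
    list(r2_base = r2b, r2_extended = r2e, delta = r2e - r2b, perm_p = p,
         n_train = n_train, n_test = n - n_train, test_index = test,
         pred_base = pred_base, pred_ext = pred_ext),
    class = "multi_pgs_eval"
  )
}

#' @export
print.multi_pgs_eval <- function(x, ...) {
  cat(sprintf(
    "multi_pgs_eval: R2 base %.4f, extended %.4f, delta %+.4f (perm p = %.4g)\n",
    x$r2_base, x$r2_extended, x$delta, x$perm_p))
  invisible(x)
}

#' Prediction-swap permutation test for an R-squared difference
#'
#' The observed statistic is `R2(pred_ext) - R2(pred_base)` on the test
#' outcomes.  Each permutation assigns, independently per test sample with
#' a fair coin, one model's prediction to hybrid A and the other's to
#' hybrid B, and records the hybrid R-squared difference; the two-sided p
#' is `(1 + #{|delta_perm| >= |delta_obs|}) / (1 + n_perm)`.
#'
#' @param y_test Held-out outcomes.
#' @param pred_base,pred_ext Model predictions on the held-out samples.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return p-value in `[1 / (n_perm + 1), 1]`.
#' @export
permutation_test_r2 <- function(y_test, pred_base, pred_ext, n_perm = 1000,
                                seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  m <- length(y_test)
  if (length(pred_base) != m || length(pred_ext) != m) {
    stop_arg("prediction vectors must match y_test length")
  }
  ss_tot <- sum((y_test - mean(y_test))^2)
  if (ss_tot <= 0) stop_arg("y_test must vary")
  err_b <- (y_test - pred_base)^2
  err_e <- (y_test - pred_ext)^2
  delta_obs <- (sum(err_b) - sum(err_e)) / ss_tot
  with_seed(seed, {
    coins <- matrix(stats::runif(n_perm * m) < 0.5, n_perm, m)
    ss_a <- coins %*% err_e + (!coins) %*% err_b
    ss_b <- coins %*% err_b + (!coins) %*% err_e
    delta_perm <- (ss_b - ss_a) / ss_tot
    (1 + sum(abs(delta_perm) >= abs(delta_obs))) / (1 + n_perm)
  })
}
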