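#' Windowed LD scores from a genotype panel
#'
#' `l_j = sum_k r2_adj(j, k)` over all variants k within `window_bp` of j
#' on the same chromosome (self-term included), where
#' `r2_adj = r2 - (1 - r2) / (n - 2)` is the standard small-sample bias
#' adjustment.  Monomorphic variants are excluded with a warning.
#'
#' @param panel A [genotype_panel]; missing dosages mean-imputed.
#' @param window_bp Window (default 1 Mb).
#' @return Data frame of class `ldscore_table`: `id`, `chrom`, `pos`, `l`.
#' @export
ld_scores <- function(panel, window_bp = 1000000) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2]]
  }
  n <- nrow(X)
  mono <- apply(X, 2, stats::sd) == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) excluded from LD scores")
  }
  vm <- panel$variant_map[!mono, , drop = FALSE]
  X <- X[, !mono, drop = FALSE]
  l <- numeric(ncol(X))
  for (ch in unique(vm$chrom)) {
    idx <- which(vm$chrom == ch)
    R2 <- stats::cor(X[, idx, drop = FALSE])^2
    near <- abs(outer(vm$pos[idx], vm$pos[idx], "-")) <= window_bp
    r2adj <- R2 - (1 - R2) / (n - 2)
    l[idx] <- rowSums(r2adj * near)
  }
  out <- data.frame(id = vm$id, chrom = vm$chrom, pos = vm$pos, l = l,
                    stringsAsFactors = FALSE)
  class(out) <- c("ldscore_table", "data.frame")
  out
}

# weighted least squares of y on x with intercept; returns c(intercept, slope)
wls_fit <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sy - slope * sx) / sw
  c(intercept, slope)
}

# block-jackknife se of a statistic computed by fn(keep_index)
jackknife_se <- function(n, n_blocks, fn) {
  n_blocks <- min(n_blocks, n)
  bounds <- floor(seq(0, n, length.out = n_blocks + 1))
  ests <- vapply(seq_len(n_blocks), function(b) {
    drop_ix <- (bounds[b] + 1):bounds[b + 1]
    fn(setdiff(seq_len(n), drop_ix))
  }, 0)
  ests <- ests[is.finite(ests)]
  if (length(ests) < 2) return(NA_real_)
  sqrt((length(ests) - 1) / length(ests) * sum((ests - mean(ests))^2))
}

align_ld <- function(stats, ld) {
  m <- match(stats$id, ld$id)
  if (anyNA(m)) stop_arg("stats and LD-score table must share variants")
  ld$l[m]
}

#' LD-score-regression heritability
#'
#' Regresses per-variant chi-square (`z^2`) on LD score with a free
#' intercept; `h2 = slope * M / N`.  Weights are updated once from a first
#' pass (1/l, then `1 / (l * (1 + N h2_0 l / M)^2)`), and the standard
#' error comes from a 20-block contiguous jackknife.
#'
#' @param stats A [summary_stats].
#' @param ld An `ldscore_table` covering the stats' variants.
#' @param M Number of variants the heritability is spread over (default:
#'   number of regression variants).
#' @param n_blocks Jackknife blocks (default 20).
#' @return An object of class `ldsc_fit` with `h2`, `h2_se`, `intercept`,
#'   `intercept_se`, `M`, `N`, `n_variants`.
#' @export
ldsc_h2 <- function(stats, ld, M = NULL, n_blocks = 20) {
  stopifnot(inherits(stats, "summary_stats"))
  if (nrow(stats) < 50) stop_arg("fewer than 50 variants: LDSC is unstable")
  l <- align_ld(stats, ld)
  chi2 <- stats$z^2
  N <- stats::median(stats$n)
  if (is.null(M)) M <- nrow(stats)

  w0 <- 1 / pmax(l, 1)
  h2_0 <- max(min(wls_fit(l, chi2, w0)[2] * M / N, 1), 0)
  w <- 1 / (pmax(l, 1) * (1 + N * h2_0 * l / M)^2)
  est <- function(keep) wls_fit(l[keep], chi2[keep], w[keep])[2] * M / N
  fit <- wls_fit(l, chi2, w)
  h2 <- fit[2] * M / N
  h2_se <- jackknife_se(nrow(stats), n_blocks, est)
  int_se <- jackknife_se(nrow(stats), n_blocks, function(keep)
    wls_fit(l[keep], chi2[keep], w[keep])[1])
  structure(
    list(h2 = h2, h2_se = h2_se, intercept = fit[1], intercept_se = int_se,
         M = M, N = N, n_variants = nrow(stats)),
    class = "ldsc_fit"
  )
}

#' @export
print.ldsc_fit <- function(x, ...) {
  if (!is.null(x$rg)) {
    cat(sprintf("ldsc_fit: rg = %.3f (se %.3f), gcov intercept %.3f\n",
                x$rg, x$rg_se, x$intercept))
  } else {
    cat(sprintf("ldsc_fit: h2 = %.3f (se %.3f), intercept %.3f (se %.3f)\n",
                x$h2, x$h2_se, x$intercept, x$intercept_se))
  }
  invisible(x)
}

#' LD-score-regression genetic correlation
#'
#' Regresses the per-variant z-score product on LD score with a free
#' intercept; the genetic covariance is `slope * M / sqrt(N1 N2)` and
#' `rg = gcov / sqrt(h2_1 h2_2)` with the heritabilities from [ldsc_h2()]
#' on each trait.  The jackknife recomputes the full ratio per deleted
#' block.  The reported rg is clipped to `[-1.25, 1.25]`; the raw value is
#' kept in `rg_raw`.
#'
#' @param stats1,stats2 [summary_stats] sharing a variant universe.
#' @param ld An `ldscore_table`.
#' @param M Variant count for scaling (default: regression variants).
#' @param n_blocks Jackknife blocks (default 20).
#' @return An `ldsc_fit` with `rg`, `rg_raw`, `rg_se`, `gcov`, `intercept`
#'   (of the product regression), `h2_1`, `h2_2`; `rg` is `NA` (flagged
#'   `undefined`) when either heritability estimate is non-positive.
#' @export
ldsc_rg <- function(stats1, stats2, ld, M = NULL, n_blocks = 20) {
  if (!identical(stats1$id, stats2$id)) {
    m <- match(stats1$id, stats2$id)
    if (anyNA(m)) stop_arg("stats1 and stats2 must share their variant universe")
    stats2 <- stats2[m, , drop = FALSE]
  }
  if (nrow(stats1) < 50) stop_arg("fewer than 50 variants: LDSC is unstable")
  l <- align_ld(stats1, ld)
  if (is.null(M)) M <- nrow(stats1)
  f1 <- ldsc_h2(stats1, ld, M, n_blocks)
  f2 <- ldsc_h2(stats2, ld, M, n_blocks)
  N1 <- f1$N; N2 <- f2$N
  zz <- stats1$z * stats2$z
  w <- 1 / (pmax(l, 1) *
              (1 + N1 * max(f1$h2, 0) * l / M) *
              (1 + N2 * max(f2$h2, 0) * l / M))
  fit <- wls_fit(l, zz, w)
  gcov <- fit[2] * M / sqrt(N1 * N2)
  chi1 <- stats1$z^2; chi2_ <- stats2$z^2
  w1 <- 1 / (pmax(l, 1) * (1 + N1 * max(f1$h2, 0) * l / M)^2)
  w2 <- 1 / (pmax(l, 1) * (1 + N2 * max(f2$h2, 0) * l / M)^2)
  rg_of <- function(keep) {
    g <- wls_fit(l[keep], zz[keep], w[keep])[2] * M / sqrt(N1 * N2)
    h1 <- wls_fit(l[keep], chi1[keep], w1[keep])[2] * M / N1
    h2 <- wls_fit(l[keep], chi2_[keep], w2[keep])[2] * M / N2
    if (h1 <= 0 || h2 <= 0) return(NA_real_)
    g / sqrt(h1 * h2)
  }
  undefined <- f1$h2 <= 0 || f2$h2 <= 0
  rg_raw <- if (undefined) NA_real_ else gcov / sqrt(f1$h2 * f2$h2)
  rg_se <- jackknife_se(nrow(stats1), n_blocks, rg_of)
  structure(
    list(rg = if (undefined) NA_real_ else max(min(rg_raw, 1.25), -1.25),
         rg_raw = rg_raw, rg_se = rg_se, gcov = gcov, intercept = fit[1],
         h2_1 = f1$h2, h2_2 = f2$h2, M = M, N = c(N1, N2),
         undefined = undefined),
    class = "ldsc_fit"
  )
}

#' Select regions shared between a focal trait and two partner traits
#'
#' Candidate variants satisfy: focal p below `p_max`, z-score product
#' magnitude with each partner above `zprod_min`, and (where a sign is
#' supplied) the sign of the z-product matching the sign of the genetic
#' correlation.  Candidates are grouped greedily: the one with the largest
#' `|z_focal * z_b|` becomes a central variant absorbing all candidates
#' within `window_bp`; repeat until none remain.
#'
#' @param focal,trait_b,trait_c [summary_stats] sharing a variant universe.
#' @param p_max Focal-trait p-value ceiling (default 1e-4).
#' @param zprod_min z-product magnitude threshold (default 15).
#' @param window_bp Region half-width (default 250 kb).
#' @param rg_signs Length-2 numeric (`b`, `c`): the sign (+1/-1) each
#'   z-product must match, or `NA` to skip the sign filter for that
#'   partner.  Default `c(NA, 1)`.
#' @return Data frame of class `shared_regions`: one row per region with
#'   `central_id`, `chrom`, `central_pos`, `start`, `end`, `n_members`,
#'   `zprod_b`, `zprod_c`, and a `members` list-column.
#' @export
shared_regions <- function(focal, trait_b, trait_c, p_max = 1e-4,
                           zprod_min = 15, window_bp = 250000,
                           rg_signs = c(NA, 1)) {
  align <- function(s) {
    m <- match(focal$id, s$id)
    if (all(is.na(m))) stop_arg("empty overlap of variant universes")
    s[m, , drop = FALSE]
  }
  b <- align(trait_b); c_ <- align(trait_c)
  zb <- focal$z * b$z
  zc <- focal$z * c_$z
  ok <- !is.na(zb) & !is.na(zc) & focal$p < p_max &
    abs(zb) > zprod_min & abs(zc) > zprod_min
  if (!is.na(rg_signs[1])) ok <- ok & sign(zb) == sign(rg_signs[1])
  if (!is.na(rg_signs[2])) ok <- ok & sign(zc) == sign(rg_signs[2])
  cand <- which(ok)
  rows <- list()
  while (length(cand)) {
    i <- cand[which.max(abs(zb[cand]))]
    mem <- cand[focal$chrom[cand] == focal$chrom[i] &
                  abs(focal$pos[cand] - focal$pos[i]) <= window_bp]
    rows[[length(rows) + 1L]] <- data.frame(
      central_id = focal$id[i], chrom = focal$chrom[i],
      central_pos = focal$pos[i],
      start = max(1, focal$pos[i] - window_bp),
      end = focal$pos[i] + window_bp,
      n_members = length(mem), zprod_b = zb[i], zprod_c = zc[i],
      stringsAsFactors = FALSE
    )
    rows[[length(rows)]]$members <- I(list(focal$id[mem]))
    cand <- setdiff(cand, mem)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    central_id = character(), chrom = character(), central_pos = integer(),
    start = integer(), end = integer(), n_members = integer(),
    zprod_b = numeric(), zprod_c = numeric(), members = I(list()),
    stringsAsFactors = FALSE
  )
  class(out) <- c("shared_regions", "data.frame")
  out
}
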