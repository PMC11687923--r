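#' Construct a summary-statistics table
#'
#' Per-variant association results for one trait: effect estimate (per alt
#' allele, trait SD units), its standard error, z, two-sided p, sample size,
#' and allele frequency.
#'
#' @param df Data frame with columns `id`, `chrom`, `pos`, `a1` (effect
#'   allele), `a2`, `beta`, `se`, `z`, `p`, `n`, `maf`.
#' @param trait Optional trait tag stored as an attribute.
#' @return A data frame of class `summary_stats`.
#' @export
summary_stats <- function(df, trait = NULL) {
  need <- c("id", "chrom", "pos", "a1", "a2", "beta", "se", "z", "p", "n", "maf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_arg("summary_stats missing columns: ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop_arg("one row per variant required")
  if (any(df$se <= 0, na.rm = TRUE)) stop_arg("se must be > 0")
  if (any(abs(df$z - df$beta / df$se) > 1e-6, na.rm = TRUE)) {
    stop_arg("z must equal beta / se")
  }
  if (any(df$p <= 0 | df$p > 1, na.rm = TRUE)) stop_arg("p must lie in (0, 1]")
  df <- df[, c(need, setdiff(names(df), need)), drop = FALSE]
  class(df) <- c("summary_stats", "data.frame")
  attr(df, "trait") <- trait
  df
}

# two-sided normal p with underflow guarded away from exactly 0
z_to_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

#' Simulate paired GWAS summary statistics under the LD-score model
#'
#' Draws per-variant z-score pairs from the bivariate normal whose moments
#' are the LD-score-regression expectations: `E[chi2_j] = 1 + N h2 l_j / M`
#' for each trait and
#' `E[z1_j z2_j] = sqrt(N1 N2) rg sqrt(h2_1 h2_2) l_j / M` across traits.
#' Betas are reported on the standardized scale (`beta = z / sqrt(N)`,
#' `se = 1 / sqrt(N)`).
#'
#' @param ld_scores Per-variant LD scores (>= 1 elementwise), length `M`.
#' @param n1,n2 GWAS sample sizes for the two traits.
#' @param h2_1,h2_2 Heritabilities in `[0, 1]`.
#' @param rg Genetic correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @param variant_map Optional data frame (`chrom`, `pos`, `id`, `ref`,
#'   `alt`) giving the variants their coordinates; a generic grid is used
#'   when omitted.
#' @return List of two [summary_stats] tables sharing variants.
#' @export
simulate_sumstats <- function(ld_scores, n1, n2, h2_1, h2_2, rg, seed = 1,
                              variant_map = NULL) {
  M <- length(ld_scores)
  if (M < 1L) stop_arg("`ld_scores` must be non-empty")
  if (any(ld_scores < 1)) stop_arg("`ld_scores` must be >= 1 elementwise")
  n1 <- check_count(n1, "n1"); n2 <- check_count(n2, "n2")
  check_scalar(h2_1, "h2_1", lo = 0, hi = 1)
  check_scalar(h2_2, "h2_2", lo = 0, hi = 1)
  check_scalar(rg, "rg", lo = -1, hi = 1)

  v1 <- 1 + n1 * h2_1 * ld_scores / M
  v2 <- 1 + n2 * h2_2 * ld_scores / M
  cv <- sqrt(n1 * n2) * rg * sqrt(h2_1 * h2_2) * ld_scores / M

  with_seed(seed, {
    # conditional factorisation of the per-variant bivariate normal
    e1 <- stats::rnorm(M)
    e2 <- stats::rnorm(M)
    z1 <- sqrt(v1) * e1
    b <- cv / v1
    resid_var <- pmax(v2 - cv^2 / v1, 0)
    z2 <- b * z1 + sqrt(resid_var) * e2
    NULL
  })

  if (is.null(variant_map)) {
    variant_map <- data.frame(
      chrom = as.character(((seq_len(M) - 1L) %/% 1000L) %% 22L + 1L),
      pos = ((seq_len(M) - 1L) %% 1000L) * 2000L + 10000L,
      id = sprintf("sim%d", seq_len(M)),
      ref = "A", alt = "G", stringsAsFactors = FALSE
    )
  }
  mk <- function(z, n, tag) {
    summary_stats(data.frame(
      id = variant_map$id, chrom = variant_map$chrom, pos = variant_map$pos,
      a1 = variant_map$alt, a2 = variant_map$ref,
      beta = z / sqrt(n), se = 1 / sqrt(n), z = z, p = z_to_p(z),
      n = n, maf = NA_real_, stringsAsFactors = FALSE
    ), trait = tag)
  }
  list(mk(z1, n1, "trait1"), mk(z2, n2, "trait2"))
}
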