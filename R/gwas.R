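#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the expectation from the observed allele frequencies.
#' Monomorphic variants (allele frequency 0 or 1) fit the expectation
#' perfectly and return p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (dosage 0 / 1 / 2).
#' @return Two-sided p in (0, 1].
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: p = 1
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop_arg("all genotype counts are zero")
  q <- (2 * n_aa + n_Aa) / (2 * n)   # alt-allele frequency
  p <- 1 - q
  if (p == 0 || q == 0) return(1)
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  max(stats::pchisq(chi2, df = 1, lower.tail = FALSE), .Machine$double.xmin)
}

#' SNP and sample quality control
#'
#' Applies the standard pre-GWAS filters in order: minor-allele frequency,
#' missingness (samples with more than `miss_max` missing dosages are
#' dropped first, then variants), Hardy-Weinberg equilibrium, and windowed
#' greedy LD pruning.  Pruning scans positions left to right per chromosome
#' and drops the later variant of any pair with r-squared above `prune_r2`
#' within `prune_window_bp`, so the earlier variant of a pair always
#' survives.
#'
#' @param panel A [genotype_panel].
#' @param maf_min Minimum minor-allele frequency (default 0.001).
#' @param hwe_alpha HWE significance level below which a variant is removed
#'   (default 0.001).
#' @param miss_max Maximum missingness per variant and per sample (default
#'   0.1).
#' @param prune_r2 LD-pruning r-squared threshold (default 0.8).
#' @param prune_window_bp Pruning window in bp (default 500 kb).
#' @return List with `panel` (filtered) and `report` (class `qc_report`):
#'   counts removed by each filter in application order, plus survivors.
#' @export
qc_filter <- function(panel, maf_min = 0.001, hwe_alpha = 0.001,
                      miss_max = 0.1, prune_r2 = 0.8,
                      prune_window_bp = 500000) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_in <- ncol(panel$dosages)
  removed <- c(maf = 0L, missingness = 0L, hwe = 0L, ld_prune = 0L)

  f <- allele_freq(panel)
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= maf_min
  removed["maf"] <- sum(!keep)
  panel <- subset_panel(panel, variants = which(keep))

  smiss <- rowMeans(is.na(panel$dosages))
  samples_removed <- sum(smiss > miss_max)
  if (samples_removed) panel <- subset_panel(panel, samples = smiss <= miss_max)
  vmiss <- colMeans(is.na(panel$dosages))
  keep <- vmiss <= miss_max
  removed["missingness"] <- sum(!keep)
  panel <- subset_panel(panel, variants = which(keep))

  hwe_p <- apply(panel$dosages, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  keep <- hwe_p >= hwe_alpha
  removed["hwe"] <- sum(!keep)
  panel <- subset_panel(panel, variants = which(keep))

  keep <- ld_prune_keep(panel, prune_r2, prune_window_bp)
  removed["ld_prune"] <- sum(!keep)
  panel <- subset_panel(panel, variants = which(keep))

  report <- structure(
    list(removed = removed, survivors = ncol(panel$dosages),
         input = n_in, samples_removed = samples_removed),
    class = "qc_report"
  )
  stopifnot(sum(removed) + report$survivors == n_in)
  list(panel = panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$input, "variants in,", x$survivors, "surviving\n")
  for (f in names(x$removed)) cat(sprintf("  %-12s removed %d\n", f, x$removed[f]))
  if (x$samples_removed) cat("  samples removed:", x$samples_removed, "\n")
  invisible(x)
}

# greedy left-to-right LD prune; returns logical keep vector
ld_prune_keep <- function(panel, prune_r2, window_bp) {
  vm <- panel$variant_map
  keep <- rep(TRUE, nrow(vm))
  for (ch in unique(vm$chrom)) {
    idx <- which(vm$chrom == ch)  # already position-sorted
    kept <- integer(0)
    for (j in idx) {
      near <- kept[vm$pos[kept] >= vm$pos[j] - window_bp]
      drop <- FALSE
      for (k in near) {
        r <- suppressWarnings(stats::cor(panel$dosages[, j], panel$dosages[, k],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > prune_r2) { drop <- TRUE; break }
      }
      if (drop) keep[j] <- FALSE else kept <- c(kept, j)
    }
  }
  keep
}

# build the covariate design matrix (intercept, age, sex, batch dummies, PCs)
covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  stopifnot(nrow(covariates) == n)
  keep <- setdiff(names(covariates), "sample_id")
  df <- covariates[, keep, drop = FALSE]
  for (nm in names(df)) {
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  }
  X <- stats::model.matrix(~ ., data = df)
  # drop any collinear columns so the QR has full rank
  qrX <- qr(X)
  X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
}

#' Covariate-adjusted per-variant association scan
#'
#' Least-squares association of each trait with each variant's dosage,
#' adjusting for the covariate table (age, sex, batch, genetic PCs).  The
#' scan residualises traits and dosages against the covariate design
#' (Frisch-Waugh), so each variant's effect, standard error, and t-statistic
#' equal those of the full multiple regression `trait ~ dosage + covariates`.
#' Missing dosages are mean-imputed per variant.  A variant with zero
#' dosage variance after imputation is flagged (`zero_variance`) and
#' reported with beta 0 and p 1 rather than raising an error.
#'
#' @param panel A [genotype_panel].
#' @param traits Numeric vector or n x T matrix of traits (finite).
#' @param covariates Covariate data frame (row order matching the panel's
#'   samples) or `NULL` for an intercept-only adjustment.
#' @return A [summary_stats] for a single trait, or a named list of them.
#' @export
association_scan <- function(panel, traits, covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.vector(traits)) traits <- matrix(traits, ncol = 1)
  traits <- as.matrix(traits)
  n <- nrow(panel$dosages)
  if (nrow(traits) != n) stop_arg("traits and panel must share samples")
  if (!all(is.finite(traits))) stop_arg("traits must be finite")
  if (is.null(colnames(traits))) {
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  }

  X <- panel$dosages
  f <- colMeans(X, na.rm = TRUE) / 2
  if (anyNA(X)) {
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- 2 * f[nas[, 2]]
  }

  C <- covariate_design(covariates, n)
  Q <- qr.Q(qr(C))
  Xr <- X - Q %*% crossprod(Q, X)
  Yr <- traits - Q %*% crossprod(Q, traits)

  xtx <- colSums(Xr^2)
  zero_var <- xtx < 1e-12
  xtx_safe <- ifelse(zero_var, 1, xtx)
  df <- n - ncol(C) - 1L
  if (df < 1) stop_arg("not enough samples for the covariate design")

  maf <- pmin(f, 1 - f)
  out <- lapply(seq_len(ncol(traits)), function(t) {
    xty <- crossprod(Xr, Yr[, t])[, 1]
    beta <- xty / xtx_safe
    rss <- sum(Yr[, t]^2) - beta * xty
    se <- sqrt(pmax(rss, 0) / df / xtx_safe)
    beta[zero_var] <- 0
    se[zero_var | se < 1e-300] <- Inf
    z <- beta / se
    z[!is.finite(z)] <- 0
    p <- 2 * stats::pt(-abs(z), df = df)
    p <- pmax(p, .Machine$double.xmin)
    p[zero_var] <- 1
    vm <- panel$variant_map
    summary_stats(data.frame(
      id = vm$id, chrom = vm$chrom, pos = vm$pos, a1 = vm$alt, a2 = vm$ref,
      beta = beta, se = se, z = z, p = p, n = n, maf = maf,
      zero_variance = zero_var, stringsAsFactors = FALSE
    ), trait = colnames(traits)[t])
  })
  names(out) <- colnames(traits)
  if (length(out) == 1L) out[[1]] else out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha_per_test Significance level for a single test.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha_per_test / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(5e-8, 20)     # 2.5e-9: genome-wide level over 20 PCs
#' bonferroni_threshold(0.05, 102 * 20)
bonferroni_threshold <- function(alpha_per_test, n_tests) {
  n_tests <- check_count(n_tests, "n_tests", min = 1L)
  check_scalar(alpha_per_test, "alpha_per_test", lo = 0, hi = 1,
               lo_open = TRUE)
  alpha_per_test / n_tests
}

#' Clump summary statistics into independent loci
#'
#' Greedy distance-based clumping: repeatedly take the unclaimed variant
#' with the smallest p not exceeding `index_p` (ties broken by chromosome
#' then position) as an index; it founds a locus claiming every unclaimed
#' variant with p at most `member_p` within `window_bp` of it on the same
#' chromosome.
#'
#' @param stats A [summary_stats], sorted by (chrom, pos).
#' @param window_bp Physical claim window around the index (default 250 kb).
#' @param index_p Index-variant significance threshold (default 1e-9).
#' @param member_p Membership significance threshold (default 5e-8).
#' @return A `locus_table` data frame: `index_id`, `chrom`, `index_pos`,
#'   `start`, `end`, `min_p`, `n_members`, `trait`, and a `members`
#'   list-column of member variant ids.
#' @export
clump <- function(stats, window_bp = 250000, index_p = 1e-9,
                  member_p = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"))
  if (nrow(stats)) {
    runs <- rle(as.character(stats$chrom))
    if (anyDuplicated(runs$values)) {
      stop_arg("`stats` must be grouped by chromosome")
    }
    for (ch in runs$values) {
      p <- stats$pos[stats$chrom == ch]
      if (length(p) > 1L && any(diff(p) < 0)) {
        stop_arg("`stats` must be position-sorted within chromosome")
      }
    }
  }
  claimed <- rep(FALSE, nrow(stats))
  rows <- list()
  repeat {
    cand <- which(!claimed & stats$p <= index_p)
    if (!length(cand)) break
    cand <- cand[order(stats$p[cand], stats$chrom[cand], stats$pos[cand])]
    i <- cand[1]
    mem <- which(!claimed &
                   stats$chrom == stats$chrom[i] &
                   abs(stats$pos - stats$pos[i]) <= window_bp &
                   stats$p <= member_p)
    mem <- union(i, mem)
    claimed[mem] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      index_id = stats$id[i], chrom = stats$chrom[i],
      index_pos = stats$pos[i],
      start = max(1, stats$pos[i] - window_bp),
      end = stats$pos[i] + window_bp,
      min_p = stats$p[i], n_members = length(mem),
      trait = attr(stats, "trait") %||% NA_character_,
      stringsAsFactors = FALSE
    )
    rows[[length(rows)]]$members <- I(list(stats$id[mem]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    index_id = character(), chrom = character(), index_pos = integer(),
    start = integer(), end = integer(), min_p = numeric(),
    n_members = integer(), trait = character(),
    members = I(list()), stringsAsFactors = FALSE
  )
  class(out) <- c("locus_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate summary statistics across traits by minimum p
#'
#' Per variant, keeps the row with the smallest p across the supplied trait
#' scans and records which trait attained it — the cross-feature view used
#' for aggregated Manhattan plots and locus discovery over all PCs.
#'
#' @param stats_list List of [summary_stats] sharing the variant universe.
#' @return A [summary_stats] with an extra `trait` column.
#' @export
aggregate_traits <- function(stats_list) {
  stopifnot(length(stats_list) >= 1L)
  ids <- stats_list[[1]]$id
  for (s in stats_list) {
    if (!identical(s$id, ids)) stop_arg("traits must share the variant universe")
  }
  P <- sapply(stats_list, function(s) s$p)
  if (is.vector(P)) P <- matrix(P, nrow = 1)
  win <- max.col(-P, ties.method = "first")
  tags <- vapply(seq_along(stats_list), function(k) {
    attr(stats_list[[k]], "trait") %||% paste0("trait", k)
  }, "")
  out <- stats_list[[1]]
  for (j in seq_len(nrow(out))) {
    out[j, c("beta", "se", "z", "p", "n", "maf")] <-
      stats_list[[win[j]]][j, c("beta", "se", "z", "p", "n", "maf")]
  }
  out$trait <- tags[win]
  attr(out, "trait") <- "min_p"
  out
}

#' Match loci between two trait scans
#'
#' Loci from two tables are shared when their index variants lie on the same
#' chromosome within `window_bp`; matching is greedy by ascending distance,
#' each locus used at most once.
#'
#' @param a,b `locus_table`s.
#' @param window_bp Matching window (default 250 kb).
#' @return List with `shared` (data frame of matched index pairs and their
#'   distance), `a_only`, `b_only`.
#' @export
merge_loci <- function(a, b, window_bp = 250000) {
  pairs <- NULL
  if (nrow(a) && nrow(b)) {
    for (i in seq_len(nrow(a))) {
      j <- which(b$chrom == a$chrom[i] &
                   abs(b$index_pos - a$index_pos[i]) <= window_bp)
      if (length(j)) {
        pairs <- rbind(pairs, data.frame(
          i = i, j = j, dist = abs(b$index_pos[j] - a$index_pos[i])
        ))
      }
    }
  }
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  shared <- data.frame(a_index = character(), b_index = character(),
                       chrom = character(), dist = integer(),
                       stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$dist), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      shared <- rbind(shared, data.frame(
        a_index = a$index_id[i], b_index = b$index_id[j],
        chrom = a$chrom[i], dist = pairs$dist[k], stringsAsFactors = FALSE
      ))
    }
  }
  list(shared = shared,
       a_only = a[!used_a, , drop = FALSE],
       b_only = b[!used_b, , drop = FALSE])
}

#' Discovery / replication split analysis
#'
#' Splits the cohort into disjoint discovery and replication sets, clumps
#' the discovery scan, and declares a discovery locus replicated when its
#' index variant reaches `replication_alpha` in the replication scan with a
#' concordant effect sign.
#'
#' @param panel A [genotype_panel].
#' @param traits Numeric vector or matrix of traits.
#' @param covariates Covariate data frame or `NULL`.
#' @param frac Discovery fraction in (0, 1).
#' @param index_p Discovery index threshold (default 1e-9).
#' @param replication_alpha Replication p threshold (default 0.05).
#' @param window_bp,member_p Clumping parameters.
#' @param seed Split seed.
#' @return `locus_table` of discovery loci with logical column `replicated`
#'   and columns `replication_p`, `replication_beta`.
#' @export
replicate_split <- function(panel, traits, covariates = NULL, frac = 0.65,
                            index_p = 1e-9, replication_alpha = 0.05,
                            window_bp = 250000, member_p = 5e-8, seed = 1) {
  check_scalar(frac, "frac", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  if (is.vector(traits)) traits <- matrix(traits, ncol = 1)
  n <- nrow(panel$dosages)
  n_disc <- round(frac * n)
  if (n_disc < 2 || n - n_disc < 2) stop_arg("degenerate split")
  disc <- with_seed(seed, sort(sample.int(n, n_disc)))
  repl <- setdiff(seq_len(n), disc)
  sub <- function(ix) {
    list(panel = subset_panel(panel, samples = ix),
         traits = traits[ix, , drop = FALSE],
         cov = if (is.null(covariates)) NULL else
           covariates[ix, , drop = FALSE])
  }
  d <- sub(disc); r <- sub(repl)
  out <- NULL
  for (t in seq_len(ncol(traits))) {
    sd_ <- association_scan(d$panel, d$traits[, t], d$cov)
    attr(sd_, "trait") <- colnames(traits)[t] %||% paste0("trait", t)
    loci <- clump(sd_, window_bp, index_p, member_p)
    if (!nrow(loci)) next
    sr <- association_scan(r$panel, r$traits[, t], r$cov)
    m <- match(loci$index_id, sr$id)
    loci$replication_p <- sr$p[m]
    loci$replication_beta <- sr$beta[m]
    disc_beta <- sd_$beta[match(loci$index_id, sd_$id)]
    loci$replicated <- !is.na(loci$replication_p) &
      loci$replication_p < replication_alpha &
      sign(loci$replication_beta) == sign(disc_beta)
    out <- if (is.null(out)) loci else rbind(out, loci)
  }
  if (is.null(out)) {
    out <- clump(summary_stats(data.frame(
      id = character(), chrom = character(), pos = integer(), a1 = character(),
      a2 = character(), beta = numeric(), se = numeric(), z = numeric(),
      p = numeric(), n = integer(), maf = numeric())), window_bp, index_p,
      member_p)
    out$replication_p <- numeric(0)
    out$replication_beta <- numeric(0)
    out$replicated <- logical(0)
  }
  out
}
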