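#' Construct a genotype panel
#'
#' A genotype panel holds alt-allele dosages for a cohort together with a
#' variant map.  Dosages are counts in `[0, 2]`; missing genotypes are `NA`.
#'
#' @param sample_ids Character vector of unique sample labels.
#' @param variant_map Data frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt`; positions strictly increasing within chromosome.
#' @param dosages Numeric matrix, samples x variants.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sample_ids, variant_map, dosages) {
  sample_ids <- as.character(sample_ids)
  dosages <- as.matrix(dosages)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- as.character(variant_map$id)
  panel <- structure(
    list(sample_ids = sample_ids, variant_map = variant_map,
         dosages = dosages),
    class = "genotype_panel"
  )
  validate_genotype_panel(panel)
}

#' @rdname genotype_panel
#' @param panel A `genotype_panel`.
#' @export
validate_genotype_panel <- function(panel) {
  vm <- panel$variant_map
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(vm))) {
    stop_arg("variant_map must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(panel$sample_ids)) stop_arg("sample_ids must be unique")
  if (anyDuplicated(vm$id)) stop_arg("variant ids must be unique")
  if (any(vm$ref == vm$alt)) stop_arg("ref and alt alleles must differ")
  for (ch in unique(vm$chrom)) {
    p <- vm$pos[vm$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop_arg("positions must be strictly increasing within chromosome ", ch)
    }
  }
  d <- panel$dosages
  if (nrow(d) != length(panel$sample_ids) || ncol(d) != nrow(vm)) {
    stop_arg("dosage matrix dimensions do not match sample/variant counts")
  }
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop_arg("dosages must lie in [0, 2]")
  }
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d samples x %d variants (%d chromosomes, %.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$variant_map$chrom)),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param panel A `genotype_panel`.
#' @param samples,variants Index vectors (logical, integer, or names) applied
#'   to samples and variants; `NULL` keeps all.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  if (is.null(samples)) samples <- seq_along(panel$sample_ids)
  if (is.null(variants)) variants <- seq_len(nrow(panel$variant_map))
  if (is.character(variants)) variants <- match(variants, panel$variant_map$id)
  genotype_panel(
    panel$sample_ids[samples],
    panel$variant_map[variants, , drop = FALSE],
    panel$dosages[samples, variants, drop = FALSE]
  )
}

#' Simulate genotypes in LD blocks
#'
#' Draws diploid dosages from a block-wise latent Gaussian copula: each LD
#' block has an AR(1) latent correlation (`block_corr^|i-j|` between variants
#' `i` and `j` of the block), two independent latent haplotype draws are
#' thresholded at the allele-frequency quantile, and their sum is the dosage.
#' Blocks are independent, so inter-block r2 is centred on zero, and the two
#' independent haplotypes give Hardy-Weinberg genotype proportions.
#'
#' Blocks are laid out cyclically over chromosomes 1-22 with intra-block
#' spacing chosen so a block spans under 250 kb, and at least 1 Mb between
#' blocks on the same chromosome.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_variants Number of variants (>= 1).
#' @param maf_range Interval in (0, 0.5] the per-variant target minor-allele
#'   frequency is drawn from (uniformly).
#' @param ld_block_size Variants per LD block.
#' @param block_corr Latent AR(1) correlation between adjacent variants of a
#'   block, in `[0, 1)`.
#' @param missing_rate Fraction of dosages set missing uniformly at random.
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @return A [genotype_panel].
#' @export
#' @examples
#' p <- simulate_genotypes(100, 50, seed = 1)
#' dim(p$dosages)
simulate_genotypes <- function(n_samples, n_variants,
                               maf_range = c(0.05, 0.5),
                               ld_block_size = 25, block_corr = 0.7,
                               missing_rate = 0, seed = 1) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  n_variants <- check_count(n_variants, "n_variants", min = 1L)
  ld_block_size <- check_count(ld_block_size, "ld_block_size", min = 1L)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2]) {
    stop_arg("`maf_range` must be an interval c(lo, hi)")
  }
  check_scalar(maf_range[1], "maf_range[1]", lo = 0, hi = 0.5, lo_open = TRUE)
  check_scalar(maf_range[2], "maf_range[2]", lo = 0, hi = 0.5, lo_open = TRUE)
  check_scalar(block_corr, "block_corr", lo = 0, hi = 1, hi_open = TRUE)
  check_scalar(missing_rate, "missing_rate", lo = 0, hi = 1, hi_open = TRUE)

  n_blocks <- ceiling(n_variants / ld_block_size)
  block_of <- rep(seq_len(n_blocks), each = ld_block_size)[seq_len(n_variants)]
  spacing <- max(1L, min(2000L,
                         as.integer(249000 %/% max(ld_block_size - 1L, 1L))))

  with_seed(seed, {
    maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
    thresh <- stats::qnorm(1 - maf)  # latent above threshold => alt allele

    dos <- matrix(0, n_samples, n_variants)
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      m <- length(idx)
      R <- block_corr^abs(outer(seq_len(m), seq_len(m), "-"))
      L <- chol(R)
      h1 <- matrix(stats::rnorm(n_samples * m), n_samples, m) %*% L
      h2 <- matrix(stats::rnorm(n_samples * m), n_samples, m) %*% L
      tb <- rep(thresh[idx], each = n_samples)
      dos[, idx] <- (h1 > tb) + (h2 > tb)
    }
    if (missing_rate > 0) {
      dos[stats::runif(length(dos)) < missing_rate] <- NA_real_
    }

    # genomic layout: contiguous block chunks per chromosome, big gaps
    chunk <- ceiling(n_blocks / 22)
    chrom_of_block <- ceiling(seq_len(n_blocks) / chunk)
    pos <- integer(n_variants)
    chrom <- character(n_variants)
    offset <- integer(22)
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      ch <- chrom_of_block[b]
      start <- offset[ch] + 1000000L
      pos[idx] <- start + (seq_along(idx) - 1L) * spacing
      chrom[idx] <- as.character(ch)
      offset[ch] <- max(pos[idx])
    }
    # avoid strand-ambiguous (A/T, C/G) pairs so allele matching is exact
    alleles <- c("A", "C", "G", "T")
    complement <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- sample(alleles, n_variants, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(alleles, c(r, complement[[r]])), 1L), "")

    vm <- data.frame(
      chrom = chrom, pos = pos,
      id = sprintf("rs%d_%d", seq_len(n_variants), pos),
      ref = ref, alt = unname(alt),
      maf = maf, block = block_of,
      stringsAsFactors = FALSE
    )
    genotype_panel(sprintf("S%04d", seq_len(n_samples)), vm, dos)
  })
}

#' Per-variant alt-allele frequency of a panel
#'
#' @param panel A [genotype_panel].
#' @return Numeric vector of alt-allele frequencies (missing dosages ignored).
#' @export
allele_freq <- function(panel) {
  colMeans(panel$dosages, na.rm = TRUE) / 2
}
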