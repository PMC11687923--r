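# Shared fixture builders: everything generated in code at test time.

# hand-built 4-sample, 3-variant panel with known dosages
tiny_panel <- function() {
  vm <- data.frame(
    chrom = c("1", "1", "2"), pos = c(1000L, 5000L, 2000L),
    id = c("v1", "v2", "v3"),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    stringsAsFactors = FALSE
  )
  dos <- matrix(c(0, 1, 2, 1,
                  2, 2, 0, 1,
                  1, 0, 1, 2), nrow = 4)
  genotype_panel(paste0("s", 1:4), vm, dos)
}

# small cohort with a planted radius effect on ROI 1 (the ventricle)
small_cohort <- function(n = 80, seed = 42, beta = 0.8, n_variants = 30,
                         shape = c(16, 16, 16), ...) {
  panel <- simulate_genotypes(n, n_variants, c(0.2, 0.4),
                              ld_block_size = 10, block_corr = 0.5,
                              seed = seed)
  eff <- effect_spec(
    effects = data.frame(variant_index = 3L, roi = 1L, beta = beta,
                         target = "radius"),
    ...)
  cohort <- simulate_cohort(panel, eff, shape, n_rois = 4, seed = seed + 1)
  list(panel = panel, cohort = cohort, eff = eff)
}

# summary_stats table built from positions and p-values (z kept consistent)
make_stats <- function(pos, p, chrom = "1", sign = 1, n = 1000, trait = "t",
                       id = paste0("s", seq_along(pos))) {
  m <- length(pos)
  z <- stats::qnorm(p / 2, lower.tail = FALSE) * rep_len(sign, m)
  se <- rep(1 / sqrt(n), m)
  summary_stats(data.frame(
    id = id, chrom = rep_len(chrom, m), pos = pos,
    a1 = "G", a2 = "A", beta = z * se, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), n = n, maf = 0.25,
    stringsAsFactors = FALSE
  ), trait = trait)
}
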