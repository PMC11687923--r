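#' Rank-based inverse-normal transform
#'
#' Blom-offset rank normalisation, the standard preprocessing for
#' continuous phenotypes in phenome-wide scans.  Ties share the average
#' rank; missing values stay missing.
#'
#' @param x Numeric vector.
#' @return Transformed vector with standard-normal marginal distribution.
#' @export
inverse_normal_transform <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

#' Phenome-wide association scan of image-derived traits
#'
#' Tests each trait against each phenotype of a typed phenotype bank,
#' always adjusting for age and sex.  Continuous phenotypes are rank
#' inverse-normal transformed (`int = TRUE`) and fit by least squares;
#' binary phenotypes by logistic regression — the automatic model choice a
#' phenome-scan tool applies from phenotype metadata.  A binary phenotype
#' with a single observed class is flagged untestable instead of erroring.
#'
#' @param scores Numeric vector or n x T matrix of image-derived traits.
#' @param phenobank Data frame of phenotypes (one column each).
#' @param types Character vector (`"continuous"` or `"binary"`), one per
#'   phenotype column.
#' @param covariates Data frame with `age` and `sex` columns.
#' @param categories Optional per-phenotype category tags.
#' @param int Apply the inverse-normal transform to continuous phenotypes.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @return A `phewas_result` data frame: one row per (trait, phenotype)
#'   with `model`, `effect`, `se`, `p`, `category`, `untestable`; the
#'   Bonferroni threshold over `n_traits * n_phenotypes` tests is stored in
#'   attribute `threshold`.
#' @export
phewas_scan <- function(scores, phenobank, types, covariates,
                        categories = NULL, int = TRUE, alpha = 0.05) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("trait", seq_len(ncol(scores)))
  }
  phenobank <- as.data.frame(phenobank)
  if (length(types) != ncol(phenobank)) {
    stop_arg("one declared type per phenotype required")
  }
  if (!all(types %in% c("continuous", "binary"))) {
    stop_arg("phenotype types must be 'continuous' or 'binary'")
  }
  if (!all(c("age", "sex") %in% names(covariates))) {
    stop_arg("covariates must contain age and sex")
  }
  if (is.null(categories)) categories <- rep(NA_character_, ncol(phenobank))
  age <- covariates$age; sex <- covariates$sex

  rows <- vector("list", ncol(scores) * ncol(phenobank))
  k <- 0L
  for (t in seq_len(ncol(scores))) {
    sc <- scores[, t]
    for (ph in seq_len(ncol(phenobank))) {
      y <- phenobank[[ph]]
      k <- k + 1L
      untestable <- FALSE; eff <- NA_real_; se <- NA_real_; p <- NA_real_
      if (types[ph] == "binary" && length(unique(y[!is.na(y)])) < 2) {
        untestable <- TRUE
        model <- "untestable"
      } else if (types[ph] == "continuous") {
        model <- "linear"
        yy <- if (int) inverse_normal_transform(y) else y
        fit <- stats::lm(yy ~ sc + age + sex)
        cf <- summary(fit)$coefficients
        if ("sc" %in% rownames(cf)) {
          eff <- cf["sc", 1]; se <- cf["sc", 2]; p <- cf["sc", 4]
        } else untestable <- TRUE
      } else {
        model <- "logistic"
        fit <- suppressWarnings(
          stats::glm(y ~ sc + age + sex, family = stats::binomial()))
        cf <- summary(fit)$coefficients
        if ("sc" %in% rownames(cf)) {
          eff <- cf["sc", 1]; se <- cf["sc", 2]; p <- cf["sc", 4]
        } else untestable <- TRUE
      }
      rows[[k]] <- data.frame(
        trait = colnames(scores)[t],
        phenotype = names(phenobank)[ph] %||% paste0("pheno", ph),
        model = model, effect = eff, se = se,
        p = if (!is.na(p)) max(p, .Machine$double.xmin) else NA_real_,
        category = categories[ph], untestable = untestable,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("phewas_result", "data.frame")
  attr(out, "threshold") <- bonferroni_threshold(
    alpha, ncol(scores) * ncol(phenobank))
  out
}

#' Voxel-wise statistical parametric map
#'
#' Per in-mask voxel, the Pearson correlation between voxel intensity and a
#' per-sample variable (e.g. a lead variant's dosage), converted to a
#' t-statistic `t = r sqrt((n - 2) / (1 - r^2))`.  The significance
#' threshold is the two-sided t quantile at `alpha` Bonferroni-corrected
#' for the number of in-mask voxels tested.  Constant voxels get t = 0 and
#' are flagged.
#'
#' @param volumes A [volume_stack].
#' @param variable Per-sample numeric variable (must vary).
#' @param brain_mask Logical array of the volume shape; `NULL` tests all
#'   voxels.
#' @param alpha Family-wise level (default 0.05).
#' @return An object of class `spmap`: `t` (array), `n`, `threshold` (t
#'   units), `significant` (logical array `|t| >= threshold`, FALSE outside
#'   the mask), `mask`, `constant_voxels` count.
#' @export
voxel_spm <- function(volumes, variable, brain_mask = NULL, alpha = 0.05) {
  stopifnot(inherits(volumes, "volume_stack"))
  n <- n_volumes(volumes)
  shape <- dim(volumes$volumes)[1:3]
  if (length(variable) != n) stop_arg("one variable value per sample required")
  if (stats::sd(variable) == 0) stop_arg("`variable` must vary across samples")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = shape)
  if (!any(brain_mask)) stop_arg("empty brain mask")
  m <- sum(brain_mask)

  V <- matrix(volumes$volumes, nrow = prod(shape))[as.vector(brain_mask), ,
                                                   drop = FALSE]
  vc <- variable - mean(variable)
  Vc <- V - rowMeans(V)
  num <- Vc %*% vc
  den <- sqrt(rowSums(Vc^2) * sum(vc^2))
  constant <- den < 1e-12
  r <- ifelse(constant, 0, num / pmax(den, 1e-300))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  tstat[constant] <- 0

  thr <- stats::qt(1 - (alpha / m) / 2, df = n - 2)
  tarr <- array(0, dim = shape)
  tarr[as.vector(brain_mask)] <- tstat
  sig <- array(FALSE, dim = shape)
  sig[as.vector(brain_mask)] <- abs(tstat) >= thr
  structure(
    list(t = tarr, n = n, threshold = thr, significant = sig,
         mask = brain_mask, constant_voxels = sum(constant), alpha = alpha),
    class = "spmap"
  )
}

#' @export
print.spmap <- function(x, ...) {
  cat(sprintf("spmap: n = %d, |t| threshold %.3f, %d significant voxels\n",
              x$n, x$threshold, sum(x$significant)))
  invisible(x)
}

#' Fraction of significantly associated voxels per ROI
#'
#' For each ROI: the number of significant voxels inside it divided by its
#' voxel count — the per-region summary of how much of a structure an
#' association map touches.
#'
#' @param spm An `spmap` from [voxel_spm()].
#' @param roi_labels Integer label array (0 = background).
#' @return Named numeric vector in `[0, 1]`, one entry per ROI label.
#' @export
roi_fraction <- function(spm, roi_labels) {
  stopifnot(inherits(spm, "spmap"))
  labs <- sort(unique(as.integer(roi_labels)))
  labs <- labs[labs != 0L]
  out <- vapply(labs, function(l) {
    inroi <- roi_labels == l
    sum(spm$significant[inroi]) / sum(inroi)
  }, 0)
  stats::setNames(out, sprintf("roi%d", labs))
}

#' Variance explained per ROI by a per-sample variable
#'
#' Variance-weighted per-voxel R-squared over the voxels of each ROI:
#' `sum_v r2_v Var_v / sum_v Var_v`, where `Var_v` is the across-sample
#' intensity variance of voxel v.  Voxels with zero variance contribute
#' nothing to either sum.
#'
#' @param volumes A [volume_stack].
#' @param variable Per-sample numeric variable.
#' @param roi_labels Integer label array (0 = background).
#' @return Named numeric vector in `[0, 1]` per ROI label.
#' @export
roi_variance_explained <- function(volumes, variable, roi_labels) {
  stopifnot(inherits(volumes, "volume_stack"))
  n <- n_volumes(volumes)
  if (length(variable) != n) stop_arg("one variable value per sample required")
  shape <- dim(volumes$volumes)[1:3]
  V <- matrix(volumes$volumes, nrow = prod(shape))
  vc <- variable - mean(variable)
  Vc <- V - rowMeans(V)
  ssv <- rowSums(Vc^2)
  num <- (Vc %*% vc)[, 1]
  r2 <- ifelse(ssv < 1e-300 | sum(vc^2) < 1e-300, 0,
               num^2 / (ssv * sum(vc^2)))
  labs <- sort(unique(as.integer(roi_labels)))
  labs <- labs[labs != 0L]
  out <- vapply(labs, function(l) {
    ix <- which(as.vector(roi_labels == l))
    tot <- sum(ssv[ix])
    if (tot <= 0) return(0)
    sum(r2[ix] * ssv[ix]) / tot
  }, 0)
  stats::setNames(pmin(pmax(out, 0), 1), sprintf("roi%d", labs))
}
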