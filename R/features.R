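#' Slice-averaged 2D feature encoding of 3D volumes
#'
#' Applies a user-supplied 2D feature function to every axial slice of each
#' volume and averages the resulting vectors — the standard trick for
#' putting a pretrained 2D image encoder to work on 3D data.  Any function
#' mapping a 2D matrix to a fixed-length numeric vector can be plugged in;
#' [random_projection_features()] provides a seeded default.
#'
#' @param volumes A [volume_stack].
#' @param feature_fn Function taking a 2D numeric matrix (an axial slice)
#'   and returning a length-d numeric vector (the same d for every slice).
#' @param axis Slicing axis; only `"axial"` (the third axis) is supported.
#' @return A `latent_matrix`: n x d matrix with sample-id rownames and
#'   attribute `extractor = "slice2d"`.
#' @export
slice_average_encode <- function(volumes, feature_fn, axis = "axial") {
  stopifnot(inherits(volumes, "volume_stack"))
  axis <- match.arg(axis, "axial")
  n <- n_volumes(volumes)
  nz <- dim(volumes$volumes)[3]
  out <- NULL
  for (i in seq_len(n)) {
    acc <- NULL
    for (k in seq_len(nz)) {
      fv <- feature_fn(volumes$volumes[, , k, i])
      if (!is.numeric(fv)) stop_arg("feature_fn must return a numeric vector")
      if (is.null(acc)) {
        acc <- as.numeric(fv)
      } else {
        if (length(fv) != length(acc)) {
          stop_arg("feature_fn returned vectors of inconsistent length")
        }
        acc <- acc + as.numeric(fv)
      }
    }
    if (is.null(out)) out <- matrix(NA_real_, n, length(acc))
    if (length(acc) != ncol(out)) {
      stop_arg("feature_fn returned vectors of inconsistent length")
    }
    out[i, ] <- acc / nz
  }
  rownames(out) <- volumes$sample_ids
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  structure(out, extractor = "slice2d")
}

#' Seeded random-projection slice features
#'
#' Returns a feature function projecting a flattened 2D slice onto `d`
#' fixed Gaussian directions.  This is the default stand-in for a
#' pretrained 2D encoder: it is deterministic given the seed, linear, and
#' information-preserving up to the projection rank, so the downstream
#' PCA/GWAS machinery can be exercised without shipping network weights.
#'
#' @param slice_shape Integer length-2 slice shape.
#' @param d Number of features.
#' @param seed Integer seed fixing the projection.
#' @return A function: 2D matrix -> length-d numeric vector.
#' @export
random_projection_features <- function(slice_shape, d = 32, seed = 1) {
  p <- prod(slice_shape)
  W <- with_seed(seed, matrix(stats::rnorm(p * d, sd = 1 / sqrt(p)), p, d))
  function(slice) {
    if (length(slice) != p) stop_arg("slice shape does not match projection")
    as.numeric(crossprod(W, as.numeric(slice)))
  }
}

#' Fit PCA on a latent feature matrix
#'
#' Columns are centred (no variance scaling, so the explained-variance
#' ratios refer to the features' native scales) and the top `k` principal
#' axes are extracted.
#'
#' @param latents n x d numeric matrix (e.g. from [encode_volumes()]).
#' @param k Number of components, `k <= min(n - 1, d)`.
#' @return List with `model` (class `pc_model`: orthonormal `loadings`
#'   (d x k), `center`, `explained_variance_ratio`) and `scores` (n x k).
#' @export
fit_pca <- function(latents, k = 10) {
  x <- as.matrix(latents)
  n <- nrow(x); d <- ncol(x)
  k <- check_count(k, "k")
  if (k > min(n - 1L, d)) {
    stop_arg(sprintf("k = %d exceeds min(n - 1, d) = %d", k, min(n - 1L, d)))
  }
  if (!all(is.finite(x))) stop_arg("latent features must be finite")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  evr <- if (total_var > 0) pr$sdev[seq_len(k)]^2 / total_var else rep(0, k)
  model <- structure(
    list(loadings = pr$rotation[, seq_len(k), drop = FALSE],
         center = pr$center,
         explained_variance_ratio = evr, k = k),
    class = "pc_model"
  )
  scores <- pr$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(x)
  list(model = model, scores = scores)
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: %d components over %d features; cumulative EVR %.3f\n",
              x$k, nrow(x$loadings), sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project new data onto a fitted PCA
#'
#' @param object A `pc_model`.
#' @param newdata n x d matrix on the training feature space.
#' @param ... Unused.
#' @return n x k score matrix.
#' @export
predict.pc_model <- function(object, newdata, ...) {
  x <- sweep(as.matrix(newdata), 2, object$center)
  x %*% object$loadings
}

#' Standardise PC scores into GWAS traits
#'
#' Each component is scaled to unit variance (already mean-zero from the
#' PCA centring), so per-allele effect sizes are in trait-SD units.
#'
#' @param scores n x k PC score matrix.
#' @return n x k matrix of standardised traits, columns named `PC1..PCk`.
#' @export
pca_traits <- function(scores) {
  s <- apply(scores, 2, stats::sd)
  s[s == 0] <- 1
  out <- sweep(scores, 2, s, "/")
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  out
}
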