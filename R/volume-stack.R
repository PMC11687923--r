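#' Construct a volume stack
#'
#' A co-registered set of 3D intensity volumes sharing one integer ROI label
#' map (0 = background), emulating template space: every sample's volume has
#' the same shape and the same anatomical parcellation.
#'
#' @param volumes 4D numeric array `(x, y, z, sample)`.
#' @param roi_labels 3D integer array of the volume shape; values must belong
#'   to `roi_dict` (plus 0 for background).
#' @param voxel_size Numeric length-3, mm per axis.
#' @param roi_dict Named integer vector declaring the ROI labels.
#' @param sample_ids Character vector, one per volume.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(volumes, roi_labels, voxel_size = c(4, 4, 4),
                         roi_dict = NULL, sample_ids = NULL) {
  if (length(dim(volumes)) != 4L) stop_arg("`volumes` must be a 4D array")
  shape <- dim(volumes)[1:3]
  if (!identical(dim(roi_labels), as.integer(shape))) {
    stop_arg("`roi_labels` shape must match the volume shape")
  }
  if (is.null(roi_dict)) {
    labs <- sort(unique(as.integer(roi_labels)))
    labs <- labs[labs != 0L]
    roi_dict <- stats::setNames(labs, sprintf("roi%d", labs))
  }
  present <- setdiff(unique(as.integer(roi_labels)), c(0L, as.integer(roi_dict)))
  if (length(present)) {
    stop_arg("roi_labels contain undeclared labels: ",
             paste(present, collapse = ", "))
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(dim(volumes)[4]))
  if (length(sample_ids) != dim(volumes)[4]) {
    stop_arg("one sample id per volume required")
  }
  structure(
    list(volumes = volumes, roi_labels = roi_labels,
         voxel_size = as.numeric(voxel_size), roi_dict = roi_dict,
         sample_ids = as.character(sample_ids)),
    class = "volume_stack"
  )
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("volume_stack: %d volumes of %s voxels, %d ROIs\n",
              dim(x$volumes)[4], paste(dim(x$volumes)[1:3], collapse = "x"),
              length(x$roi_dict)))
  invisible(x)
}

n_volumes <- function(stack) dim(stack$volumes)[4]

#' ROI template geometry
#'
#' Deterministic placement of `n_rois` ellipsoids on a fixed grid inside the
#' volume: this plays the role of a registration template, shared by every
#' simulated sample.  Semi-axis ratios have product 1 so the
#' equivalent-sphere radius of an ROI equals its radius parameter.
#'
#' @param volume_shape Integer length-3, >= 16 per axis.
#' @param n_rois Number of ROIs (>= 2).
#' @return List with `centers` (n x 3), `base_radius`, `axis_ratios` (n x 3),
#'   `parcel_margin` (label map drawn at `base_radius * parcel_margin`).
#' @export
roi_template <- function(volume_shape, n_rois) {
  if (length(volume_shape) != 3L || any(volume_shape < 16)) {
    stop_arg("`volume_shape` must be length 3 with every axis >= 16")
  }
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  g <- ceiling(n_rois^(1 / 3))
  cells <- as.matrix(expand.grid(seq_len(g), seq_len(g), seq_len(g)))
  cells <- cells[seq_len(n_rois), , drop = FALSE]
  centers <- sweep(cells - 0.5, 2, volume_shape / g, "*")
  base_radius <- 0.55 * min(volume_shape) / (2 * g)
  ratios <- cbind(1 + 0.1 * ((seq_len(n_rois) %% 3) - 1), 1, 1)
  ratios[, 2] <- 1 / ratios[, 1]  # keep product of semi-axis ratios at 1
  list(centers = centers, base_radius = base_radius, axis_ratios = ratios,
       parcel_margin = 1.45)
}

# boolean ellipsoid mask given coordinate grids
ellipsoid_mask <- function(grids, center, semi_axes) {
  ((grids$x - center[1]) / semi_axes[1])^2 +
    ((grids$y - center[2]) / semi_axes[2])^2 +
    ((grids$z - center[3]) / semi_axes[3])^2 <= 1
}

coord_grids <- function(shape) {
  list(
    x = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape),
    z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  )
}

#' Measure ROI size and intensity per sample
#'
#' For each sample and ROI parcel, reports the mean intensity over the
#' structure (the parcel voxels above `threshold`; all parcel voxels when
#' none pass), the count of suprathreshold voxels, and the
#' equivalent-sphere radius derived from that count
#' (`(3 V / 4 pi)^(1/3)` in voxel units) — the measurements the
#' planted-effect recovery analyses regress on dosage.
#'
#' @param stack A [volume_stack].
#' @param threshold Intensity cut for the voxel count (default half the unit
#'   baseline ROI intensity the simulator plants).
#' @return List of n x n_roi matrices `mean_intensity`, `voxel_count`,
#'   `eq_radius`.
#' @export
measure_rois <- function(stack, threshold = 0.5) {
  labs <- as.integer(stack$roi_dict)
  n <- n_volumes(stack)
  res <- lapply(c("mean_intensity", "voxel_count", "eq_radius"), function(.)
    matrix(NA_real_, n, length(labs),
           dimnames = list(stack$sample_ids, names(stack$roi_dict))))
  names(res) <- c("mean_intensity", "voxel_count", "eq_radius")
  idx <- lapply(labs, function(l) which(stack$roi_labels == l))
  for (i in seq_len(n)) {
    v <- stack$volumes[, , , i]
    for (r in seq_along(labs)) {
      vals <- v[idx[[r]]]
      above <- vals > threshold
      res$mean_intensity[i, r] <- if (any(above)) mean(vals[above]) else
        mean(vals)
      res$voxel_count[i, r] <- sum(above)
    }
  }
  res$eq_radius <- (3 * res$voxel_count / (4 * pi))^(1 / 3)
  res
}
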