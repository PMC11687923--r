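#' Specify planted genetic and covariate effects on ROIs
#'
#' Ground truth for the simulated cohort: each row of `effects` adds
#' `beta * dosage` to an ROI's radius (voxel units) or mean intensity
#' (intensity units).  Age and sex act additively on every ROI's intensity,
#' emulating global atrophy-like covariate structure.
#'
#' @param effects Data frame with columns `variant_index`, `roi`,
#'   `beta`, `target` (`"radius"` or `"intensity"`); may have zero rows.
#' @param age_slope Intensity change per year of (centred) age.
#' @param sex_offset Intensity offset for sex = 1.
#' @param noise_sd Gaussian sd of the per-(sample, ROI) intensity noise; > 0
#'   unless `deterministic = TRUE` behaviour is wanted with `noise_sd = 0`.
#' @param radius_noise_sd Gaussian sd of per-(sample, ROI) radius noise
#'   (voxel units).
#' @param voxel_noise_sd Gaussian sd of i.i.d. voxel noise over the whole
#'   volume.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(effects = data.frame(variant_index = integer(),
                                             roi = integer(),
                                             beta = numeric(),
                                             target = character()),
                        age_slope = 0, sex_offset = 0,
                        noise_sd = 0.1, radius_noise_sd = 0.15,
                        voxel_noise_sd = 0.05) {
  if (nrow(effects) &&
      !all(effects$target %in% c("radius", "intensity"))) {
    stop_arg("effect target must be 'radius' or 'intensity'")
  }
  check_scalar(noise_sd, "noise_sd", lo = 0)
  check_scalar(radius_noise_sd, "radius_noise_sd", lo = 0)
  check_scalar(voxel_noise_sd, "voxel_noise_sd", lo = 0)
  structure(
    list(effects = effects, age_slope = age_slope, sex_offset = sex_offset,
         noise_sd = noise_sd, radius_noise_sd = radius_noise_sd,
         voxel_noise_sd = voxel_noise_sd),
    class = "effect_spec"
  )
}

#' Simulate an imaging cohort from a genotype panel
#'
#' Renders one template-registered volume per sample: ellipsoidal ROIs at
#' fixed template positions whose radius and intensity respond additively to
#' planted per-allele effects, centred age, sex, and Gaussian noise.  The
#' shared ROI label map is drawn at the template radius times a parcel
#' margin, so genetically enlarged ROIs stay inside their parcel.  A
#' continuous dementia-like score is a monotone (increasing) function of the
#' first ROI's radius — the designated "ventricle" — plus noise.
#'
#' @param panel A [genotype_panel]; missing dosages are mean-imputed for
#'   effect computation.
#' @param effects An [effect_spec].
#' @param volume_shape Integer length-3 (>= 16 per axis).
#' @param n_rois Number of template ROIs (>= 2).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param n_genetic_pcs Genotype principal components added to the covariate
#'   table (population-structure axes).
#' @return List with `volumes` ([volume_stack]), `covariates` (data frame:
#'   `sample_id`, `age`, `sex`, `batch`, `pc1..pck`), `dementia_score`, and
#'   `truth` (per-sample true radius/intensity matrices, for recovery tests).
#' @export
simulate_cohort <- function(panel, effects = effect_spec(),
                            volume_shape = c(32, 32, 32), n_rois = 6,
                            seed = 1, n_genetic_pcs = 10) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(effects, "effect_spec"))
  tpl <- roi_template(volume_shape, n_rois)
  ef <- effects$effects
  if (nrow(ef)) {
    if (any(ef$roi < 1 | ef$roi > n_rois)) {
      stop_arg("effect references unknown ROI label")
    }
    if (any(ef$variant_index < 1 | ef$variant_index > ncol(panel$dosages))) {
      stop_arg("effect references unknown variant index")
    }
  }
  n <- length(panel$sample_ids)

  dos <- panel$dosages
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    nas <- which(is.na(dos), arr.ind = TRUE)
    dos[nas] <- mu[nas[, 2]]
  }

  with_seed(seed, {
    age <- stats::runif(n, 45, 80)
    sex <- stats::rbinom(n, 1, 0.5)
    batch <- sample(c("b1", "b2", "b3"), n, replace = TRUE)

    # per-sample per-ROI true radius and intensity
    radius <- matrix(tpl$base_radius, n, n_rois) +
      matrix(stats::rnorm(n * n_rois, sd = effects$radius_noise_sd), n, n_rois)
    intensity <- matrix(1, n, n_rois) +
      effects$age_slope * (age - mean(age)) +
      effects$sex_offset * sex +
      matrix(stats::rnorm(n * n_rois, sd = effects$noise_sd), n, n_rois)
    if (nrow(ef)) {
      for (k in seq_len(nrow(ef))) {
        g <- dos[, ef$variant_index[k]]
        if (ef$target[k] == "radius") {
          radius[, ef$roi[k]] <- radius[, ef$roi[k]] + ef$beta[k] * g
        } else {
          intensity[, ef$roi[k]] <- intensity[, ef$roi[k]] + ef$beta[k] * g
        }
      }
    }
    radius <- pmax(radius, 1)  # ellipsoids never vanish

    grids <- coord_grids(volume_shape)
    labels <- array(0L, dim = volume_shape)
    for (r in seq_len(n_rois)) {
      m <- ellipsoid_mask(grids, tpl$centers[r, ],
                          tpl$base_radius * tpl$parcel_margin *
                            tpl$axis_ratios[r, ])
      labels[m] <- r
    }

    vols <- array(stats::rnorm(prod(volume_shape) * n,
                               sd = effects$voxel_noise_sd),
                  dim = c(volume_shape, n))
    for (i in seq_len(n)) {
      v <- vols[, , , i]
      for (r in seq_len(n_rois)) {
        m <- ellipsoid_mask(grids, tpl$centers[r, ],
                            radius[i, r] * tpl$axis_ratios[r, ])
        v[m] <- v[m] + intensity[i, r]
      }
      vols[, , , i] <- v
    }

    dementia <- 0.8 * radius[, 1] + stats::rnorm(n, sd = 0.3)

    k <- min(n_genetic_pcs, n - 1L, ncol(dos))
    cov <- data.frame(sample_id = panel$sample_ids, age = age, sex = sex,
                      batch = batch, stringsAsFactors = FALSE)
    if (k > 0) {
      vsub <- unique(round(seq(1, ncol(dos), length.out = min(1000, ncol(dos)))))
      gs <- sweep(dos[, vsub, drop = FALSE], 2,
                  colMeans(dos[, vsub, drop = FALSE]))
      sds <- apply(gs, 2, stats::sd)
      gs[, sds > 0] <- sweep(gs[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
      pcs <- stats::prcomp(gs, center = FALSE, rank. = k)$x
      colnames(pcs) <- paste0("pc", seq_len(ncol(pcs)))
      cov <- cbind(cov, as.data.frame(pcs))
    }

    stack <- volume_stack(vols, labels,
                          voxel_size = rep(128 / volume_shape[1], 3),
                          roi_dict = stats::setNames(seq_len(n_rois),
                                                     paste0("roi", seq_len(n_rois))),
                          sample_ids = panel$sample_ids)
    list(volumes = stack, covariates = cov, dementia_score = dementia,
         truth = list(radius = radius, intensity = intensity,
                      template = tpl))
  })
}
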