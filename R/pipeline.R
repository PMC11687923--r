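default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "latentgwas_out",
    verbose = TRUE,
    stages = c("simulate", "features", "gwas", "interpret", "pgs", "gencorr"),
    simulate = list(
      n_samples = 500, n_variants = 2000, maf_range = c(0.05, 0.5),
      ld_block_size = 25, block_corr = 0.7, missing_rate = 0.01,
      volume_shape = c(32, 32, 32), n_rois = 6,
      n_causal = 3, causal_beta = 0.6
    ),
    features = list(
      k = 10, latent_dim = 16, hidden_dim = 128, epochs = 15,
      batch_size = 64, lr = 1e-3,
      lambda_recon = 1, lambda_kld = 1e-4, lambda_pred = 1e-2,
      conditioning = c("age", "sex")
    ),
    gwas = list(
      maf_min = 0.001, hwe_alpha = 0.001, miss_max = 0.1, prune_r2 = 0.8,
      prune_window_bp = 500000, clump_window_bp = 250000,
      index_p = 1e-9, member_p = 5e-8, genome_wide_alpha = 5e-8
    ),
    interpret = list(n_phenotypes = 20, alpha = 0.05),
    pgs = list(p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-2),
               train_frac = 0.6, n_perm = 1000),
    gencorr = list(ld_window_bp = 1000000, p_max = 1e-4, zprod_min = 15,
                   region_window_bp = 250000)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_arg("unknown config key(s): ",
             paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      merge_config(defaults[[nm]], user[[nm]], paste0(path, nm, "."))
    } else user[[nm]]
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Starts from the documented defaults and overrides them with user
#' settings (a nested list or a YAML file).  Unknown keys are rejected;
#' numeric parameters are checked against their domains.
#'
#' @param config Named list of overrides, or `NULL`.
#' @param file Optional YAML file of overrides (applied before `config`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL, file = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file))
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  bad <- setdiff(cfg$stages,
                 c("simulate", "features", "gwas", "interpret", "pgs", "gencorr"))
  if (length(bad)) stop_arg("unknown stage(s): ", paste(bad, collapse = ", "))
  check_scalar(cfg$gwas$maf_min, "gwas.maf_min", lo = 0, hi = 0.5)
  check_scalar(cfg$gwas$prune_r2, "gwas.prune_r2", lo = 0, hi = 1)
  check_scalar(cfg$gwas$index_p, "gwas.index_p", lo = 0, hi = 1, lo_open = TRUE)
  check_scalar(cfg$pgs$train_frac, "pgs.train_frac", lo = 0, hi = 1,
               lo_open = TRUE, hi_open = TRUE)
  check_count(cfg$features$k, "features.k")
  check_count(cfg$simulate$n_samples, "simulate.n_samples", min = 2L)
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(cfg, stage, ...) {
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
}

run_stage <- function(name, cfg, expr) {
  pipe_log(cfg, name, "starting")
  tryCatch(expr, error = function(e) {
    stop_arg(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full synthetic imaging-genetics pipeline
#'
#' Executes the enabled stages in order — simulate, features, gwas,
#' interpret, pgs, gencorr — writing every artifact under the configured
#' output directory and returning a manifest of files with MD5 content
#' hashes.  One global seed fans out to per-stage child seeds via
#' [child_seed()], so identical configurations reproduce identical
#' artifacts for deterministic stages.
#'
#' @param config A [pipeline_config] (or a list/NULL coerced through it).
#' @return Data frame manifest (`file`, `stage`, `md5`), invisibly written
#'   to `manifest.tsv` in the output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0); stages <- character(0)
  add <- function(f, stage) {
    files <<- c(files, f); stages <<- c(stages, rep(stage, length(f)))
  }
  pth <- function(...) file.path(cfg$out_dir, paste0(...))
  env <- new.env()

  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", cfg, {
      s <- cfg$simulate
      env$panel <- simulate_genotypes(
        s$n_samples, s$n_variants, s$maf_range, s$ld_block_size,
        s$block_corr, s$missing_rate, seed = child_seed(cfg$seed, "simulate"))
      nv <- ncol(env$panel$dosages)
      causal <- round(seq(nv * 0.1, nv * 0.9, length.out = s$n_causal))
      env$effects <- effect_spec(
        effects = data.frame(
          variant_index = causal,
          roi = rep_len(seq_len(s$n_rois), s$n_causal),
          beta = rep_len(c(s$causal_beta, -s$causal_beta), s$n_causal),
          target = rep_len(c("radius", "intensity"), s$n_causal)
        ),
        age_slope = 0.01, sex_offset = 0.05, radius_noise_sd = 0.6)
      env$cohort <- simulate_cohort(
        env$panel, env$effects, s$volume_shape, s$n_rois,
        seed = child_seed(cfg$seed, "cohort"))
      write_genotypes(env$panel, pth("genotypes.tsv"))
      add(c(pth("genotypes.tsv"), pth("genotypes.tsv.variants.tsv")), "simulate")
      add(write_volumes(env$cohort$volumes, pth("cohort")), "simulate")
      utils::write.table(env$cohort$covariates, pth("covariates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = env$panel$sample_ids,
                   dementia = env$cohort$dementia_score),
        pth("dementia.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      add(c(pth("covariates.tsv"), pth("dementia.tsv")), "simulate")
    })
  }

  if ("features" %in% cfg$stages) {
    run_stage("features", cfg, {
      f <- cfg$features
      env$model <- train_cvae(
        env$cohort$volumes, env$cohort$covariates, env$cohort$dementia_score,
        cvae_config(latent_dim = f$latent_dim, hidden_dim = f$hidden_dim,
                    lambda_recon = f$lambda_recon, lambda_kld = f$lambda_kld,
                    lambda_pred = f$lambda_pred, epochs = f$epochs,
                    batch_size = f$batch_size, lr = f$lr,
                    seed = child_seed(cfg$seed, "train"),
                    conditioning = f$conditioning))
      env$latents <- encode_volumes(env$model, env$cohort$volumes)
      k <- min(f$k, ncol(env$latents), nrow(env$latents) - 1L)
      pc <- fit_pca(env$latents, k)
      env$pc_model <- pc$model
      env$traits <- pca_traits(pc$scores)
      saveRDS(list(format_version = 1L, model = env$model,
                   pc_model = pc$model), pth("model.rds"))
      utils::write.table(
        data.frame(sample_id = rownames(env$latents), unclass(env$latents)),
        pth("latents.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = rownames(env$traits), env$traits),
        pth("pc_traits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(component = seq_len(k),
                   evr = env$pc_model$explained_variance_ratio),
        pth("pc_evr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      add(pth(c("model.rds", "latents.tsv", "pc_traits.tsv", "pc_evr.tsv")),
          "features")
    })
  }

  if ("gwas" %in% cfg$stages) {
    run_stage("gwas", cfg, {
      g <- cfg$gwas
      qc <- qc_filter(env$panel, g$maf_min, g$hwe_alpha, g$miss_max,
                      g$prune_r2, g$prune_window_bp)
      env$qc_panel <- qc$panel
      utils::write.table(
        data.frame(filter = c(names(qc$report$removed), "survivors"),
                   count = c(qc$report$removed, qc$report$survivors)),
        pth("qc_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      env$scans <- association_scan(env$qc_panel, env$traits,
                                    env$cohort$covariates)
      if (inherits(env$scans, "summary_stats")) env$scans <- list(env$scans)
      for (t in seq_along(env$scans)) {
        write_sumstats(env$scans[[t]], pth("sumstats_", names(env$scans)[t] %||%
                                             paste0("trait", t), ".tsv"))
      }
      env$agg <- aggregate_traits(env$scans)
      write_sumstats(env$agg, pth("sumstats_minp.tsv"))
      threshold <- bonferroni_threshold(g$genome_wide_alpha, length(env$scans))
      env$loci <- clump(env$agg, g$clump_window_bp, threshold, g$member_p)
      write_loci(env$loci, pth("loci.tsv"))
      add(c(pth("qc_report.tsv"),
            pth(paste0("sumstats_", names(env$scans), ".tsv")),
            pth("sumstats_minp.tsv"), pth("loci.tsv")), "gwas")
    })
  }

  if ("interpret" %in% cfg$stages) {
    run_stage("interpret", cfg, {
      it <- cfg$interpret
      n <- nrow(env$traits)
      bank <- with_seed(child_seed(cfg$seed, "phenobank"), {
        np <- it$n_phenotypes
        half <- np %/% 2
        cont <- sapply(seq_len(half), function(j)
          0.3 * env$traits[, 1 + (j %% ncol(env$traits))] + stats::rnorm(n))
        bin <- sapply(seq_len(np - half), function(j)
          stats::rbinom(n, 1, 0.3))
        b <- data.frame(cont, bin)
        names(b) <- sprintf("pheno%02d", seq_len(np))
        attr(b, "types") <- c(rep("continuous", half),
                              rep("binary", np - half))
        b
      })
      env$phewas <- phewas_scan(env$traits, bank, attr(bank, "types"),
                                env$cohort$covariates, alpha = it$alpha)
      utils::write.table(env$phewas, pth("phewas.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      lead <- if (nrow(env$loci)) env$loci$index_id[1] else
        env$agg$id[which.min(env$agg$p)]
      dose <- env$panel$dosages[, match(lead, env$panel$variant_map$id)]
      dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
      mask <- env$cohort$volumes$roi_labels > 0
      env$spm <- voxel_spm(env$cohort$volumes, dose, mask, alpha = it$alpha)
      RNifti::writeNifti(RNifti::asNifti(env$spm$t), pth("spm_t.nii.gz"))
      frac <- roi_fraction(env$spm, env$cohort$volumes$roi_labels)
      rve <- roi_variance_explained(env$cohort$volumes, env$traits[, 1],
                                    env$cohort$volumes$roi_labels)
      utils::write.table(
        data.frame(roi = names(frac), significant_fraction = frac,
                   pc1_variance_explained = rve),
        pth("roi_summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      add(pth(c("phewas.tsv", "spm_t.nii.gz", "roi_summary.tsv")), "interpret")
    })
  }

  if ("pgs" %in% cfg$stages) {
    run_stage("pgs", cfg, {
      p <- cfg$pgs
      y <- env$cohort$dementia_score
      dem_scan <- association_scan(env$qc_panel, y, env$cohort$covariates)
      attr(dem_scan, "trait") <- "dementia"
      base_w <- fit_ct_pgs(dem_scan, env$qc_panel, y, p$p_thresholds,
                           cfg$gwas$clump_window_bp,
                           seed = child_seed(cfg$seed, "pgs_base"))
      extra_w <- lapply(env$scans[seq_len(min(2, length(env$scans)))],
                        function(s) fit_ct_pgs(s, env$qc_panel,
                                               y, p$p_thresholds,
                                               cfg$gwas$clump_window_bp,
                                               seed = child_seed(cfg$seed, "pgs_x")))
      base_scores <- matrix(pgs_score(env$qc_panel, base_w), ncol = 1)
      extra_scores <- sapply(extra_w, function(w) pgs_score(env$qc_panel, w))
      env$pgs_eval <- multi_pgs_eval(
        y, base_scores, extra_scores, env$cohort$covariates,
        train_frac = p$train_frac, n_perm = p$n_perm,
        seed = child_seed(cfg$seed, "pgs_eval"))
      write_pgs_weights(base_w, pth("pgs_weights_base.tsv"))
      utils::write.table(
        data.frame(trait = "dementia", r2_base = env$pgs_eval$r2_base,
                   r2_extended = env$pgs_eval$r2_extended,
                   delta = env$pgs_eval$delta, perm_p = env$pgs_eval$perm_p),
        pth("pgs_eval.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      add(pth(c("pgs_weights_base.tsv", "pgs_eval.tsv")), "pgs")
    })
  }

  if ("gencorr" %in% cfg$stages) {
    run_stage("gencorr", cfg, {
      gc_ <- cfg$gencorr
      env$ld <- ld_scores(env$qc_panel, gc_$ld_window_bp)
      utils::write.table(env$ld, pth("ld_scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      s1 <- env$scans[[1]]; s2 <- env$scans[[min(2, length(env$scans))]]
      h2 <- ldsc_h2(s1, env$ld)
      rg <- ldsc_rg(s1, s2, env$ld)
      utils::write.table(
        data.frame(quantity = c("h2_PC1", "h2_se_PC1", "intercept_PC1",
                                "rg_PC1_PC2", "rg_se_PC1_PC2"),
                   value = c(h2$h2, h2$h2_se, h2$intercept, rg$rg, rg$rg_se)),
        pth("ldsc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      dem_scan <- association_scan(env$qc_panel, env$cohort$dementia_score,
                                   env$cohort$covariates)
      reg <- shared_regions(s1, s2, dem_scan, gc_$p_max, gc_$zprod_min,
                            gc_$region_window_bp)
      df <- as.data.frame(reg[, setdiff(names(reg), "members"), drop = FALSE])
      df$members <- vapply(reg$members, paste, "", collapse = ",")
      utils::write.table(df, pth("shared_regions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add(pth(c("ld_scores.tsv", "ldsc.tsv", "shared_regions.tsv")), "gencorr")
    })
  }

  manifest <- data.frame(file = basename(files), stage = stages,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
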