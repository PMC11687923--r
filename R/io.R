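parse_error <- function(path, line, msg) {
  stop_arg(sprintf("%s:%d: %s", path, line, msg))
}

#' Read and write genotype panels as dosage TSV
#'
#' The dosage dialect is a TSV with header `sample_id` followed by the
#' variant ids (one row per sample, missing as `NA`), plus a sidecar TSV at
#' `<path>.variants.tsv` with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' Round-trips are bit-exact.  Parse errors carry file and line context.
#'
#' @param panel A [genotype_panel].
#' @param path Dosage TSV path (sidecar written/read alongside).
#' @return `write_genotypes` returns `path` invisibly; `read_genotypes`
#'   returns a [genotype_panel].
#' @export
write_genotypes <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(sample_id = panel$sample_ids,
                   panel$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  vm <- panel$variant_map[, c("id", "chrom", "pos", "ref", "alt")]
  utils::write.table(vm, paste0(path, ".variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  side <- paste0(path, ".variants.tsv")
  if (!file.exists(path)) stop_arg("no such file: ", path)
  if (!file.exists(side)) stop_arg("missing variant sidecar: ", side)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 1L || hdr[1] != "sample_id") {
    parse_error(path, 1L, "malformed header: first column must be sample_id")
  }
  if (anyDuplicated(hdr[-1])) {
    parse_error(path, 1L, sprintf("duplicated variant id '%s' in header",
                                  hdr[-1][duplicated(hdr[-1])][1]))
  }
  dos <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = c("character",
                             rep("numeric", length(hdr) - 1L)))
  vm <- utils::read.table(side, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "integer", "character", "character"))
  if (anyDuplicated(vm$id)) {
    parse_error(side, which(duplicated(vm$id))[1] + 1L, "duplicated variant id")
  }
  if (!identical(vm$id, hdr[-1])) {
    parse_error(side, 1L, "sidecar variant ids do not match dosage header")
  }
  for (ch in unique(vm$chrom)) {
    ix <- which(vm$chrom == ch)
    bad <- ix[which(diff(vm$pos[ix]) <= 0) + 1L]
    if (length(bad)) {
      parse_error(side, bad[1] + 1L,
                  "positions not strictly increasing within chromosome")
    }
  }
  genotype_panel(dos$sample_id, vm, as.matrix(dos[, -1, drop = FALSE]))
}

#' Minimal VCF writer and reader for genotype panels
#'
#' Writes a minimal VCFv4.2 with GT entries derived from rounded dosages
#' (`0/0`, `0/1`, `1/1`, missing as `./.`).  The reader maps GT back to
#' dosage, treating half-calls (`./1`, `0/.`) and missing GT as missing;
#' phased separators are accepted.  Parse errors carry file and line.
#'
#' @param panel A [genotype_panel].
#' @param path VCF path.
#' @return `write_vcf` returns `path` invisibly; `read_vcf` a
#'   [genotype_panel].
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  vm <- panel$variant_map
  gt_of <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[round(d) + 1L])
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(vm)), function(j) {
    paste(c(vm$chrom[j], vm$pos[j], vm$id[j], vm$ref[j], vm$alt[j], ".",
            "PASS", ".", "GT", gt_of(panel$dosages[, j])), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (!length(hdr_i)) parse_error(path, length(lines), "missing #CHROM header")
  hdr <- strsplit(lines[hdr_i[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) parse_error(path, hdr_i[1], "no sample columns")
  samples <- hdr[-(1:9)]
  body_i <- seq(hdr_i[1] + 1L, length(lines))
  body_i <- body_i[nzchar(lines[body_i])]
  n_var <- length(body_i)
  vm <- data.frame(chrom = character(n_var), pos = integer(n_var),
                   id = character(n_var), ref = character(n_var),
                   alt = character(n_var), stringsAsFactors = FALSE)
  dos <- matrix(NA_real_, length(samples), n_var)
  for (k in seq_len(n_var)) {
    ln <- body_i[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr)) {
      parse_error(path, ln, sprintf("expected %d fields, found %d",
                                    length(hdr), length(f)))
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt)
    if (is.na(gi)) parse_error(path, ln, "FORMAT lacks GT")
    vm$chrom[k] <- f[1]
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) parse_error(path, ln, "non-integer POS")
    vm$pos[k] <- pos
    vm$id[k] <- f[3]; vm$ref[k] <- f[4]; vm$alt[k] <- f[5]
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gi)
    alleles <- strsplit(gts, "[/|]")
    dos[, k] <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".")) return(NA_real_)
      v <- suppressWarnings(as.integer(a))
      if (anyNA(v) || any(v > 1)) return(NA_real_)
      sum(v)
    }, 0)
  }
  dup <- which(duplicated(vm$id))
  if (length(dup)) {
    parse_error(path, body_i[dup[1]], sprintf("duplicated variant id '%s'",
                                              vm$id[dup[1]]))
  }
  genotype_panel(samples, vm, dos)
}

#' Read and write volume stacks
#'
#' NIfTI is the primary on-disk format: one 4D intensity image and one 3D
#' label image (`<prefix>_volumes.nii.gz`, `<prefix>_labels.nii.gz`), plus
#' a TSV of sample ids and a small metadata TSV (voxel size, ROI
#' dictionary).  The `bundle` format is a serialized fallback
#' (`<prefix>.rds`) for hosts without NIfTI support; it round-trips
#' bit-exactly.
#'
#' @param stack A [volume_stack].
#' @param prefix Path prefix.
#' @param format `"nifti"` or `"bundle"`.
#' @return `write_volumes` returns the files written (invisibly);
#'   `read_volumes` a [volume_stack].
#' @export
write_volumes <- function(stack, prefix, format = c("nifti", "bundle")) {
  stopifnot(inherits(stack, "volume_stack"))
  format <- match.arg(format)
  if (format == "bundle") {
    f <- paste0(prefix, ".rds")
    saveRDS(stack, f)
    return(invisible(f))
  }
  fv <- paste0(prefix, "_volumes.nii.gz")
  fl <- paste0(prefix, "_labels.nii.gz")
  fm <- paste0(prefix, "_meta.tsv")
  RNifti::writeNifti(RNifti::asNifti(stack$volumes,
                                     pixdim = stack$voxel_size), fv)
  RNifti::writeNifti(RNifti::asNifti(stack$roi_labels,
                                     pixdim = stack$voxel_size,
                                     datatype = "int16"), fl)
  meta <- data.frame(
    key = c(rep("sample_id", length(stack$sample_ids)),
            rep("voxel_size", 3), rep("roi", length(stack$roi_dict))),
    name = c(stack$sample_ids, c("x", "y", "z"), names(stack$roi_dict)),
    value = c(stack$sample_ids, stack$voxel_size,
              as.integer(stack$roi_dict)),
    stringsAsFactors = FALSE
  )
  utils::write.table(meta, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fv, fl, fm))
}

#' @rdname write_volumes
#' @export
read_volumes <- function(prefix, format = c("nifti", "bundle")) {
  format <- match.arg(format)
  if (format == "bundle") {
    stack <- readRDS(paste0(prefix, ".rds"))
    stopifnot(inherits(stack, "volume_stack"))
    return(stack)
  }
  fv <- paste0(prefix, "_volumes.nii.gz")
  fl <- paste0(prefix, "_labels.nii.gz")
  fm <- paste0(prefix, "_meta.tsv")
  for (f in c(fv, fl, fm)) if (!file.exists(f)) stop_arg("no such file: ", f)
  vols <- array(as.numeric(RNifti::readNifti(fv)),
                dim = dim(RNifti::readNifti(fv)))
  labs_img <- RNifti::readNifti(fl)
  labs <- array(as.integer(labs_img), dim = dim(labs_img))
  if (!identical(dim(labs), as.integer(dim(vols)[1:3]))) {
    stop_arg("label map shape does not match volume shape")
  }
  meta <- utils::read.table(fm, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "character"))
  sample_ids <- meta$name[meta$key == "sample_id"]
  voxel_size <- as.numeric(meta$value[meta$key == "voxel_size"])
  roi <- meta[meta$key == "roi", , drop = FALSE]
  roi_dict <- stats::setNames(as.integer(roi$value), roi$name)
  volume_stack(vols, labs, voxel_size, roi_dict, sample_ids)
}

#' Read and write summary statistics TSV
#'
#' Columns `CHR`, `POS`, `ID`, `A1` (effect allele), `A2`, `BETA`, `SE`,
#' `Z`, `P`, `N`, `MAF` in that order.
#'
#' @param stats A [summary_stats].
#' @param path TSV path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats` a
#'   [summary_stats].
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  df <- data.frame(CHR = stats$chrom, POS = stats$pos, ID = stats$id,
                   A1 = stats$a1, A2 = stats$a2, BETA = stats$beta,
                   SE = stats$se, Z = stats$z, P = stats$p, N = stats$n,
                   MAF = stats$maf, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @param trait Trait tag attached to the returned table.
#' @export
read_sumstats <- function(path, trait = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("CHR", "POS", "ID", "A1", "A2", "BETA", "SE", "Z", "P", "N", "MAF")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    parse_error(path, 1L, paste("missing columns:", paste(miss, collapse = ", ")))
  }
  summary_stats(data.frame(
    id = as.character(df$ID), chrom = as.character(df$CHR), pos = df$POS,
    a1 = df$A1, a2 = df$A2, beta = df$BETA, se = df$SE, z = df$Z, p = df$P,
    n = df$N, maf = df$MAF, stringsAsFactors = FALSE
  ), trait = trait)
}

#' Read and write PGS weight tables (ID, EA, OA, WEIGHT)
#'
#' @param weights A `pgs_weights` data frame.
#' @param path TSV path.
#' @return `write_pgs_weights` returns `path` invisibly; `read_pgs_weights`
#'   a `pgs_weights`.
#' @export
write_pgs_weights <- function(weights, path) {
  df <- data.frame(ID = weights$id, EA = weights$effect_allele,
                   OA = weights$other_allele, WEIGHT = weights$weight,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pgs_weights
#' @export
read_pgs_weights <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  as_pgs_weights(data.frame(id = as.character(df$ID), effect_allele = df$EA,
                            other_allele = df$OA, weight = df$WEIGHT,
                            stringsAsFactors = FALSE))
}

#' Write a locus table as TSV (member ids comma-collapsed)
#'
#' @param loci A `locus_table`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  df <- as.data.frame(loci[, setdiff(names(loci), "members"), drop = FALSE])
  df$members <- vapply(loci$members, paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
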