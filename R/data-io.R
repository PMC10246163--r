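# Reading, writing and preparing modality arrays: group masks, mean
# removal, train-set standardization, trilinear resampling, NIfTI/CSV IO.

#' Compute a group mask over a set of volumes
#'
#' A single mask shared by all subjects, derived from the voxelwise
#' group-mean volume. Under `"rescaled_below"` the group mean is rescaled to
#' \[0, 1\] by its min/max and voxels below `threshold` are excluded (used
#' for gray-matter and fractional-anisotropy maps); under `"absolute_below"`
#' voxels whose group-mean absolute value falls below `threshold` are
#' excluded (used for signed spatial ICA maps).
#'
#' @param volumes A `modality_array` of kind `"volume"`, or an
#'   n-subjects-by-voxels numeric matrix.
#' @param rule `"rescaled_below"` or `"absolute_below"`.
#' @param threshold Exclusion threshold; default 0.15. Must lie in (0, 1)
#'   for the rescaled rule.
#' @return A list of class `group_mask`: logical `keep` per voxel, the
#'   `rule`, `threshold`, and the grid dimensions when known.
#' @export
compute_group_mask <- function(volumes,
                               rule = c("rescaled_below", "absolute_below"),
                               threshold = 0.15) {
  rule <- match.arg(rule)
  grid_dim <- NULL
  if (inherits(volumes, "modality_array")) {
    grid_dim <- volumes$grid_dim
    volumes <- volumes$values
  }
  volumes <- as.matrix(volumes)
  abort_if(nrow(volumes) < 1, "need at least one volume")
  abort_if(!all(is.finite(volumes)), "volumes contain non-finite values")
  if (rule == "rescaled_below") {
    abort_if(threshold <= 0 || threshold >= 1,
             "threshold must lie in (0, 1) for the rescaled rule")
  }
  gm <- colMeans(volumes)
  if (rule == "rescaled_below") {
    rng <- range(gm)
    if (rng[2] > rng[1]) {
      keep <- (gm - rng[1]) / (rng[2] - rng[1]) >= threshold
    } else {
      keep <- rep(FALSE, length(gm))
    }
  } else {
    keep <- abs(gm) >= threshold
  }
  abort_if(!any(keep), "mask excludes all voxels")
  structure(list(keep = keep, rule = rule, threshold = threshold,
                 grid_dim = grid_dim), class = "group_mask")
}

#' @export
print.group_mask <- function(x, ...) {
  cat(sprintf("<group_mask> %d / %d voxels kept (%s, threshold %g)\n",
              sum(x$keep), length(x$keep), x$rule, x$threshold))
  invisible(x)
}

#' Remove the dataset or per-subject mean from modality arrays
#'
#' `"dataset"` scope subtracts the voxelwise mean over subjects from every
#' subject (used for volumetric gray-matter and anisotropy maps);
#' `"per_subject"` subtracts each subject's own scalar mean (used for
#' spatial ICA maps).
#'
#' @param arrays n-by-features matrix or `modality_array`.
#' @param scope `"dataset"` or `"per_subject"`.
#' @param center For `"dataset"` scope, an optional precomputed voxelwise
#'   mean (e.g. from the training split) to subtract instead of the mean of
#'   `arrays` itself.
#' @return Object of the same shape with the mean removed; for dataset
#'   scope the subtracted mean is attached as attribute `"center"`.
#' @export
remove_mean <- function(arrays, scope = c("dataset", "per_subject"),
                        center = NULL) {
  scope <- match.arg(scope)
  wrap <- NULL
  if (inherits(arrays, "modality_array")) {
    wrap <- arrays
    arrays <- arrays$values
  }
  arrays <- as.matrix(arrays)
  abort_if(nrow(arrays) < 1, "empty input")
  if (scope == "dataset") {
    center <- center %||% colMeans(arrays)
    abort_if(length(center) != ncol(arrays), "center length mismatch")
    out <- sweep(arrays, 2, center, "-")
    attr(out, "center") <- center
  } else {
    out <- sweep(arrays, 1, rowMeans(arrays), "-")
  }
  if (!is.null(wrap)) {
    wrap$values <- out
    return(wrap)
  }
  out
}

#' Fit per-feature standardization statistics on the training split
#'
#' Computes per-feature mean and standard deviation on the training split
#' only; features with zero variance are dropped with a warning. Apply the
#' fitted statistics to any split with [apply_standardizer()] — validation
#' and test data are standardized with training moments, so their own
#' moments need not be 0/1.
#'
#' @param train_arrays Training-split matrix (subjects x features) or
#'   `modality_array`.
#' @param mask Optional `group_mask` (or logical vector); only retained
#'   features are standardized, the rest are dropped.
#' @return A list of class `standardizer`: `mean`, `sd`, logical `keep`
#'   relative to the original feature space, and `n_dropped`.
#' @export
fit_standardizer <- function(train_arrays, mask = NULL) {
  if (inherits(train_arrays, "modality_array")) {
    train_arrays <- train_arrays$values
  }
  x <- as.matrix(train_arrays)
  abort_if(nrow(x) < 2, "need at least two training subjects")
  keep <- rep(TRUE, ncol(x))
  if (!is.null(mask)) {
    if (inherits(mask, "group_mask")) mask <- mask$keep
    abort_if(length(mask) != ncol(x), "mask length mismatch")
    keep <- as.logical(mask)
  }
  mu <- rep(NA_real_, ncol(x))
  sdv <- rep(NA_real_, ncol(x))
  mu[keep] <- colMeans(x[, keep, drop = FALSE])
  sdv[keep] <- apply(x[, keep, drop = FALSE], 2, stats::sd)
  degenerate <- keep & (!is.finite(sdv) | sdv <= 0)
  if (any(degenerate)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(degenerate)),
            call. = FALSE)
    keep <- keep & !degenerate
  }
  abort_if(!any(keep), "no features left after dropping zero-variance ones")
  structure(list(mean = mu[keep], sd = sdv[keep], keep = keep,
                 n_dropped = sum(degenerate)), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param arrays Matrix (or `modality_array`) to standardize with the
#'   training statistics.
#' @param stats A fitted `standardizer`.
#' @return `apply_standardizer()`: matrix of z-scored retained features.
#' @export
apply_standardizer <- function(arrays, stats) {
  stopifnot(inherits(stats, "standardizer"))
  if (inherits(arrays, "modality_array")) arrays <- arrays$values
  x <- as.matrix(arrays)
  abort_if(ncol(x) != length(stats$keep), "feature count mismatch")
  x <- x[, stats$keep, drop = FALSE]
  sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
}

#' Resample a 3-D volume to a new voxel spacing by trilinear interpolation
#'
#' The output grid spans the same physical extent as the input (voxel
#' centers from 0 to `(n-1) * spacing` mm per axis) sampled at
#' `target_spacing`.
#'
#' @param volume 3-D numeric array.
#' @param spacing Source voxel spacing, mm per axis (length 1 or 3).
#' @param target_spacing Target spacing, mm per axis (length 1 or 3).
#' @return 3-D array on the resampled grid, with attribute `"spacing"`.
#' @export
resample_volume <- function(volume, spacing, target_spacing) {
  abort_if(length(dim(volume)) != 3, "volume must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3)
  target_spacing <- rep_len(as.numeric(target_spacing), 3)
  abort_if(any(spacing <= 0) || any(target_spacing <= 0),
           "spacings must be positive")
  src_dim <- dim(volume)
  extent <- (src_dim - 1) * spacing
  out_dim <- pmax(1L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
  # fractional source indices (1-based) of each target voxel center
  ax <- lapply(1:3, function(k) {
    pos <- (seq_len(out_dim[k]) - 1) * target_spacing[k]
    1 + pos / spacing[k]
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  i0 <- pmin(pmax(floor(g$x), 1), src_dim[1] - 1 + (src_dim[1] == 1))
  j0 <- pmin(pmax(floor(g$y), 1), src_dim[2] - 1 + (src_dim[2] == 1))
  k0 <- pmin(pmax(floor(g$z), 1), src_dim[3] - 1 + (src_dim[3] == 1))
  fx <- pmin(pmax(g$x - i0, 0), 1)
  fy <- pmin(pmax(g$y - j0, 0), 1)
  fz <- pmin(pmax(g$z - k0, 0), 1)
  i1 <- pmin(i0 + 1, src_dim[1]); j1 <- pmin(j0 + 1, src_dim[2])
  k1 <- pmin(k0 + 1, src_dim[3])
  at <- function(i, j, k) volume[cbind(i, j, k)]
  vals <-
    at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
    at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
    at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    at(i1, j1, k0) * fx       * fy       * (1 - fz) +
    at(i1, j0, k1) * fx       * (1 - fy) * fz +
    at(i0, j1, k1) * (1 - fx) * fy       * fz +
    at(i1, j1, k1) * fx       * fy       * fz
  out <- array(vals, out_dim)
  attr(out, "spacing") <- target_spacing
  out
}

#' Vectorize / restore a symmetric connectivity matrix
#'
#' Connectivity matrices enter the encoder as their strict lower triangle
#' (row-major over rows below the diagonal); `devectorize_connectivity()`
#' rebuilds the full symmetric matrix with zeros on the diagonal.
#'
#' @param mat Square symmetric matrix.
#' @param tol Symmetry tolerance.
#' @return `vectorize_connectivity()`: numeric vector of length
#'   `m * (m - 1) / 2`.
#' @export
vectorize_connectivity <- function(mat, tol = 1e-6) {
  abort_if(!is.matrix(mat) || nrow(mat) != ncol(mat),
           "connectivity matrix must be square")
  abort_if(max(abs(mat - t(mat))) > tol,
           "connectivity matrix is not symmetric within tolerance %g", tol)
  mat[lower.tri(mat)]
}

#' @rdname vectorize_connectivity
#' @param v Vector from `vectorize_connectivity()`.
#' @param m Matrix side length.
#' @export
devectorize_connectivity <- function(v, m) {
  abort_if(length(v) != m * (m - 1) / 2, "length does not match m")
  out <- matrix(0, m, m)
  out[lower.tri(out)] <- v
  out + t(out)
}

#' Write / read a multimodal cohort on disk
#'
#' Volumes are written as compressed NIfTI (one file per subject, voxel
#' spacing in the header), connectivity matrices as per-subject CSV,
#' metadata as `metadata.csv`, and the generator configuration and seed (for
#' synthetic cohorts) as a JSON sidecar. `read_cohort()` restores the
#' arrays and metadata; generator internals are not persisted, so planted
#' shifts must be applied before writing.
#'
#' @param cohort A `multimodal_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a
#'   `multimodal_cohort` without generator internals.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol_dir <- file.path(dir, "volumes")
  mat_dir <- file.path(dir, "matrices")
  dir.create(vol_dir, showWarnings = FALSE)
  dir.create(mat_dir, showWarnings = FALSE)
  ids <- cohort$metadata$subject_id
  for (i in seq_along(ids)) {
    vol <- array(cohort$a$values[i, ], cohort$a$grid_dim)
    img <- RNifti::asNifti(vol, pixdim = cohort$a$voxel_spacing %||% c(1, 1, 1))
    RNifti::writeNifti(img, file.path(vol_dir, paste0(ids[i], ".nii.gz")))
    m <- matrix(cohort$b$values[i, ], cohort$b$grid_dim[1])
    utils::write.csv(m, file.path(mat_dir, paste0(ids[i], ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  sidecar <- list(kind_a = cohort$a$kind, kind_b = cohort$b$kind,
                  grid_dim_a = cohort$a$grid_dim,
                  grid_dim_b = cohort$b$grid_dim,
                  voxel_spacing = cohort$a$voxel_spacing)
  if (!is.null(cohort$generator)) {
    sidecar$config <- unclass(cohort$generator$config)
    sidecar$seed <- cohort$generator$config$seed
  }
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  abort_if(!file.exists(meta_path), "no metadata.csv under %s", dir)
  metadata <- tibble::as_tibble(utils::read.csv(meta_path,
                                                stringsAsFactors = FALSE))
  sidecar <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                 simplifyVector = TRUE)
  ids <- metadata$subject_id
  vols <- lapply(ids, function(id) {
    as.numeric(RNifti::readNifti(file.path(dir, "volumes",
                                           paste0(id, ".nii.gz"))))
  })
  a_vals <- do.call(rbind, vols)
  rownames(a_vals) <- ids
  mats <- lapply(ids, function(id) {
    as.numeric(as.matrix(utils::read.csv(
      file.path(dir, "matrices", paste0(id, ".csv"))
    )))
  })
  b_vals <- do.call(rbind, mats)
  rownames(b_vals) <- ids
  structure(list(
    a = new_modality(a_vals, sidecar$kind_a, sidecar$grid_dim_a, ids,
                     sidecar$voxel_spacing),
    b = new_modality(b_vals, sidecar$kind_b, sidecar$grid_dim_b, ids),
    metadata = metadata,
    generator = NULL
  ), class = "multimodal_cohort")
}

#' Write a group mask as a 0/1 NIfTI volume
#'
#' @param mask A `group_mask` with known grid dimensions.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_spacing mm per axis.
#' @export
write_mask <- function(mask, path, voxel_spacing = c(1, 1, 1)) {
  stopifnot(inherits(mask, "group_mask"))
  abort_if(is.null(mask$grid_dim), "mask has no grid dimensions")
  img <- RNifti::asNifti(array(as.numeric(mask$keep), mask$grid_dim),
                         pixdim = voxel_spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
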