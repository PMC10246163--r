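#' Configuration for a synthetic paired-modality cohort
#'
#' Builds the parameter set for [generate_cohort()]. The defaults emulate a
#' multi-site schizophrenia cohort: 278 subjects of whom 49.28% are patients
#' and 25.54% are female, scanned at 7 sites. Modality A is a stack of 3-D
#' volumetric maps rendered from smooth Gaussian-blob spatial bases; modality
#' B is a square symmetric connectivity matrix rendered from symmetric
#' rank-one bases. Both are driven by ground-truth latent factors split into
#' a private block per modality and a block shared by the two modalities.
#'
#' @param n_subjects Number of subjects.
#' @param patient_fraction Fraction of subjects carrying the diagnosis.
#' @param female_fraction Fraction of female subjects.
#' @param n_sites Number of acquisition sites (assigned uniformly; no site
#'   effect is injected into the arrays).
#' @param d_pr1,d_sh,d_pr2 Ground-truth latent dimensionalities of the
#'   private-A, shared and private-B subspaces.
#' @param volume_dim Integer length-3 grid for modality A volumes.
#' @param matrix_dim Side length of the modality B connectivity matrix.
#' @param mixing `"linear"` or `"mild-nonlinear"` (elementwise `tanh` of the
#'   linear mixing, exercising non-linear cross-modal covariation).
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian noise on
#'   both modalities.
#' @param shared_strength Scale applied to the shared block's contribution
#'   to both modalities; `0` removes all shared information.
#' @param mode_decay Geometric decay of basis amplitude across the factors
#'   of each subspace (factor j scaled by `mode_decay^(j-1)`), emulating
#'   the dominant-mode variance spectrum of imaging-derived components;
#'   `1` gives exchangeable equal-amplitude factors.
#' @param voxel_spacing Voxel size in mm for modality A.
#' @param seed Integer seed; identical configurations regenerate
#'   bit-identical cohorts.
#'
#' @return A list of class `synthetic_config`.
#' @seealso [generate_cohort()], [plant_subgroup()]
#' @export
synthetic_config <- function(n_subjects = 278,
                             patient_fraction = 0.4928,
                             female_fraction = 0.2554,
                             n_sites = 7,
                             d_pr1 = 4, d_sh = 6, d_pr2 = 4,
                             volume_dim = c(8, 8, 8),
                             matrix_dim = 10,
                             mixing = c("linear", "mild-nonlinear"),
                             noise_sd = 0.5,
                             shared_strength = 1,
                             mode_decay = 0.8,
                             voxel_spacing = c(1.5, 1.5, 1.5),
                             seed = 1) {
  mixing <- match.arg(mixing)
  abort_if(!is_count(n_subjects) || n_subjects < 2, "n_subjects must be >= 2")
  abort_if(!is_prob(patient_fraction), "patient_fraction must lie in [0, 1]")
  abort_if(!is_prob(female_fraction), "female_fraction must lie in [0, 1]")
  abort_if(!is_count(n_sites), "n_sites must be a positive count")
  for (d in c(d_pr1, d_sh, d_pr2)) {
    abort_if(!is_count(d), "latent sizes must be positive counts")
  }
  abort_if(length(volume_dim) != 3 || any(volume_dim < 2),
           "volume_dim must be three axis lengths >= 2")
  abort_if(!is_count(matrix_dim) || matrix_dim < 2,
           "matrix_dim must be a count >= 2")
  abort_if(!is.numeric(noise_sd) || noise_sd < 0, "noise_sd must be >= 0")
  abort_if(!is.numeric(shared_strength) || shared_strength < 0,
           "shared_strength must be >= 0")
  abort_if(!is.numeric(mode_decay) || mode_decay <= 0 || mode_decay > 1,
           "mode_decay must lie in (0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects),
    patient_fraction = patient_fraction,
    female_fraction = female_fraction,
    n_sites = as.integer(n_sites),
    d_pr1 = as.integer(d_pr1), d_sh = as.integer(d_sh),
    d_pr2 = as.integer(d_pr2),
    volume_dim = as.integer(volume_dim),
    matrix_dim = as.integer(matrix_dim),
    mixing = mixing,
    noise_sd = noise_sd,
    shared_strength = shared_strength,
    mode_decay = mode_decay,
    voxel_spacing = voxel_spacing,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> n=%d (%.1f%% patients, %.1f%% female, %d sites)\n",
    x$n_subjects, 100 * x$patient_fraction, 100 * x$female_fraction, x$n_sites
  ))
  cat(sprintf(
    "  latents pr1/sh/pr2 = %d/%d/%d; volume %s; matrix %dx%d; %s mixing\n",
    x$d_pr1, x$d_sh, x$d_pr2, paste(x$volume_dim, collapse = "x"),
    x$matrix_dim, x$matrix_dim, x$mixing
  ))
  cat(sprintf("  noise_sd=%g shared_strength=%g seed=%d\n",
              x$noise_sd, x$shared_strength, x$seed))
  invisible(x)
}

# Smooth Gaussian-blob spatial basis maps: one 3-D blob per latent factor,
# random center and width, unit maximum. Returned as d x n_voxel matrix.
blob_bases <- function(d, dim3) {
  coords <- as.matrix(expand.grid(
    x = seq_len(dim3[1]), y = seq_len(dim3[2]), z = seq_len(dim3[3])
  ))
  out <- matrix(0, d, nrow(coords))
  for (j in seq_len(d)) {
    center <- 1 + stats::runif(3) * (dim3 - 1)
    width <- stats::runif(1, min = 1.2, max = 2.5)
    d2 <- colSums((t(coords) - center)^2)
    out[j, ] <- exp(-d2 / (2 * width^2))
  }
  out
}

# Symmetric rank-one connectivity basis patterns, one per latent factor,
# flattened row-major to length m^2. Unit Frobenius norm.
sym_bases <- function(d, m) {
  out <- matrix(0, d, m * m)
  for (j in seq_len(d)) {
    u <- stats::rnorm(m)
    pat <- tcrossprod(u)
    pat <- pat / sqrt(sum(pat^2))
    out[j, ] <- as.vector(pat)
  }
  out
}

# Deterministic re-mixing of latents through stored bases and noise.
mix_modalities <- function(latents, gen) {
  cfg <- gen$config
  s <- cfg$shared_strength
  load_a <- cbind(latents$private_a, s * latents$shared)
  load_b <- cbind(latents$private_b, s * latents$shared)
  sig_a <- load_a %*% gen$bases_a
  sig_b <- load_b %*% gen$bases_b
  if (cfg$mixing == "mild-nonlinear") {
    sig_a <- tanh(sig_a)
    sig_b <- tanh(sig_b)
  }
  list(a = sig_a + gen$noise_a, b = sig_b + gen$noise_b,
       signal_a = sig_a, signal_b = sig_b)
}

new_modality <- function(values, kind, grid_dim, subject_ids,
                         voxel_spacing = NULL) {
  structure(list(
    values = values, kind = kind, grid_dim = as.integer(grid_dim),
    subject_ids = subject_ids, voxel_spacing = voxel_spacing
  ), class = "modality_array")
}

#' @export
print.modality_array <- function(x, ...) {
  cat(sprintf("<modality_array> kind=%s, %d subjects x [%s]\n", x$kind,
              nrow(x$values), paste(x$grid_dim, collapse = "x")))
  invisible(x)
}

#' Generate a paired-modality cohort with known latent ground truth
#'
#' Draws standard-normal private and shared latent factors per subject,
#' renders modality A as volumes through Gaussian-blob spatial bases and
#' modality B as symmetric connectivity matrices through symmetric rank-one
#' bases, adds i.i.d. Gaussian noise, and attaches an fBIRN-like metadata
#' table (diagnosis, sex, site). The mixing bases, noise arrays and latents
#' are stored with the cohort so that [plant_subgroup()] can regenerate the
#' arrays deterministically.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `cohort` (class `multimodal_cohort`: fields
#'   `a`, `b` of class `modality_array`, `metadata` tibble, `generator`
#'   internals) and `latents` (class `ground_truth_latents`: matrices
#'   `private_a`, `shared`, `private_b`, plus `diagnosis_shift` and `seed`).
#' @examples
#' sim <- generate_cohort(synthetic_config(n_subjects = 20, seed = 7))
#' dim(sim$cohort$a$values)
#' table(sim$cohort$metadata$diagnosis)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  p_a <- prod(config$volume_dim)
  p_b <- config$matrix_dim^2
  abort_if(p_a < 1 || p_b < 1 || n < 1, "degenerate cohort shape")

  with_seed(config$seed, {
    ids <- sprintf("S%04d", seq_len(n))

    n_pat <- round(n * config$patient_fraction)
    n_fem <- round(n * config$female_fraction)
    diagnosis <- rep("HC", n)
    diagnosis[sample.int(n, n_pat)] <- "SZ"
    sex <- rep("M", n)
    sex[sample.int(n, n_fem)] <- "F"
    site <- sprintf("site%02d", sample(rep_len(seq_len(config$n_sites), n)))
    metadata <- tibble::tibble(
      subject_id = ids, diagnosis = diagnosis, sex = sex, site = site
    )

    latents <- structure(list(
      private_a = matrix(stats::rnorm(n * config$d_pr1), n, config$d_pr1),
      shared = matrix(stats::rnorm(n * config$d_sh), n, config$d_sh),
      private_b = matrix(stats::rnorm(n * config$d_pr2), n, config$d_pr2),
      diagnosis_shift = c(pr1 = 0, sh = 0, pr2 = 0),
      seed = config$seed
    ), class = "ground_truth_latents")
    rownames(latents$private_a) <- ids
    rownames(latents$shared) <- ids
    rownames(latents$private_b) <- ids

    bases_a <- blob_bases(config$d_pr1 + config$d_sh, config$volume_dim)
    bases_b <- sym_bases(config$d_pr2 + config$d_sh, config$matrix_dim)
    # dominant-mode amplitude decay, applied within each factor subspace
    dec <- config$mode_decay
    scale_a <- c(dec^(seq_len(config$d_pr1) - 1), dec^(seq_len(config$d_sh) - 1))
    scale_b <- c(dec^(seq_len(config$d_pr2) - 1), dec^(seq_len(config$d_sh) - 1))
    bases_a <- bases_a * scale_a
    bases_b <- bases_b * scale_b

    noise_a <- matrix(stats::rnorm(n * p_a, sd = config$noise_sd), n, p_a)
    noise_b <- matrix(0, n, p_b)
    if (config$noise_sd > 0) {
      m <- config$matrix_dim
      for (i in seq_len(n)) {
        e <- matrix(stats::rnorm(p_b, sd = config$noise_sd), m, m)
        e <- (e + t(e)) / sqrt(2)          # symmetric, off-diagonal sd kept
        diag(e) <- stats::rnorm(m, sd = config$noise_sd) # undo sqrt(2) inflation
        noise_b[i, ] <- as.vector(e)
      }
    }

    gen <- list(config = config, bases_a = bases_a, bases_b = bases_b,
                noise_a = noise_a, noise_b = noise_b, latents = latents)
    mixed <- mix_modalities(latents, gen)
    rownames(mixed$a) <- ids
    rownames(mixed$b) <- ids

    cohort <- structure(list(
      a = new_modality(mixed$a, "volume", config$volume_dim, ids,
                       config$voxel_spacing),
      b = new_modality(mixed$b, "connectivity_matrix",
                       c(config$matrix_dim, config$matrix_dim), ids),
      metadata = metadata,
      generator = gen
    ), class = "multimodal_cohort")

    list(cohort = cohort, latents = latents)
  })
}

#' @export
print.multimodal_cohort <- function(x, ...) {
  cat(sprintf(
    "<multimodal_cohort> %d subjects (%d patients, %d female, %d sites)\n",
    nrow(x$metadata), sum(x$metadata$diagnosis == "SZ"),
    sum(x$metadata$sex == "F"), length(unique(x$metadata$site))
  ))
  cat(sprintf("  A: %s [%s]   B: %s [%s]\n",
              x$a$kind, paste(x$a$grid_dim, collapse = "x"),
              x$b$kind, paste(x$b$grid_dim, collapse = "x")))
  invisible(x)
}

#' Ground-truth latents stored with a synthetic cohort
#'
#' @param cohort A cohort from [generate_cohort()] or [plant_subgroup()].
#' @return The `ground_truth_latents` object the arrays were mixed from.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  abort_if(is.null(cohort$generator),
           "cohort carries no generator internals (not synthetic)")
  cohort$generator$latents
}

#' Plant a diagnosis-linked latent shift in a synthetic cohort
#'
#' Adds a constant mean offset to the chosen latent subspace for all
#' patients (diagnosis `"SZ"`) and regenerates both modality arrays through
#' the cohort's stored mixing bases and noise, so the only change is the
#' planted group difference. Used to create recoverable patient subgroups
#' for validating cluster enrichment and shared-dimension analyses.
#'
#' @param cohort A synthetic cohort from [generate_cohort()].
#' @param subspace One of `"pr1"`, `"sh"`, `"pr2"`.
#' @param shift Scalar mean offset, in ground-truth latent standard
#'   deviations (the factors are unit-variance).
#' @param dims Which dimensions of the subspace to shift (default: all).
#' @return The cohort with regenerated arrays; retrieve the shifted factors
#'   with [ground_truth()].
#' @export
plant_subgroup <- function(cohort, subspace = c("pr1", "sh", "pr2"),
                           shift, dims = NULL) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  subspace <- match.arg(subspace)
  abort_if(is.null(cohort$generator), "cohort carries no generator internals")
  abort_if(!is.numeric(shift) || length(shift) != 1 || !is.finite(shift),
           "shift must be a finite scalar")
  patients <- cohort$metadata$diagnosis == "SZ"
  abort_if(!any(patients), "cohort has no patients to shift")

  lat <- cohort$generator$latents
  field <- switch(subspace, pr1 = "private_a", sh = "shared",
                  pr2 = "private_b")
  dmax <- ncol(lat[[field]])
  dims <- dims %||% seq_len(dmax)
  abort_if(any(dims < 1 | dims > dmax), "dims out of range for subspace %s",
           subspace)
  lat[[field]][patients, dims] <- lat[[field]][patients, dims] + shift
  lat$diagnosis_shift[[subspace]] <- lat$diagnosis_shift[[subspace]] + shift

  gen <- cohort$generator
  gen$latents <- lat
  mixed <- mix_modalities(lat, gen)
  rownames(mixed$a) <- cohort$a$subject_ids
  rownames(mixed$b) <- cohort$b$subject_ids
  cohort$a$values <- mixed$a
  cohort$b$values <- mixed$b
  cohort$generator <- gen
  cohort
}

#' Noiseless signal arrays of a synthetic cohort
#'
#' @param cohort A synthetic cohort.
#' @return List with matrices `a` and `b` of the pre-noise signal, useful
#'   for residual-variance checks.
#' @export
cohort_signal <- function(cohort) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  abort_if(is.null(cohort$generator), "cohort carries no generator internals")
  mixed <- mix_modalities(cohort$generator$latents, cohort$generator)
  list(a = mixed$signal_a, b = mixed$signal_b)
}
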