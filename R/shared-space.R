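# Cross-fold matching of shared latent dimensions, diagnosis correlation,
# and decoded interpolation along a chosen shared dimension.

#' Match shared latent dimensions across folds
#'
#' Different training folds may find the same shared factor in a different
#' dimension and with a different sign. For every non-reference fold, the
#' absolute Pearson correlation matrix between the reference fold's shared
#' posterior means and that fold's (over the same subjects) is solved as a
#' linear assignment maximizing total absolute correlation; the matched
#' sign is recorded. A reference dimension is flagged robust when its mean
#' absolute matched correlation across folds exceeds `threshold`.
#'
#' @param shared_list List of n-subjects x d_sh matrices of shared
#'   posterior means, one per fold, rows aligned; element `ref` is the
#'   reference fold.
#' @param ref Reference fold index (default 1).
#' @param threshold Robustness threshold on the mean absolute cross-fold
#'   correlation (default 0.7).
#' @return Tibble of class `shared_dim_report`: `dim`, `mean_abs_r`,
#'   `robust`, and list columns `matched` (index per fold) and `sign`.
#'   Constant dimensions are excluded with a warning.
#' @export
match_shared_dims <- function(shared_list, ref = 1, threshold = 0.7) {
  abort_if(length(shared_list) < 2, "need at least two folds")
  shared_list <- lapply(shared_list, as.matrix)
  d <- ncol(shared_list[[ref]])
  abort_if(!all(vapply(shared_list, ncol, integer(1)) == d),
           "folds disagree on the shared dimensionality")
  abort_if(length(unique(vapply(shared_list, nrow, integer(1)))) != 1,
           "every fold must encode the same subjects")
  const_ref <- apply(shared_list[[ref]], 2, stats::sd) == 0
  if (any(const_ref)) {
    warning(sprintf("excluding %d constant reference dimension(s)",
                    sum(const_ref)), call. = FALSE)
  }
  live <- which(!const_ref)
  others <- setdiff(seq_along(shared_list), ref)
  matched <- matrix(NA_integer_, d, length(others))
  sgn <- matrix(NA_real_, d, length(others))
  absr <- matrix(NA_real_, d, length(others))
  for (j in seq_along(others)) {
    xk <- shared_list[[others[j]]]
    const_k <- apply(xk, 2, stats::sd) == 0
    cmat <- suppressWarnings(stats::cor(shared_list[[ref]], xk))
    cmat[is.na(cmat)] <- 0
    cmat[, const_k] <- 0
    cmat[const_ref, ] <- 0
    a <- solve_assignment(-abs(cmat))
    for (i in live) {
      matched[i, j] <- a[i]
      r <- cmat[i, a[i]]
      sgn[i, j] <- ifelse(r >= 0, 1, -1)
      absr[i, j] <- abs(r)
    }
  }
  out <- tibble::tibble(
    dim = live,
    mean_abs_r = rowMeans(absr, na.rm = TRUE)[live],
    robust = rowMeans(absr, na.rm = TRUE)[live] > threshold,
    matched = lapply(live, function(i) matched[i, ]),
    sign = lapply(live, function(i) sgn[i, ])
  )
  class(out) <- c("shared_dim_report", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Point-biserial correlation of a latent dimension with diagnosis
#'
#' Pearson correlation between the dimension's values and the 0/1 patient
#' indicator, with the two-sided test from [stats::cor.test()]. Positive
#' correlations mean higher values in patients.
#'
#' @param values Numeric vector (one value per subject).
#' @param diagnosis Vector over the same subjects; `positive` marks
#'   patients.
#' @param positive Patient level (default `"SZ"`), ignored for logical
#'   input.
#' @return Tibble: `correlation`, `p_value`, `n`.
#' @export
correlate_with_diagnosis <- function(values, diagnosis, positive = "SZ") {
  ind <- if (is.logical(diagnosis)) diagnosis else diagnosis == positive
  abort_if(length(values) != length(ind), "length mismatch")
  abort_if(!any(ind) || all(ind), "both classes must be present")
  ct <- stats::cor.test(values, as.numeric(ind))
  tibble::tibble(correlation = unname(ct$estimate),
                 p_value = ct$p.value, n = length(values))
}

#' Per-dimension diagnosis correlations for a shared-dimension report
#'
#' Augments a [match_shared_dims()] report with the point-biserial
#' diagnosis correlation of every (robust or not) dimension in the
#' reference fold's encoding, which carries the headline values; per-fold
#' correlations (sign-aligned via the matching) are attached as a list
#' column.
#'
#' @param report A `shared_dim_report`.
#' @param shared_list The same list of per-fold shared-mean matrices.
#' @param diagnosis Diagnosis vector aligned with the matrices' rows.
#' @param ref Reference fold index.
#' @param positive Patient level.
#' @return The report with columns `dx_correlation`, `dx_p` (reference
#'   fold) and list column `dx_by_fold`.
#' @export
shared_dim_diagnosis <- function(report, shared_list, diagnosis, ref = 1,
                                 positive = "SZ") {
  stopifnot(inherits(report, "shared_dim_report"))
  shared_list <- lapply(shared_list, as.matrix)
  others <- setdiff(seq_along(shared_list), ref)
  res <- lapply(seq_len(nrow(report)), function(i) {
    dim_i <- report$dim[i]
    ct0 <- correlate_with_diagnosis(shared_list[[ref]][, dim_i], diagnosis,
                                    positive)
    by_fold <- vapply(seq_along(others), function(j) {
      m <- report$matched[[i]][j]
      if (is.na(m)) return(NA_real_)
      s <- report$sign[[i]][j]
      correlate_with_diagnosis(s * shared_list[[others[j]]][, m], diagnosis,
                               positive)$correlation
    }, numeric(1))
    list(r = ct0$correlation, p = ct0$p_value, by_fold = by_fold)
  })
  report$dx_correlation <- vapply(res, `[[`, numeric(1), "r")
  report$dx_p <- vapply(res, `[[`, numeric(1), "p")
  report$dx_by_fold <- lapply(res, `[[`, "by_fold")
  report
}

#' Default interpolation endpoints for a shared dimension
#'
#' @param values Cohort values on the dimension.
#' @param probs Quantile pair (default 5th and 95th percentile).
#' @return Length-2 numeric endpoints.
#' @export
dimension_endpoints <- function(values, probs = c(0.05, 0.95)) {
  unname(stats::quantile(values, probs = probs))
}

#' Decode an interpolation along one shared latent dimension
#'
#' Varies the chosen shared dimension linearly between two endpoints while
#' every other shared dimension and both private blocks are held at the
#' prior mean (zero), and decodes each step through both decoders. This
#' renders the pure effect of the dimension on both modalities.
#'
#' @param model A trained [dmvae_model()].
#' @param dim Shared dimension index (1-based).
#' @param endpoints Length-2 numeric range to traverse (e.g. from
#'   [dimension_endpoints()]).
#' @param n_steps Number of interpolation steps (>= 2).
#' @return List of class `dimension_interpolation`: `steps` (latent values
#'   traversed), decoded matrices `a` and `b` (one row per step), `dim`.
#' @export
interpolate_dimension <- function(model, dim, endpoints, n_steps = 7) {
  stopifnot(inherits(model, "dmvae"))
  abort_if(!is_count(dim) || dim > model$dims$d_sh,
           "dim out of range (shared space has %d dimensions)",
           model$dims$d_sh)
  abort_if(length(endpoints) != 2 || !all(is.finite(endpoints)),
           "endpoints must be two finite values")
  abort_if(!is_count(n_steps) || n_steps < 2, "n_steps must be >= 2")
  steps <- seq(endpoints[1], endpoints[2], length.out = n_steps)
  sh <- matrix(0, n_steps, model$dims$d_sh)
  sh[, dim] <- steps
  a <- decode(model, matrix(0, n_steps, model$dims$d_pr1), sh, side = "a")
  b <- decode(model, matrix(0, n_steps, model$dims$d_pr2), sh, side = "b")
  structure(list(steps = steps, a = a, b = b, dim = as.integer(dim)),
            class = "dimension_interpolation")
}

#' @export
print.dimension_interpolation <- function(x, ...) {
  cat(sprintf(
    "<dimension_interpolation> shared dim %d, %d steps in [%.3g, %.3g]\n",
    x$dim, length(x$steps), min(x$steps), max(x$steps)
  ))
  invisible(x)
}
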