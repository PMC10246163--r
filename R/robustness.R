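# Stratified fold protocol, Hungarian matching of clusterings to the
# reference fold, robustness / enrichment statistics, significance and
# site-effect checks, and cross-pair heterogeneity of enriched MCPs.

#' Build a stratified cross-validation fold plan
#'
#' Splits subjects into `n_folds` test folds stratified on diagnosis
#' (every fold's class counts are within one subject of perfect balance).
#' For each fold, a stratified 10% of the remaining subjects forms the
#' validation set and the rest the training set.
#'
#' @param metadata Tibble with `subject_id` and the stratification column.
#' @param n_folds Number of folds (default 10).
#' @param seed Seed; the same seed reproduces the identical plan.
#' @param stratify Column to stratify on (default `"diagnosis"`).
#' @param val_fraction Fraction of non-test subjects held out for
#'   validation (default 0.1).
#' @return List of class `fold_plan`: `folds` (per fold: `test`, `val`,
#'   `train` id vectors), `n_folds`, `seed`, `stratify`.
#' @export
make_fold_plan <- function(metadata, n_folds = 10, seed = 1,
                           stratify = "diagnosis", val_fraction = 0.1) {
  abort_if(!is_count(n_folds) || n_folds < 2, "n_folds must be >= 2")
  abort_if(!all(c("subject_id", stratify) %in% names(metadata)),
           "metadata must contain subject_id and %s", stratify)
  strata <- split(metadata$subject_id, metadata[[stratify]])
  abort_if(any(lengths(strata) < n_folds),
           "every stratum needs at least n_folds subjects")
  with_seed(seed, {
    fold_of <- stats::setNames(integer(nrow(metadata)), metadata$subject_id)
    # deal subjects around the folds, continuing the rotation across
    # strata so total fold sizes also stay within one subject
    pos <- 0L
    for (ids in strata) {
      ids <- sample(ids)
      fold_of[ids] <- ((pos + seq_along(ids) - 1L) %% n_folds) + 1L
      pos <- (pos + length(ids)) %% n_folds
    }
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- names(fold_of)[fold_of == f]
      rest <- names(fold_of)[fold_of != f]
      rest_meta <- metadata[match(rest, metadata$subject_id), ]
      val <- unlist(lapply(split(rest, rest_meta[[stratify]]), function(ids) {
        n_val <- max(1L, round(length(ids) * val_fraction))
        sample(ids, n_val)
      }), use.names = FALSE)
      list(test = test, val = val, train = setdiff(rest, val))
    })
    structure(list(folds = folds, n_folds = as.integer(n_folds),
                   seed = as.integer(seed), stratify = stratify,
                   subject_ids = metadata$subject_id),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), integer(1))
  cat(sprintf("<fold_plan> %d folds stratified on %s (test sizes %s)\n",
              x$n_folds, x$stratify, paste(sizes, collapse = "/")))
  invisible(x)
}

# Jaccard overlap (%) between two member-id sets.
overlap_pct <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  100 * length(intersect(a, b)) / u
}

#' Match one fold's clusters to the reference fold's clusters
#'
#' Computes the pairwise overlap (Jaccard percentage of subjects assigned
#' to both clusters) between every reference cluster and every cluster of
#' fold `k`, and solves the maximum-overlap linear assignment with the
#' Hungarian algorithm. When fold `k` has fewer clusters, unmatched
#' reference clusters get overlap 0.
#'
#' @param labels_ref,labels_k Named integer label vectors covering the same
#'   subject ids (the whole cohort is clustered in every fold).
#' @return List of class `matched_clustering`: `mapping` tibble
#'   (`cluster_ref`, `cluster_k`, `overlap` %), the full `overlap_matrix`,
#'   and `total` (sum of matched overlaps).
#' @export
match_clusters <- function(labels_ref, labels_k) {
  abort_if(is.null(names(labels_ref)) || is.null(names(labels_k)),
           "label vectors must be named by subject id")
  abort_if(!setequal(names(labels_ref), names(labels_k)),
           "labelings cover different subject ids")
  labels_ref <- stats::setNames(as.integer(labels_ref), names(labels_ref))
  labels_k <- stats::setNames(as.integer(labels_k), names(labels_k))
  cl_ref <- sort(unique(labels_ref))
  cl_k <- sort(unique(labels_k))
  ov <- matrix(0, length(cl_ref), length(cl_k),
               dimnames = list(as.character(cl_ref), as.character(cl_k)))
  members_ref <- split(names(labels_ref), labels_ref)
  members_k <- split(names(labels_k), labels_k)
  for (i in seq_along(cl_ref)) {
    for (j in seq_along(cl_k)) {
      ov[i, j] <- overlap_pct(members_ref[[as.character(cl_ref[i])]],
                              members_k[[as.character(cl_k[j])]])
    }
  }
  # pad to square with zeros so the assignment is a bijection on
  # min(k_ref, k_k) real clusters
  n <- max(dim(ov))
  cost <- matrix(0, n, n)
  cost[seq_len(nrow(ov)), seq_len(ncol(ov))] <- -ov
  a <- solve_assignment(cost)
  mapping <- tibble::tibble(
    cluster_ref = cl_ref,
    cluster_k = vapply(seq_along(cl_ref), function(i) {
      j <- a[i]
      if (j <= length(cl_k)) cl_k[j] else NA_integer_
    }, integer(1)),
    overlap = vapply(seq_along(cl_ref), function(i) {
      j <- a[i]
      if (j <= length(cl_k)) ov[i, j] else 0
    }, numeric(1))
  )
  structure(list(mapping = mapping, overlap_matrix = ov,
                 total = sum(mapping$overlap)),
            class = "matched_clustering")
}

#' @export
print.matched_clustering <- function(x, ...) {
  cat(sprintf("<matched_clustering> total matched overlap %.1f\n", x$total))
  print(x$mapping)
  invisible(x)
}

# Per-fold member sets of each reference cluster after Hungarian matching.
matched_member_sets <- function(labels_list, ref = 1) {
  ref_labels <- labels_list[[ref]]
  cl_ref <- sort(unique(ref_labels))
  lapply(seq_along(labels_list), function(k) {
    if (k == ref) {
      m <- split(names(ref_labels), ref_labels)
      return(list(members = m[as.character(cl_ref)],
                  overlap = stats::setNames(rep(100, length(cl_ref)),
                                            as.character(cl_ref))))
    }
    mc <- match_clusters(ref_labels, labels_list[[k]])
    members <- lapply(seq_along(cl_ref), function(i) {
      ck <- mc$mapping$cluster_k[i]
      if (is.na(ck)) character(0)
      else names(labels_list[[k]])[labels_list[[k]] == ck]
    })
    names(members) <- as.character(cl_ref)
    list(members = members,
         overlap = stats::setNames(mc$mapping$overlap,
                                   as.character(cl_ref)))
  })
}

#' Robustness and enrichment statistics per MCP across folds
#'
#' Matches every fold's clustering to the reference fold, then reports per
#' reference MCP: the robustness (mean overlap with its matched partners
#' across the other folds), and the mean and standard deviation across all
#' folds of the percentage of patients (%SZ) and of female subjects (%F)
#' among the matched members. MCPs whose mean %SZ exceeds 70 are flagged
#' as diagnosis-enriched.
#'
#' @param labels_list List of named label vectors, one per fold, all
#'   covering the whole cohort; element `ref` is the reference fold.
#' @param metadata Tibble with `subject_id`, `diagnosis` (`"SZ"` =
#'   patient) and `sex` (`"F"` = female).
#' @param ref Index of the reference fold (default 1).
#' @param enrich_threshold Percentage above which an MCP counts as
#'   patient-enriched (default 70).
#' @return Tibble of class `mcp_stats`: per MCP the member count in the
#'   reference fold, `robustness_mean/sd`, `sz_mean/sd`, `f_mean/sd`,
#'   and `enriched`.
#' @export
mcp_statistics <- function(labels_list, metadata, ref = 1,
                           enrich_threshold = 70) {
  abort_if(length(labels_list) < 2, "need at least two folds")
  sets <- matched_member_sets(labels_list, ref)
  cl_ref <- names(sets[[ref]]$members)
  is_sz <- stats::setNames(metadata$diagnosis == "SZ", metadata$subject_id)
  is_f <- stats::setNames(metadata$sex == "F", metadata$subject_id)
  pct <- function(flag, ids) {
    if (length(ids) == 0) return(NA_real_)
    100 * mean(flag[ids])
  }
  rows <- lapply(cl_ref, function(c0) {
    rob <- vapply(seq_along(sets)[-ref], function(k) sets[[k]]$overlap[[c0]],
                  numeric(1))
    sz <- vapply(seq_along(sets), function(k) {
      pct(is_sz, sets[[k]]$members[[c0]])
    }, numeric(1))
    fem <- vapply(seq_along(sets), function(k) {
      pct(is_f, sets[[k]]$members[[c0]])
    }, numeric(1))
    tibble::tibble(
      mcp = as.integer(c0),
      n_ref = length(sets[[ref]]$members[[c0]]),
      robustness_mean = mean(rob), robustness_sd = stats::sd(rob),
      sz_mean = mean(sz, na.rm = TRUE), sz_sd = stats::sd(sz, na.rm = TRUE),
      f_mean = mean(fem, na.rm = TRUE), f_sd = stats::sd(fem, na.rm = TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$enriched <- out$sz_mean > enrich_threshold
  class(out) <- c("mcp_stats", class(out))
  out
}

#' Pairwise tests of equal patient proportions between MCPs
#'
#' For every pair of clusters, a two-sided Fisher's exact test on the 2x2
#' table of patient counts, with Holm correction across all pairs. The
#' same machinery applies to any binary stratum (e.g. sex) via `positive`.
#'
#' @param labels Named cluster label vector.
#' @param outcome Named binary vector (logical, or compared against
#'   `positive`) over the same subjects.
#' @param positive Value of `outcome` counted as positive when `outcome`
#'   is not logical.
#' @return Tibble: `mcp_a`, `mcp_b`, positive counts and sizes, `p_value`,
#'   `p_adj` (Holm).
#' @export
enrichment_significance <- function(labels, outcome, positive = "SZ") {
  abort_if(is.null(names(labels)), "labels must be named by subject id")
  if (!is.logical(outcome)) outcome <- outcome == positive
  ids <- names(labels)
  abort_if(!all(ids %in% names(outcome)) && length(outcome) != length(labels),
           "outcome does not cover the labelled subjects")
  if (!is.null(names(outcome))) outcome <- outcome[ids]
  cl <- sort(unique(labels))
  abort_if(length(cl) < 2, "need at least two clusters")
  pairs <- utils::combn(cl, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    in_a <- labels == a; in_b <- labels == b
    abort_if(sum(in_a) == 0 || sum(in_b) == 0, "cluster of size 0")
    tab <- matrix(c(sum(outcome[in_a]), sum(!outcome[in_a]),
                    sum(outcome[in_b]), sum(!outcome[in_b])), 2, 2)
    ft <- stats::fisher.test(tab)
    tibble::tibble(mcp_a = a, mcp_b = b,
                   pos_a = sum(outcome[in_a]), n_a = sum(in_a),
                   pos_b = sum(outcome[in_b]), n_b = sum(in_b),
                   p_value = ft$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Site-effect check on per-MCP patient percentages
#'
#' For each reference MCP and each site, computes the percentage of
#' patients among the MCP's matched members from that site in every fold,
#' takes the median over folds, and reports the standard deviation of
#' these medians across sites. MCPs at or above `flag_threshold`
#' percentage points are flagged.
#'
#' @param labels_list Per-fold named label vectors (as in
#'   [mcp_statistics()]).
#' @param metadata Tibble with `subject_id`, `diagnosis`, `site`.
#' @param ref Reference fold index.
#' @param flag_threshold Flagging threshold in percentage points
#'   (default 5).
#' @return Tibble: `mcp`, `site_sd`, `flagged`, and the per-site medians
#'   as a list column.
#' @export
site_effect_check <- function(labels_list, metadata, ref = 1,
                              flag_threshold = 5) {
  abort_if(!"site" %in% names(metadata), "metadata lacks a site column")
  sets <- matched_member_sets(labels_list, ref)
  cl_ref <- names(sets[[ref]]$members)
  is_sz <- stats::setNames(metadata$diagnosis == "SZ", metadata$subject_id)
  site_of <- stats::setNames(metadata$site, metadata$subject_id)
  sites <- sort(unique(metadata$site))
  rows <- lapply(cl_ref, function(c0) {
    med <- vapply(sites, function(s) {
      per_fold <- vapply(seq_along(sets), function(k) {
        ids <- sets[[k]]$members[[c0]]
        ids <- ids[site_of[ids] == s]
        if (length(ids) == 0) NA_real_ else 100 * mean(is_sz[ids])
      }, numeric(1))
      stats::median(per_fold, na.rm = TRUE)
    }, numeric(1))
    sd_sites <- stats::sd(med, na.rm = TRUE)
    if (length(sites) < 2 || all(is.na(med))) sd_sites <- 0
    tibble::tibble(mcp = as.integer(c0), site_sd = sd_sites,
                   flagged = sd_sites >= flag_threshold,
                   site_medians = list(med))
  })
  dplyr::bind_rows(rows)
}

#' Distinctness of patient capture across enriched MCPs
#'
#' For enriched MCPs (possibly from different modality-pair analyses),
#' entry (r, c) is the percentage of the row MCP's patients not captured
#' by the column MCP, averaged over folds; the diagonal holds the
#' percentage of the pooled patients that only the row MCP captures.
#' Rows and columns are sorted by decreasing diagonal.
#'
#' @param member_sets Named list; each element is a list over folds of
#'   character vectors of patient ids captured by that MCP.
#' @param all_patients Optional character vector of every patient id in
#'   the cohort; when given, the mean and sd over folds of the percentage
#'   of all patients jointly captured by the MCPs is attached as attribute
#'   `"union_coverage"`.
#' @return A square matrix of class `heterogeneity_matrix` (see above).
#' @export
heterogeneity_overlap <- function(member_sets, all_patients = NULL) {
  abort_if(length(member_sets) < 2, "need at least two enriched MCPs")
  abort_if(is.null(names(member_sets)), "member_sets must be named")
  n_folds <- unique(lengths(member_sets))
  abort_if(length(n_folds) != 1, "all MCPs must cover the same folds")
  nm <- names(member_sets)
  acc <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  cnt <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  diag_acc <- stats::setNames(numeric(length(nm)), nm)
  coverage <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    sets_f <- lapply(member_sets, `[[`, f)
    all_sz <- unique(unlist(sets_f))
    if (!is.null(all_patients)) {
      coverage[f] <- 100 * length(intersect(all_sz, all_patients)) /
        length(all_patients)
    }
    for (r in nm) {
      others <- unique(unlist(sets_f[setdiff(nm, r)]))
      if (length(all_sz) > 0) {
        diag_acc[r] <- diag_acc[r] +
          100 * length(setdiff(sets_f[[r]], others)) / length(all_sz)
      }
      for (co in nm) {
        if (r == co || length(sets_f[[r]]) == 0) next
        acc[r, co] <- acc[r, co] +
          100 * length(setdiff(sets_f[[r]], sets_f[[co]])) /
          length(sets_f[[r]])
        cnt[r, co] <- cnt[r, co] + 1
      }
    }
  }
  out <- acc / pmax(cnt, 1)
  diag(out) <- diag_acc / n_folds
  ord <- order(diag(out), decreasing = TRUE)
  out <- out[ord, ord, drop = FALSE]
  if (!is.null(all_patients)) {
    attr(out, "union_coverage") <- c(mean = mean(coverage),
                                     sd = stats::sd(coverage))
  }
  class(out) <- c("heterogeneity_matrix", class(out))
  out
}
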