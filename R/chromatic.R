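# Fused embedding, K selection, K-Means++ clustering, meta-chromatic
# pattern (MCP) coloring and decoding of MCPs back to modality space.

#' Build the fused latent embedding of a cohort
#'
#' Each subject is represented by the concatenation of posterior means
#' `[pr1 | sh | pr2]`, where the shared block is the product-of-experts
#' fusion of the two modalities' shared posteriors. Only means are used
#' (the most likely value under the posterior), never samples, so the
#' embedding is deterministic. Diagnosis is never an input.
#'
#' @param model A trained [dmvae_model()].
#' @param x_a,x_b Feature matrices over the same subjects (rows aligned,
#'   rownames = subject ids).
#' @return A numeric matrix of class `fused_embedding`
#'   (subjects x `d_pr1 + d_sh + d_pr2`, 64 columns under defaults) with
#'   attribute `"blocks"` giving the column indices of each subspace.
#' @export
embed_subjects <- function(model, x_a, x_b) {
  stopifnot(inherits(model, "dmvae"))
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  abort_if(nrow(x_a) != nrow(x_b), "modalities must cover the same subjects")
  pa <- encode(model, x_a, side = "a")
  pb <- encode(model, x_b, side = "b")
  sh <- poe_combine(pa$shared, pb$shared)
  emb <- cbind(pa$private$mean, sh$mean, pb$private$mean)
  d <- model$dims
  blocks <- list(pr1 = seq_len(d$d_pr1),
                 sh = d$d_pr1 + seq_len(d$d_sh),
                 pr2 = d$d_pr1 + d$d_sh + seq_len(d$d_pr2))
  rownames(emb) <- rownames(x_a)
  colnames(emb) <- c(paste0("pr1_", seq_len(d$d_pr1)),
                     paste0("sh_", seq_len(d$d_sh)),
                     paste0("pr2_", seq_len(d$d_pr2)))
  structure(emb, blocks = blocks, class = c("fused_embedding", "matrix",
                                            "array"))
}

embedding_blocks <- function(embedding) {
  blocks <- attr(embedding, "blocks")
  abort_if(is.null(blocks), "embedding carries no subspace block indices")
  blocks
}

# K-Means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance to the nearest chosen one.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  centers[1, ] <- x[idx[1], ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        # fewer distinct points than k: fall back to any unused point
        pool <- setdiff(seq_len(n), idx[seq_len(j - 1)])
        idx[j] <- pool[sample.int(length(pool), 1)]
      } else {
        idx[j] <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- x[idx[j], ]
      d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
  }
  centers
}

#' Cluster the fused embedding with K-Means++
#'
#' K-Means with ++-style seeding, multiple restarts, and the best inertia
#' kept. Lloyd iterations are delegated to [stats::kmeans()].
#'
#' @param embedding Numeric matrix (ideally a [embed_subjects()] result).
#' @param k Number of clusters (>= 2; `k = 1` is allowed for degenerate
#'   curves in elbow scans).
#' @param seed Seed making the seeding and restarts reproducible.
#' @param nstart Number of ++ restarts (best inertia kept).
#' @param iter_max Lloyd iteration cap per restart.
#' @return List of class `mcp_clustering`: integer `labels` (named by
#'   subject when the embedding has rownames, values `0 .. k-1`),
#'   `centers` (k x d, rows in label order), `inertia` (total
#'   within-cluster sum of squares), `k`, `seed`.
#' @export
cluster_kmeanspp <- function(embedding, k, seed = 1, nstart = 50,
                             iter_max = 100) {
  x <- unclass(embedding)
  attr(x, "blocks") <- NULL
  x <- as.matrix(x)
  abort_if(!is_count(k) || k > nrow(x), "k must be a count <= n subjects")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(nstart)) {
      init <- kmeanspp_init(x, k)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL
      )
      if (!is.null(km) && (is.null(best) ||
                           km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
  })
  abort_if(is.null(best), "k-means failed for every restart")
  labels <- as.integer(best$cluster) - 1L
  names(labels) <- rownames(x)
  structure(list(labels = labels, centers = unname(best$centers),
                 inertia = best$tot.withinss, k = as.integer(k),
                 seed = as.integer(seed),
                 blocks = attr(embedding, "blocks")),
            class = "mcp_clustering")
}

#' @export
print.mcp_clustering <- function(x, ...) {
  cat(sprintf("<mcp_clustering> k=%d over %d subjects; inertia %.4g\n",
              x$k, length(x$labels), x$inertia))
  print(table(MCP = x$labels))
  invisible(x)
}

#' Choose the number of MCPs with the elbow criterion
#'
#' Scans `k_range`, records the within-cluster sum of squares (WCSS), and
#' returns the `k` maximizing the discrete second difference of the WCSS
#' curve (the sharpest bend); ties go to the smaller `k`. Endpoints of the
#' range cannot host a second difference and are never selected.
#'
#' @param embedding Numeric matrix of subjects.
#' @param k_range Candidate `k` values (at least 3 consecutive values).
#' @param seed,nstart Passed to [cluster_kmeanspp()].
#' @return List of class `elbow_selection`: chosen `k` and the full
#'   `curve` tibble (`k`, `wcss`, `second_diff`) for inspection.
#' @export
select_k_elbow <- function(embedding, k_range = 2:8, seed = 1, nstart = 20) {
  k_range <- sort(unique(as.integer(k_range)))
  abort_if(length(k_range) < 3,
           "k_range too small: need at least 3 candidate values")
  abort_if(min(k_range) < 1 || max(k_range) > nrow(embedding) - 1,
           "k_range must lie within [1, n_subjects - 1]")
  abort_if(any(diff(k_range) != 1), "k_range must be consecutive")
  wcss <- vapply(k_range, function(k) {
    cluster_kmeanspp(embedding, k, seed = derive_seed(seed, paste0("k", k)),
                     nstart = nstart)$inertia
  }, numeric(1))
  d2 <- rep(NA_real_, length(k_range))
  interior <- 2:(length(k_range) - 1)
  d2[interior] <- wcss[interior - 1] - 2 * wcss[interior] + wcss[interior + 1]
  pick <- interior[which.max(d2[interior])] # which.max takes first = smaller k
  structure(list(
    k = k_range[pick],
    curve = tibble::tibble(k = k_range, wcss = wcss, second_diff = d2)
  ), class = "elbow_selection")
}

#' @export
print.elbow_selection <- function(x, ...) {
  cat(sprintf("<elbow_selection> k = %d\n", x$k))
  print(x$curve)
  invisible(x)
}

# Per-subspace L2 norms of cluster centers: k x 3 matrix (pr1, sh, pr2).
center_subspace_norms <- function(centers, blocks) {
  out <- vapply(c("pr1", "sh", "pr2"), function(b) {
    row_norms(centers[, blocks[[b]], drop = FALSE])
  }, numeric(nrow(centers)))
  matrix(out, nrow = nrow(centers),
         dimnames = list(NULL, c("pr1", "sh", "pr2")))
}

#' Color MCPs by per-subspace irregularity
#'
#' The red, green and blue channels of an MCP are the L2 norms of its
#' center in the private-A, shared and private-B subspaces (distance from
#' the prior mean, zero), each divided by the maximum such norm over all
#' MCPs; the MCP farthest from the prior in a subspace therefore has that
#' channel exactly 1. If every center has norm 0 in a subspace the channel
#' is defined as 0.
#'
#' @param clustering An [cluster_kmeanspp()] result, or a center matrix if
#'   `blocks` is supplied.
#' @param blocks Subspace column indices (taken from the clustering or the
#'   embedding when omitted).
#' @return A tibble: `mcp`, `n_members` (when known), subspace norms
#'   `norm_pr1`, `norm_sh`, `norm_pr2`, and channels `red`, `green`,
#'   `blue` in \[0, 1\].
#' @export
color_mcps <- function(clustering, blocks = NULL) {
  if (inherits(clustering, "mcp_clustering")) {
    centers <- clustering$centers
    blocks <- blocks %||% clustering$blocks
    sizes <- as.integer(table(factor(clustering$labels,
                                     levels = seq_len(nrow(centers)) - 1L)))
  } else {
    centers <- as.matrix(clustering)
    sizes <- rep(NA_integer_, nrow(centers))
  }
  abort_if(is.null(blocks), "subspace blocks unknown; pass `blocks`")
  abort_if(nrow(centers) < 1, "need at least one center")
  norms <- center_subspace_norms(centers, blocks)
  channel <- apply(norms, 2, function(v) {
    m <- max(v)
    if (m > 0) v / m else rep(0, length(v))
  })
  channel <- matrix(channel, nrow = nrow(centers))
  tibble::tibble(
    mcp = seq_len(nrow(centers)) - 1L,
    n_members = sizes,
    norm_pr1 = norms[, 1], norm_sh = norms[, 2], norm_pr2 = norms[, 3],
    red = channel[, 1], green = channel[, 2], blue = channel[, 3]
  )
}

#' Color subjects by probabilistic MCP assignment
#'
#' A subject's weight on each MCP is one over the L2 distance to that
#' MCP's center raised to the fourth power, normalized to sum to one; its
#' color is the weight-averaged MCP color. A subject coincident with a
#' center takes that center's color exactly (full weight split equally
#' among coincident centers).
#'
#' @param embedding Subject embedding matrix.
#' @param clustering An [cluster_kmeanspp()] result (or center matrix).
#' @param mcp_colors Tibble from [color_mcps()].
#' @return Tibble `subject_id`, `red`, `green`, `blue`, with the full
#'   weight matrix attached as attribute `"weights"`.
#' @export
color_subjects <- function(embedding, clustering, mcp_colors) {
  centers <- if (inherits(clustering, "mcp_clustering")) {
    clustering$centers
  } else {
    as.matrix(clustering)
  }
  x <- as.matrix(unclass(embedding))
  abort_if(ncol(x) != ncol(centers), "embedding/centers dimension mismatch")
  rgb_mat <- as.matrix(mcp_colors[, c("red", "green", "blue")])
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  d2 <- pmax(d2, 0)
  w <- 1 / (d2^2) # distance^-4 = (distance^2)^-2
  coincident <- !is.finite(w)
  any_hit <- rowSums(coincident) > 0
  w[any_hit, ] <- coincident[any_hit, , drop = FALSE] * 1
  w <- w / rowSums(w)
  cols <- w %*% rgb_mat
  out <- tibble::tibble(
    subject_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    red = cols[, 1], green = cols[, 2], blue = cols[, 3]
  )
  attr(out, "weights") <- w
  out
}

#' Decode an MCP back into both modality spaces
#'
#' Averages the fused latent vectors of the MCP's members (optionally
#' restricted to a subject subset, e.g. the patients assigned to a
#' diagnosis-enriched MCP) and pushes the average through both decoders.
#'
#' @param model A trained [dmvae_model()].
#' @param embedding A [embed_subjects()] matrix.
#' @param labels Cluster labels named by subject id (`0 .. k-1`).
#' @param mcp_index Which MCP to decode.
#' @param subjects Optional subject ids to intersect with the members.
#' @return List: decoded feature vectors `a` and `b`, the averaged
#'   `latent`, and `members` used.
#' @export
decode_mcp <- function(model, embedding, labels, mcp_index, subjects = NULL) {
  stopifnot(inherits(model, "dmvae"))
  blocks <- embedding_blocks(embedding)
  members <- names(labels)[labels == mcp_index]
  if (!is.null(subjects)) members <- intersect(members, subjects)
  abort_if(length(members) == 0,
           "MCP %s has no members after filtering", mcp_index)
  lat <- colMeans(unclass(embedding)[members, , drop = FALSE])
  a <- decode(model, lat[blocks$pr1], lat[blocks$sh], side = "a")
  b <- decode(model, lat[blocks$pr2], lat[blocks$sh], side = "b")
  list(a = drop(a), b = drop(b), latent = lat, members = members)
}
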