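# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fold plan into one row per subject and fold role
#'
#' @param x A [make_fold_plan()] result.
#' @param ... Unused.
#' @return Tibble: `fold`, `subject_id`, `role` (train/val/test).
#' @export
tidy.fold_plan <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(x$n_folds), function(f) {
    fl <- x$folds[[f]]
    tibble::tibble(
      fold = f,
      subject_id = c(fl$train, fl$val, fl$test),
      role = rep(c("train", "val", "test"),
                 c(length(fl$train), length(fl$val), length(fl$test)))
    )
  }))
}

#' Tidy a DMVAE fit into its per-epoch training log
#'
#' @param x A [train_fold()] result.
#' @param ... Unused.
#' @return The log tibble (epoch, train/validation totals, term-wise
#'   validation losses).
#' @export
tidy.dmvae_fit <- function(x, ...) x$log

#' One-row summary of a DMVAE fit
#'
#' @param x A [train_fold()] result.
#' @param ... Unused.
#' @return Tibble: epochs run, best epoch, best validation loss, parameter
#'   count.
#' @export
glance.dmvae_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val = x$best_val,
    n_params = length(nl_flatten(x$model$params)),
    n_train = length(x$split$train),
    n_val = length(x$split$val)
  )
}

#' Tidy a matched clustering into its cluster mapping
#'
#' @param x A [match_clusters()] result.
#' @param ... Unused.
#' @export
tidy.matched_clustering <- function(x, ...) x$mapping

#' Tidy a heterogeneity matrix into long form
#'
#' @param x A [heterogeneity_overlap()] matrix.
#' @param ... Unused.
#' @return Tibble: `row_mcp`, `col_mcp`, `distinct_pct`.
#' @export
tidy.heterogeneity_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    row_mcp = rep(rownames(m), times = ncol(m)),
    col_mcp = rep(colnames(m), each = nrow(m)),
    distinct_pct = as.vector(m)
  )
}

#' One-row summary of a pipeline run manifest
#'
#' @param x A [run_pipeline()] manifest.
#' @param ... Unused.
#' @export
glance.chromafuse_run <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_folds = x$n_folds,
                 k = x$k, seed = x$seed,
                 n_artifacts = length(x$artifacts))
}

#' Plot training and validation loss curves
#'
#' @param object A [train_fold()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dmvae_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log[, c("epoch", "train_total",
                                           "val_total")],
                            -"epoch", names_to = "split",
                            values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "objective",
                  title = "DMVAE training (dashed: best validation)") +
    ggplot2::theme_minimal()
}

#' Plot the within-cluster sum-of-squares curve of an elbow scan
#'
#' @param object A [select_k_elbow()] result.
#' @param ... Unused.
#' @export
autoplot.elbow_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::labs(y = "within-cluster sum of squares",
                  title = sprintf("Elbow selection: k = %d", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot per-MCP robustness and enrichment statistics
#'
#' @param object An [mcp_statistics()] tibble.
#' @param ... Unused.
#' @export
autoplot.mcp_stats <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "mcp", "robustness_mean",
                  "sz_mean", "f_mean"),
    -"mcp", names_to = "statistic", values_to = "pct"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$mcp), y = .data$pct,
                                   fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 70, linetype = 3) +
    ggplot2::labs(x = "MCP", y = "%",
                  title = "MCP robustness / %SZ / %F (dotted: enrichment)") +
    ggplot2::theme_minimal()
}

#' Plot a heterogeneity matrix as a tile map
#'
#' @param object A [heterogeneity_overlap()] matrix.
#' @param ... Unused.
#' @export
autoplot.heterogeneity_matrix <- function(object, ...) {
  df <- tidy.heterogeneity_matrix(object)
  df$row_mcp <- factor(df$row_mcp, levels = rev(rownames(object)))
  df$col_mcp <- factor(df$col_mcp, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_mcp, y = .data$row_mcp,
                                   fill = .data$distinct_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f", .data$distinct_pct)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "distinct %") +
    ggplot2::theme_minimal()
}

#' Scatter the fused embedding in two principal components
#'
#' A light visualization helper: projects the embedding with PCA and
#' colors subjects by their chromatic colors.
#'
#' @param embedding An [embed_subjects()] matrix.
#' @param subject_colors Tibble from [color_subjects()].
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, subject_colors) {
  pc <- stats::prcomp(unclass(embedding), rank. = 2)
  df <- tibble::tibble(
    pc1 = pc$x[, 1], pc2 = pc$x[, 2],
    color = grDevices::rgb(subject_colors$red, subject_colors$green,
                           subject_colors$blue)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(color = df$color, size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = "Chromatic embedding (PCA projection)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
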