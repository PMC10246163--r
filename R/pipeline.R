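# End-to-end orchestration: configuration, per-fold preprocessing and
# training, clustering and coloring, robustness and shared-space reports,
# cross-reconstruction evaluation, artifact writing and run manifests.

#' Pipeline configuration
#'
#' Assembles and validates the full run configuration. Defaults follow the
#' reference protocol (10 stratified folds, 300 epochs at learning rate
#' 1e-5, 16/32/16 latent dimensions); synthetic-study configurations in the
#' examples and tests shrink these through the same fields.
#'
#' @param synthetic List of [synthetic_config()] arguments for a generated
#'   cohort, or `NULL` when `data_dir` points at a cohort on disk.
#' @param data_dir Directory readable by [read_cohort()] (ignored when
#'   `synthetic` is given).
#' @param preprocess List: `mask_rule` (`NULL`, `"rescaled_below"` or
#'   `"absolute_below"`), `mask_threshold`, `mean_scope_a`
#'   (`"dataset"` or `"per_subject"`).
#' @param model List: `d_pr1`, `d_sh`, `d_pr2`, `hidden_a`, `hidden_b`.
#' @param training List of [training_config()] arguments (except `seed`,
#'   which is derived from the global seed).
#' @param clustering List: fixed `k`, or `k_range` for the elbow
#'   criterion; `nstart` restarts.
#' @param folds List: `n_folds`, `val_fraction`.
#' @param seed Global seed; all stage seeds are derived from it.
#' @param out_dir Output directory for artifacts and the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(), data_dir = NULL,
                            preprocess = list(), model = list(),
                            training = list(), clustering = list(),
                            folds = list(), seed = 1,
                            out_dir = tempfile("chromafuse_run_")) {
  pp <- utils::modifyList(
    list(mask_rule = NULL, mask_threshold = 0.15, mean_scope_a = "dataset"),
    preprocess
  )
  md <- utils::modifyList(
    list(d_pr1 = 16, d_sh = 32, d_pr2 = 16, hidden_a = 32, hidden_b = 32),
    model
  )
  tr <- utils::modifyList(
    list(epochs = 300, lr = 1e-5, lambda1 = 1, lambda2 = 1,
         batch_size = 32, optimizer = "adamp", sample = TRUE),
    training
  )
  cl <- utils::modifyList(list(k = NULL, k_range = c(2, 8), nstart = 50),
                          clustering)
  fd <- utils::modifyList(list(n_folds = 10, val_fraction = 0.1), folds)
  structure(list(synthetic = synthetic, data_dir = data_dir,
                 preprocess = pp, model = md, training = tr,
                 clustering = cl, folds = fd, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Per-fold feature preparation. The group mask (a geometry choice) is
# computed once on all subjects; centering and z-scoring use the fold's
# training split only.
prepare_fold_features <- function(cohort, plan_fold, pp, mask_a = NULL) {
  ids <- cohort$metadata$subject_id
  tr <- match(plan_fold$train, ids)

  xa <- cohort$a$values
  if (!is.null(mask_a)) xa <- xa[, mask_a$keep, drop = FALSE]
  if (identical(pp$mean_scope_a, "per_subject")) {
    xa <- remove_mean(xa, "per_subject")
  } else {
    center <- colMeans(xa[tr, , drop = FALSE])
    xa <- remove_mean(xa, "dataset", center = center)
  }
  st_a <- suppressWarnings(fit_standardizer(xa[tr, , drop = FALSE]))
  fa <- apply_standardizer(xa, st_a)
  rownames(fa) <- ids

  m <- cohort$b$grid_dim[1]
  xb <- t(apply(cohort$b$values, 1, function(v) {
    vectorize_connectivity(matrix(v, m, m))
  }))
  st_b <- suppressWarnings(fit_standardizer(xb[tr, , drop = FALSE]))
  fb <- apply_standardizer(xb, st_b)
  rownames(fb) <- ids

  list(a = fa, b = fb, stats_a = st_a, stats_b = st_b)
}

write_artifact <- function(df, dir, name) {
  path <- file.path(dir, name)
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        paste(signif(unlist(v), 8), collapse = ";")
      }, character(1))
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  name
}

#' Run the full chromatic-fusion pipeline
#'
#' Executes: cohort acquisition (synthetic or from disk), stratified fold
#' plan, per-fold preprocessing and DMVAE training with best-validation
#' checkpointing, whole-cohort embedding per fold, K selection (elbow) on
#' the reference fold, K-Means++ clustering of every fold, MCP coloring,
#' Hungarian-matched robustness / enrichment / significance / site
#' statistics, shared-dimension matching with diagnosis correlations, and
#' the cross-reconstruction evaluation. All tabular artifacts and a JSON
#' manifest are written under `config$out_dir`; rerunning from the saved
#' manifest reproduces the deterministic artifacts byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list of class `chromafuse_run`), invisibly
#'   containing the in-memory results as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  artifacts <- character(0)

  cohort <- stage("cohort", {
    if (!is.null(config$data_dir)) {
      read_cohort(config$data_dir)
    } else {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- derive_seed(config$seed, "cohort")
      sim <- generate_cohort(do.call(synthetic_config, args))
      sim$cohort
    }
  })
  metadata <- cohort$metadata

  plan <- stage("folds", make_fold_plan(
    metadata, n_folds = config$folds$n_folds,
    seed = derive_seed(config$seed, "folds"),
    val_fraction = config$folds$val_fraction
  ))
  artifacts <- c(artifacts,
                 write_artifact(tidy(plan), config$out_dir, "fold_plan.csv"))

  mask_a <- NULL
  if (!is.null(config$preprocess$mask_rule)) {
    mask_a <- stage("mask", compute_group_mask(
      cohort$a, rule = config$preprocess$mask_rule,
      threshold = config$preprocess$mask_threshold
    ))
  }

  fits <- vector("list", plan$n_folds)
  feats <- vector("list", plan$n_folds)
  embeddings <- vector("list", plan$n_folds)
  stage("train", {
    for (f in seq_len(plan$n_folds)) {
      feats[[f]] <- prepare_fold_features(cohort, plan$folds[[f]],
                                          config$preprocess, mask_a)
      tc <- do.call(training_config, c(
        config$training, list(seed = derive_seed(config$seed,
                                                 paste0("fold", f)))
      ))
      fits[[f]] <- train_fold(
        feats[[f]]$a, feats[[f]]$b,
        split = plan$folds[[f]], config = tc,
        d_pr1 = config$model$d_pr1, d_sh = config$model$d_sh,
        d_pr2 = config$model$d_pr2,
        hidden_a = config$model$hidden_a, hidden_b = config$model$hidden_b
      )
      embeddings[[f]] <- embed_subjects(fits[[f]]$model,
                                        feats[[f]]$a, feats[[f]]$b)
    }
  })

  cluster_res <- stage("cluster", {
    k <- config$clustering[["k"]] # exact: never partial-match k_range
    elbow <- NULL
    if (is.null(k)) {
      kr <- config$clustering$k_range
      elbow <- select_k_elbow(embeddings[[1]], seq(kr[1], kr[2]),
                              seed = derive_seed(config$seed, "elbow"))
      k <- elbow$k
    }
    clusterings <- lapply(seq_len(plan$n_folds), function(f) {
      cluster_kmeanspp(embeddings[[f]], k,
                       seed = derive_seed(config$seed, paste0("km", f)),
                       nstart = config$clustering$nstart)
    })
    list(k = k, elbow = elbow, clusterings = clusterings)
  })
  labels_list <- lapply(cluster_res$clusterings, `[[`, "labels")

  chroma <- stage("color", {
    mcp_colors <- color_mcps(cluster_res$clusterings[[1]])
    subj_colors <- color_subjects(embeddings[[1]],
                                  cluster_res$clusterings[[1]], mcp_colors)
    list(mcp_colors = mcp_colors, subj_colors = subj_colors)
  })
  artifacts <- c(
    artifacts,
    write_artifact(chroma$mcp_colors, config$out_dir, "mcp_table.csv"),
    write_artifact(chroma$subj_colors, config$out_dir, "subject_colors.csv")
  )

  robust <- stage("robustness", {
    stats <- mcp_statistics(labels_list, metadata)
    signif <- enrichment_significance(labels_list[[1]],
                                      stats::setNames(metadata$diagnosis,
                                                      metadata$subject_id))
    site <- site_effect_check(labels_list, metadata)
    list(stats = stats, significance = signif, site = site)
  })
  artifacts <- c(artifacts,
                 write_artifact(robust$stats, config$out_dir,
                                "mcp_stats.csv"))

  shared <- stage("shared", {
    blocks <- embedding_blocks(embeddings[[1]])
    shared_list <- lapply(embeddings, function(e) {
      unclass(e)[, blocks$sh, drop = FALSE]
    })
    rep <- match_shared_dims(shared_list)
    shared_dim_diagnosis(rep, shared_list,
                         metadata$diagnosis[match(rownames(embeddings[[1]]),
                                                  metadata$subject_id)])
  })
  artifacts <- c(artifacts,
                 write_artifact(shared, config$out_dir, "shared_dims.csv"))

  crossrec <- stage("crossrec", evaluate_cross_reconstruction(fits, feats,
                                                              plan))
  artifacts <- c(artifacts,
                 write_artifact(crossrec, config$out_dir,
                                "cross_reconstruction.csv"))

  manifest <- structure(list(
    package = "chromafuse",
    version = as.character(utils::packageVersion("chromafuse")),
    seed = config$seed,
    k = cluster_res$k,
    n_subjects = nrow(metadata),
    n_folds = plan$n_folds,
    config = unclass_config(config),
    artifacts = artifacts
  ), class = "chromafuse_run")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  results <- list(cohort = cohort, plan = plan, fits = fits,
                  embeddings = embeddings, clusterings =
                    cluster_res$clusterings, elbow = cluster_res$elbow,
                  chroma = chroma, robust = robust, shared = shared,
                  crossrec = crossrec, features = feats)
  attr(manifest, "results") <- results
  invisible(manifest)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$synthetic <- lapply(out$synthetic, function(x) x)
  out
}

#' @export
print.chromafuse_run <- function(x, ...) {
  cat(sprintf("<chromafuse_run> n=%d, %d folds, k=%d, seed=%d\n",
              x$n_subjects, x$n_folds, x$k, x$seed))
  cat("  artifacts:", paste(x$artifacts, collapse = ", "), "\n")
  invisible(x)
}

#' Re-run a pipeline from a saved manifest
#'
#' Reads `manifest.json` from a previous run and re-executes the pipeline
#' with the identical configuration and seeds, writing to `out_dir`.
#'
#' @param manifest_path Path to a `manifest.json` (or its directory).
#' @param out_dir Output directory for the re-run (defaults to the
#'   configuration's recorded directory).
#' @return The new run manifest, invisibly.
#' @export
rerun_pipeline <- function(manifest_path, out_dir = NULL) {
  if (dir.exists(manifest_path)) {
    manifest_path <- file.path(manifest_path, "manifest.json")
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  config <- pipeline_config(
    synthetic = as.list(cfg$synthetic), data_dir = cfg$data_dir,
    preprocess = as.list(cfg$preprocess), model = as.list(cfg$model),
    training = as.list(cfg$training),
    clustering = as.list(cfg$clustering), folds = as.list(cfg$folds),
    seed = cfg$seed, out_dir = out_dir %||% cfg$out_dir
  )
  # JSON round-trips NULL mask_rule / k away; restore explicit NULLs
  if (is.null(cfg$preprocess$mask_rule)) config$preprocess$mask_rule <- NULL
  if (is.null(cfg$clustering$k) || length(cfg$clustering$k) == 0) {
    config$clustering$k <- NULL
  }
  run_pipeline(config)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the [pipeline_config()] arguments; unknown keys
#' are rejected. Used by the command-line interface; `overrides` lets CLI
#' flags replace top-level keys.
#'
#' @param path YAML file.
#' @param overrides Named list of top-level keys to replace (e.g. `seed`,
#'   `out_dir`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path) %||% list()
  allowed <- c("synthetic", "data_dir", "preprocess", "model", "training",
               "clustering", "folds", "seed", "out_dir")
  bad <- setdiff(names(y), allowed)
  abort_if(length(bad) > 0, "unknown configuration key(s): %s",
           paste(bad, collapse = ", "))
  y <- utils::modifyList(y, overrides)
  do.call(pipeline_config, y)
}

#' Evaluate cross-reconstruction against prior and normal baselines
#'
#' On each fold's held-out test subjects, compares three reconstructions
#' of each modality by masked mean squared error: `prior` (both latent
#' blocks at the prior mean, zero — the lower bound), `normal` (the
#' subject's own encoded private and shared means — the upper bound), and
#' `cross` (prior-mean private block plus the shared mean encoded from
#' the other modality). All paths use posterior means, never samples.
#'
#' @param fits List of [train_fold()] results, one per fold.
#' @param feats Per-fold feature lists (elements `a`, `b`) as produced by
#'   the pipeline's preprocessing.
#' @param plan The [make_fold_plan()] used for training.
#' @return Tibble of class `crossrec_table`: per direction (`a->b`,
#'   `b->a`) the mean and sd over folds of the three test MSEs.
#' @export
evaluate_cross_reconstruction <- function(fits, feats, plan) {
  abort_if(length(fits) != plan$n_folds || length(feats) != plan$n_folds,
           "need one fitted model and feature set per fold")
  per_fold <- lapply(seq_len(plan$n_folds), function(f) {
    model <- fits[[f]]$model
    abort_if(!isTRUE(model$trained), "missing trained model for fold %d", f)
    test <- plan$folds[[f]]$test
    xa <- feats[[f]]$a[test, , drop = FALSE]
    xb <- feats[[f]]$b[test, , drop = FALSE]
    mse <- function(pred, truth) mean(rowMeans((pred - truth)^2))
    one_dir <- function(present, target, x_present, x_target) {
      n <- nrow(x_present)
      d_pr <- if (target == "a") model$dims$d_pr1 else model$dims$d_pr2
      zeros_pr <- matrix(0, n, d_pr)
      zeros_sh <- matrix(0, n, model$dims$d_sh)
      prior <- decode(model, zeros_pr, zeros_sh, side = target)
      own <- encode(model, x_target, side = target)
      normal <- decode(model, as.matrix(own$private$mean),
                       as.matrix(own$shared$mean), side = target)
      cross <- cross_reconstruct(model, x_present,
                                 paste0(present, "->", target))
      c(prior = mse(prior, x_target), normal = mse(normal, x_target),
        cross = mse(cross, x_target))
    }
    rbind(`a->b` = one_dir("a", "b", xa, xb),
          `b->a` = one_dir("b", "a", xb, xa))
  })
  dirs <- c("a->b", "b->a")
  rows <- lapply(dirs, function(d) {
    vals <- t(vapply(per_fold, function(m) m[d, ], numeric(3)))
    tibble::tibble(
      direction = d,
      prior_mean = mean(vals[, "prior"]), prior_sd = stats::sd(vals[, "prior"]),
      normal_mean = mean(vals[, "normal"]),
      normal_sd = stats::sd(vals[, "normal"]),
      cross_mean = mean(vals[, "cross"]), cross_sd = stats::sd(vals[, "cross"])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$normal_mean > out$prior_mean)) {
    warning("normal reconstruction MSE exceeds the prior baseline",
            call. = FALSE)
  }
  class(out) <- c("crossrec_table", class(out))
  out
}
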