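balanced_metadata <- function(n, frac_sz = 0.5, seed = 3) {
  chromafuse:::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      diagnosis = sample(rep(c("SZ", "HC"),
                             c(round(n * frac_sz), n - round(n * frac_sz)))),
      sex = sample(c("F", "M"), n, replace = TRUE),
      site = sample(sprintf("site%02d", 1:5), n, replace = TRUE)
    )
  })
}

test_that("stratified folds balance classes to within one subject", {
  md <- balanced_metadata(100, 0.5)
  plan <- make_fold_plan(md, n_folds = 10, seed = 1)
  for (f in plan$folds) {
    dx <- md$diagnosis[match(f$test, md$subject_id)]
    expect_equal(sum(dx == "SZ"), 5)
    expect_equal(length(f$test), 10)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
  }
  # test folds partition the cohort
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test")), md$subject_id)
})

test_that("a 278-subject cohort at 49.28% patients folds like the source
          demographics", {
  md <- balanced_metadata(278, 0.4928, seed = 6)
  plan <- make_fold_plan(md, n_folds = 10, seed = 2)
  sizes <- vapply(plan$folds, function(f) length(f$test), integer(1))
  n_pat <- vapply(plan$folds, function(f) {
    sum(md$diagnosis[match(f$test, md$subject_id)] == "SZ")
  }, integer(1))
  expect_true(all(sizes %in% 27:28))
  expect_true(all(n_pat %in% 13:14))
})

test_that("fold plans are reproducible by seed", {
  md <- balanced_metadata(60)
  expect_identical(make_fold_plan(md, 5, seed = 7),
                   make_fold_plan(md, 5, seed = 7))
  expect_false(identical(make_fold_plan(md, 5, seed = 7),
                         make_fold_plan(md, 5, seed = 8)))
  expect_error(make_fold_plan(md[1:5, ], 10), "at least n_folds")
})

test_that("identical and permuted labelings match with 100% overlap", {
  set.seed(10)
  labs <- sample(0:2, 30, replace = TRUE)
  names(labs) <- sprintf("S%02d", 1:30)
  mc <- match_clusters(labs, labs)
  expect_equal(mc$mapping$overlap, rep(100, 3))
  expect_equal(mc$mapping$cluster_ref, mc$mapping$cluster_k)
  # a pure relabeling still matches at 100%
  perm <- c(`0` = 2L, `1` = 0L, `2` = 1L)
  labs_p <- perm[as.character(labs)]
  names(labs_p) <- names(labs)
  mc2 <- match_clusters(labs, labs_p)
  expect_equal(mc2$mapping$overlap, rep(100, 3))
  expect_equal(mc2$mapping$cluster_k[mc2$mapping$cluster_ref == 0], 2L)
})

test_that("Hungarian matching equals exhaustive permutation search", {
  # 12 subjects, 3 clusters, hand-crafted partial overlap
  l0 <- c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2)
  lk <- c(0, 0, 1, 1, 1, 1, 2, 2, 2, 2, 0, 0)
  names(l0) <- names(lk) <- sprintf("S%02d", 1:12)
  mc <- match_clusters(l0, lk)
  ov <- mc$overlap_matrix
  best <- -brute_force_assignment(-ov)
  expect_equal(mc$total, best)
})

test_that("unequal cluster counts leave unmatched reference clusters at 0", {
  l0 <- c(rep(0L, 4), rep(1L, 4), rep(2L, 4))
  lk <- c(rep(0L, 6), rep(1L, 6))
  names(l0) <- names(lk) <- sprintf("S%02d", 1:12)
  mc <- match_clusters(l0, lk)
  expect_equal(sum(is.na(mc$mapping$cluster_k)), 1)
  expect_equal(mc$mapping$overlap[is.na(mc$mapping$cluster_k)], 0)
})

test_that("MCP statistics are exact on constructed folds", {
  md <- balanced_metadata(40, 0.5, seed = 4)
  labs <- rep(c(0L, 1L), each = 20)
  names(labs) <- md$subject_id
  # all folds identical: robustness 100 +- 0
  st <- mcp_statistics(list(labs, labs, labs), md)
  expect_equal(st$robustness_mean, c(100, 100))
  expect_equal(st$robustness_sd, c(0, 0))
  # a cluster of only patients in every fold: %SZ = 100 +- 0
  labs2 <- ifelse(md$diagnosis == "SZ", 0L, 1L)
  names(labs2) <- md$subject_id
  st2 <- mcp_statistics(list(labs2, labs2), md)
  expect_equal(st2$sz_mean[st2$mcp == 0], 100)
  expect_equal(st2$sz_sd[st2$mcp == 0], 0)
  expect_true(st2$enriched[st2$mcp == 0])
  expect_false(st2$enriched[st2$mcp == 1])
  # statistics are invariant to relabeling within any fold
  relab <- c(`0` = 5L, `1` = 3L)[as.character(labs)]
  names(relab) <- md$subject_id
  st3 <- mcp_statistics(list(labs, relab, labs), md)
  expect_equal(st3$robustness_mean, st$robustness_mean)
  expect_equal(st3$sz_mean, st$sz_mean)
})

test_that("the enrichment flag threshold is 70%", {
  expect_equal(formals(mcp_statistics)$enrich_threshold, 70)
})

test_that("pairwise enrichment tests agree with the exact hypergeometric", {
  md <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:40),
    diagnosis = rep(c("SZ", "HC"), each = 20)
  )
  # clusters with proportions 1.0 vs 0.0
  labs <- rep(c(0L, 1L), each = 20)
  names(labs) <- md$subject_id
  outcome <- stats::setNames(md$diagnosis, md$subject_id)
  res <- enrichment_significance(labs, outcome)
  expect_lt(res$p_adj, 0.0005)
  # exhaustive hypergeometric oracle for the 2x2 table
  probs <- stats::dhyper(0:20, 20, 20, 20)
  p_exact <- sum(probs[probs <= stats::dhyper(20, 20, 20, 20) *
                         (1 + 1e-7)])
  expect_equal(res$p_value, p_exact, tolerance = 1e-10)
  # identical proportions give p near 1
  labs_eq <- rep(c(0L, 1L), times = 20)
  names(labs_eq) <- md$subject_id
  res_eq <- enrichment_significance(labs_eq, outcome)
  expect_gt(res_eq$p_value, 0.5)
})

test_that("Holm correction preserves the p-value ordering", {
  set.seed(23)
  md <- balanced_metadata(90, 0.5, seed = 14)
  labs <- sample(0:2, 90, replace = TRUE)
  labs[md$diagnosis == "SZ"][1:20] <- 0L
  names(labs) <- md$subject_id
  res <- enrichment_significance(labs,
                                 stats::setNames(md$diagnosis,
                                                 md$subject_id))
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
})

test_that("site dispersion is zero for a single site and small for
          diagnosis-sorted clusters", {
  md <- balanced_metadata(40, 0.5, seed = 4)
  md$site <- "site01"
  labs <- rep(c(0L, 1L), each = 20)
  names(labs) <- md$subject_id
  res <- site_effect_check(list(labs, labs), md)
  expect_equal(res$site_sd, c(0, 0))
  # near-pure clusters on a multi-site cohort stay under the 5% flag
  md2 <- balanced_metadata(300, 0.5, seed = 9)
  labs2 <- ifelse(md2$diagnosis == "SZ", 0L, 1L)
  names(labs2) <- md2$subject_id
  res2 <- site_effect_check(list(labs2, labs2, labs2), md2)
  expect_true(all(res2$site_sd < 5))
  expect_false(any(res2$flagged))
})

test_that("heterogeneity overlap reduces to set arithmetic", {
  a <- sprintf("P%02d", 1:10)
  b <- c(a[1:4], sprintf("Q%02d", 1:6)) # shares 4 of r's 10 patients
  sets <- list(mcp_r = list(a), mcp_c = list(b))
  h <- heterogeneity_overlap(sets, all_patients = union(a, b))
  expect_equal(h["mcp_r", "mcp_c"], 60)
  expect_equal(h["mcp_c", "mcp_r"], 60)
  expect_equal(attr(h, "union_coverage")[["mean"]], 100)
  # identical member sets: off-diagonal 0; disjoint sets: 100
  same <- heterogeneity_overlap(list(x = list(a), y = list(a)))
  expect_equal(same["x", "y"], 0)
  expect_equal(unname(diag(same)), c(0, 0))
  disj <- heterogeneity_overlap(list(x = list(a[1:5]), y = list(a[6:10])))
  expect_equal(disj["x", "y"], 100)
  expect_equal(unname(diag(disj)), c(50, 50))
})
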