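make_trained_toy <- function(seed = 31) {
  m <- dmvae_model(6, 7, d_pr1 = 2, d_sh = 3, d_pr2 = 2,
                   hidden_a = 4, hidden_b = 4, seed = seed)
  m$trained <- TRUE
  m
}

test_that("the fused embedding concatenates [pr1 | sh | pr2] posterior means", {
  m <- make_trained_toy()
  x_a <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("s", 1:5), NULL))
  x_b <- matrix(rnorm(35), 5, 7, dimnames = list(paste0("s", 1:5), NULL))
  emb <- embed_subjects(m, x_a, x_b)
  expect_equal(dim(emb), c(5L, 7L))
  blocks <- chromafuse:::embedding_blocks(emb)
  pa <- encode(m, x_a, "a")
  pb <- encode(m, x_b, "b")
  # slice-equality against the per-modality posteriors
  expect_equal(unclass(emb)[, blocks$pr1], unname(pa$private$mean),
               ignore_attr = TRUE)
  expect_equal(unclass(emb)[, blocks$pr2], unname(pb$private$mean),
               ignore_attr = TRUE)
  sh <- poe_combine(pa$shared, pb$shared)
  expect_equal(unclass(emb)[, blocks$sh], unname(sh$mean),
               ignore_attr = TRUE)
  # identical subjects get identical rows
  x_a2 <- x_a; x_a2[2, ] <- x_a[1, ]
  x_b2 <- x_b; x_b2[2, ] <- x_b[1, ]
  emb2 <- embed_subjects(m, x_a2, x_b2)
  expect_identical(unclass(emb2)[1, ], unclass(emb2)[2, ])
})

test_that("the default fused embedding is 64-dimensional", {
  m <- dmvae_model(5, 5, seed = 1)
  m$trained <- TRUE
  emb <- embed_subjects(m, matrix(rnorm(10), 2, 5), matrix(rnorm(10), 2, 5))
  expect_equal(ncol(emb), 64L)
})

test_that("k-means++ clustering recovers planted structure", {
  set.seed(71)
  centers_true <- rbind(c(0, 0), c(8, 0), c(0, 8))
  lab_true <- rep(1:3, each = 30)
  x <- centers_true[lab_true, ] + matrix(rnorm(180, sd = 0.4), 90, 2)
  rownames(x) <- paste0("s", 1:90)
  cl <- cluster_kmeanspp(x, 3, seed = 5, nstart = 20)
  expect_equal(partition_agreement(cl$labels, lab_true), 1.0)
  # two planted blobs
  x2 <- x[lab_true != 3, ]
  cl2 <- cluster_kmeanspp(x2, 2, seed = 5, nstart = 20)
  expect_equal(partition_agreement(cl2$labels, lab_true[lab_true != 3]), 1.0)
})

test_that("clustering a duplicated point set recovers the distinct points", {
  pts <- rbind(c(0, 0), c(5, 5), c(-3, 4))
  x <- pts[rep(1:3, times = 4), ]
  rownames(x) <- paste0("s", 1:12)
  cl <- cluster_kmeanspp(x, 3, seed = 2, nstart = 10)
  expect_equal(cl$inertia, 0)
  expect_setequal(split(seq_len(12), cl$labels) |> lengths(), rep(4, 3))
  reordered <- cl$centers[order(cl$centers[, 1]), ]
  expect_equal(reordered, pts[order(pts[, 1]), ], ignore_attr = TRUE)
})

test_that("cluster labels are invariant under joint rotation", {
  set.seed(9)
  x <- matrix(rnorm(60 * 4), 60, 4)
  x[1:30, 1] <- x[1:30, 1] + 6
  rownames(x) <- paste0("s", 1:60)
  theta <- 0.7
  q <- diag(4)
  q[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
                        2, 2)
  cl1 <- cluster_kmeanspp(x, 2, seed = 3, nstart = 20)
  cl2 <- cluster_kmeanspp(x %*% q, 2, seed = 3, nstart = 20)
  expect_equal(partition_agreement(cl1$labels, cl2$labels), 1.0)
})

test_that("elbow selection finds planted cluster counts and returns the curve", {
  set.seed(13)
  centers_true <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  x <- centers_true[rep(1:3, each = 25), ] + matrix(rnorm(225, sd = 0.5),
                                                    75, 3)
  sel <- select_k_elbow(x, 2:8, seed = 4)
  expect_equal(sel$k, 3L)
  # WCSS is non-increasing in k (fixed seeds, generous restarts)
  expect_true(all(diff(sel$curve$wcss) <= 1e-8))
  expect_error(select_k_elbow(x, 2:3), "k_range too small")
})

test_that("MCP colors are subspace norms scaled by the per-subspace maximum", {
  blocks <- list(pr1 = 1:2, sh = 3:4, pr2 = 5:6)
  # two clusters with pr1 norms (3, 4) -> red channels (0.75, 1)
  centers <- rbind(c(3, 0, 1, 0, 0, 2), c(0, 4, 0, 2, 1, 0))
  cols <- color_mcps(centers, blocks = blocks)
  expect_equal(cols$red, c(0.75, 1))
  expect_equal(cols$norm_pr1, c(3, 4))
  # single cluster with nonzero norms is (1, 1, 1)
  one <- color_mcps(matrix(1, 1, 6), blocks = blocks)
  expect_equal(unlist(one[, c("red", "green", "blue")]), c(1, 1, 1),
               ignore_attr = TRUE)
  # a center at the origin among nonzero ones is (0, 0, 0)
  both <- color_mcps(rbind(0, c(1, 1, 1, 1, 1, 1)), blocks = blocks)
  expect_equal(unlist(both[1, c("red", "green", "blue")]), c(0, 0, 0),
               ignore_attr = TRUE)
  # all-zero subspace norms give channel 0, not 0/0
  zs <- color_mcps(rbind(c(1, 0, 0, 0, 0, 0), c(2, 0, 0, 0, 0, 0)),
                   blocks = blocks)
  expect_equal(zs$green, c(0, 0))
  expect_equal(zs$blue, c(0, 0))
})

test_that("subject colors follow the inverse-fourth-power weighting", {
  blocks <- list(pr1 = 1, sh = 2, pr2 = 3)
  centers <- rbind(c(0, 0, 0), c(3, 0, 0))
  cols <- color_mcps(centers, blocks = blocks)
  # distances (1, 2) -> weights (16/17, 1/17), by direct evaluation
  subj <- matrix(c(1, 0, 0), 1, 3, dimnames = list("s1", NULL))
  d <- sqrt(c(sum((subj - centers[1, ])^2), sum((subj - centers[2, ])^2)))
  expect_equal(d, c(1, 2))
  sc <- color_subjects(subj, centers, cols)
  w <- attr(sc, "weights")
  expect_equal(drop(w), (d^-4) / sum(d^-4))
  expect_equal(drop(w), c(16 / 17, 1 / 17))
  expect_equal(sc$red, 16 / 17 * cols$red[1] + 1 / 17 * cols$red[2])
  # a subject on a center takes that center's color exactly
  on_center <- matrix(centers[2, ], 1, 3, dimnames = list("s2", NULL))
  sc2 <- color_subjects(on_center, centers, cols)
  expect_equal(unlist(sc2[, c("red", "green", "blue")]),
               unlist(cols[2, c("red", "green", "blue")]),
               ignore_attr = TRUE)
  # equidistant subjects average the two colors
  mid <- matrix(c(1.5, 2, 0), 1, 3, dimnames = list("s3", NULL))
  sc3 <- color_subjects(mid, centers, cols)
  expect_equal(sc3$red, mean(cols$red))
  expect_equal(sc3$green, mean(cols$green))
})

test_that("decoding an MCP averages member latents before the decoder", {
  m <- dmvae_model(6, 7, d_pr1 = 2, d_sh = 3, d_pr2 = 2,
                   hidden_a = 0, hidden_b = 0, seed = 8)
  m$trained <- TRUE
  x_a <- matrix(rnorm(18), 3, 6, dimnames = list(paste0("s", 1:3), NULL))
  x_b <- matrix(rnorm(21), 3, 7, dimnames = list(paste0("s", 1:3), NULL))
  emb <- embed_subjects(m, x_a, x_b)
  labels <- c(s1 = 0L, s2 = 0L, s3 = 1L)
  # two-member manual average oracle
  lat <- colMeans(unclass(emb)[1:2, ])
  blocks <- chromafuse:::embedding_blocks(emb)
  dec <- decode_mcp(m, emb, labels, 0)
  expect_equal(dec$latent, lat)
  expect_equal(dec$a, drop(decode(m, lat[blocks$pr1], lat[blocks$sh], "a")))
  # single-member MCP equals that subject's own reconstruction
  dec1 <- decode_mcp(m, emb, labels, 1)
  own <- unclass(emb)["s3", ]
  expect_equal(dec1$a, drop(decode(m, own[blocks$pr1], own[blocks$sh], "a")))
  # linear decoder: decode(mean) = mean(decode)
  per_subject <- rbind(
    drop(decode(m, unclass(emb)[1, blocks$pr1], unclass(emb)[1, blocks$sh], "a")),
    drop(decode(m, unclass(emb)[2, blocks$pr1], unclass(emb)[2, blocks$sh], "a"))
  )
  expect_equal(dec$a, colMeans(per_subject))
  # filtering to an empty subgroup errors
  expect_error(decode_mcp(m, emb, labels, 1, subjects = "s1"), "no members")
})
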