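test_that("encoding is deterministic with the documented block sizes", {
  m <- dmvae_model(10, 12, seed = 2) # defaults: 16 / 32 / 16
  x <- matrix(rnorm(30), 3, 10)
  p1 <- encode(m, x, "a")
  p2 <- encode(m, x, "a")
  expect_identical(p1, p2)
  expect_equal(ncol(p1$private$mean), 16)
  expect_equal(ncol(p1$shared$mean), 32)
  expect_true(all(is.finite(p1$private$mean)))
  expect_true(all(is.finite(exp(p1$shared$logvar))))
  expect_error(encode(m, matrix(0, 2, 7), "a"), "expects 10 features")
})

test_that("product of experts matches the closed form and a grid oracle", {
  # equal unit experts halve the variance
  p <- poe_combine(gaussian_block(0, 0), gaussian_block(0, 0))
  expect_equal(p$mean, 0)
  expect_equal(exp(p$logvar), 0.5)
  # hand value: N(1, 0.5) x N(-1, 2) -> var 0.4, mean 0.6
  p2 <- poe_combine(gaussian_block(1, log(0.5)), gaussian_block(-1, log(2)))
  expect_equal(exp(p2$logvar), 0.4, tolerance = 1e-12)
  expect_equal(p2$mean, 0.6, tolerance = 1e-12)
  g <- grid_gaussian_product(1, 0.5, -1, 2)
  expect_lt(abs(g$mean - p2$mean), 1e-4)
  expect_lt(abs(g$var - exp(p2$logvar)), 1e-4)
  # a vague expert leaves the other almost untouched
  p3 <- poe_combine(gaussian_block(0.7, log(0.3)), gaussian_block(5, log(1e6)))
  expect_lt(abs(p3$mean - 0.7) / 0.7, 1e-3)
  expect_lt(abs(exp(p3$logvar) - 0.3) / 0.3, 1e-3)
  expect_error(poe_combine(gaussian_block(c(0, 0), c(0, 0)),
                           gaussian_block(0, 0)), "mismatched")
})

test_that("KL to the prior matches closed form and Monte Carlo", {
  expect_equal(kl_to_prior(gaussian_block(0, 0)), 0)
  expect_equal(kl_to_prior(gaussian_block(1, 0)), 0.5)
  set.seed(33)
  mu <- rnorm(32, sd = 0.8)
  lv <- rnorm(32, sd = 0.5)
  analytic <- kl_to_prior(gaussian_block(mu, lv))
  # Monte-Carlo oracle: E_q[log q(z) - log p(z)]
  nmc <- 1e6
  z <- matrix(rnorm(nmc * 32, mean = rep(mu, each = nmc),
                    sd = rep(exp(lv / 2), each = nmc)), nmc, 32)
  lq <- rowSums(dnorm(z, rep(mu, each = nmc), rep(exp(lv / 2), each = nmc),
                      log = TRUE))
  lp <- rowSums(dnorm(z, log = TRUE))
  diff <- lq - lp
  se <- sd(diff) / sqrt(nmc)
  expect_lt(abs(mean(diff) - analytic), 3 * se)
})

test_that("decoding is deterministic and linear decoders are matrix products", {
  m <- dmvae_model(6, 5, d_pr1 = 2, d_sh = 3, d_pr2 = 2,
                   hidden_a = 0, hidden_b = 0, seed = 4)
  pr <- matrix(rnorm(4), 2, 2)
  sh <- matrix(rnorm(6), 2, 3)
  expect_identical(decode(m, pr, sh, "a"), decode(m, pr, sh, "a"))
  # matrix-product oracle for the linear decoder
  W <- m$params$dec_a$W[[1]]
  b <- m$params$dec_a$b[[1]]
  expect_equal(decode(m, pr, sh, "a"),
               sweep(cbind(pr, sh) %*% W, 2, b, "+"))
  # zero latents give a well-defined prior-mean reconstruction
  prior_rec <- decode(m, matrix(0, 1, 2), matrix(0, 1, 3), "a")
  expect_equal(drop(prior_rec), b)
  expect_error(decode(m, matrix(0, 1, 3), matrix(0, 1, 3), "a"), "latent")
})

test_that("the objective has 5 KL + 6 reconstruction terms, all KLs >= 0", {
  m <- dmvae_model(7, 8, d_pr1 = 2, d_sh = 3, d_pr2 = 2,
                   hidden_a = 5, hidden_b = 5, seed = 6)
  lb <- dmvae_loss(m, matrix(rnorm(21), 3, 7), matrix(rnorm(24), 3, 8),
                   lambda1 = 1.2, lambda2 = 0.8, sample = TRUE, seed = 2)
  expect_length(lb$terms, 11)
  kl_terms <- lb$terms[startsWith(names(lb$terms), "kl_")]
  rec_terms <- lb$terms[startsWith(names(lb$terms), "recon_")]
  expect_length(kl_terms, 5)
  expect_length(rec_terms, 6)
  expect_true(all(kl_terms >= 0))
  expect_equal(lb$total,
               sum(kl_terms) + 1.2 * sum(rec_terms[1:3]) +
                 0.8 * sum(rec_terms[4:6]))
})

test_that("a posterior at the prior with exact reconstruction zeroes every
          term except the fused-posterior KL", {
  # linear model, all weights/biases zero, zero input: both encoders emit
  # the prior and reconstructions are exact. The product of two unit
  # experts has variance 1/2, so the fused posterior's KL cannot be zero:
  # it equals d_sh * 0.5 * (0.5 - log(0.5) - 1) by the closed form.
  m <- dmvae_model(3, 3, d_pr1 = 1, d_sh = 1, d_pr2 = 1,
                   hidden_a = 0, hidden_b = 0, seed = 1)
  m$params <- chromafuse:::nl_map(function(x) x * 0, m$params)
  lb <- dmvae_loss(m, matrix(0, 2, 3), matrix(0, 2, 3))
  other <- lb$terms[names(lb$terms) != "kl_poe"]
  expect_true(all(abs(other) < 1e-15))
  expect_equal(unname(lb$terms[["kl_poe"]]), 0.5 * (0.5 - log(0.5) - 1),
               tolerance = 1e-12)
})

test_that("the total matches an independent scalar re-implementation", {
  m <- dmvae_model(1, 1, d_pr1 = 1, d_sh = 1, d_pr2 = 1,
                   hidden_a = 0, hidden_b = 0, seed = 12)
  xa <- matrix(0.37, 1, 1)
  xb <- matrix(-0.81, 1, 1)
  eps <- chromafuse:::with_seed(5, chromafuse:::make_eps(1, m$dims, TRUE))
  fw <- chromafuse:::dmvae_forward(m$params, m$dims, xa, xb, 1.3, 0.6, eps)
  expect_lt(abs(fw$total - scalar_dmvae_loss(m$params, 0.37, -0.81, eps,
                                             1.3, 0.6)), 1e-8)
})

test_that("analytic gradients pass a finite-difference check", {
  m <- dmvae_model(5, 6, d_pr1 = 2, d_sh = 3, d_pr2 = 2,
                   hidden_a = 4, hidden_b = 4, seed = 3)
  set.seed(14)
  xa <- matrix(rnorm(15), 3, 5)
  xb <- matrix(rnorm(18), 3, 6)
  expect_lt(chromafuse:::grad_check(m, xa, xb, lambda1 = 1.4,
                                    lambda2 = 0.7, sample = TRUE), 1e-4)
  expect_lt(chromafuse:::grad_check(m, xa, xb, sample = FALSE), 1e-4)
})

test_that("non-finite losses abort naming the offending term", {
  m <- dmvae_model(3, 3, d_pr1 = 1, d_sh = 1, d_pr2 = 1,
                   hidden_a = 0, hidden_b = 0, seed = 1)
  m$params$dec_a$W[[1]][1, 1] <- Inf
  expect_error(dmvae_loss(m, matrix(1, 1, 3), matrix(1, 1, 3)),
               "recon_a")
})

test_that("training returns the best-validation snapshot and logs terms", {
  sim <- tiny_cohort(n = 60, seed = 55)
  plan <- make_fold_plan(sim$cohort$metadata, n_folds = 3, seed = 2)
  res <- fit_study_fold(sim$cohort, plan, 1, epochs = 8, seed = 4)
  fit <- res$fit
  expect_equal(nrow(fit$log), 8)
  expect_equal(fit$best_epoch, which.min(fit$log$val_total))
  expect_equal(fit$best_val, min(fit$log$val_total))
  expect_true(all(c("kl_poe", "recon_b_cross") %in% names(fit$log)))
  expect_true(fit$model$trained)
  # epochs = 1 returns the epoch-1 snapshot
  tc1 <- training_config(epochs = 1, lr = 1e-3, seed = 4)
  fit1 <- train_fold(res$features$a, res$features$b,
                     split = plan$folds[[1]], config = tc1,
                     d_pr1 = 2, d_sh = 3, d_pr2 = 2,
                     hidden_a = 4, hidden_b = 4)
  expect_equal(fit1$best_epoch, 1L)
})

test_that("training defaults follow the reference protocol", {
  tc <- training_config()
  expect_equal(tc$epochs, 300L)
  expect_equal(tc$lr, 1e-5)
  expect_equal(tc$optimizer, "adamp")
  md <- dmvae_model(4, 4)
  expect_equal(md$dims$d_pr1, 16L)
  expect_equal(md$dims$d_sh, 32L)
  expect_equal(md$dims$d_pr2, 16L)
})

test_that("identical seeds reproduce the training run exactly", {
  sim <- tiny_cohort(n = 40, seed = 66)
  plan <- make_fold_plan(sim$cohort$metadata, n_folds = 2, seed = 9)
  r1 <- fit_study_fold(sim$cohort, plan, 1, epochs = 4, seed = 11)
  r2 <- fit_study_fold(sim$cohort, plan, 1, epochs = 4, seed = 11)
  expect_identical(r1$fit$log, r2$fit$log)
  expect_identical(r1$fit$model$params, r2$fit$model$params)
})

test_that("shrinking the reconstruction weights drives posteriors to the prior", {
  sim <- tiny_cohort(n = 40, seed = 77, noise_sd = 0.2)
  plan <- make_fold_plan(sim$cohort$metadata, n_folds = 2, seed = 3)
  pf <- chromafuse:::prepare_fold_features(sim$cohort, plan$folds[[1]],
                                           list(mean_scope_a = "dataset"))
  kl_sum_at <- function(lam) {
    tc <- training_config(epochs = 12, lr = 5e-3, lambda1 = lam,
                          lambda2 = lam, seed = 8)
    fit <- train_fold(pf$a, pf$b, split = plan$folds[[1]], config = tc,
                      d_pr1 = 2, d_sh = 3, d_pr2 = 2,
                      hidden_a = 8, hidden_b = 8)
    last <- fit$log[nrow(fit$log), ]
    sum(last$kl_pr1, last$kl_sh1, last$kl_pr2, last$kl_sh2, last$kl_poe)
  }
  expect_lt(kl_sum_at(0.01), kl_sum_at(1))
})

test_that("cross-reconstruction is sample-free and collapses to the prior
          baseline when the shared mean is zero", {
  m <- dmvae_model(4, 5, d_pr1 = 2, d_sh = 2, d_pr2 = 2,
                   hidden_a = 3, hidden_b = 3, seed = 21)
  expect_error(cross_reconstruct(m, matrix(0, 1, 4)), "untrained")
  m$trained <- TRUE
  x <- matrix(rnorm(8), 2, 4)
  r1 <- cross_reconstruct(m, x, "a->b")
  r2 <- cross_reconstruct(m, x, "a->b")
  expect_identical(r1, r2)
  # definitional collapse: zero shared mean -> the prior-point decoding
  post <- encode(m, x, "a")
  prior_dec <- decode(m, matrix(0, 2, 2), matrix(0, 2, 2), "b")
  manual <- decode(m, matrix(0, 2, 2), as.matrix(post$shared$mean), "b")
  expect_equal(r1, manual)
  zero_sh <- decode(m, matrix(0, 2, 2), 0 * as.matrix(post$shared$mean), "b")
  expect_equal(zero_sh, prior_dec)
})
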