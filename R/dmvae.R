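# The disentangled multimodal VAE: two encoders that parameterize
# axis-aligned Gaussian posteriors split into a private and a shared block,
# a product-of-experts fusion of the two shared posteriors, two decoders,
# and the 11-term objective (5 KL divergences + 6 reconstruction terms,
# including the two cross-generation terms). Gradients are analytic
# reverse-mode; the reconstruction likelihood is a unit-variance Gaussian,
# so reconstruction terms are reported as half summed squared error with
# the additive normalization constant dropped.

LOGVAR_CLAMP <- 15 # |log-variance| bound for numerical safety

#' Diagonal-Gaussian block
#'
#' A mean / log-variance pair describing an axis-aligned Gaussian over one
#' latent subspace. Vectors describe a single subject; matrices hold one
#' subject per row.
#'
#' @param mean Numeric vector or matrix of means.
#' @param logvar Log-variances, same shape as `mean`.
#' @return Object of class `gaussian_block`.
#' @export
gaussian_block <- function(mean, logvar) {
  abort_if(length(mean) != length(logvar) ||
             !identical(dim(mean), dim(logvar)),
           "mean and logvar must have identical shapes")
  abort_if(!all(is.finite(mean)) || !all(is.finite(logvar)),
           "gaussian_block requires finite mean and logvar")
  structure(list(mean = mean, logvar = logvar), class = "gaussian_block")
}

#' @export
print.gaussian_block <- function(x, ...) {
  d <- if (is.matrix(x$mean)) ncol(x$mean) else length(x$mean)
  n <- if (is.matrix(x$mean)) nrow(x$mean) else 1L
  cat(sprintf("<gaussian_block> %d dim(s), %d row(s)\n", d, n))
  invisible(x)
}

block_var <- function(block) exp(block$logvar)

#' Construct an untrained DMVAE
#'
#' Encoders map a modality's feature vector to the concatenated
#' `[mean | log-variance]` of its private and shared posterior blocks;
#' decoders map `[private | shared]` latents back to feature space. Hidden
#' layers use `tanh`; heads and outputs are linear. Sizes are fully
#' configurable so that tiny exactly-checkable models can be built.
#'
#' @param input_dim_a,input_dim_b Feature dimension of each modality
#'   (masked voxels for volumes, strict lower triangle for connectivity).
#' @param d_pr1,d_sh,d_pr2 Latent sizes; defaults 16 / 32 / 16.
#' @param hidden_a,hidden_b Integer vectors of hidden-layer widths
#'   (use `integer(0)` for a purely linear encoder/decoder).
#' @param seed Seed for weight initialization.
#' @return Object of class `dmvae` with fields `params` (the four weight
#'   sets), `arch`, `dims`, `trained`.
#' @export
dmvae_model <- function(input_dim_a, input_dim_b,
                        d_pr1 = 16, d_sh = 32, d_pr2 = 16,
                        hidden_a = 32, hidden_b = 32, seed = 1) {
  for (d in c(input_dim_a, input_dim_b, d_pr1, d_sh, d_pr2)) {
    abort_if(!is_count(d), "all dimensions must be positive counts")
  }
  hidden_a <- as.integer(hidden_a)
  hidden_b <- as.integer(hidden_b)
  hidden_a <- hidden_a[hidden_a > 0] # 0 or integer(0) = linear stack
  hidden_b <- hidden_b[hidden_b > 0]
  la <- d_pr1 + d_sh
  lb <- d_pr2 + d_sh
  arch <- list(
    enc_a = c(input_dim_a, hidden_a, 2 * la),
    dec_a = c(la, rev(hidden_a), input_dim_a),
    enc_b = c(input_dim_b, hidden_b, 2 * lb),
    dec_b = c(lb, rev(hidden_b), input_dim_b)
  )
  params <- with_seed(seed, list(
    enc_a = mlp_init(arch$enc_a),
    dec_a = mlp_init(arch$dec_a),
    enc_b = mlp_init(arch$enc_b),
    dec_b = mlp_init(arch$dec_b)
  ))
  structure(list(
    params = params, arch = arch,
    dims = list(d_pr1 = as.integer(d_pr1), d_sh = as.integer(d_sh),
                d_pr2 = as.integer(d_pr2),
                input_a = as.integer(input_dim_a),
                input_b = as.integer(input_dim_b)),
    seed = as.integer(seed), trained = FALSE
  ), class = "dmvae")
}

#' @export
print.dmvae <- function(x, ...) {
  cat(sprintf(
    "<dmvae>%s inputs %d / %d; latents pr1=%d sh=%d pr2=%d\n",
    if (x$trained) " (trained)" else " (untrained)",
    x$dims$input_a, x$dims$input_b, x$dims$d_pr1, x$dims$d_sh, x$dims$d_pr2
  ))
  n_par <- length(nl_flatten(x$params))
  cat(sprintf("  %d parameters; encoder stacks [%s] / [%s]\n", n_par,
              paste(x$arch$enc_a, collapse = "-"),
              paste(x$arch$enc_b, collapse = "-")))
  invisible(x)
}

clamp_logvar <- function(lv) pmin(pmax(lv, -LOGVAR_CLAMP), LOGVAR_CLAMP)

# Forward an encoder and split the head into posterior blocks.
encode_raw <- function(params, x, d_pr, d_sh) {
  fw <- mlp_forward(params, x)
  l <- d_pr + d_sh
  mu <- fw$out[, seq_len(l), drop = FALSE]
  lv_raw <- fw$out[, l + seq_len(l), drop = FALSE]
  lv <- clamp_logvar(lv_raw)
  list(
    mu_pr = mu[, seq_len(d_pr), drop = FALSE],
    mu_sh = mu[, d_pr + seq_len(d_sh), drop = FALSE],
    lv_pr = lv[, seq_len(d_pr), drop = FALSE],
    lv_sh = lv[, d_pr + seq_len(d_sh), drop = FALSE],
    clamp_open = (lv_raw > -LOGVAR_CLAMP & lv_raw < LOGVAR_CLAMP),
    acts = fw$acts
  )
}

#' Encode a modality into its partitioned posterior
#'
#' Deterministic given the parameters and input: returns the approximate
#' posterior's private and shared diagonal-Gaussian blocks.
#'
#' @param model A [dmvae_model()].
#' @param x Feature matrix (subjects x features) or a single feature
#'   vector for the chosen side.
#' @param side `"a"` or `"b"`.
#' @return A list of class `partitioned_posterior` with `private` and
#'   `shared` [gaussian_block()]s (matrix-valued, one row per subject).
#' @export
encode <- function(model, x, side = c("a", "b")) {
  stopifnot(inherits(model, "dmvae"))
  side <- match.arg(side)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  want <- if (side == "a") model$dims$input_a else model$dims$input_b
  abort_if(ncol(x) != want,
           "side %s expects %d features, got %d", side, want, ncol(x))
  d_pr <- if (side == "a") model$dims$d_pr1 else model$dims$d_pr2
  enc <- if (side == "a") model$params$enc_a else model$params$enc_b
  raw <- encode_raw(enc, x, d_pr, model$dims$d_sh)
  structure(list(
    private = gaussian_block(raw$mu_pr, raw$lv_pr),
    shared = gaussian_block(raw$mu_sh, raw$lv_sh),
    side = side
  ), class = "partitioned_posterior")
}

#' @export
print.partitioned_posterior <- function(x, ...) {
  cat(sprintf("<partitioned_posterior> side %s: private %d + shared %d dims\n",
              x$side, ncol(as.matrix(x$private$mean)),
              ncol(as.matrix(x$shared$mean))))
  invisible(x)
}

# Product-of-experts moments from means and variances (elementwise).
poe_moments <- function(mu1, v1, mu2, v2) {
  vp <- 1 / (1 / v1 + 1 / v2)
  mup <- vp * (mu1 / v1 + mu2 / v2)
  list(mu = mup, v = vp)
}

#' Product-of-experts fusion of two shared posteriors
#'
#' Multiplies two diagonal-Gaussian densities and renormalizes; in closed
#' form the precisions add and the mean is the precision-weighted average:
#' `1/var = 1/var1 + 1/var2`, `mean = var * (mean1/var1 + mean2/var2)`.
#'
#' @param sh1,sh2 [gaussian_block()]s of equal shape.
#' @return The fused `gaussian_block`.
#' @export
poe_combine <- function(sh1, sh2) {
  stopifnot(inherits(sh1, "gaussian_block"), inherits(sh2, "gaussian_block"))
  abort_if(length(sh1$mean) != length(sh2$mean),
           "expert blocks have mismatched lengths")
  v1 <- block_var(sh1)
  v2 <- block_var(sh2)
  abort_if(any(v1 <= 0) || any(v2 <= 0), "expert variances must be positive")
  mom <- poe_moments(sh1$mean, v1, sh2$mean, v2)
  gaussian_block(mom$mu, log(mom$v))
}

#' KL divergence of a diagonal-Gaussian block from the standard normal
#'
#' `0.5 * sum(mu^2 + var - log(var) - 1)` over dimensions, against the
#' zero-mean unit-covariance prior.
#'
#' @param block A [gaussian_block()].
#' @return A nonnegative scalar for a vector block; one value per row for
#'   a matrix block.
#' @export
kl_to_prior <- function(block) {
  stopifnot(inherits(block, "gaussian_block"))
  v <- block_var(block)
  per_dim <- 0.5 * (block$mean^2 + v - block$logvar - 1)
  if (is.matrix(per_dim)) rowSums(per_dim) else sum(per_dim)
}

#' Decode latents into modality space
#'
#' @param model A [dmvae_model()].
#' @param private,shared Latent vectors or matrices (rows = subjects); pass
#'   zeros for the prior mean of a block.
#' @param side Which decoder: `"a"` or `"b"`.
#' @return Decoded feature matrix (subjects x features).
#' @export
decode <- function(model, private, shared, side = c("a", "b")) {
  stopifnot(inherits(model, "dmvae"))
  side <- match.arg(side)
  if (is.null(dim(private))) private <- matrix(private, nrow = 1)
  if (is.null(dim(shared))) shared <- matrix(shared, nrow = 1)
  d_pr <- if (side == "a") model$dims$d_pr1 else model$dims$d_pr2
  abort_if(ncol(private) != d_pr || ncol(shared) != model$dims$d_sh,
           "latent sizes do not match decoder input (%d + %d)",
           d_pr, model$dims$d_sh)
  dec <- if (side == "a") model$params$dec_a else model$params$dec_b
  mlp_forward(dec, cbind(private, shared))$out
}

# Draw (or zero) the reparameterization noise for every sampled block.
make_eps <- function(n, dims, sample) {
  blank <- function(d) matrix(if (sample) stats::rnorm(n * d) else 0, n, d)
  list(pr1 = blank(dims$d_pr1), sh1 = blank(dims$d_sh),
       pr2 = blank(dims$d_pr2), sh2 = blank(dims$d_sh),
       shp = blank(dims$d_sh))
}

# Full forward pass of the objective. eps fixed by the caller so the pass
# is deterministic and finite-difference checkable.
dmvae_forward <- function(params, dims, x_a, x_b, lambda1, lambda2, eps) {
  n <- nrow(x_a)
  ea <- encode_raw(params$enc_a, x_a, dims$d_pr1, dims$d_sh)
  eb <- encode_raw(params$enc_b, x_b, dims$d_pr2, dims$d_sh)
  v <- list(pr1 = exp(ea$lv_pr), sh1 = exp(ea$lv_sh),
            pr2 = exp(eb$lv_pr), sh2 = exp(eb$lv_sh))
  poe <- poe_moments(ea$mu_sh, v$sh1, eb$mu_sh, v$sh2)

  z <- list(
    pr1 = ea$mu_pr + sqrt(v$pr1) * eps$pr1,
    sh1 = ea$mu_sh + sqrt(v$sh1) * eps$sh1,
    pr2 = eb$mu_pr + sqrt(v$pr2) * eps$pr2,
    sh2 = eb$mu_sh + sqrt(v$sh2) * eps$sh2,
    shp = poe$mu + sqrt(poe$v) * eps$shp
  )

  kl <- function(mu, lv) sum(0.5 * (mu^2 + exp(lv) - lv - 1)) / n
  kls <- c(
    kl_pr1 = kl(ea$mu_pr, ea$lv_pr),
    kl_sh1 = kl(ea$mu_sh, ea$lv_sh),
    kl_pr2 = kl(eb$mu_pr, eb$lv_pr),
    kl_sh2 = kl(eb$mu_sh, eb$lv_sh),
    kl_poe = sum(0.5 * (poe$mu^2 + poe$v - log(poe$v) - 1)) / n
  )

  dec_pass <- function(dec, zp, zs, x) {
    fw <- mlp_forward(dec, cbind(zp, zs))
    list(fw = fw, err = fw$out - x, value = 0.5 * sum((fw$out - x)^2) / n)
  }
  rec <- list(
    a_self = dec_pass(params$dec_a, z$pr1, z$sh1, x_a),
    a_poe = dec_pass(params$dec_a, z$pr1, z$shp, x_a),
    a_cross = dec_pass(params$dec_a, z$pr1, z$sh2, x_a),
    b_self = dec_pass(params$dec_b, z$pr2, z$sh2, x_b),
    b_poe = dec_pass(params$dec_b, z$pr2, z$shp, x_b),
    b_cross = dec_pass(params$dec_b, z$pr2, z$sh1, x_b)
  )
  recs <- c(
    recon_a_self = rec$a_self$value, recon_a_poe = rec$a_poe$value,
    recon_a_cross = rec$a_cross$value,
    recon_b_self = rec$b_self$value, recon_b_poe = rec$b_poe$value,
    recon_b_cross = rec$b_cross$value
  )
  total <- sum(kls) + lambda1 * sum(recs[1:3]) + lambda2 * sum(recs[4:6])
  terms <- c(kls, recs)
  if (!all(is.finite(terms))) {
    bad <- names(terms)[!is.finite(terms)]
    stop(sprintf("non-finite loss in term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  list(terms = terms, total = total, n = n,
       ea = ea, eb = eb, v = v, poe = poe, z = z, rec = rec,
       lambda1 = lambda1, lambda2 = lambda2, eps = eps,
       x_a = x_a, x_b = x_b)
}

add_net_grads <- function(acc, g) {
  for (l in seq_along(g$W)) {
    acc$W[[l]] <- acc$W[[l]] + g$W[[l]]
    acc$b[[l]] <- acc$b[[l]] + g$b[[l]]
  }
  acc
}

# Analytic reverse pass for the full objective; returns gradients with the
# same nesting as params.
dmvae_backward <- function(params, dims, fw) {
  n <- fw$n
  g <- nl_zeros_like(params)
  dz <- list(pr1 = 0 * fw$z$pr1, sh1 = 0 * fw$z$sh1, pr2 = 0 * fw$z$pr2,
             sh2 = 0 * fw$z$sh2, shp = 0 * fw$z$shp)

  back_rec <- function(which_dec, rec, lambda, d_pr) {
    d_out <- lambda * rec$err / n
    bk <- mlp_backward(params[[which_dec]], rec$fw$acts, d_out)
    g[[which_dec]] <<- add_net_grads(g[[which_dec]], bk)
    list(d_pr = bk$d_in[, seq_len(d_pr), drop = FALSE],
         d_sh = bk$d_in[, d_pr + seq_len(dims$d_sh), drop = FALSE])
  }
  r <- back_rec("dec_a", fw$rec$a_self, fw$lambda1, dims$d_pr1)
  dz$pr1 <- dz$pr1 + r$d_pr; dz$sh1 <- dz$sh1 + r$d_sh
  r <- back_rec("dec_a", fw$rec$a_poe, fw$lambda1, dims$d_pr1)
  dz$pr1 <- dz$pr1 + r$d_pr; dz$shp <- dz$shp + r$d_sh
  r <- back_rec("dec_a", fw$rec$a_cross, fw$lambda1, dims$d_pr1)
  dz$pr1 <- dz$pr1 + r$d_pr; dz$sh2 <- dz$sh2 + r$d_sh
  r <- back_rec("dec_b", fw$rec$b_self, fw$lambda2, dims$d_pr2)
  dz$pr2 <- dz$pr2 + r$d_pr; dz$sh2 <- dz$sh2 + r$d_sh
  r <- back_rec("dec_b", fw$rec$b_poe, fw$lambda2, dims$d_pr2)
  dz$pr2 <- dz$pr2 + r$d_pr; dz$shp <- dz$shp + r$d_sh
  r <- back_rec("dec_b", fw$rec$b_cross, fw$lambda2, dims$d_pr2)
  dz$pr2 <- dz$pr2 + r$d_pr; dz$sh1 <- dz$sh1 + r$d_sh

  # samples and per-block KL terms -> (mu, logvar) gradients
  d_mu <- list(); d_lv <- list()
  blocks <- list(
    pr1 = list(mu = fw$ea$mu_pr, lv = fw$ea$lv_pr, v = fw$v$pr1),
    sh1 = list(mu = fw$ea$mu_sh, lv = fw$ea$lv_sh, v = fw$v$sh1),
    pr2 = list(mu = fw$eb$mu_pr, lv = fw$eb$lv_pr, v = fw$v$pr2),
    sh2 = list(mu = fw$eb$mu_sh, lv = fw$eb$lv_sh, v = fw$v$sh2)
  )
  for (nm in names(blocks)) {
    bl <- blocks[[nm]]
    d_mu[[nm]] <- dz[[nm]] + bl$mu / n
    d_lv[[nm]] <- dz[[nm]] * 0.5 * sqrt(bl$v) * fw$eps[[nm]] +
      0.5 * (bl$v - 1) / n
  }

  # product-of-experts block: sample + its KL, chained to both experts
  mup <- fw$poe$mu; vp <- fw$poe$v
  v1 <- fw$v$sh1; v2 <- fw$v$sh2
  mu1 <- fw$ea$mu_sh; mu2 <- fw$eb$mu_sh
  d_mup <- dz$shp + mup / n
  d_vp <- dz$shp * fw$eps$shp * 0.5 / sqrt(vp) + 0.5 * (1 - 1 / vp) / n
  d_mu$sh1 <- d_mu$sh1 + d_mup * vp / v1
  d_mu$sh2 <- d_mu$sh2 + d_mup * vp / v2
  d_v1 <- d_mup * (mu2 - mup) / (v1 + v2) + d_vp * (vp / v1)^2
  d_v2 <- d_mup * (mu1 - mup) / (v1 + v2) + d_vp * (vp / v2)^2
  d_lv$sh1 <- d_lv$sh1 + d_v1 * v1
  d_lv$sh2 <- d_lv$sh2 + d_v2 * v2

  # assemble encoder-head gradients: [mu_pr | mu_sh | lv_pr | lv_sh]
  head_a <- cbind(d_mu$pr1, d_mu$sh1, d_lv$pr1, d_lv$sh1)
  head_a[, ncol(d_mu$pr1) + ncol(d_mu$sh1) +
             seq_len(ncol(d_lv$pr1) + ncol(d_lv$sh1))] <-
    cbind(d_lv$pr1, d_lv$sh1) * fw$ea$clamp_open
  bk <- mlp_backward(params$enc_a, fw$ea$acts, head_a)
  g$enc_a <- add_net_grads(g$enc_a, bk)

  head_b <- cbind(d_mu$pr2, d_mu$sh2, d_lv$pr2, d_lv$sh2)
  head_b[, ncol(d_mu$pr2) + ncol(d_mu$sh2) +
             seq_len(ncol(d_lv$pr2) + ncol(d_lv$sh2))] <-
    cbind(d_lv$pr2, d_lv$sh2) * fw$eb$clamp_open
  bk <- mlp_backward(params$enc_b, fw$eb$acts, head_b)
  g$enc_b <- add_net_grads(g$enc_b, bk)

  g
}

#' Evaluate the DMVAE objective with its term-wise breakdown
#'
#' The objective has exactly 11 components: 5 KL divergences (private and
#' shared blocks of both modalities plus the product-of-experts shared
#' posterior, each against the standard-normal prior) and 6 reconstruction
#' terms (each modality decoded from its own shared block, from the fused
#' shared block, and — the cross-generation terms — from the other
#' modality's shared block, always together with the modality's own
#' encoded private block). Reconstruction terms are half summed squared
#' errors per subject, averaged over the batch (unit-variance Gaussian
#' likelihood with the constant dropped); the total applies the modality
#' weights to the reconstruction sums.
#'
#' @param model A [dmvae_model()].
#' @param x_a,x_b Matched feature matrices, one row per subject.
#' @param lambda1,lambda2 Reconstruction weights for modalities A and B.
#' @param sample Draw reparameterized samples (training behaviour) or use
#'   posterior means (`FALSE`, deterministic evaluation).
#' @param seed Seed for the reparameterization noise when `sample = TRUE`.
#' @return A list of class `loss_breakdown`: named `terms` (length 11),
#'   `total`, and the batch size `n`.
#' @export
dmvae_loss <- function(model, x_a, x_b, lambda1 = 1, lambda2 = 1,
                       sample = FALSE, seed = 1) {
  stopifnot(inherits(model, "dmvae"))
  if (is.null(dim(x_a))) x_a <- matrix(x_a, nrow = 1)
  if (is.null(dim(x_b))) x_b <- matrix(x_b, nrow = 1)
  abort_if(nrow(x_a) != nrow(x_b), "modality batches must be matched")
  abort_if(lambda1 <= 0 || lambda2 <= 0, "lambda weights must be positive")
  eps <- if (sample) {
    with_seed(seed, make_eps(nrow(x_a), model$dims, TRUE))
  } else {
    make_eps(nrow(x_a), model$dims, FALSE)
  }
  fw <- dmvae_forward(model$params, model$dims, x_a, x_b,
                      lambda1, lambda2, eps)
  structure(list(terms = fw$terms, total = fw$total, n = fw$n),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total %.6g over %d subject(s)\n",
              x$total, x$n))
  print(round(x$terms, 6))
  invisible(x)
}

#' Training configuration for the DMVAE
#'
#' Defaults follow the reference protocol: an Adam-family optimizer
#' (labelled AdamP) for 300 epochs at learning rate 1e-5. Tiny synthetic
#' studies in the test-suite shrink epochs and raise the learning rate
#' through these fields.
#'
#' @param epochs Number of passes over the training split.
#' @param lr Learning rate.
#' @param lambda1,lambda2 Reconstruction weights.
#' @param batch_size Minibatch size.
#' @param optimizer Optimizer label; any Adam-family name is accepted and
#'   runs the Adam update.
#' @param lr_schedule `"constant"`, or `"cosine"` for cosine annealing of
#'   the learning rate to zero over the epochs (late-training annealing
#'   lets the latent axes settle, which stabilizes shared dimensions
#'   across folds).
#' @param sample Use reparameterized samples during training (evaluation
#'   always uses means).
#' @param seed Seed controlling initialization order, shuffling and noise.
#' @return List of class `training_config`.
#' @export
training_config <- function(epochs = 300, lr = 1e-5, lambda1 = 1,
                            lambda2 = 1, batch_size = 32,
                            optimizer = "adamp", sample = TRUE,
                            lr_schedule = c("constant", "cosine"),
                            seed = 1) {
  lr_schedule <- match.arg(lr_schedule)
  abort_if(!is_count(epochs), "epochs must be >= 1")
  abort_if(!is.numeric(lr) || lr <= 0, "lr must be positive")
  abort_if(lambda1 <= 0 || lambda2 <= 0, "lambda weights must be positive")
  abort_if(!is_count(batch_size), "batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), lr = lr, lambda1 = lambda1,
                 lambda2 = lambda2, batch_size = as.integer(batch_size),
                 optimizer = optimizer, sample = isTRUE(sample),
                 lr_schedule = lr_schedule,
                 seed = as.integer(seed)), class = "training_config")
}

#' Train a DMVAE on one fold's training split
#'
#' Runs minibatch gradient descent on the 11-term objective, evaluates the
#' objective on the validation split after every epoch with posterior
#' means (no sampling), and returns the parameter snapshot from the epoch
#' with the lowest validation total.
#'
#' @param x_a,x_b Feature matrices over all subjects (rows aligned).
#' @param split List with integer (or rowname) vectors `train` and `val`;
#'   a `test` element is carried through untouched.
#' @param config A [training_config()].
#' @param model Optional pre-built [dmvae_model()]; built from `...` when
#'   absent.
#' @param ... Passed to [dmvae_model()] when `model` is `NULL`
#'   (`d_pr1`, `d_sh`, `d_pr2`, `hidden_a`, `hidden_b`).
#' @return A list of class `dmvae_fit`: `model` (best-validation snapshot,
#'   `trained = TRUE`), `log` (tibble: epoch, train_total, val_total and
#'   the 11 validation terms), `best_epoch`, `split`, `config`.
#' @export
train_fold <- function(x_a, x_b, split, config = training_config(),
                       model = NULL, ...) {
  stopifnot(inherits(config, "training_config"))
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  abort_if(nrow(x_a) != nrow(x_b), "modalities must cover the same subjects")
  resolve <- function(idx) {
    if (is.character(idx)) match(idx, rownames(x_a)) else as.integer(idx)
  }
  tr <- resolve(split$train); va <- resolve(split$val)
  abort_if(length(tr) < 1 || length(va) < 1, "empty train or validation split")
  abort_if(anyNA(tr) || anyNA(va), "split ids not found in feature rows")
  abort_if(length(intersect(tr, va)) > 0, "train and validation overlap")

  if (is.null(model)) {
    model <- dmvae_model(ncol(x_a), ncol(x_b), ...,
                         seed = derive_seed(config$seed, "init"))
  }
  dims <- model$dims
  params <- model$params
  state <- adam_init(params)

  val_eps <- make_eps(length(va), dims, FALSE)
  eval_val <- function(p) {
    dmvae_forward(p, dims, x_a[va, , drop = FALSE], x_b[va, , drop = FALSE],
                  config$lambda1, config$lambda2, val_eps)
  }

  log_rows <- vector("list", config$epochs)
  best <- list(val = Inf, params = params, epoch = 0L)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr_epoch <- if (identical(config$lr_schedule, "cosine")) {
        config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
      } else {
        config$lr
      }
      perm <- sample(tr)
      starts <- seq(1, length(perm), by = config$batch_size)
      train_tot <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1, length(perm))]
        eps <- make_eps(length(idx), dims, config$sample)
        fw <- dmvae_forward(params, dims,
                            x_a[idx, , drop = FALSE],
                            x_b[idx, , drop = FALSE],
                            config$lambda1, config$lambda2, eps)
        gr <- dmvae_backward(params, dims, fw)
        upd <- adam_step(params, gr, state, lr_epoch)
        params <- upd$params
        state <- upd$state
        train_tot <- train_tot + fw$total * length(idx)
      }
      vfw <- eval_val(params)
      if (vfw$total < best$val) {
        best <- list(val = vfw$total, params = params, epoch = epoch)
      }
      log_rows[[epoch]] <- c(epoch = epoch,
                             train_total = train_tot / length(tr),
                             val_total = vfw$total, vfw$terms)
    }
  })

  log <- tibble::as_tibble(do.call(rbind, log_rows))
  model$params <- best$params
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  structure(list(model = model, log = log, best_epoch = best$epoch,
                 best_val = best$val, split = split, config = config),
            class = "dmvae_fit")
}

#' @export
print.dmvae_fit <- function(x, ...) {
  cat(sprintf(
    "<dmvae_fit> %d epoch(s); best validation %.6g at epoch %d\n",
    nrow(x$log), x$best_val, x$best_epoch
  ))
  invisible(x)
}

#' Cross-generate the missing modality from the one that is present
#'
#' Encodes the present modality, takes the mean of its shared posterior,
#' and decodes the other modality from the prior mean of its private block
#' (zeros) concatenated with that shared mean. Evaluation is sample-free,
#' so repeated calls are bitwise identical.
#'
#' @param model A trained [dmvae_model()].
#' @param x Feature matrix of the present modality.
#' @param direction `"a->b"` or `"b->a"`.
#' @return Decoded feature matrix of the missing modality.
#' @export
cross_reconstruct <- function(model, x, direction = c("a->b", "b->a")) {
  stopifnot(inherits(model, "dmvae"))
  direction <- match.arg(direction)
  abort_if(!isTRUE(model$trained),
           "model is untrained; call train_fold() first")
  present <- if (direction == "a->b") "a" else "b"
  target <- if (direction == "a->b") "b" else "a"
  post <- encode(model, x, side = present)
  sh <- as.matrix(post$shared$mean)
  d_pr <- if (target == "a") model$dims$d_pr1 else model$dims$d_pr2
  decode(model, matrix(0, nrow(sh), d_pr), sh, side = target)
}

# Finite-difference verification of the analytic gradient on a model;
# returns the maximum relative deviation over all parameters.
grad_check <- function(model, x_a, x_b, lambda1 = 1, lambda2 = 1,
                       sample = TRUE, seed = 7, h = 1e-5) {
  dims <- model$dims
  eps <- with_seed(seed, make_eps(nrow(x_a), dims, sample))
  fw <- dmvae_forward(model$params, dims, x_a, x_b, lambda1, lambda2, eps)
  g <- nl_flatten(dmvae_backward(model$params, dims, fw))
  theta <- nl_flatten(model$params)
  num <- numeric(length(theta))
  f <- function(th) {
    p <- nl_unflatten(model$params, th)
    dmvae_forward(p, dims, x_a, x_b, lambda1, lambda2, eps)$total
  }
  for (i in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    num[i] <- (f(tp) - f(tm)) / (2 * h)
  }
  max(abs(num - g)) / max(1, max(abs(num)))
}
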