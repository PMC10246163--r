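# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; no data files.

# Small default-condition synthetic cohort for structural tests.
tiny_cohort <- function(n = 40, seed = 101, ...) {
  generate_cohort(synthetic_config(n_subjects = n, seed = seed, ...))
}

# The study conditions used by the simulation-based checks: modest latent
# truth (3/6/3), moderate noise, strong shared coupling.
study_config <- function(n = 150, seed = 1, shared_strength = 1.5, ...) {
  synthetic_config(n_subjects = n, d_pr1 = 3, d_sh = 6, d_pr2 = 3,
                   noise_sd = 0.3, shared_strength = shared_strength,
                   seed = seed, ...)
}

study_model_args <- list(d_pr1 = 4, d_sh = 8, d_pr2 = 4,
                         hidden_a = 24, hidden_b = 24)

# Train one model on fold `f` of a cohort and return fit + features.
fit_study_fold <- function(cohort, plan, f, epochs, lr = 5e-3,
                           lr_schedule = "constant", seed = 1) {
  pf <- chromafuse:::prepare_fold_features(cohort, plan$folds[[f]],
                                           list(mean_scope_a = "dataset"))
  tc <- training_config(epochs = epochs, lr = lr, batch_size = 32,
                        lr_schedule = lr_schedule, seed = seed)
  fit <- do.call(train_fold, c(
    list(pf$a, pf$b, split = plan$folds[[f]], config = tc),
    study_model_args
  ))
  list(fit = fit, features = pf)
}

# All permutations of 1..n (n small), one per row.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# Brute-force optimum of a square assignment problem (minimization).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  p <- all_perms(n)
  vals <- apply(p, 1, function(pp) sum(cost[cbind(seq_len(n), pp)]))
  min(vals)
}

# Numeric-grid product of two 1-d Gaussian densities, renormalized;
# returns moments. Independent oracle for the product-of-experts fusion.
grid_gaussian_product <- function(mu1, v1, mu2, v2, width = 12, n = 40001) {
  lo <- min(mu1 - width * sqrt(v1), mu2 - width * sqrt(v2))
  hi <- max(mu1 + width * sqrt(v1), mu2 + width * sqrt(v2))
  x <- seq(lo, hi, length.out = n)
  dens <- stats::dnorm(x, mu1, sqrt(v1)) * stats::dnorm(x, mu2, sqrt(v2))
  dens <- dens / sum(dens)
  m <- sum(x * dens)
  list(mean = m, var = sum((x - m)^2 * dens))
}

# Scalar re-implementation of the 11-term objective for a 1-d-per-block
# linear model with no hidden layers; written independently of the
# package's matrix code path.
scalar_dmvae_loss <- function(params, xa, xb, eps, lambda1, lambda2) {
  lin <- function(w, b, x) sum(w * x) + b
  # encoder a: input scalar -> (mu_pr, mu_sh, lv_pr, lv_sh)
  ea <- vapply(1:4, function(j) lin(params$enc_a$W[[1]][, j],
                                    params$enc_a$b[[1]][j], xa), numeric(1))
  eb <- vapply(1:4, function(j) lin(params$enc_b$W[[1]][, j],
                                    params$enc_b$b[[1]][j], xb), numeric(1))
  mu <- list(pr1 = ea[1], sh1 = ea[2], pr2 = eb[1], sh2 = eb[2])
  v <- list(pr1 = exp(ea[3]), sh1 = exp(ea[4]),
            pr2 = exp(eb[3]), sh2 = exp(eb[4]))
  vp <- 1 / (1 / v$sh1 + 1 / v$sh2)
  mup <- vp * (mu$sh1 / v$sh1 + mu$sh2 / v$sh2)
  z <- list(pr1 = mu$pr1 + sqrt(v$pr1) * eps$pr1[1, 1],
            sh1 = mu$sh1 + sqrt(v$sh1) * eps$sh1[1, 1],
            pr2 = mu$pr2 + sqrt(v$pr2) * eps$pr2[1, 1],
            sh2 = mu$sh2 + sqrt(v$sh2) * eps$sh2[1, 1],
            shp = mup + sqrt(vp) * eps$shp[1, 1])
  kl1 <- function(m, vv) 0.5 * (m^2 + vv - log(vv) - 1)
  dec <- function(p, zp, zs) p$W[[1]][1, 1] * zp + p$W[[1]][2, 1] * zs +
    p$b[[1]][1]
  r <- function(hat, x) 0.5 * (hat - x)^2
  kls <- kl1(mu$pr1, v$pr1) + kl1(mu$sh1, v$sh1) + kl1(mu$pr2, v$pr2) +
    kl1(mu$sh2, v$sh2) + kl1(mup, vp)
  ra <- r(dec(params$dec_a, z$pr1, z$sh1), xa) +
    r(dec(params$dec_a, z$pr1, z$shp), xa) +
    r(dec(params$dec_a, z$pr1, z$sh2), xa)
  rb <- r(dec(params$dec_b, z$pr2, z$sh2), xb) +
    r(dec(params$dec_b, z$pr2, z$shp), xb) +
    r(dec(params$dec_b, z$pr2, z$sh1), xb)
  kls + lambda1 * ra + lambda2 * rb
}

# Relabel-invariant agreement between two partitions (1 = identical).
partition_agreement <- function(a, b) {
  ta <- table(a, b)
  sum(apply(ta, 1, max)) / length(a)
}
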