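test_that("identical configurations regenerate bit-identical cohorts", {
  a <- generate_cohort(synthetic_config(n_subjects = 30, seed = 11))
  b <- generate_cohort(synthetic_config(n_subjects = 30, seed = 11))
  expect_identical(a$cohort$a$values, b$cohort$a$values)
  expect_identical(a$cohort$b$values, b$cohort$b$values)
  expect_identical(a$cohort$metadata, b$cohort$metadata)
  expect_identical(a$latents$shared, b$latents$shared)
  c2 <- generate_cohort(synthetic_config(n_subjects = 30, seed = 12))
  expect_false(identical(a$cohort$a$values, c2$cohort$a$values))
})

test_that("metadata proportions match the configured cohort profile", {
  for (n in c(60, 278)) {
    sim <- generate_cohort(synthetic_config(n_subjects = n, seed = 3))
    md <- sim$cohort$metadata
    expect_lte(abs(sum(md$diagnosis == "SZ") - n * 0.4928), 1)
    expect_lte(abs(sum(md$sex == "F") - n * 0.2554), 1)
    expect_setequal(unique(md$site), sprintf("site%02d", 1:7))
  }
})

test_that("zero-noise linear mixing is an exact linear function of latents", {
  sim <- generate_cohort(synthetic_config(n_subjects = 50, noise_sd = 0,
                                          mixing = "linear", seed = 21))
  lat <- sim$latents
  load_a <- cbind(lat$private_a, lat$shared)
  # least-squares refit of the mixing must reproduce the arrays exactly
  fit <- lm.fit(load_a, sim$cohort$a$values)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  load_b <- cbind(lat$private_b, lat$shared)
  fit_b <- lm.fit(load_b, sim$cohort$b$values)
  expect_lt(max(abs(fit_b$residuals)), 1e-9)
})

test_that("mild-nonlinear mixing is the elementwise tanh of the linear one", {
  cfgl <- synthetic_config(n_subjects = 20, noise_sd = 0, seed = 5,
                           mixing = "linear")
  cfgn <- synthetic_config(n_subjects = 20, noise_sd = 0, seed = 5,
                           mixing = "mild-nonlinear")
  a <- generate_cohort(cfgl)$cohort$a$values
  b <- generate_cohort(cfgn)$cohort$a$values
  expect_equal(b, tanh(a), tolerance = 1e-12)
})

test_that("residual variance about the noiseless signal matches noise_sd^2", {
  sd0 <- 0.4
  sim <- generate_cohort(synthetic_config(n_subjects = 500, noise_sd = sd0,
                                          seed = 9))
  sig <- cohort_signal(sim$cohort)
  res_a <- sim$cohort$a$values - sig$a
  res_b <- sim$cohort$b$values - sig$b
  expect_lt(abs(mean(res_a^2) / sd0^2 - 1), 0.05)
  expect_lt(abs(mean(res_b^2) / sd0^2 - 1), 0.05)
})

test_that("connectivity matrices are symmetric", {
  sim <- generate_cohort(synthetic_config(n_subjects = 10, seed = 2))
  m <- matrix(sim$cohort$b$values[3, ], 10, 10)
  expect_lt(max(abs(m - t(m))), 1e-6)
})

test_that("shared factors couple the modalities (CCA oracle)", {
  sim <- generate_cohort(synthetic_config(n_subjects = 200, noise_sd = 0.1,
                                          seed = 13))
  # brute-force CCA on the raw arrays after projecting onto the known
  # ground-truth mixing directions of the shared block
  cfg <- sim$cohort$generator$config
  sh_a <- sim$cohort$a$values %*% t(sim$cohort$generator$bases_a[
    cfg$d_pr1 + seq_len(cfg$d_sh), , drop = FALSE])
  sh_b <- sim$cohort$b$values %*% t(sim$cohort$generator$bases_b[
    cfg$d_pr2 + seq_len(cfg$d_sh), , drop = FALSE])
  cc <- stats::cancor(sh_a, sh_b)
  expect_gte(cc$cor[1], 0.9)
})

test_that("plant_subgroup with zero shift is a bitwise no-op", {
  sim <- generate_cohort(synthetic_config(n_subjects = 30, seed = 7))
  shifted <- plant_subgroup(sim$cohort, "sh", 0)
  expect_identical(shifted$a$values, sim$cohort$a$values)
  expect_identical(shifted$b$values, sim$cohort$b$values)
})

test_that("a private-A shift never touches modality B", {
  sim <- generate_cohort(synthetic_config(n_subjects = 30, seed = 7))
  shifted <- plant_subgroup(sim$cohort, "pr1", 2.5)
  expect_identical(shifted$b$values, sim$cohort$b$values)
  expect_false(identical(shifted$a$values, sim$cohort$a$values))
})

test_that("a planted shared shift is recovered from the ground truth", {
  sim <- generate_cohort(synthetic_config(n_subjects = 200, seed = 31))
  shifted <- plant_subgroup(sim$cohort, "sh", 3)
  lat <- ground_truth(shifted)
  pat <- shifted$metadata$diagnosis == "SZ"
  for (j in seq_len(ncol(lat$shared))) {
    d <- mean(lat$shared[pat, j]) - mean(lat$shared[!pat, j])
    se <- sqrt(stats::var(lat$shared[pat, j]) / sum(pat) +
                 stats::var(lat$shared[!pat, j]) / sum(!pat))
    expect_lt(abs(d - 3), 2 * se)
  }
  expect_equal(lat$diagnosis_shift[["sh"]], 3)
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(n_subjects = 1), "n_subjects")
  expect_error(synthetic_config(patient_fraction = 1.2), "patient_fraction")
  expect_error(synthetic_config(d_sh = 0), "latent sizes")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  sim <- generate_cohort(synthetic_config(n_subjects = 20, seed = 1))
  expect_error(plant_subgroup(sim$cohort, "pr1", 1, dims = 99), "dims")
  expect_error(plant_subgroup(sim$cohort, "xx", 1))
})
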