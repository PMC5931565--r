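test_that("REML estimates agree with an independent mixed-model implementation", {
  pl_cfg <- cfg_unit(n = 250, q = 2)
  sim <- simulate_dataset(pl_cfg, seed = 12)
  gd <- assemble_longitudinal(sim$pheno, covariates = c("cov1", "cov2"))
  fit <- fit_variance_components(gd)

  df <- sim$pheno
  df$id <- factor(df$id)
  ref <- nlme::lme(y ~ time + cov1 + cov2, random = ~ 1 + time | id,
                   data = df, method = "REML")
  Dref <- nlme::getVarCov(ref)
  s2ref <- ref$sigma^2

  expect_equal(unname(fit$vc$D), unname(matrix(as.numeric(Dref), 2, 2)),
               tolerance = 1e-4)
  expect_equal(fit$vc$sigma2, s2ref, tolerance = 1e-4)
  expect_equal(unname(fit$reduced$beta_star), unname(nlme::fixef(ref)),
               tolerance = 1e-4)
})

test_that("our whitened reduced solve reproduces lme4's fixed and random effects", {
  pl <- make_pipeline(cfg_unit(n = 180), seed = 13)
  expect_equal(unname(pl$fit$reduced$beta_star),
               unname(lme4::fixef(pl$fit$lmer_fit)), tolerance = 1e-9)
  re <- lme4::ranef(pl$fit$lmer_fit)$.id
  expect_equal(unname(pl$fit$reduced$b_star),
               unname(as.matrix(re)), tolerance = 1e-6)
})

test_that("noise-free data with jitter recover the generating coefficients", {
  cfg <- sim_config(n = 60, k = 4, q = 2, sigma = 0, D = matrix(0, 2, 2),
                    beta_cov = c(0.7, -1.1))
  sim <- simulate_dataset(cfg, seed = 14)
  set.seed(15)
  sim$pheno$y <- sim$pheno$y + rnorm(nrow(sim$pheno), 0, 1e-6)
  gd <- assemble_longitudinal(sim$pheno, covariates = c("cov1", "cov2"))
  fit <- fit_variance_components(gd)

  expect_true(fit$vc$singular)             # D at the boundary, flagged
  expect_equal(unname(fit$reduced$beta_star),
               c(cfg$beta0, cfg$beta1, cfg$beta_cov), tolerance = 1e-6)
  expect_equal(fit$vc$sigma, 1e-6, tolerance = 0.3)  # jitter SD recovered
  expect_error(gallop_precompute(gd, fit), "singular")
})

test_that("transformed and untransformed reduced solves coincide", {
  # beta* from the whitened system vs the raw Henderson system
  pl <- make_pipeline(cfg_unit(n = 120), seed = 16)
  h <- henderson_solve(pl$gd$y, pl$gd$X, pl$gd$t, pl$gd$subject,
                       pl$fit$vc$P_star, weights = pl$gd$w)
  expect_equal(pl$fit$reduced$beta_star, h$beta, tolerance = 1e-8)
  expect_equal(unname(pl$fit$reduced$b_star), unname(h$b), tolerance = 1e-8)
})

test_that("omitted SNP effects inflate D as predicted", {
  expect_equal(variance_inflation(diag(2), 0, 0, 0.5), diag(2))
  D <- matrix(c(1, -0.2, -0.2, 1), 2, 2)
  expect_equal(variance_inflation(D, 1, 0, 0.5),
               matrix(c(1.5, -0.2, -0.2, 1), 2, 2))
  # simulation check: fit the reduced model to data with a real SNP effect
  cfg <- sim_config(n = 8000)
  sim <- simulate_dataset(cfg, beta2 = 0.8, beta3 = 0.8, seed = 17)
  gd <- assemble_longitudinal(sim$pheno, covariates = paste0("cov", 1:3))
  fit <- fit_variance_components(gd, keep_fit = FALSE)
  Dstar <- variance_inflation(cfg$D, 0.8, 0.8, var(sim$dosage[, 1]))
  expect_lt(max(abs(fit$vc$D - Dstar)), 0.3)  # Monte-Carlo noise in d11 dominates
  expect_gt(fit$vc$D[1, 1], cfg$D[1, 1])   # genuinely inflated, not just close
  expect_gt(fit$vc$D[2, 2], cfg$D[2, 2])
})
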