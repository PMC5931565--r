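test_that("predictive R^2 behaves at its fixed points", {
  y <- rnorm(50)
  expect_equal(compute_r2(y, rep(mean(y), 50)), 0)
  expect_equal(compute_r2(y, y), 1)
  expect_error(compute_r2(rep(1, 10), rnorm(10)), "constant")
  expect_error(compute_r2(y, y[-1]), "length")
})

test_that("threshold calibration returns the smallest captured -log10 p", {
  mk <- function(refit_mlp, gallop_mlp) {
    data.frame(p_cs = 10^(-gallop_mlp), p_long = 1,
               refit_p_cs = 10^(-refit_mlp), refit_p_long = 1)
  }
  # identical p-values: tau is the smallest refit value above the cut
  r <- mk(c(6, 7, 7.4, 8, 9), c(6, 7, 7.4, 8, 9))
  expect_equal(threshold_calibration(r, 7.3), 7.4)
  # uniformly conservative fast path: tau drops below the cut
  r2 <- mk(c(6, 7, 7.4, 8, 9), c(6, 7, 7.4, 8, 9) - 0.3)
  expect_equal(threshold_calibration(r2, 7.3), 7.1)
  expect_lt(threshold_calibration(r2, 7.3), 7.3)
  # nothing exceeds the cut: undefined, flagged
  expect_warning(tau <- threshold_calibration(mk(5, 5), 7.3), "undefined")
  expect_true(is.na(tau))
})

test_that("at a truly null SNP the fast and refit p-values agree to 0.01 in -log10 p", {
  # with no SNP effect the reduced and full REML fits differ only through
  # two extra fixed-effect parameters, so the fixed-variance approximation
  # is essentially exact
  cfg <- sim_config()   # n = 2000, the full study configuration
  sim <- simulate_dataset(cfg, beta2 = 0, beta3 = 0, seed = 110)
  gd <- assemble_longitudinal(sim$pheno, covariates = paste0("cov", 1:3))
  fit <- fit_variance_components(gd, keep_fit = FALSE)
  sc <- gallop_score(gallop_precompute(gd, fit), sim$dosage[, 1])
  rf <- gallop:::refit_snp_lmer(sim$pheno, sim$dosage[, 1],
                                covariates = paste0("cov", 1:3))
  expect_lt(abs(log10(sc$p_cs) - log10(rf$p2)), 0.01)
  expect_lt(abs(log10(sc$p_long) - log10(rf$p3)), 0.01)
})

test_that("a small accuracy study pairs fast and refit results coherently", {
  cfg <- cfg_unit(n = 150)
  rep6 <- run_accuracy_study(cfg, n_replicates = 6, seed = 107)
  expect_s3_class(rep6, "gallop_accuracy")
  expect_equal(nrow(rep6), 6)
  expect_setequal(round(sort(rep6$beta2_true), 6), round(seq(0, 1, length.out = 6), 6))
  expect_true(all(rep6$refit_ok))
  # estimates from the two routes track each other
  expect_lt(max(abs(rep6$beta_cs - rep6$refit_beta_cs)), 0.1)
  expect_lt(max(abs(rep6$beta_long - rep6$refit_beta_long)), 0.05)
  # fixed-variance SEs are never materially below the refit SEs
  expect_true(all(rep6$se_cs >= rep6$refit_se_cs * 0.99))
  expect_true(all(rep6$se_long >= rep6$refit_se_long * 0.99))
  # the SNP adds explanatory power up to BLUP-shrinkage noise (the reduced
  # model's random effects absorb most of a subject-constant SNP effect)
  expect_true(all(rep6$r2_full - rep6$r2_reduced > -0.01))
  # reproducible from the stored seed
  rep6b <- run_accuracy_study(cfg, n_replicates = 6, seed = 107)
  expect_equal(rep6$p_long, rep6b$p_long)
})
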