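test_that("bordered fast path equals the exact Henderson solve per SNP", {
  pl <- make_pipeline(cfg_unit(n = 200), beta2 = 0.3, beta3 = 0.15, m = 20, seed = 21)
  sc <- gallop_score(pl$pc, pl$sim$dosage)
  expect_true(all(sc$status == "ok"))
  expect_lt(max(oracle_rel_diff(pl$gd, pl$fit, sc, pl$sim$dosage)), 1e-8)
})

test_that("precompute core matrix reproduces the reduced-system solution", {
  pl <- make_pipeline(cfg_unit(n = 120), seed = 22)
  # A11 for a no-covariate dataset is the matrix of raw sums
  cfg0 <- cfg_unit(n = 4, q = 0)
  sim0 <- simulate_dataset(cfg0, seed = 23)
  gd0 <- assemble_longitudinal(sim0$pheno)
  bl <- gallop:::subject_blocks(gd0)
  expect_equal(unname(bl$A11),
               matrix(c(gd0$N, sum(gd0$t), sum(gd0$t), sum(gd0$t^2)), 2, 2))
  # M-factorized reduced solve equals the Henderson solve on X*
  h <- henderson_solve(pl$gd$y, pl$gd$X, pl$gd$t, pl$gd$subject,
                       pl$fit$vc$P_star, weights = pl$gd$w)
  expect_equal(pl$pc$beta_star, h$beta, tolerance = 1e-8)
})

test_that("blocked scoring is bit-comparable to one-at-a-time scoring", {
  pl <- make_pipeline(cfg_unit(n = 150), m = 100, seed = 24)
  block <- gallop_score(pl$pc, pl$sim$dosage)
  singles <- do.call(rbind, lapply(seq_len(100), function(j)
    gallop_score(pl$pc, pl$sim$dosage[, j, drop = FALSE],
                 snp_ids = colnames(pl$sim$dosage)[j])))
  for (col in c("beta_cs", "beta_long", "se_cs", "se_long"))
    expect_lt(max(abs(block[[col]] - singles[[col]])), 1e-12)
  # and both match the slow per-subject reference path
  rf <- gallop:::score_snp_ref(pl$pc, pl$sim$dosage[, 7])
  expect_equal(block$beta_cs[7], rf$beta2, tolerance = 1e-12)
  expect_equal(block$se_long[7], rf$se3, tolerance = 1e-12)
})

test_that("results are invariant to subject permutation", {
  cfg <- cfg_unit(n = 80)
  sim <- simulate_dataset(cfg, beta2 = 0.5, beta3 = 0.2, m = 5, seed = 25)
  covs <- paste0("cov", 1:3)

  run <- function(pheno, G) {
    gd <- assemble_longitudinal(pheno, covariates = covs)
    fit <- fit_variance_components(gd, keep_fit = FALSE)
    gallop_score(gallop_precompute(gd, fit), G[gd$subj_ids, , drop = FALSE])
  }
  r1 <- run(sim$pheno, sim$dosage)
  set.seed(26)
  perm <- sample(unique(sim$pheno$id))
  pheno2 <- sim$pheno[order(match(sim$pheno$id, perm)), ]
  r2 <- run(pheno2, sim$dosage)
  expect_equal(r1$beta_cs, r2$beta_cs, tolerance = 1e-9)
  expect_equal(r1$p_long, r2$p_long, tolerance = 1e-9)
})

test_that("reflecting dosages (s -> 2 - s) flips effect signs, SEs unchanged", {
  pl <- make_pipeline(cfg_unit(n = 150), beta2 = 0.4, beta3 = 0.3, m = 8, seed = 27)
  a <- gallop_score(pl$pc, pl$sim$dosage)
  b <- gallop_score(pl$pc, 2 - pl$sim$dosage)
  expect_equal(a$beta_cs, -b$beta_cs, tolerance = 1e-9)
  expect_equal(a$beta_long, -b$beta_long, tolerance = 1e-9)
  expect_equal(a$se_cs, b$se_cs, tolerance = 1e-9)
  expect_equal(a$se_long, b$se_long, tolerance = 1e-9)
})

test_that("degenerate SNPs are flagged, not scored", {
  pl <- make_pipeline(cfg_unit(n = 100), m = 2, seed = 28)
  G <- cbind(zero = rep(0, 100), const = rep(1.3, 100), ok = pl$sim$dosage[, 1])
  sc <- gallop_score(pl$pc, G)
  expect_equal(sc$status, c("monomorphic", "monomorphic", "ok"))
  expect_true(all(is.na(sc$beta_cs[1:2])))
  expect_true(all(is.na(sc$p_long[1:2])))
  expect_false(is.na(sc$beta_cs[3]))
})

test_that("missing dosages: mean imputation equals scoring the imputed vector", {
  pl <- make_pipeline(cfg_unit(n = 100), m = 3, seed = 29)
  G <- pl$sim$dosage
  G[c(4, 9), 2] <- NA
  sc <- gallop_score(pl$pc, G, dosage_missing = "mean_impute")
  expect_equal(sc$status, c("ok", "imputed", "ok"))
  expect_equal(sc$n_used, rep(100L, 3))    # imputation keeps every subject

  s_imp <- G[, 2]
  s_imp[is.na(s_imp)] <- mean(G[, 2], na.rm = TRUE)
  ex <- score_snp_exact(pl$gd, pl$fit, s_imp)
  expect_equal(sc$beta_cs[2], ex$beta2, tolerance = 1e-8)
  expect_equal(sc$se_long[2], ex$se3, tolerance = 1e-8)

  skp <- gallop_score(pl$pc, G, dosage_missing = "skip")
  expect_equal(skp$status[2], "skipped")
  expect_true(is.na(skp$beta_cs[2]))

  G[, 3] <- NA                             # nothing observed at all
  sc3 <- gallop_score(pl$pc, G)
  expect_equal(sc3$status[3], "skipped")
  expect_equal(sc3$n_used[3], 0L)
})

test_that("Wald statistics and p-values follow the standard normal", {
  wp <- wald_pvalues(0, 1)
  expect_equal(wp$z, 0)
  expect_equal(wp$p, 1)
  expect_equal(wald_pvalues(1.959964, 1)$p, 0.05, tolerance = 1e-6)
  expect_error(wald_pvalues(1, -1), "positive")
})
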