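# Small, well-identified configurations for unit tests. With the default
# residual SD (2.5) and the intercept sitting at the edge of the (0, 10)
# time window, the random-intercept variance is weakly identified below a
# few hundred subjects; sigma = 1 keeps small-n REML fits off the boundary
# so unit tests exercise the regular code path. Acceptance tests use the
# default configuration at n >= 500, where this is not an issue.
cfg_unit <- function(n = 150, ...) sim_config(n = n, sigma = 1, ...)

# simulate + assemble + fit + precompute in one go
make_pipeline <- function(cfg, beta2 = 0, beta3 = 0, m = 1, seed = NULL) {
  sim <- simulate_dataset(cfg, beta2 = beta2, beta3 = beta3, m = m, seed = seed)
  covs <- if (cfg$q) paste0("cov", seq_len(cfg$q)) else character(0)
  gd <- assemble_longitudinal(sim$pheno, covariates = covs)
  fit <- fit_variance_components(gd)
  pc <- gallop_precompute(gd, fit)
  list(sim = sim, gd = gd, fit = fit, pc = pc, covs = covs)
}

# max relative difference between fast-path results and the exact solver
oracle_rel_diff <- function(gd, fit, sc, G) {
  vapply(seq_len(ncol(G)), function(j) {
    e <- score_snp_exact(gd, fit, G[, j])
    got <- c(sc$beta_cs[j], sc$beta_long[j], sc$se_cs[j], sc$se_long[j])
    ref <- c(e$beta2, e$beta3, e$se2, e$se3)
    max(abs(got - ref) / pmax(abs(ref), 1e-12))
  }, numeric(1))
}

as_2x2 <- function(row3) matrix(c(row3[1], row3[2], row3[2], row3[3]), 2, 2)
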