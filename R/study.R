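#' Accuracy study: fast bordered scores versus full per-SNP REML refits
#'
#' Simulates `n_replicates` longitudinal datasets, one causal SNP each, with
#' main and interaction effects taking independently permuted values on an
#' equally spaced grid over `cfg$effect_range`. Each dataset is scored twice:
#' with the fast bordered solve at the reduced-model variance components, and
#' (optionally) with a full REML refit of the SNP model via [lme4::lmer()]
#' using normal Wald p-values — the exact-but-slow comparator. Predictive
#' `R^2 = 1 - ||y - yhat||^2 / ||y - ybar||^2` is recorded for the full and
#' reduced fits in two variants: marginal (population-level fitted values
#' `X beta_hat`, the GWAS notion of variance explained, under which the SNP
#' contribution is `r2_full - r2_reduced`) and conditional (fitted values
#' including the random effects; the reduced model's BLUPs absorb most of a
#' subject-constant SNP effect, so that difference is near zero). The
#' reduced-model variance-component estimates of every replicate are kept.
#'
#' @param cfg a [sim_config]; the grid length is taken from `n_replicates`.
#' @param n_replicates number of simulated datasets (= grid points).
#' @param refit run the per-SNP REML refit comparator (default `TRUE`).
#' @param seed seed for the whole study (one stream).
#' @return data.frame of class `gallop_accuracy`, one row per replicate:
#'   true effects, fast estimates/SEs/p-values, refit estimates/SEs/p-values,
#'   `r2_full`/`r2_reduced` (marginal), `r2_full_cond`/`r2_reduced_cond`
#'   (conditional), and reduced-fit `d11, d12, d22, sigma_hat`.
#' @export
run_accuracy_study <- function(cfg, n_replicates = 200, refit = TRUE, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 2)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(cfg$effect_range[1], cfg$effect_range[2], length.out = n_replicates)
  b2_true <- sample(grid)
  b3_true <- sample(grid)

  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    sim <- simulate_dataset(cfg, beta2 = b2_true[i], beta3 = b3_true[i])
    gd <- assemble_longitudinal(sim$pheno, covariates = colnames(sim$pheno)[-(1:3)])
    fit <- fit_variance_components(gd, keep_fit = TRUE)
    pc <- gallop_precompute(gd, fit)
    sc <- gallop_score(pc, sim$dosage[, 1])

    out <- data.frame(
      rep = i, beta2_true = b2_true[i], beta3_true = b3_true[i],
      beta_cs = sc$beta_cs, se_cs = sc$se_cs, p_cs = sc$p_cs,
      beta_long = sc$beta_long, se_long = sc$se_long, p_long = sc$p_long,
      d11 = fit$vc$D[1, 1], d12 = fit$vc$D[1, 2], d22 = fit$vc$D[2, 2],
      sigma_hat = fit$vc$sigma,
      refit_beta_cs = NA_real_, refit_se_cs = NA_real_, refit_p_cs = NA_real_,
      refit_beta_long = NA_real_, refit_se_long = NA_real_, refit_p_long = NA_real_,
      r2_full = NA_real_, r2_reduced = NA_real_,
      r2_full_cond = NA_real_, r2_reduced_cond = NA_real_, refit_ok = NA
    )

    if (refit) {
      rf <- refit_snp_lmer(sim$pheno, sim$dosage[, 1],
                           covariates = colnames(sim$pheno)[-(1:3)])
      out$refit_beta_cs <- rf$beta2; out$refit_se_cs <- rf$se2; out$refit_p_cs <- rf$p2
      out$refit_beta_long <- rf$beta3; out$refit_se_long <- rf$se3; out$refit_p_long <- rf$p3
      out$refit_ok <- rf$converged
      yred <- gd$y[gd$w > 0]
      Xred <- model.matrix(fit$lmer_fit)
      out$r2_full <- compute_r2(rf$y, rf$fitted_marginal)
      out$r2_reduced <- compute_r2(yred, drop(Xred %*% lme4::fixef(fit$lmer_fit)))
      out$r2_full_cond <- compute_r2(rf$y, rf$fitted)
      out$r2_reduced_cond <- compute_r2(yred, fitted(fit$lmer_fit))
    }
    rows[[i]] <- out
  }
  report <- do.call(rbind, rows)
  attr(report, "cfg") <- cfg
  attr(report, "seed") <- seed
  attr(report, "comparator") <- "lme4::lmer REML refit, normal Wald p-values"
  class(report) <- c("gallop_accuracy", class(report))
  report
}

# Full-model per-SNP REML refit: the exact comparator. Returns normal-Wald
# p-values for the SNP main and interaction effects plus fitted values
# (including random effects) for R^2 accounting.
refit_snp_lmer <- function(pheno, s, covariates = character(0),
                           id = "id", time = "time", outcome = "y") {
  df <- pheno[!is.na(pheno[[outcome]]), , drop = FALSE]
  snames <- if (!is.null(names(s))) names(s) else unique(pheno[[id]])
  df$.s <- s[match(df[[id]], snames)]
  df$.t <- df[[time]]; df$.y <- df[[outcome]]; df$.id <- factor(df[[id]])
  fml <- as.formula(paste(".y ~ .t + .s + .t:.s",
                          if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else "",
                          "+ (1 + .t | .id)"))
  msgs <- character(0)
  quiet_lmer <- function(...) withCallingHandlers(
    lme4::lmer(fml, data = df, REML = TRUE, control = lme4::lmerControl(...)),
    warning = function(w) { msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning") },
    message = function(m) { msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage") }
  )
  fit <- quiet_lmer(calc.derivs = FALSE)
  if (near_boundary(fit)) {      # same false-optimum guard as the reduced fit
    fit2 <- quiet_lmer(optimizer = "bobyqa", calc.derivs = FALSE)
    if (lme4::REMLcrit(fit2) < lme4::REMLcrit(fit)) fit <- fit2
  }
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  j2 <- which(names(fe) == ".s"); j3 <- which(names(fe) == ".t:.s")
  z2 <- fe[j2] / se[j2]; z3 <- fe[j3] / se[j3]
  list(beta2 = unname(fe[j2]), se2 = unname(se[j2]), p2 = 2 * pnorm(-abs(unname(z2))),
       beta3 = unname(fe[j3]), se3 = unname(se[j3]), p3 = 2 * pnorm(-abs(unname(z3))),
       converged = length(msgs) == 0, y = df$.y, fitted = fitted(fit),
       fitted_marginal = drop(model.matrix(fit) %*% fe))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predictive R-squared
#'
#' `R^2 = 1 - ||y - yhat||^2 / ||y - ybar||^2`, a simple goodness-of-fit
#' ratio used to quantify the contribution of SNP effects as
#' `R^2(full) - R^2(reduced)`.
#'
#' @param y observed outcomes; @param fitted fitted values, same length.
#' @return scalar.
#' @export
compute_r2 <- function(y, fitted) {
  stopifnot(length(y) == length(fitted))
  ok <- !is.na(y) & !is.na(fitted)
  y <- y[ok]; fitted <- fitted[ok]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant outcome: R^2 undefined")
  1 - sum((y - fitted)^2) / sst
}

#' Significance threshold needed to capture all refit-significant SNPs
#'
#' Given paired -log10 p-values from the fast path and the exact refit,
#' returns `tau`: the smallest fast-path -log10 p among all (effect,
#' replicate) pairs whose refit -log10 p exceeds `refit_cut`. Scanning with
#' the relaxed threshold `tau` and re-checking hits with a full refit then
#' loses none of the refit-significant SNPs. Main and interaction effects
#' are pooled.
#'
#' @param report a [gallop_accuracy][run_accuracy_study] data.frame.
#' @param refit_cut -log10 p cut for refit significance (genome-wide 7.3).
#' @return `tau`, or `NA` (with a warning) if no pair exceeds the cut.
#' @export
threshold_calibration <- function(report, refit_cut = 7.3) {
  stopifnot(all(c("p_cs", "p_long", "refit_p_cs", "refit_p_long") %in% names(report)))
  gallop_mlp <- -log10(c(report$p_cs, report$p_long))
  refit_mlp <- -log10(c(report$refit_p_cs, report$refit_p_long))
  ok <- is.finite(gallop_mlp) & is.finite(refit_mlp)
  hit <- ok & refit_mlp > refit_cut
  if (!any(hit)) {
    warning("no pair exceeds refit_cut = ", refit_cut, "; threshold undefined")
    return(NA_real_)
  }
  min(gallop_mlp[hit])
}
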