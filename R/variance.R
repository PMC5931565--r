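#' REML variance components of the SNP-free reduced model
#'
#' Fits the reduced linear mixed model
#' `y = beta0 + beta1 t + C beta_cov + b0 + b1 t + e` with per-subject random
#' intercept and slope `b ~ N(0, D)` and homoscedastic independent errors
#' `e ~ N(0, sigma^2)`, by REML through [lme4::lmer()]. Zero-weight rows are
#' excluded from the fit, which is equivalent to the weighted formulation.
#' The penalty matrix `P* = (D/sigma^2)^(-1)` and the fixed and random
#' effects of the reduced penalized least-squares system are derived from
#' the estimates.
#'
#' A boundary (singular) fit — `D` not positive definite — is flagged;
#' downstream precomputation refuses such fits because the penalty is then
#' undefined.
#'
#' @param gd a [gallop_data][assemble_longitudinal] object.
#' @param keep_fit keep the fitted `merMod` object (needed for accuracy
#'   studies and fitted-value comparisons). Default `TRUE`.
#' @return object of class `gallop_fit` with components
#'   \describe{
#'     \item{vc}{`D` (2x2), `sigma2`, `sigma`, `P_star`, `singular`,
#'       `convergence` messages.}
#'     \item{reduced}{`beta_star` (fixed effects), `theta` and `b_star`
#'       (transformed and plain random effects, n x 2), `fitted`,
#'       `residuals` (length N, `NA` on zero-weight rows).}
#'     \item{lmer_fit}{the `merMod`, if `keep_fit`.}
#'   }
#' @export
fit_variance_components <- function(gd, keep_fit = TRUE) {
  stopifnot(inherits(gd, "gallop_data"))
  n_ge2 <- sum(rowsum(gd$w, gd$subject)[, 1] >= 2)
  if (n_ge2 < 2)
    stop("random slope not identifiable: need >= 2 subjects with >= 2 valid observations")

  ok <- gd$w > 0
  df <- data.frame(.y = gd$y[ok], .t = gd$t[ok],
                   .id = factor(gd$subject[ok], levels = seq_len(gd$n)))
  cov_terms <- character(0)
  if (gd$q) {
    Cm <- gd$X[ok, -(1:2), drop = FALSE]
    cn <- make.names(gd$cov_names, unique = TRUE)
    colnames(Cm) <- cn
    df <- cbind(df, as.data.frame(Cm))
    cov_terms <- cn
  }
  fml <- as.formula(paste(".y ~ .t", if (length(cov_terms))
    paste("+", paste(cov_terms, collapse = " + ")) else "", "+ (1 + .t | .id)"))

  msgs <- character(0)
  quiet_lmer <- function(...) withCallingHandlers(
    lme4::lmer(fml, data = df, REML = TRUE, control = lme4::lmerControl(...)),
    warning = function(w) { msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning") },
    message = function(m) { msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage") }
  )
  fit <- quiet_lmer(calc.derivs = FALSE)
  # the default optimizer occasionally collapses a variance component at a
  # false optimum; on a boundary or near-boundary fit, retry with bobyqa
  # and keep whichever achieves the lower REML criterion
  if (near_boundary(fit)) {
    fit2 <- quiet_lmer(optimizer = "bobyqa", calc.derivs = FALSE)
    if (lme4::REMLcrit(fit2) < lme4::REMLcrit(fit)) fit <- fit2
  }

  vcobj <- lme4::VarCorr(fit)
  D <- matrix(as.numeric(vcobj$.id), 2, 2,
              dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
  sigma2 <- sigma(fit)^2
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  singular <- lme4::isSingular(fit, tol = 1e-4) || min(ev) <= 1e-8 * max(ev, 1)

  vc <- list(D = D, sigma2 = sigma2, sigma = sqrt(sigma2),
             P_star = if (!singular) solve(D / sigma2) else NULL,
             singular = singular, convergence = msgs)

  if (singular) {
    beta_star <- lme4::fixef(fit)
    reduced <- list(beta_star = beta_star, theta = NULL, b_star = NULL,
                    fitted = NULL, residuals = NULL)
  } else {
    reduced <- reduced_solve(gd, vc$P_star)
  }

  structure(list(vc = vc, reduced = reduced,
                 lmer_fit = if (keep_fit) fit else NULL,
                 n = gd$n, p = gd$p),
            class = "gallop_fit")
}

#' @export
print.gallop_fit <- function(x, ...) {
  cat("Reduced-model REML fit (random intercept + slope)\n")
  cat("  D (random-effect covariance):\n")
  print(round(x$vc$D, 4))
  cat(sprintf("  residual sigma: %.4f%s\n", x$vc$sigma,
              if (x$vc$singular) "  [boundary fit: D singular]" else ""))
  cat("  fixed effects:\n")
  print(round(x$reduced$beta_star, 4))
  invisible(x)
}

# TRUE when the random-effect covariance is singular or nearly so (smallest
# eigenvalue below 1% of the largest) — either a genuine boundary fit or a
# collapsed-variance false optimum worth a second optimizer pass
near_boundary <- function(fit) {
  if (lme4::isSingular(fit, tol = 1e-4)) return(TRUE)
  D <- matrix(as.numeric(lme4::VarCorr(fit)[[1]]), 2, 2)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  min(ev) < 1e-2 * max(ev)
}

# Solve the reduced penalized least-squares system in its whitened form:
#   beta* = (A11 - Atil'Atil)^(-1) (q1 - Atil' qtil),  theta = qtil - Atil beta*,
#   b* = Phi' theta.
# All per-subject 2x2 algebra is vectorized over subjects.
reduced_solve <- function(gd, P_star, blocks = NULL, rot = NULL) {
  if (is.null(blocks)) blocks <- subject_blocks(gd)
  if (is.null(rot)) rot <- rotate_all(blocks$S, P_star)
  Phi <- rot$Phi
  p11 <- Phi[, 1]; p21 <- Phi[, 2]; p12 <- Phi[, 3]; p22 <- Phi[, 4]

  A1 <- p11 * blocks$R1 + p12 * blocks$R2     # first rows of Phi_i R_i (n x p)
  A2 <- p21 * blocks$R1 + p22 * blocks$R2
  qt1 <- p11 * blocks$r[, 1] + p12 * blocks$r[, 2]
  qt2 <- p21 * blocks$r[, 1] + p22 * blocks$r[, 2]

  M <- blocks$A11 - crossprod(A1) - crossprod(A2)
  rhs <- blocks$q1 - drop(crossprod(A1, qt1)) - drop(crossprod(A2, qt2))
  cM <- tryCatch(chol(M), error = function(e)
    stop("reduced system matrix not positive definite (collinear fixed effects?)"))
  beta_star <- drop(backsolve(cM, backsolve(cM, rhs, transpose = TRUE)))
  names(beta_star) <- colnames(gd$X)

  th1 <- qt1 - drop(A1 %*% beta_star)
  th2 <- qt2 - drop(A2 %*% beta_star)
  b1 <- p11 * th1 + p21 * th2                  # b* = Phi' theta
  b2 <- p12 * th1 + p22 * th2

  fitted <- drop(gd$X %*% beta_star) + b1[gd$subject] + b2[gd$subject] * gd$t
  fitted[gd$w == 0] <- NA_real_
  resid <- ifelse(gd$w > 0, gd$y - fitted, NA_real_)

  list(beta_star = beta_star,
       theta = cbind(th1, th2), b_star = cbind(b1, b2),
       fitted = fitted, residuals = resid,
       M = M, cholM = cM, blocks = blocks, rot = rot)
}

#' Predicted inflation of the random-effect covariance under an omitted SNP
#'
#' When the reduced (SNP-free) model is fitted to data generated with true
#' SNP effects `beta2` (main) and `beta3` (interaction with time), the
#' omitted effects are absorbed by the random intercept and slope, inflating
#' their covariance to
#' `D* = D + var(SNP) * [beta2^2, beta2*beta3; beta2*beta3, beta3^2]`.
#' This quantifies how conservative the fixed-variance approximation becomes
#' for truly associated SNPs.
#'
#' @param D 2x2 random-effect covariance of the full model.
#' @param beta2,beta3 true main and interaction SNP effects.
#' @param var_snp variance of the dosage across subjects (>= 0).
#' @return 2x2 matrix `D*`.
#' @examples
#' variance_inflation(diag(2), beta2 = 1, beta3 = 0, var_snp = 0.5)
#' @export
variance_inflation <- function(D, beta2, beta3, var_snp) {
  stopifnot(is.matrix(D), all(dim(D) == 2), var_snp >= 0)
  D + var_snp * matrix(c(beta2^2, beta2 * beta3, beta2 * beta3, beta3^2), 2, 2)
}
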