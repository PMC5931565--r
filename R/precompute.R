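#' One-time precomputation shared by all SNPs
#'
#' Derives, from the assembled data and the reduced-model fit, everything the
#' per-SNP bordered solve reuses: the per-subject rotated blocks and the three
#' border features
#' `E_i = R_i - K_i'Atil_i` (2 x p), `F_i = S_i - K_i'K_i` (2 x 2) and
#' `g_i = r_i - R_i beta* - K_i'theta_i` (length 2), with `K_i = Phi_i S_i`,
#' plus the factorized core matrix `M = A11 - sum_i Atil_i'Atil_i`. Because a
#' SNP dosage is constant over a subject's occasions, each SNP then enters
#' only through two weighted sums of these features (weights `s_i` and
#' `s_i^2`), so a whole block of SNPs is scored with a handful of matrix
#' products and no per-row expansion of the genotype vector.
#'
#' @param gd a [gallop_data][assemble_longitudinal] object.
#' @param fit a [gallop_fit][fit_variance_components]; must not be a boundary
#'   (singular) fit.
#' @return object of class `gallop_precompute`.
#' @export
gallop_precompute <- function(gd, fit) {
  stopifnot(inherits(gd, "gallop_data"), inherits(fit, "gallop_fit"))
  if (fit$vc$singular)
    stop("variance-component fit is singular (boundary); refusing to precompute. ",
         "Refit with a model in which D is positive definite.")
  P_star <- fit$vc$P_star

  blocks <- subject_blocks(gd)
  rot <- rotate_all(blocks$S, P_star)
  red <- reduced_solve(gd, P_star, blocks = blocks, rot = rot)

  Phi <- rot$Phi
  p11 <- Phi[, 1]; p21 <- Phi[, 2]; p12 <- Phi[, 3]; p22 <- Phi[, 4]
  s11 <- blocks$S[, 1]; s12 <- blocks$S[, 2]; s22 <- blocks$S[, 3]

  # K = Phi S (2x2 per subject)
  K11 <- p11 * s11 + p12 * s12
  K12 <- p11 * s12 + p12 * s22
  K21 <- p21 * s11 + p22 * s12
  K22 <- p21 * s12 + p22 * s22

  A1 <- p11 * blocks$R1 + p12 * blocks$R2   # rows of Atil_i = Phi_i R_i
  A2 <- p21 * blocks$R1 + p22 * blocks$R2

  # E = R - K'Atil (2 x p per subject), rows stored as n x p matrices
  E1 <- blocks$R1 - (K11 * A1 + K21 * A2)
  E2 <- blocks$R2 - (K12 * A1 + K22 * A2)

  # F = S - K'K (2x2 symmetric per subject)
  F11 <- s11 - (K11 * K11 + K21 * K21)
  F12 <- s12 - (K11 * K12 + K21 * K22)
  F22 <- s22 - (K12 * K12 + K22 * K22)

  # g = r - R beta* - K'theta
  beta_star <- red$beta_star
  th1 <- red$theta[, 1]; th2 <- red$theta[, 2]
  g1 <- blocks$r[, 1] - drop(blocks$R1 %*% beta_star) - (K11 * th1 + K21 * th2)
  g2 <- blocks$r[, 2] - drop(blocks$R2 %*% beta_star) - (K12 * th1 + K22 * th2)

  Minv <- chol2inv(red$cholM)

  structure(list(
    E1 = E1, E2 = E2, Fmat = cbind(F11, F12, F22), g = cbind(g1, g2),
    M = red$M, Minv = Minv,
    beta_star = beta_star, theta = red$theta, b_star = red$b_star,
    D = fit$vc$D, sigma2 = fit$vc$sigma2, sigma = fit$vc$sigma,
    P_star = P_star, subj_ids = gd$subj_ids, n = gd$n, p = gd$p
  ), class = "gallop_precompute")
}

#' @export
print.gallop_precompute <- function(x, ...) {
  cat(sprintf("GALLOP precompute: %d subjects, %d fixed effects, sigma = %.4f\n",
              x$n, x$p, x$sigma))
  invisible(x)
}
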