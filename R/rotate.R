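#' Per-subject whitening rotation of the penalized random-effect block
#'
#' Computes the 2x2 transform `Phi = Omega^(-1/2) U'` from the
#' eigendecomposition `U Omega U'` of `S + P*`, so that
#' `Phi (S + P*) Phi' = I`. Applying `Phi` to each subject's block turns the
#' random-effect part of the penalized least-squares system into the
#' identity, which is what makes the per-SNP bordered solve cheap.
#'
#' Eigenvalues are returned in ascending order; eigenvector signs are
#' arbitrary. Downstream results are invariant to either convention because
#' `Phi` only ever enters through `Phi'Phi = (S + P*)^(-1)`-like products.
#'
#' @param S 2x2 symmetric positive semidefinite matrix (a subject's `Z'WZ`).
#' @param P_star 2x2 symmetric positive-definite penalty `(D/sigma^2)^(-1)`.
#' @return list with `Phi` (2x2), `U` (eigenvectors), `omega` (eigenvalues,
#'   ascending).
#' @examples
#' r <- rotate_penalized(diag(2) * 3, diag(2))
#' r$Phi %*% (diag(2) * 3 + diag(2)) %*% t(r$Phi)  # identity
#' @export
rotate_penalized <- function(S, P_star) {
  stopifnot(is.matrix(S), all(dim(S) == 2), is.matrix(P_star), all(dim(P_star) == 2))
  A <- S + P_star
  if (abs(A[1, 2] - A[2, 1]) > 1e-8 * max(1, abs(A[1, 2])))
    stop("S + P* is not symmetric")
  e <- rotate_all(matrix(c(S[1, 1], S[1, 2], S[2, 2]), 1), P_star)
  list(Phi = matrix(e$Phi[1, ], 2, 2),
       U = matrix(e$U[1, ], 2, 2),
       omega = unname(e$omega[1, ]))
}

# Vectorized closed-form eigendecomposition of the 2x2 matrices
# A_i = S_i + P*, for all subjects at once. Smat is n x 3 (s11, s12, s22).
# Returns Phi as n x 4 in column-major element order (phi11, phi21, phi12,
# phi22), U likewise, omega n x 2 ascending.
rotate_all <- function(Smat, P_star) {
  a <- Smat[, 1] + P_star[1, 1]
  b <- Smat[, 2] + P_star[1, 2]
  c <- Smat[, 3] + P_star[2, 2]
  tr <- a + c
  disc <- sqrt((a - c)^2 + 4 * b^2)
  l1 <- (tr - disc) / 2   # smallest
  l2 <- (tr + disc) / 2
  if (any(l1 <= 0))
    stop("S + P* not positive definite for subject(s) ",
         paste(head(which(l1 <= 0), 5), collapse = ", "),
         "; check the penalty matrix")
  # eigenvector for l2: (b, l2 - a), with a safe fallback when the matrix is
  # already (numerically) diagonal with a >= c
  v2x <- b
  v2y <- l2 - a
  degen <- abs(v2x) + abs(v2y) <= .Machine$double.eps * pmax(1, abs(l2))
  v2x[degen] <- 1; v2y[degen] <- 0
  nrm <- sqrt(v2x^2 + v2y^2)
  v2x <- v2x / nrm; v2y <- v2y / nrm
  # orthogonal partner, eigenvector for l1
  v1x <- -v2y; v1y <- v2x
  U <- cbind(v1x, v1y, v2x, v2y)          # columns of U, column-major
  s1 <- 1 / sqrt(l1); s2 <- 1 / sqrt(l2)
  # Phi = diag(s1, s2) %*% t(U): row1 = s1 * v1', row2 = s2 * v2'
  Phi <- cbind(s1 * v1x, s2 * v2x, s1 * v1y, s2 * v2y)
  colnames(Phi) <- c("phi11", "phi21", "phi12", "phi22")
  list(Phi = Phi, U = U, omega = cbind(l1, l2))
}
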