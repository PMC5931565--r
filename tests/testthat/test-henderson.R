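test_that("solution matches a brute-force dense build of the full system", {
  set.seed(5)
  n <- 3; k <- 2; N <- n * k
  subject <- rep(1:3, each = k)
  time <- c(0, 1, 0.5, 2, 1, 3)
  X <- cbind(1, time)
  y <- rnorm(N, 1 + 0.5 * time)
  P <- matrix(c(1.2, -0.1, -0.1, 0.8), 2, 2)
  w <- c(1, 1, 1, 0, 1, 1)

  # independent oracle: assemble the (p + 2n) square matrix element by element
  Z <- matrix(0, N, 2 * n)
  for (r in 1:N) Z[r, (2 * subject[r] - 1):(2 * subject[r])] <- c(1, time[r])
  W <- diag(w)
  H <- rbind(cbind(t(X) %*% W %*% X, t(X) %*% W %*% Z),
             cbind(t(Z) %*% W %*% X, t(Z) %*% W %*% Z + kronecker(diag(n), P)))
  rhs <- c(t(X) %*% W %*% y, t(Z) %*% W %*% y)
  ref <- unname(solve(H, rhs))
  ref_cov <- unname(1.7 * solve(H)[1:2, 1:2])

  h <- henderson_solve(y, X, time, subject, P, weights = w, sigma2 = 1.7)
  expect_equal(unname(h$beta), ref[1:2], tolerance = 1e-12)
  expect_equal(as.numeric(t(h$b)), ref[3:8], tolerance = 1e-12)
  expect_equal(unname(h$cov_beta), ref_cov, tolerance = 1e-12)
})

test_that("a huge penalty shrinks random effects to zero and recovers weighted least squares", {
  set.seed(6)
  N <- 40
  subject <- rep(1:10, each = 4)
  time <- runif(N, 0, 5)
  X <- cbind(1, time, rnorm(N))
  y <- rnorm(N, drop(X %*% c(2, -1, 0.5)))
  w <- rep(1, N); w[c(3, 17)] <- 0
  h <- henderson_solve(y, X, time, subject, diag(2) * 1e12, weights = w)
  ols <- lm.wfit(X, y, w)
  expect_equal(unname(h$beta), unname(ols$coefficients), tolerance = 1e-6)
  expect_lt(max(abs(h$b)), 1e-6)
})

test_that("collinear fixed-effect columns are reported by name", {
  N <- 20
  subject <- rep(1:5, each = 4)
  time <- rep(0:3, 5)
  X <- cbind(a = 1, time = time, dup = 2 * time)
  y <- rnorm(N)
  expect_error(henderson_solve(y, X, time, subject, diag(2)), "dup")
})

test_that("per-SNP exact scores agree with lme4 at matched variance components", {
  # fix (D, sigma^2) at the REML optimum of the FULL model, then the
  # penalized solve must reproduce lmer's fixed effects and standard errors
  pl <- make_pipeline(cfg_unit(n = 200), beta2 = 0.4, beta3 = 0.25, seed = 91)
  s <- pl$sim$dosage[, 1]
  df <- pl$sim$pheno
  df$.s <- s[match(df$id, rownames(pl$sim$dosage))]
  df$.id <- factor(df$id)
  full <- lme4::lmer(y ~ time + .s + time:.s + cov1 + cov2 + cov3 + (1 + time | .id),
                     df, REML = TRUE)
  Dfull <- matrix(as.numeric(lme4::VarCorr(full)$.id), 2, 2)
  s2full <- sigma(full)^2

  fit2 <- pl$fit
  fit2$vc$D <- Dfull; fit2$vc$sigma2 <- s2full; fit2$vc$sigma <- sqrt(s2full)
  fit2$vc$P_star <- solve(Dfull / s2full)
  ex <- score_snp_exact(pl$gd, fit2, s)

  fe <- lme4::fixef(full); se <- sqrt(diag(as.matrix(vcov(full))))
  expect_equal(ex$beta2, unname(fe[".s"]), tolerance = 1e-6)
  expect_equal(ex$beta3, unname(fe["time:.s"]), tolerance = 1e-6)
  expect_equal(ex$se2, unname(se[names(fe) == ".s"]), tolerance = 1e-4)
  expect_equal(ex$se3, unname(se[names(fe) == "time:.s"]), tolerance = 1e-4)
})
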