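#' Configuration for simulating longitudinal GWAS datasets
#'
#' Defaults reproduce the generative design used throughout the package's
#' calibration studies: n = 2000 subjects observed on k = 4 occasions at
#' times uniform on (0, 10); three independent time-varying covariates drawn
#' from N(2, sd = 0.5); fixed intercept -2.6 and time slope -1.9 with
#' covariate coefficients drawn once per dataset from N(0, 1); random
#' intercept/slope covariance `D = [[1, -0.2], [-0.2, 1]]`; residual SD 2.5;
#' and continuous dosages uniform on (0, 2) (imputed-genotype convention).
#' SNP effect grids span 200 equally spaced values in `[0, 1]`.
#'
#' @param n,k subjects and occasions per subject.
#' @param q number of covariates.
#' @param t_range time window for uniform measurement occasions.
#' @param beta0,beta1 fixed intercept and time slope.
#' @param beta_cov covariate coefficients; `NULL` draws them from N(0, 1)
#'   once per simulated dataset.
#' @param cov_mean,cov_sd covariate distribution N(cov_mean, sd = cov_sd).
#'   `cov_par_is_sd = FALSE` reads `cov_sd` as a variance instead.
#' @param D 2x2 random-effect covariance (positive semidefinite).
#' @param sigma residual SD (>= 0; 0 gives the noise-free limit).
#' @param dosage_law `"uniform"` for continuous dosages U(0, 2) or
#'   `"binomial"` for hard calls Binomial(2, maf).
#' @param maf minor allele frequency for the binomial law.
#' @param grid_points,effect_range SNP effect grid definition.
#' @param cov_par_is_sd see `cov_sd`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n = 2000, k = 4, q = 3, t_range = c(0, 10),
                       beta0 = -2.6, beta1 = -1.9, beta_cov = NULL,
                       cov_mean = 2, cov_sd = 0.5,
                       D = matrix(c(1, -0.2, -0.2, 1), 2, 2), sigma = 2.5,
                       dosage_law = c("uniform", "binomial"), maf = 0.3,
                       grid_points = 200, effect_range = c(0, 1),
                       cov_par_is_sd = TRUE) {
  dosage_law <- match.arg(dosage_law)
  stopifnot(n >= 1, k >= 1, q >= 0, length(t_range) == 2, t_range[2] > t_range[1],
            is.matrix(D), all(dim(D) == 2), sigma >= 0,
            maf > 0, maf < 1, grid_points >= 1, all(is.finite(effect_range)))
  if (abs(D[1, 2] - D[2, 1]) > 1e-12) stop("D must be symmetric")
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("D must be positive semidefinite")
  if (!is.null(beta_cov) && length(beta_cov) != q)
    stop("beta_cov must have length q")
  structure(list(n = n, k = k, q = q, t_range = t_range,
                 beta0 = beta0, beta1 = beta1, beta_cov = beta_cov,
                 cov_mean = cov_mean,
                 cov_sd = if (cov_par_is_sd) cov_sd else sqrt(cov_sd),
                 D = D, sigma = sigma, dosage_law = dosage_law, maf = maf,
                 grid_points = grid_points, effect_range = effect_range),
            class = "sim_config")
}

#' Simulate a longitudinal GWAS dataset
#'
#' Generates phenotype and dosage data from the full mixed model
#' `y_ij = beta0 + beta1 t_ij + beta2 s_i + beta3 t_ij s_i + C_ij beta_cov
#'  + b0_i + b1_i t_ij + e_ij` with `b_i ~ N(0, D)`, `e_ij ~ N(0, sigma^2)`
#' and dosages drawn per `cfg$dosage_law`. The outcome is driven by the
#' first SNP; any additional SNPs (`m > 1`) are independent null markers,
#' useful for type-I-error studies.
#'
#' @param cfg a [sim_config].
#' @param beta2,beta3 main and SNP-by-time effects of the causal SNP.
#' @param m number of SNPs in the dosage block.
#' @param seed optional seed (`set.seed` is called if non-NULL; otherwise the
#'   current RNG stream is used).
#' @return list of class `gallop_sim`: `pheno` (long-format data.frame with
#'   columns id, time, y, cov1..covq), `dosage` (n x m matrix, rownames =
#'   subject ids), and `truth` (all generating values, including the
#'   realized random effects).
#' @export
simulate_dataset <- function(cfg, beta2 = 0, beta3 = 0, m = 1, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), m >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n; k <- cfg$k; q <- cfg$q; N <- n * k

  id_num <- rep(seq_len(n), each = k)
  t <- runif(N, cfg$t_range[1], cfg$t_range[2])
  C <- if (q) matrix(rnorm(N * q, cfg$cov_mean, cfg$cov_sd), N, q,
                     dimnames = list(NULL, paste0("cov", seq_len(q)))) else
    matrix(numeric(0), N, 0)
  beta_cov <- if (q) { if (is.null(cfg$beta_cov)) rnorm(q) else cfg$beta_cov } else numeric(0)

  # random effects via symmetric square root (valid for semidefinite D)
  ed <- eigen(cfg$D, symmetric = TRUE)
  Dhalf <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  b <- matrix(rnorm(2 * n), n, 2) %*% Dhalf

  G <- switch(cfg$dosage_law,
              uniform = matrix(runif(n * m, 0, 2), n, m),
              binomial = matrix(rbinom(n * m, 2, cfg$maf) + 0, n, m))
  subj_ids <- sprintf("S%0*d", nchar(n), seq_len(n))
  dimnames(G) <- list(subj_ids, paste0("snp", seq_len(m)))
  s <- G[, 1]

  eps <- if (cfg$sigma > 0) rnorm(N, 0, cfg$sigma) else numeric(N)
  y <- cfg$beta0 + cfg$beta1 * t + beta2 * s[id_num] + beta3 * t * s[id_num] +
    (if (q) drop(C %*% beta_cov) else 0) +
    b[id_num, 1] + b[id_num, 2] * t + eps

  pheno <- data.frame(id = subj_ids[id_num], time = t, y = y,
                      stringsAsFactors = FALSE)
  if (q) pheno <- cbind(pheno, as.data.frame(C))

  structure(list(
    pheno = pheno, dosage = G,
    truth = list(beta0 = cfg$beta0, beta1 = cfg$beta1, beta2 = beta2,
                 beta3 = beta3, beta_cov = beta_cov, D = cfg$D,
                 sigma = cfg$sigma, b = b, seed = seed)
  ), class = "gallop_sim")
}

#' Inject missing outcomes completely at random
#'
#' Sets each outcome to `NA` independently with the given probability,
#' preserving the row structure (missing rows are what the 0/1 observation
#' weights encode downstream).
#'
#' @param pheno long-format phenotype data.frame with a `y` column (or the
#'   column named by `outcome`).
#' @param rate missingness probability in `[0, 1)`.
#' @param outcome outcome column name.
#' @param seed optional seed.
#' @return the data.frame with `NA`s injected.
#' @export
inject_missingness <- function(pheno, rate, outcome = "y", seed = NULL) {
  stopifnot(rate >= 0, rate < 1, outcome %in% names(pheno))
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(pheno)
  drop <- runif(nrow(pheno)) < rate
  pheno[[outcome]][drop] <- NA_real_
  pheno
}
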