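#' Assemble a long-format longitudinal dataset for mixed-model analysis
#'
#' Validates a long-format phenotype table (one row per subject and
#' measurement occasion), orders rows by subject, derives the fixed-effect
#' design `X* = [1, t, C]` and 0/1 observation weights. Rows with a missing
#' outcome, missing time, or any missing covariate get weight 0 and are
#' zeroed out, which is algebraically identical to deleting them from every
#' weighted cross product; subjects with no valid rows are dropped.
#'
#' @param data data.frame with at least the id, time and outcome columns.
#' @param id,time,outcome names of the subject identifier, measurement time
#'   and outcome columns.
#' @param covariates character vector of covariate column names. `NULL` uses
#'   every remaining numeric column; `character(0)` means no covariates.
#' @param missing_policy `"zero_weight"` (default) gives invalid rows weight
#'   0; `"strict"` errors on any missing value instead.
#' @return An object of class `gallop_data`: the ordered phenotype table plus
#'   numeric outcome/time/design/weight vectors, the subject index, and
#'   dimensions (`n` subjects, `N` rows, `p = 2 + q` fixed effects).
#' @examples
#' df <- data.frame(id = rep(1:3, each = 2), time = rep(0:1, 3),
#'                  y = rnorm(6), bmi = rnorm(6, 25))
#' gd <- assemble_longitudinal(df, covariates = "bmi")
#' gd$n; gd$p
#' @export
assemble_longitudinal <- function(data, id = "id", time = "time", outcome = "y",
                                  covariates = NULL,
                                  missing_policy = c("zero_weight", "strict")) {
  missing_policy <- match.arg(missing_policy)
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("empty phenotype table")
  for (col in c(id, time, outcome)) {
    if (!col %in% names(data)) stop("column '", col, "' not found in phenotype table")
  }
  if (is.null(covariates)) {
    rest <- setdiff(names(data), c(id, time, outcome))
    covariates <- rest[vapply(data[rest], is.numeric, logical(1))]
  } else if (length(covariates)) {
    miss <- setdiff(covariates, names(data))
    if (length(miss)) stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  }

  ids <- as.character(data[[id]])
  if (anyNA(ids)) stop("missing subject identifiers")
  if (!is.numeric(data[[time]])) stop("time column '", time, "' must be numeric")
  if (!is.numeric(data[[outcome]])) stop("outcome column '", outcome, "' must be numeric")

  # subjects in first-appearance order, rows grouped per subject (stable sort)
  subj_ids <- unique(ids)
  subject <- match(ids, subj_ids)
  ord <- order(subject, method = "radix")
  data <- data[ord, , drop = FALSE]
  subject <- subject[ord]
  rownames(data) <- NULL

  t_raw <- data[[time]]
  y_raw <- data[[outcome]]
  C_raw <- if (length(covariates)) as.matrix(data[, covariates, drop = FALSE]) else
    matrix(numeric(0), nrow(data), 0)
  storage.mode(C_raw) <- "double"

  bad <- is.na(y_raw) | is.na(t_raw)
  if (ncol(C_raw)) bad <- bad | rowSums(is.na(C_raw)) > 0L
  if (missing_policy == "strict" && any(bad))
    stop(sum(bad), " row(s) with missing outcome, time or covariates under strict policy")
  w <- as.numeric(!bad)

  # drop subjects with no valid observation
  valid_per_subj <- rowsum(w, subject)[, 1]
  keep_subj <- which(valid_per_subj > 0)
  n_dropped <- length(subj_ids) - length(keep_subj)
  if (length(keep_subj) == 0L) stop("no subject has a valid observation")
  if (n_dropped > 0L) {
    keep_rows <- subject %in% keep_subj
    data <- data[keep_rows, , drop = FALSE]
    rownames(data) <- NULL
    t_raw <- t_raw[keep_rows]; y_raw <- y_raw[keep_rows]
    C_raw <- C_raw[keep_rows, , drop = FALSE]
    w <- w[keep_rows]; bad <- bad[keep_rows]
    subj_ids <- subj_ids[keep_subj]
    subject <- match(as.character(data[[id]]), subj_ids)
  }

  # zero out invalid rows so that weighted sums over all rows equal sums over
  # valid rows exactly (the W-matrix trick)
  y <- ifelse(bad, 0, y_raw)
  t <- ifelse(bad, 0, t_raw)
  C <- C_raw
  if (ncol(C)) C[bad, ] <- 0
  X <- cbind(`(Intercept)` = 1, time = t, C)
  X[bad, ] <- 0
  if (length(covariates)) colnames(X) <- c("(Intercept)", "time", covariates)

  p <- ncol(X)
  if (p >= sum(w)) stop("fewer valid observations (", sum(w),
                        ") than fixed-effect parameters (", p, ")")

  structure(list(
    pheno = data, id_col = id, time_col = time, outcome_col = outcome,
    cov_names = covariates,
    y = y, t = t, X = X, w = w,
    subject = subject, subj_ids = subj_ids,
    n = length(subj_ids), N = nrow(data), p = p, q = length(covariates),
    n_dropped = n_dropped, missing_policy = missing_policy
  ), class = "gallop_data")
}

#' @export
print.gallop_data <- function(x, ...) {
  cat("Longitudinal GWAS phenotype data\n")
  cat(sprintf("  subjects: %d (%d dropped, no valid rows)\n", x$n, x$n_dropped))
  cat(sprintf("  rows: %d (%d zero-weighted)\n", x$N, sum(x$w == 0)))
  cat(sprintf("  fixed effects: intercept + time + %d covariate(s)%s\n", x$q,
              if (x$q) paste0(" [", paste(x$cov_names, collapse = ", "), "]") else ""))
  invisible(x)
}

# Per-subject weighted sums used throughout: S_i (2x2), R_i (2xp), r_i (2).
# Computed with rowsum() so that zero-weight rows contribute exact zeros in
# the same summation order as physically deleted rows.
subject_blocks <- function(gd) {
  w <- gd$w; t <- gd$t; y <- gd$y; X <- gd$X
  Xw <- X * w
  Xtw <- Xw * t
  base <- cbind(w, w * t, w * t * t, w * y, w * t * y, Xw, Xtw)
  sums <- rowsum(base, gd$subject, reorder = TRUE)
  p <- gd$p
  list(
    S  = sums[, 1:3, drop = FALSE],                 # s11, s12, s22
    r  = sums[, 4:5, drop = FALSE],                 # r1, r2
    R1 = sums[, 5 + seq_len(p), drop = FALSE],      # first row of R_i  (Z row 1)
    R2 = sums[, 5 + p + seq_len(p), drop = FALSE],  # second row of R_i (Z row t)
    A11 = crossprod(Xw, X),                         # sum_i X_i' W_i X_i
    q1 = drop(crossprod(Xw, y))
  )
}
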