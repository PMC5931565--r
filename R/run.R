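#' Run a genome-wide longitudinal association scan, file to file
#'
#' The end-to-end pipeline: read the phenotype table, open the dosage store,
#' reconcile subjects (intersection, ordered as in the phenotype file), fit
#' the reduced mixed model once, then stream SNP chunks through the bordered
#' solver and write one result row per SNP. A run-metadata JSON
#' (`<out_path>.meta.json`) records the configuration, variance components
#' and counts. Re-running with identical inputs produces a byte-identical
#' results file.
#'
#' @param pheno_path phenotype file (delimited text, see [read_phenotype()]).
#' @param geno_path dosage store: delimited text or flat-binary with JSON
#'   sidecar (see [open_dosage_store()]).
#' @param out_path results TSV path.
#' @param id,time,outcome phenotype column names.
#' @param covariates covariate columns (`NULL`: every other numeric column).
#' @param chunk_size SNPs per block.
#' @param missing_policy phenotype missingness policy, see
#'   [assemble_longitudinal()].
#' @param dosage_missing missing-dosage policy, see [gallop_score()].
#' @param raw write full-precision numbers.
#' @param oracle_mlp if non-`NULL`, SNPs whose best -log10 p exceeds this
#'   value (or that were flagged `unstable`) are re-checked with the exact
#'   dense solver; the comparison is written to `<out_path>.oracle.tsv`.
#' @param seed seed applied before any stochastic step (none in the default
#'   pipeline; recorded in the metadata).
#' @param verbose log progress with `message()`.
#' @return the results data.frame, invisibly.
#' @export
gallop_run <- function(pheno_path, geno_path, out_path,
                       id = "id", time = "time", outcome = "y",
                       covariates = NULL, chunk_size = 1000,
                       missing_policy = "zero_weight",
                       dosage_missing = "mean_impute",
                       raw = FALSE, oracle_mlp = NULL, seed = NULL,
                       verbose = TRUE) {
  log_ <- function(...) if (verbose) message("[gallop] ", sprintf(...))
  if (!is.null(seed)) set.seed(seed)

  pheno <- read_phenotype(pheno_path)
  store <- open_dosage_store(geno_path)
  log_("phenotype: %d rows, %d unique subjects; dosages: %d subjects x %d SNPs",
       nrow(pheno), length(unique(pheno[[id]])), store$n, store$m)

  pheno_ids <- unique(as.character(pheno[[id]]))
  common <- intersect(pheno_ids, store$subjects)
  if (length(common) < 2)
    stop("fewer than 2 subjects shared between phenotype and dosage files")
  n_drop_p <- length(pheno_ids) - length(common)
  n_drop_g <- store$n - length(common)
  if (n_drop_p) log_("dropping %d phenotype subject(s) absent from dosage store", n_drop_p)
  if (n_drop_g) log_("ignoring %d dosage subject(s) absent from phenotype", n_drop_g)
  pheno <- pheno[as.character(pheno[[id]]) %in% common, , drop = FALSE]

  gd <- assemble_longitudinal(pheno, id = id, time = time, outcome = outcome,
                              covariates = covariates,
                              missing_policy = missing_policy)
  log_("assembled %d subjects, %d rows (%d zero-weighted, %d subjects dropped)",
       gd$n, gd$N, sum(gd$w == 0), gd$n_dropped)

  fit <- fit_variance_components(gd, keep_fit = FALSE)
  log_("REML variance components: D = [%.4f, %.4f; %.4f, %.4f], sigma = %.4f%s",
       fit$vc$D[1, 1], fit$vc$D[1, 2], fit$vc$D[2, 1], fit$vc$D[2, 2],
       fit$vc$sigma, if (fit$vc$singular) " [SINGULAR]" else "")
  if (fit$vc$singular)
    stop("reduced-model fit is singular (boundary); the penalized solve is undefined")
  pc <- gallop_precompute(gd, fit)

  geno_idx <- match(gd$subj_ids, store$subjects)
  chunks <- chunk_indices(store$m, chunk_size)
  res_list <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    G <- read_dosage_block(store, chunks[[ci]])[geno_idx, , drop = FALSE]
    res_list[[ci]] <- gallop_score(pc, G, snp_ids = store$snps[chunks[[ci]]],
                                   dosage_missing = dosage_missing)
    log_("chunk %d/%d: %d SNPs scored", ci, length(chunks), ncol(G))
  }
  res <- do.call(rbind, res_list)
  flagged <- table(res$status)
  log_("status counts: %s", paste(names(flagged), flagged, sep = "=", collapse = ", "))

  write_results(res, out_path, raw = raw)
  meta <- list(
    package = "gallop", version = as.character(packageVersion("gallop")),
    pheno_path = pheno_path, geno_path = geno_path,
    n_subjects = gd$n, n_rows = gd$N, n_zero_weight = sum(gd$w == 0),
    n_pheno_dropped = n_drop_p, n_geno_ignored = n_drop_g,
    covariates = gd$cov_names, chunk_size = chunk_size,
    missing_policy = missing_policy, dosage_missing = dosage_missing,
    seed = seed, D = fit$vc$D, sigma = fit$vc$sigma,
    status_counts = as.list(flagged))
  jsonlite::write_json(meta, paste0(out_path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  if (!is.null(oracle_mlp)) {
    mlp <- pmax(-log10(res$p_cs), -log10(res$p_long), na.rm = TRUE)
    sel <- which((is.finite(mlp) & mlp > oracle_mlp) | res$status == "unstable")
    if (length(sel)) {
      log_("oracle re-check of %d SNP(s)", length(sel))
      orc <- lapply(sel, function(j) {
        G <- read_dosage_block(store, which(store$snps == res$snp[j]))[geno_idx, 1]
        G <- handle_missing_dosage(G, dosage_missing)$G[, 1]
        ex <- score_snp_exact(gd, fit, G)
        wp <- wald_pvalues(c(ex$beta2, ex$beta3), c(ex$se2, ex$se3))
        data.frame(snp = res$snp[j],
                   beta_cs = ex$beta2, se_cs = ex$se2, p_cs = wp$p[1],
                   beta_long = ex$beta3, se_long = ex$se3, p_long = wp$p[2])
      })
      write_results(do.call(rbind, orc), paste0(out_path, ".oracle.tsv"), raw = raw)
    } else log_("no SNP exceeds the oracle threshold")
  }
  invisible(res)
}
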