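#' Read and write long-format phenotype files
#'
#' Delimited text with a header row; the id, time and outcome columns are
#' required, every remaining numeric column is treated as a covariate unless
#' `covariates` narrows the set. Reading and writing round-trip losslessly.
#'
#' @param path file path.
#' @param na string(s) encoding missing values.
#' @return `read_phenotype`: a data.frame.
#' @export
read_phenotype <- function(path, na = "NA") {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  as.data.frame(data.table::fread(path, na.strings = na, data.table = FALSE,
                                  showProgress = FALSE))
}

#' @rdname read_phenotype
#' @param pheno data.frame to write.
#' @param sep field separator.
#' @export
write_phenotype <- function(pheno, path, sep = "\t") {
  data.table::fwrite(fmt_full(pheno), path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}

# print doubles with 17 significant digits so read -> write -> read is
# bit-lossless (the default 15 drops the last ulp)
fmt_full <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.na(df[[j]])] <- NA_character_
      df[[j]] <- x
    }
  }
  df
}

#' Write a dosage matrix as delimited text
#'
#' First column `id`, one column per SNP, header row of SNP identifiers.
#'
#' @param G subjects x SNPs dosage matrix; rownames are subject ids (or pass
#'   `subjects`).
#' @param path output path.
#' @param subjects subject identifiers.
#' @param sep field separator.
#' @export
write_dosage_text <- function(G, path, subjects = rownames(G), sep = "\t") {
  G <- as.matrix(G)
  if (is.null(subjects)) stop("subject ids required (rownames or `subjects`)")
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  df <- data.table::data.table(id = subjects)
  df <- cbind(df, data.table::as.data.table(G))
  data.table::fwrite(df, path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a dosage matrix as a chunked flat-binary store with JSON sidecar
#'
#' The payload is the n x m dosage array as consecutive 8-byte doubles, one
#' SNP contiguous after another (column-major in the subjects x SNPs
#' orientation), so a block of consecutive SNPs is a single contiguous read.
#' Missing dosages are stored as the sentinel value declared in the sidecar
#' `<path>.json`, which also records dimensions, subject and SNP
#' identifiers, and the chunk geometry.
#'
#' @param G subjects x SNPs dosage matrix (rownames = subject ids).
#' @param path payload path; the sidecar is written to `<path>.json`.
#' @param chunk_size advisory chunk width recorded in the sidecar.
#' @param sentinel numeric value encoding missing dosages.
#' @export
write_dosage_binary <- function(G, path, chunk_size = 1000, sentinel = -9) {
  G <- as.matrix(G)
  if (is.null(rownames(G))) stop("dosage matrix needs subject ids as rownames")
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  if (any(!is.na(G) & G == sentinel))
    stop("sentinel value ", sentinel, " collides with an observed dosage")
  x <- as.numeric(G)
  x[is.na(x)] <- sentinel
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(x, con, size = 8, endian = "little")
  meta <- list(format = "gallop-dosage-bin-1", n = nrow(G), m = ncol(G),
               subjects = rownames(G), snps = colnames(G),
               missing_sentinel = sentinel, layout = "snp_contiguous",
               endian = "little", chunk_size = chunk_size)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Open a dosage store (text or binary) for chunked access
#'
#' A path with a `<path>.json` sidecar is opened as a flat-binary store
#' (blocks are read directly from disk); anything else is parsed as
#' delimited text and held in memory. Both yield identical blocks.
#'
#' @param path store path.
#' @return object of class `dosage_store` with `n`, `m`, `subjects`, `snps`.
#' @export
open_dosage_store <- function(path) {
  if (!file.exists(path)) stop("dosage store not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(meta$format, "gallop-dosage-bin-1"))
      stop("unrecognized dosage container format: ", meta$format)
    expect_bytes <- as.numeric(meta$n) * as.numeric(meta$m) * 8
    if (file.size(path) < expect_bytes)
      stop("truncated dosage payload: ", file.size(path), " bytes, sidecar declares ",
           expect_bytes)
    if (anyDuplicated(meta$subjects)) stop("duplicate subject ids in dosage store")
    structure(list(type = "binary", path = path, n = meta$n, m = meta$m,
                   subjects = meta$subjects, snps = meta$snps,
                   sentinel = meta$missing_sentinel,
                   chunk_size = meta$chunk_size %||% 1000),
              class = "dosage_store")
  } else {
    df <- data.table::fread(path, na.strings = "NA", data.table = FALSE,
                            showProgress = FALSE)
    subjects <- as.character(df[[1]])
    if (anyDuplicated(subjects)) stop("duplicate subject ids in dosage store")
    G <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(G) <- "double"
    rownames(G) <- subjects
    structure(list(type = "text", path = path, n = nrow(G), m = ncol(G),
                   subjects = subjects, snps = colnames(G), data = G),
              class = "dosage_store")
  }
}

#' @export
print.dosage_store <- function(x, ...) {
  cat(sprintf("Dosage store (%s): %d subjects x %d SNPs [%s]\n",
              x$type, x$n, x$m, x$path))
  invisible(x)
}

#' Read a block of consecutive SNPs from a dosage store
#'
#' @param store a [dosage_store][open_dosage_store].
#' @param cols integer indices of consecutive SNP columns.
#' @return n x length(cols) matrix, `NA` for missing dosages, dimnames set.
#' @export
read_dosage_block <- function(store, cols) {
  stopifnot(inherits(store, "dosage_store"), length(cols) >= 1,
            all(cols >= 1), all(cols <= store$m))
  if (any(diff(cols) != 1L)) stop("cols must be consecutive")
  if (store$type == "text") {
    G <- store$data[, cols, drop = FALSE]
  } else {
    con <- file(store$path, "rb")
    on.exit(close(con))
    seek(con, 8 * store$n * (cols[1] - 1))
    x <- readBin(con, "double", n = store$n * length(cols), size = 8,
                 endian = "little")
    if (length(x) < store$n * length(cols)) stop("truncated dosage payload")
    x[x == store$sentinel] <- NA_real_
    G <- matrix(x, store$n, length(cols),
                dimnames = list(store$subjects, store$snps[cols]))
  }
  G
}

#' Split m SNPs into consecutive chunks
#'
#' @param m total number of SNPs; @param chunk_size maximum chunk width.
#' @return list of integer index vectors covering `1:m` in order.
#' @examples
#' lengths(chunk_indices(97, 10))  # nine chunks of 10 and one of 7
#' @export
chunk_indices <- function(m, chunk_size) {
  stopifnot(m >= 1, chunk_size >= 1)
  split(seq_len(m), ceiling(seq_len(m) / chunk_size))
}

#' Write per-SNP association results as TSV
#'
#' One row per input SNP (unscored SNPs carry their status). Numeric columns
#' are printed with 6 significant digits unless `raw = TRUE`, which writes
#' full precision.
#'
#' @param res result data.frame from [gallop_score()].
#' @param path output path.
#' @param raw write full-precision numbers.
#' @export
write_results <- function(res, path, raw = FALSE) {
  out <- res
  if (!raw) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) signif(x, 6))
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
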