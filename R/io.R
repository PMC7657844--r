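# File formats: dense CSV/TSV with a sample-id column, Matrix Market counts
# with gene/barcode sidecars, embedding CSVs at full double precision, and
# JSON run reports.

#' Read a dense sample-by-feature matrix from CSV/TSV
#'
#' Expects a header row; if the first column is non-numeric it is used as
#' sample ids.
#'
#' @param path file path.
#' @param format "csv" or "tsv" (default inferred from the extension).
#' @return numeric matrix with row names.
#' @export
read_dense_matrix <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) abort_ee(paste0("cannot parse ", path, ": ",
                                        conditionMessage(e)), "ee_parse_error")
  )
  if (ncol(df) == 0L || nrow(df) == 0L) {
    abort_ee(paste0("empty matrix in ", path), "ee_parse_error")
  }
  ids <- NULL
  if (!is.numeric(df[[1L]])) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    abort_ee(paste0("non-numeric data columns in ", path), "ee_parse_error")
  }
  X <- as.matrix(df)
  rownames(X) <- ids %||% paste0("sample", seq_len(nrow(X)))
  X
}

#' Write a dense matrix with a sample-id column
#'
#' Values are written with 17 significant digits so a write-read round trip
#' is lossless for doubles.
#'
#' @param X numeric matrix.
#' @param path output path.
#' @param id_col name of the id column (default "sample_id").
#' @param sep field separator.
#' @export
write_dense_matrix <- function(X, path, id_col = "sample_id", sep = ",") {
  ids <- rownames(X) %||% paste0("sample", seq_len(nrow(X)))
  cols <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  header <- paste(c(id_col, cols), collapse = sep)
  body <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(ids[i], sprintf("%.17g", X[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write an embedding CSV
#'
#' Columns \code{sample_id, dim_1, ..., dim_d} at full double precision.
#'
#' @param emb \code{ee_embedding} or bare coordinate matrix.
#' @param path output path.
#' @export
write_embedding_csv <- function(emb, path) {
  X <- if (inherits(emb, "ee_embedding")) emb$coords else emb
  colnames(X) <- paste0("dim_", seq_len(ncol(X)))
  write_dense_matrix(X, path)
}

#' Read an embedding CSV
#'
#' @param path file written by [write_embedding_csv()].
#' @return numeric coordinate matrix.
#' @export
read_embedding_csv <- function(path) {
  read_dense_matrix(path, format = "csv")
}

#' Read Matrix Market counts with sidecars
#'
#' Reads a \code{.mtx} file in the common genomics orientation (genes in
#' rows, cells in columns) together with \code{genes_path} and
#' \code{barcodes_path} sidecars (one id per line, first column used), and
#' returns a cells-by-genes [count_matrix()].
#'
#' @param mtx_path Matrix Market file.
#' @param genes_path,barcodes_path sidecar id files; defaults look for
#'   \code{genes.tsv} and \code{barcodes.tsv} next to the matrix.
#' @return \code{count_matrix}.
#' @export
read_counts_mtx <- function(mtx_path, genes_path = NULL, barcodes_path = NULL) {
  dir <- dirname(mtx_path)
  genes_path <- genes_path %||% file.path(dir, "genes.tsv")
  barcodes_path <- barcodes_path %||% file.path(dir, "barcodes.tsv")
  M <- tryCatch(as.matrix(Matrix::readMM(mtx_path)),
                error = function(e) abort_ee(paste0("cannot parse ", mtx_path, ": ",
                                                    conditionMessage(e)),
                                             "ee_parse_error"))
  read_ids <- function(p, n, what) {
    if (!file.exists(p)) return(paste0(what, seq_len(n)))
    ids <- utils::read.table(p, sep = "\t", stringsAsFactors = FALSE)[[1L]]
    if (length(ids) != n) {
      abort_ee(sprintf("%s has %d ids but matrix has %d", p, length(ids), n),
               "ee_parse_error")
    }
    as.character(ids)
  }
  genes <- read_ids(genes_path, nrow(M), "gene")
  cells <- read_ids(barcodes_path, ncol(M), "cell")
  count_matrix(t(M), cell_ids = cells, gene_ids = genes)
}

#' Write a JSON run report
#'
#' Records everything needed to reproduce a run: parameters, seed, input
#' hash, iteration count, final energy, and the energy trace.
#'
#' @param emb \code{ee_embedding}.
#' @param path output path.
#' @param input_path optional input file to hash (md5).
#' @param extra optional named list merged into the report.
#' @export
write_run_report <- function(emb, path, input_path = NULL, extra = list()) {
  p <- emb$params
  report <- c(list(
    params = list(lambda = p$lambda, perplexity = p$perplexity, dim = p$dim,
                  beta = p$beta, mu = p$mu, max_iter = p$max_iter,
                  tol = p$tol, seed = p$seed, init_scale = p$init_scale),
    workers = emb$workers %||% 1L,
    n_samples = nrow(emb$coords),
    n_iter = emb$n_iter,
    converged = emb$converged,
    reason = emb$reason,
    final_energy = emb$energy_trace[length(emb$energy_trace)],
    energy_trace = emb$energy_trace,
    input_md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path)) else NULL
  ), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
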