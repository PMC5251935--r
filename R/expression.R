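#' Validate a gene-by-sample expression matrix
#'
#' The package represents expression data as a plain numeric matrix with
#' genes in rows and samples (cells) in columns, identified by unique
#' `rownames` / `colnames`. Entries must be finite and non-negative
#' (raw counts, molecule counts or FPKM).
#'
#' @param m A numeric matrix, genes x samples.
#' @param arg Name used in error messages.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples).", arg))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("`%s` has duplicated gene identifiers.", arg))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` has duplicated sample identifiers.", arg))
  }
  if (any(!is.finite(m))) {
    abort(sprintf("`%s` contains non-finite entries.", arg))
  }
  if (any(m < 0)) {
    abort(sprintf("`%s` contains negative entries; expression must be >= 0.", arg))
  }
  invisible(m)
}

#' Read an expression matrix from TSV/CSV or MatrixMarket files
#'
#' Delimited input must carry gene identifiers in the first column and a
#' header row of sample identifiers; the delimiter is guessed from the file
#' extension (`.csv` vs anything else, tab). Gzip compression is transparent.
#' MatrixMarket (`.mtx`) input requires companion row/column identifier
#' files, one identifier per line.
#'
#' @param path Path to the matrix file.
#' @param row_ids,col_ids Paths to gene / sample identifier files
#'   (MatrixMarket input only).
#' @return A numeric matrix, genes x samples.
#' @export
read_expression <- function(path, row_ids = NULL, col_ids = NULL) {
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    if (is.null(row_ids) || is.null(col_ids)) {
      abort("MatrixMarket input needs `row_ids` and `col_ids` identifier files.")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readr::read_lines(row_ids)
    colnames(m) <- readr::read_lines(col_ids)
  } else {
    delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
    m <- as.matrix(tbl[, -1, drop = FALSE])
    rownames(m) <- as.character(tbl[[1]])
  }
  storage.mode(m) <- "double"
  validate_expression_matrix(m, "matrix read from file")
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path; first column `gene_id`, then one column per sample.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  tbl <- tibble::as_tibble(m, rownames = "gene_id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Turn an expression matrix into a long tibble
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`.
#' @export
expression_tidy <- function(m) {
  validate_expression_matrix(m)
  tibble::as_tibble(m, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "value")
}
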