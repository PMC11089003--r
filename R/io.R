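#' Write / read a count matrix as a 10x-style Matrix Market triplet
#'
#' `matrix.mtx` plus `barcodes.tsv` and `features.tsv` sidecars in `dir`.
#' The hash matrix, if present, goes to `hashes.mtx` with `hash_ids.tsv`.
#'
#' @param counts genes x cells sparse (or dense) count matrix.
#' @param dir output directory (created if needed).
#' @param hashes optional hashes x cells matrix.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir, hashes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  if (!is.null(hashes)) {
    hm <- methods::as(methods::as(Matrix::Matrix(hashes, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(hm, file.path(dir, "hashes.mtx"))
    writeLines(rownames(hashes), file.path(dir, "hash_ids.tsv"))
  }
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  out <- list(counts = m)
  hp <- file.path(dir, "hashes.mtx")
  if (file.exists(hp)) {
    h <- as.matrix(Matrix::readMM(hp))
    dimnames(h) <- list(readLines(file.path(dir, "hash_ids.tsv")),
                        colnames(m))
    out$hashes <- h
  }
  out
}

#' Write a tibble as TSV
#'
#' Thin wrapper around [readr::write_tsv()] that drops list-columns (with a
#' note) so every module result can be exported.
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) x <- x[, !is_list, drop = FALSE]
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
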