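# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad_config <- function(msg) abort(msg, class = "mgstates_config_error")

# dirichlet draw via gamma; rows = draws
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# cell totals of a sparse or dense genes x cells matrix
cell_totals <- function(m) {
  if (inherits(m, "sparseMatrix")) Matrix::colSums(m) else colSums(m)
}

gene_detect_cells <- function(m) {
  if (inherits(m, "sparseMatrix")) Matrix::rowSums(m > 0) else rowSums(m > 0)
}

assert_counts_matrix <- function(m, arg = "counts") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort(sprintf("`%s` must have gene rownames and cell colnames", arg))
  invisible(m)
}
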