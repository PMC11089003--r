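#' Per-droplet quality-control metrics
#'
#' Computes, for every droplet of a genes x cells count matrix, the total UMI
#' count, the number of detected genes (>= 1 read), and the fraction of
#' counts mapping to mitochondrial genes (0 for empty droplets).
#'
#' @param counts genes x cells count matrix (sparse or dense) with dimnames.
#' @param mito_genes character vector of mitochondrial gene names; names not
#'   present in the matrix are ignored with a warning. Alternatively a regex
#'   prefix via `mito_pattern`.
#' @param library_id single library label or per-cell vector (used by the
#'   per-library outlier rule of [filter_cells()]).
#' @param mito_pattern if `mito_genes` is `NULL`, rownames matching this
#'   regular expression (default `"^MT-"`) are treated as mitochondrial.
#' @return tibble: `barcode`, `library_id`, `total_counts`, `n_genes`,
#'   `mito_fraction`.
#' @export
compute_cell_qc <- function(counts, mito_genes = NULL, library_id = "lib1",
                            mito_pattern = "^MT-") {
  assert_counts_matrix(counts)
  if (ncol(counts) == 0)
    return(tibble(barcode = character(), library_id = character(),
                  total_counts = numeric(), n_genes = integer(),
                  mito_fraction = numeric()))
  if (is.null(mito_genes)) {
    mito_genes <- grep(mito_pattern, rownames(counts), value = TRUE)
  } else {
    missing <- setdiff(mito_genes, rownames(counts))
    if (length(missing))
      warn(sprintf("%d mito gene(s) not in matrix; ignored", length(missing)))
    mito_genes <- intersect(mito_genes, rownames(counts))
  }
  tot <- cell_totals(counts)
  ng <- if (inherits(counts, "sparseMatrix"))
    Matrix::colSums(counts > 0) else colSums(counts > 0)
  mt <- if (length(mito_genes))
    cell_totals(counts[mito_genes, , drop = FALSE]) else rep(0, ncol(counts))
  tibble(barcode = colnames(counts),
         library_id = rep(library_id, length.out = ncol(counts)),
         total_counts = as.numeric(tot),
         n_genes = as.integer(ng),
         mito_fraction = as.numeric(ifelse(tot > 0, mt / tot, 0)))
}

#' Two-stage droplet filtering: hard thresholds then per-library outliers
#'
#' Stage 1 removes droplets with fewer than `min_counts` reads, fewer than
#' `min_genes` detected genes, or a mitochondrial fraction strictly above
#' `max_mito` (boundary semantics are strict: exactly `min_counts` reads or
#' exactly `max_mito` mitochondrial share is kept). Stage 2, applied per
#' library to stage-1 survivors, removes droplets whose total counts or gene
#' counts lie more than `sd_k` standard deviations from the library mean
#' (two-sided by default; `side = "upper"` restricts to the high tail).
#' Libraries with fewer than 3 survivors skip stage 2 with a warning.
#'
#' @param qc tibble from [compute_cell_qc()].
#' @param min_counts,min_genes,max_mito,sd_k filter parameters.
#' @param side `"two-sided"` (default) or `"upper"` for the s.d. rule.
#' @return list with `kept` (character barcodes) and `ledger` (tibble
#'   `barcode`, `stage`, `reason` for every removed droplet; the first
#'   triggered reason is recorded).
#' @export
filter_cells <- function(qc, min_counts = 1000, min_genes = 100,
                         max_mito = 0.15, sd_k = 3,
                         side = c("two-sided", "upper")) {
  side <- match.arg(side)
  stopifnot(all(c("barcode", "library_id", "total_counts", "n_genes",
                  "mito_fraction") %in% names(qc)))
  reason1 <- dplyr::case_when(
    qc$total_counts < min_counts ~ "low_counts",
    qc$n_genes < min_genes ~ "low_genes",
    qc$mito_fraction > max_mito ~ "high_mito",
    TRUE ~ NA_character_)
  ledger <- tibble(barcode = qc$barcode[!is.na(reason1)], stage = 1L,
                   reason = reason1[!is.na(reason1)])
  surv <- qc[is.na(reason1), , drop = FALSE]

  out2 <- list()
  for (lib in unique(surv$library_id)) {
    s <- surv[surv$library_id == lib, , drop = FALSE]
    if (nrow(s) < 3) {
      warn(sprintf("library %s has <3 survivors; s.d. rule skipped", lib))
      next
    }
    flag <- function(x) {
      mu <- mean(x); s_ <- sd(x)
      if (s_ == 0) return(rep(FALSE, length(x)))
      if (side == "two-sided") abs(x - mu) > sd_k * s_ else x - mu > sd_k * s_
    }
    f_counts <- flag(s$total_counts)
    f_genes <- flag(s$n_genes)
    rm_idx <- f_counts | f_genes
    if (any(rm_idx))
      out2[[lib]] <- tibble(
        barcode = s$barcode[rm_idx], stage = 2L,
        reason = ifelse(f_counts[rm_idx], "counts_outlier", "genes_outlier"))
  }
  ledger <- bind_rows(ledger, bind_rows(out2))
  list(kept = setdiff(qc$barcode, ledger$barcode), ledger = ledger)
}

#' Drop genes detected in too few cells
#'
#' A gene is kept iff it has a nonzero count in at least `min_cells` cells
#' (genes detected in fewer than three cells are excluded by default).
#'
#' @param counts genes x cells count matrix.
#' @param min_cells minimum number of cells with a nonzero count.
#' @return character vector of kept gene names.
#' @export
filter_genes <- function(counts, min_cells = 3) {
  if (nrow(counts) == 0 || ncol(counts) == 0) return(character())
  rownames(counts)[gene_detect_cells(counts) >= min_cells]
}
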