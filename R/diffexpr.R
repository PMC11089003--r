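#' Log-normalize a count matrix (counts per 10k, log1p)
#'
#' Each cell's counts are scaled to `scale` total counts and transformed with
#' `log1p`. Zero counts map to zero, so sparsity is preserved. The transform
#' is recorded in `attr(, "transform")` for provenance.
#'
#' @param counts genes x cells count matrix; no all-zero cells (run
#'   [filter_cells()] first).
#' @param scale library-size scale factor (default 10,000).
#' @return normalized genes x cells matrix (same storage class family).
#' @export
normalize_log <- function(counts, scale = 10000) {
  tot <- cell_totals(counts)
  if (any(tot == 0))
    abort("matrix contains all-zero cells; run filter_cells() first")
  norm <- if (inherits(counts, "sparseMatrix"))
    log1p(counts %*% Matrix::Diagonal(x = scale / tot)) else
    log1p(sweep(counts, 2, scale / tot, `*`))
  dimnames(norm) <- dimnames(counts)
  attr(norm, "transform") <- list(scheme = "log1p_CP10K", scale = scale)
  norm
}

#' Per-gene log2 fold change between two cell groups
#'
#' Means are taken on the de-logged normalized scale (`expm1` of the values)
#' and the fold change uses a pseudocount of 1:
#' `log2((mean_a + 1) / (mean_b + 1))`.
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param cells_a,cells_b disjoint, nonempty cell name (or index) vectors.
#' @return named numeric vector of log2 fold changes, one per gene.
#' @export
log_fold_change <- function(norm, cells_a, cells_b) {
  if (length(cells_a) == 0 || length(cells_b) == 0)
    abort("both groups must be nonempty")
  if (length(intersect(cells_a, cells_b)) > 0)
    abort("groups must be disjoint")
  mu <- function(cells) {
    m <- norm[, cells, drop = FALSE]
    if (inherits(m, "sparseMatrix")) Matrix::rowSums(expm1(m)) / ncol(m) else
      rowMeans(expm1(m))
  }
  lfc <- log2((mu(cells_a) + 1) / (mu(cells_b) + 1))
  setNames(as.numeric(lfc), rownames(norm))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks are used for ties. In `"approx"` mode the p-value comes from the
#' normal approximation with tie-corrected variance and continuity
#' correction. In `"exact"` mode (default for `n_a + n_b <= 12`) the p-value
#' is the exact probability, over all `choose(n_a + n_b, n_a)` assignments of
#' the pooled values to groups, of a rank sum at least as far from its mean
#' as observed. All values tied across both groups gives p = 1.
#'
#' @param values_a,values_b nonempty numeric vectors.
#' @param mode `"auto"` (exact when total n <= 12), `"exact"`, or `"approx"`.
#' @return list with `statistic` (group-a rank sum W), `p` and `mode`.
#' @export
wilcoxon_test <- function(values_a, values_b,
                          mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  na <- length(values_a); nb <- length(values_b)
  if (na == 0 || nb == 0) abort("both samples must be nonempty")
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  if (length(unique(pooled)) == 1)
    return(list(statistic = w, p = 1, mode = "degenerate"))
  if (mode == "auto") mode <- if (na + nb <= 12) "exact" else "approx"
  n <- na + nb
  mu_w <- na * (n + 1) / 2
  if (mode == "exact") {
    idx <- combn(n, na)
    sums <- colSums(matrix(r[idx], nrow = na))
    p <- mean(abs(sums - mu_w) >= abs(w - mu_w) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(w - mu_w) - 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
  }
  list(statistic = w, p = p, mode = mode)
}

#' Wilcoxon marker detection with detection and fold-change prefilters
#'
#' A gene is tested iff it is detected in at least `min_pct` of cells in
#' either group and its absolute fold change is at least `logfc_threshold`
#' on the natural-log scale (`|ln FC| >= 0.1`, i.e. `|log2FC| >= 0.1/ln 2`;
#' fold changes are reported in log2). P-values come from [wilcoxon_test()]
#' in approximate mode and are Bonferroni-adjusted; the default multiplier
#' is the total number of genes in the matrix.
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param cells_a,cells_b disjoint, nonempty cell groups.
#' @param min_pct minimum detection fraction in either group (default 0.01).
#' @param logfc_threshold minimum absolute natural-log fold change (default
#'   0.1).
#' @param bonferroni_multiplier `"matrix"` (all genes in the matrix, default)
#'   or `"tested"` (genes surviving the prefilters), or a number.
#' @param group_a,group_b labels recorded in the output.
#' @return a `mg_de_table` tibble: `gene`, `log2FC`, `pct_a`, `pct_b`, `p`,
#'   `p_adj`, `group_a`, `group_b`, sorted by `p` then `-|log2FC|`.
#' @export
find_markers <- function(norm, cells_a, cells_b, min_pct = 0.01,
                         logfc_threshold = 0.1,
                         bonferroni_multiplier = "matrix",
                         group_a = "A", group_b = "B") {
  det_pct <- function(cells) {
    m <- norm[, cells, drop = FALSE]
    as.numeric(if (inherits(m, "sparseMatrix")) Matrix::rowSums(m > 0) else
      rowSums(m > 0)) / length(cells)
  }
  pct_a <- det_pct(cells_a); pct_b <- det_pct(cells_b)
  lfc <- log_fold_change(norm, cells_a, cells_b)
  log2_cut <- logfc_threshold / log(2)
  test_idx <- which(pmax(pct_a, pct_b) >= min_pct & abs(lfc) >= log2_cut)
  mult <- if (identical(bonferroni_multiplier, "matrix")) nrow(norm) else
    if (identical(bonferroni_multiplier, "tested")) length(test_idx) else
      as.numeric(bonferroni_multiplier)
  if (length(test_idx) == 0)
    return(structure(tibble(gene = character(), log2FC = numeric(),
                            pct_a = numeric(), pct_b = numeric(),
                            p = numeric(), p_adj = numeric(),
                            group_a = character(), group_b = character()),
                     class = c("mg_de_table", class(tibble()))))
  a <- as.matrix(norm[test_idx, cells_a, drop = FALSE])
  b <- as.matrix(norm[test_idx, cells_b, drop = FALSE])
  p <- vapply(seq_along(test_idx), function(i)
    wilcoxon_test(a[i, ], b[i, ], mode = "approx")$p, numeric(1))
  out <- tibble(gene = rownames(norm)[test_idx],
                log2FC = as.numeric(lfc[test_idx]),
                pct_a = pct_a[test_idx], pct_b = pct_b[test_idx],
                p = p, p_adj = pmin(1, p * mult),
                group_a = group_a, group_b = group_b) |>
    arrange(.data$p, -abs(.data$log2FC))
  structure(out, class = c("mg_de_table", class(out)))
}

#' One-vs-rest marker detection for every cluster
#'
#' Runs [find_markers()] for each cluster against the union of all other
#' cells. Singleton clusters are still computed, with a warning.
#'
#' @param norm normalized matrix.
#' @param labels per-cell cluster labels (named by cell or in column order).
#' @param ... passed to [find_markers()].
#' @return named list of `mg_de_table`s, one per cluster.
#' @export
find_all_markers <- function(norm, labels, ...) {
  if (length(labels) != ncol(norm))
    abort("`labels` must have one entry per cell")
  labs <- unique(labels)
  if (length(labs) < 2) abort("need at least 2 clusters")
  cells <- colnames(norm)
  out <- lapply(labs, function(cl) {
    in_cl <- cells[labels == cl]
    if (length(in_cl) == 1)
      warn(sprintf("cluster %s has a single cell", cl))
    find_markers(norm, in_cl, setdiff(cells, in_cl),
                 group_a = cl, group_b = "rest", ...)
  })
  setNames(out, labs)
}
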