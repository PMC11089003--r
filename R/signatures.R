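#' Gene-set module score with expression-bin-matched controls
#'
#' Genes are ranked by average expression across cells and cut into `n_bins`
#' equal-frequency bins. For every set gene, `n_ctrl` control genes are
#' sampled (with replacement) from that gene's bin; the per-cell score is the
#' mean expression of the set genes minus the mean over the pooled control
#' draws. Scores are invariant to adding a constant to the whole matrix.
#'
#' @param norm normalized genes x cells matrix.
#' @param genes character vector of set genes; genes absent from the matrix
#'   are dropped with a warning, an empty set after dropping is an error.
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed integer seed for control sampling.
#' @param name set label recorded in the result.
#' @return tibble `barcode`, `score`, `set`; control parameters and the
#'   sampled control genes in attributes `params` / `control_genes`.
#' @export
module_score <- function(norm, genes, n_bins = 25, n_ctrl = 100,
                         seed = 1L, name = "set") {
  if (nrow(norm) < n_bins)
    abort("matrix has fewer genes than `n_bins`")
  missing <- setdiff(genes, rownames(norm))
  if (length(missing))
    warn(sprintf("%d set gene(s) absent from matrix; dropped",
                 length(missing)))
  genes <- intersect(genes, rownames(norm))
  if (length(genes) == 0) abort("gene set empty after dropping missing genes")
  avg <- if (inherits(norm, "sparseMatrix"))
    Matrix::rowSums(norm) / ncol(norm) else rowMeans(norm)
  # equal-frequency bins via ranks (shift-invariant, robust to skew)
  bin <- ceiling(rank(avg, ties.method = "first") / length(avg) * n_bins)
  ctrl <- withr::with_seed(as.integer(seed), {
    unlist(lapply(genes, function(g) {
      pool <- rownames(norm)[bin == bin[match(g, rownames(norm))]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  cm <- function(rows) {
    m <- norm[rows, , drop = FALSE]
    as.numeric(if (inherits(m, "sparseMatrix"))
      Matrix::colSums(m) / nrow(m) else colMeans(m))
  }
  score <- cm(genes) - cm(ctrl)
  out <- tibble(barcode = colnames(norm), score = score, set = name)
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  attr(out, "control_genes") <- ctrl
  out
}

#' Score a panel of gene sets and optionally call the top state per cell
#'
#' @param norm normalized matrix.
#' @param panels named list of gene-name vectors.
#' @param label if `TRUE`, add a hard `label` column: the panel with the
#'   highest score, ties broken by panel order.
#' @param ... passed to [module_score()] (a distinct seed is derived per
#'   panel from `seed` + panel position).
#' @param seed base seed.
#' @return tibble with `barcode`, one score column per panel, and optionally
#'   `label`.
#' @export
score_state_panel <- function(norm, panels, label = TRUE, seed = 1L, ...) {
  if (length(panels) == 0) abort("need at least one panel")
  if (is.null(names(panels))) abort("`panels` must be named")
  # per-panel seed keyed to the sorted panel name, so reordering panels
  # permutes columns without changing any panel's control draw
  scores <- imap(panels, function(g, nm)
    module_score(norm, g,
                 seed = seed + match(nm, sort(names(panels))) - 1L,
                 name = nm, ...)$score)
  out <- tibble(barcode = colnames(norm), !!!scores)
  if (label) {
    m <- as.matrix(out[, names(panels), drop = FALSE])
    out$label <- names(panels)[apply(m, 1, which.max)]  # ties -> first panel
  }
  out
}

#' Read gene sets from a GMT or two-column TSV file
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' TSV: columns `set` and `gene` (header optional if exactly two columns).
#'
#' @param path file path; format inferred from the `.gmt` extension.
#' @return named list of gene-name character vectors.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
    names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
    return(sets)
  }
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("set", "gene") %in% names(df)) && ncol(df) == 2)
    names(df) <- c("set", "gene")
  split(df$gene, df$set)
}
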