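#' Build a logFC signature from a differential-expression table
#'
#' Keeps genes with `p < p_cut` and, when `apply_logfc_cut` is on, with
#' `|log2FC| >= logfc_cut`. The reference side of a cross-dataset map uses
#' both cuts (logFC cutoff 0.25, P < 0.05); the query side conventionally
#' uses the p cut only.
#'
#' @param de a DE tibble with `gene`, `log2FC`, `p` columns (e.g. from
#'   [find_markers()]).
#' @param logfc_cut absolute log2 fold-change cutoff (default 0.25).
#' @param p_cut p-value cutoff (default 0.05; applied to raw `p` — pass
#'   `use_adjusted = TRUE` to filter on `p_adj`).
#' @param apply_logfc_cut logical flag.
#' @param use_adjusted filter on `p_adj` instead of `p`.
#' @param source label recorded on the signature.
#' @return named numeric vector of log2FC (names = genes), class
#'   `mg_signature`, with `source` and `filters` attributes. Empty signatures
#'   are allowed, with a warning.
#' @export
build_signature <- function(de, logfc_cut = 0.25, p_cut = 0.05,
                            apply_logfc_cut = TRUE, use_adjusted = FALSE,
                            source = "signature") {
  stopifnot(all(c("gene", "log2FC", "p") %in% names(de)))
  pv <- if (use_adjusted) de$p_adj else de$p
  keep <- pv < p_cut
  if (apply_logfc_cut) keep <- keep & abs(de$log2FC) >= logfc_cut
  if (!any(keep)) warn(sprintf("signature %s is empty", source))
  structure(setNames(de$log2FC[keep], de$gene[keep]),
            source = source,
            filters = list(logfc_cut = if (apply_logfc_cut) logfc_cut else NA,
                           p_cut = p_cut, use_adjusted = use_adjusted),
            class = "mg_signature")
}

#' Convert a mouse signature to human identifiers through an ortholog table
#'
#' Conservative resolution: when a mouse gene has several human orthologs,
#' the human gene with the highest log2FC in the human reference table is
#' chosen (genes absent from the reference rank lowest; remaining ties break
#' alphabetically). When several mouse genes resolve to the same human gene,
#' the mouse gene with the highest mouse log2FC wins. Unmapped mouse genes
#' are dropped. The result is independent of the row order of the table.
#'
#' @param mouse_sig `mg_signature` on mouse identifiers.
#' @param table tibble with `mouse_gene`, `human_gene` columns.
#' @param human_ref tibble with `gene`, `log2FC`: the human reference used
#'   for one-to-many tie-breaking.
#' @return `mg_signature` on human identifiers; the per-gene decisions are
#'   attached as `attr(, "ledger")` (mouse_gene, human_gene, n_candidates,
#'   rule).
#' @export
convert_orthologs <- function(mouse_sig, table, human_ref) {
  stopifnot(all(c("mouse_gene", "human_gene") %in% names(table)))
  if (nrow(table) == 0) {
    warn("empty ortholog table; empty signature returned")
    return(structure(setNames(numeric(0), character(0)),
                     ledger = tibble(), class = "mg_signature"))
  }
  href <- setNames(human_ref$log2FC, human_ref$gene)
  tab <- table |>
    filter(.data$mouse_gene %in% names(mouse_sig)) |>
    distinct(.data$mouse_gene, .data$human_gene) |>
    arrange(.data$mouse_gene, .data$human_gene)  # order-independence
  if (nrow(tab) == 0) {
    warn("no signature gene is mapped by the table")
    return(structure(setNames(numeric(0), character(0)),
                     ledger = tibble(), class = "mg_signature"))
  }
  # one-to-many: best human ortholog by human-reference logFC
  tab$href_lfc <- unname(href[tab$human_gene])
  tab$href_lfc[is.na(tab$href_lfc)] <- -Inf
  step1 <- tab |>
    group_by(.data$mouse_gene) |>
    mutate(n_candidates = n()) |>
    arrange(dplyr::desc(.data$href_lfc), .data$human_gene,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  # many-to-one: best mouse gene by mouse logFC
  step1$mouse_lfc <- unname(mouse_sig[step1$mouse_gene])
  resolved <- step1 |>
    group_by(.data$human_gene) |>
    mutate(n_mouse = n()) |>
    arrange(dplyr::desc(.data$mouse_lfc), .data$mouse_gene,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(rule = dplyr::case_when(
      .data$n_candidates > 1 & .data$n_mouse > 1 ~ "one_to_many+many_to_one",
      .data$n_candidates > 1 ~ "one_to_many",
      .data$n_mouse > 1 ~ "many_to_one",
      TRUE ~ "one_to_one"))
  out <- setNames(resolved$mouse_lfc, resolved$human_gene)
  structure(out[order(names(out))],
            source = attr(mouse_sig, "source"),
            ledger = select(resolved, "mouse_gene", "human_gene",
                            "n_candidates", "n_mouse", "rule"),
            class = "mg_signature")
}

#' Pairwise Pearson correlation of logFC signatures
#'
#' For every (reference state, query cluster) pair, genes present in both
#' signatures are intersected; with at least `min_shared` shared genes the
#' Pearson correlation of the two logFC vectors is computed with a p-value
#' from the t transform on `n - 2` degrees of freedom. P-values are
#' Benjamini-Hochberg adjusted jointly across all cells of the map (use
#' `adjust = "bonferroni"` for family-wise control). With
#' `positive_only = TRUE`, cells with `r <= 0` are flagged as masked for
#' display; `r`, `p` and `p_adj` are retained.
#'
#' @param ref_sigs,query_sigs named lists of `mg_signature`s on one shared
#'   identifier namespace (convert first).
#' @param min_shared minimum shared genes per cell (default 10).
#' @param positive_only mask non-positive correlations for display.
#' @param adjust multiple-testing method across the map (default `"BH"`).
#' @return a `mg_correlation_map` tibble: `ref_state`, `query_cluster`, `r`,
#'   `p`, `p_adj`, `n_genes`, `masked`. Pairs below `min_shared` are reported
#'   with `NA` r/p.
#' @export
correlate_signatures <- function(ref_sigs, query_sigs, min_shared = 10,
                                 positive_only = FALSE, adjust = "BH") {
  stopifnot(length(ref_sigs) > 0, length(query_sigs) > 0)
  if (is.null(names(ref_sigs)) || is.null(names(query_sigs)))
    abort("signature lists must be named")
  grid <- tidyr::expand_grid(ref_state = names(ref_sigs),
                             query_cluster = names(query_sigs))
  res <- purrr::pmap_dfr(grid, function(ref_state, query_cluster) {
    a <- ref_sigs[[ref_state]]; b <- query_sigs[[query_cluster]]
    shared <- intersect(names(a), names(b))
    if (length(shared) < min_shared)
      return(tibble(ref_state, query_cluster, r = NA_real_, p = NA_real_,
                    n_genes = length(shared)))
    ct <- suppressWarnings(cor.test(unname(a[shared]), unname(b[shared]),
                                    method = "pearson"))
    tibble(ref_state, query_cluster, r = unname(ct$estimate),
           p = ct$p.value, n_genes = length(shared))
  })
  res$p_adj <- NA_real_
  ok <- !is.na(res$p)
  res$p_adj[ok] <- p.adjust(res$p[ok], method = adjust)
  res$masked <- positive_only & !is.na(res$r) & res$r <= 0
  structure(res, min_shared = min_shared, adjust = adjust,
            class = c("mg_correlation_map", class(res)))
}

#' Percentage of one gene set found in another, with Jaccard index
#'
#' @param set_a,set_b character vectors; `set_a` must be nonempty.
#' @return tibble `pct_a_in_b` (100 * |A n B| / |A|), `jaccard`,
#'   `n_a`, `n_b`, `n_shared`.
#' @export
signature_overlap_pct <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0) abort("`set_a` must be nonempty")
  shared <- length(intersect(set_a, set_b))
  tibble(pct_a_in_b = 100 * shared / length(set_a),
         jaccard = shared / length(union(set_a, set_b)),
         n_a = length(set_a), n_b = length(set_b), n_shared = shared)
}

#' Risk-gene detection and deregulation report
#'
#' For each panel gene (matched case-insensitively against matrix rownames):
#' the number of cells with at least one raw read, and per contrast the
#' log2FC where the contrast's adjusted p is below `sig_cut` (`NA` = not
#' significant). Rows are ordered by hierarchical clustering (Euclidean
#' distance, average linkage) of the logFC profiles (masked entries treated
#' as 0 for clustering only).
#'
#' @param counts raw genes x cells count matrix.
#' @param contrasts named list of DE tibbles (`gene`, `log2FC`, `p_adj`).
#' @param panel character vector of risk-gene names.
#' @param sig_cut adjusted-p cutoff for showing a logFC (default 0.05).
#' @return tibble: `gene` (matrix spelling), `panel_gene`, `found`,
#'   `n_cells_detected`, one `logFC_<contrast>` column per contrast, ordered
#'   by the clustering; missing panel genes keep `found = FALSE`.
#' @export
risk_gene_report <- function(counts, contrasts = list(), panel,
                             sig_cut = 0.05) {
  idx <- match(toupper(panel), toupper(rownames(counts)))
  found <- !is.na(idx)
  n_det <- rep(0L, length(panel))
  if (any(found)) {
    sub <- counts[idx[found], , drop = FALSE]
    n_det[found] <- as.integer(if (inherits(sub, "sparseMatrix"))
      Matrix::rowSums(sub >= 1) else rowSums(sub >= 1))
  }
  out <- tibble(gene = ifelse(found, rownames(counts)[idx], NA_character_),
                panel_gene = panel, found = found,
                n_cells_detected = n_det)
  for (nm in names(contrasts)) {
    de <- contrasts[[nm]]
    m <- match(toupper(out$panel_gene), toupper(de$gene))
    lfc <- de$log2FC[m]
    lfc[is.na(m) | de$p_adj[m] >= sig_cut] <- NA_real_
    out[[paste0("logFC_", nm)]] <- lfc
  }
  lfc_cols <- grep("^logFC_", names(out), value = TRUE)
  if (length(lfc_cols) >= 1 && nrow(out) > 2) {
    prof <- as.matrix(out[, lfc_cols, drop = FALSE])
    prof[is.na(prof)] <- 0
    ord <- hclust(dist(prof, method = "euclidean"),
                  method = "average")$order
    out <- out[ord, , drop = FALSE]
  }
  out
}
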