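de_fixture <- function() {
  tibble::tibble(
    gene = c("A", "B", "C", "D"),
    log2FC = c(0.3, 0.2, -0.5, 1.1),
    p = c(0.01, 0.01, 0.2, 0.001),
    p_adj = c(0.04, 0.04, 0.8, 0.004))
}

test_that("signature filters follow the reference/query asymmetry", {
  de <- de_fixture()
  ref <- build_signature(de, source = "ref")                 # both cuts
  expect_setequal(names(ref), c("A", "D"))                   # B fails 0.25
  qry <- build_signature(de, apply_logfc_cut = FALSE)        # p-only
  expect_setequal(names(qry), c("A", "B", "D"))
  tight <- build_signature(de, p_cut = 0.005,
                           apply_logfc_cut = FALSE)
  expect_true(all(names(tight) %in% names(qry)))             # monotone
  expect_warning(build_signature(de, p_cut = 1e-9), "empty")
})

test_that("ortholog conversion applies the conservative tie-breaks", {
  sig <- structure(c(m1 = 1.2, m2 = 0.4, m3 = 0.8),
                   class = "mg_signature")
  tab <- tibble::tibble(
    mouse_gene = c("m3", "m3", "m1", "m2", "m9"),
    human_gene = c("g1", "g2", "gShared", "gShared", "gX"))
  href <- tibble::tibble(gene = c("g1", "g2"), log2FC = c(0.5, 2.0))
  out <- convert_orthologs(sig, tab, href)
  expect_equal(unname(out["g2"]), 0.8)      # highest human-reference logFC
  expect_false("g1" %in% names(out))
  expect_equal(unname(out["gShared"]), 1.2) # highest mouse logFC wins
  expect_false("m9" %in% attr(out, "ledger")$mouse_gene)  # not in signature
  # bijective table: pure relabeling
  bij <- tibble::tibble(mouse_gene = c("m1", "m2", "m3"),
                        human_gene = c("h1", "h2", "h3"))
  rel <- convert_orthologs(sig, bij, href)
  expect_equal(sort(unname(rel)), sort(unname(sig)))
  # shuffling table rows changes nothing
  shuf <- tab[c(4, 1, 5, 3, 2), ]
  expect_identical(convert_orthologs(sig, shuf, href), out)
  expect_warning(convert_orthologs(sig, tab[0, ], href), "empty")
})

test_that("correlation maps behave at the fixed points and under symmetry", {
  withr::with_seed(10, {
    s1 <- structure(setNames(rnorm(50), sprintf("G%02d", 1:50)),
                    class = "mg_signature")
    s2 <- structure(setNames(rnorm(50), sprintf("G%02d", 1:50)),
                    class = "mg_signature")
  })
  self <- correlate_signatures(list(A = s1), list(A = s1))
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_lt(self$p, 1e-20)
  fwd <- correlate_signatures(list(A = s1), list(B = s2))
  rev <- correlate_signatures(list(B = s2), list(A = s1))
  expect_equal(fwd$r, rev$r)
  expect_equal(fwd$p, rev$p)
  # below min_shared -> missing, not zero
  tiny <- structure(setNames(rnorm(5), sprintf("G%02d", 1:5)),
                    class = "mg_signature")
  miss <- correlate_signatures(list(A = tiny), list(B = s2), min_shared = 10)
  expect_true(is.na(miss$r))
  expect_equal(miss$n_genes, 5)
})

test_that("BH adjustment is monotone and masking is presentation-only", {
  withr::with_seed(11, {
    refs <- lapply(setNames(1:4, paste0("R", 1:4)), function(i)
      structure(setNames(rnorm(60), sprintf("G%02d", 1:60)),
                class = "mg_signature"))
    qrys <- lapply(setNames(1:3, paste0("Q", 1:3)), function(i)
      structure(setNames(rnorm(60), sprintf("G%02d", 1:60)),
                class = "mg_signature"))
  })
  m0 <- correlate_signatures(refs, qrys)
  expect_true(all(diff(m0$p_adj[order(m0$p)]) >= -1e-12))
  m1 <- correlate_signatures(refs, qrys, positive_only = TRUE)
  expect_equal(m0$r, m1$r)
  expect_equal(m0$p_adj, m1$p_adj)
  expect_true(all(m1$masked == (m1$r <= 0)))
})

test_that("overlap percentages follow set arithmetic", {
  expect_equal(signature_overlap_pct(letters[1:4], letters[1:4])$pct_a_in_b,
               100)
  expect_equal(signature_overlap_pct(letters[1:3], letters[10:12])$pct_a_in_b,
               0)
  res <- signature_overlap_pct(c("a", "b", "c", "d"), c("a", "b", "x"))
  expect_equal(res$pct_a_in_b, 50)
  expect_equal(res$jaccard, 2 / 5)
  expect_error(signature_overlap_pct(character(0), "a"))
})

test_that("risk-gene report counts detection and masks non-significant logFC", {
  m <- random_counts(20, 50, lambda = 0.5, seed = 20, sparse = TRUE)
  de <- tibble::tibble(gene = rownames(m)[1:10],
                       log2FC = seq(-1, 1, length.out = 10),
                       p_adj = rep(c(0.01, 0.5), 5))
  rep1 <- risk_gene_report(m, list(ko = de),
                           panel = c(rownames(m)[1:10], "ABSENT"))
  dn <- as.matrix(m)
  for (g in rownames(m)[1:10]) {
    row <- rep1[rep1$panel_gene == g, ]
    expect_equal(row$n_cells_detected, sum(dn[g, ] >= 1))
  }
  absent <- rep1[rep1$panel_gene == "ABSENT", ]
  expect_false(absent$found)
  expect_equal(absent$n_cells_detected, 0L)
  sig_genes <- de$gene[de$p_adj < 0.05]
  shown <- rep1$panel_gene[!is.na(rep1$logFC_ko)]
  expect_setequal(shown, sig_genes)
  # case-insensitive matching; all-ones matrix detects everywhere
  ones <- matrix(1, 3, 4, dimnames = list(c("TREM2", "APOE", "BIN1"),
                                          paste0("c", 1:4)))
  rep2 <- risk_gene_report(ones, panel = c("trem2", "apoe"))
  expect_equal(rep2$n_cells_detected, c(4L, 4L))
})

test_that("planted reference-query correspondence is recovered through orthologs", {
  hits <- 0
  for (seed in 1:20) {
    withr::with_seed(seed, {
      genes_h <- sprintf("H%03d", 1:300)
      ref <- lapply(setNames(1:4, paste0("ref", 1:4)), function(i)
        structure(setNames(rnorm(300), genes_h), class = "mg_signature"))
      # query clusters = noisy copies of one reference each, via mouse names
      genes_m <- sprintf("M%03d", 1:300)
      tab <- tibble::tibble(mouse_gene = genes_m, human_gene = genes_h)
      qry <- lapply(setNames(1:4, paste0("qry", 1:4)), function(i) {
        noisy <- unname(ref[[i]]) + rnorm(300, sd = 0.6)
        convert_orthologs(
          structure(setNames(noisy, genes_m), class = "mg_signature"),
          tab, tibble::tibble(gene = genes_h, log2FC = 0))
      })
    })
    cm <- correlate_signatures(ref, qry)
    best <- cm |>
      dplyr::group_by(ref_state) |>
      dplyr::slice_max(r, n = 1) |>
      dplyr::pull(query_cluster)
    hits <- hits + all(best == paste0("qry", 1:4))
  }
  expect_gte(hits / 20, 0.95)
})
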