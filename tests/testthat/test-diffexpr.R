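test_that("log-normalization follows the CP10K formula and preserves zeros", {
  m <- matrix(c(0, 5, 5, 10, 0, 0), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  m[1, 2] <- 1  # avoid the all-zero cell error
  norm <- normalize_log(m)
  expect_equal(norm[1, 1], 0)
  expect_equal(norm[3, 2], 0)
  # a cell expressing one gene only hits log1p(scale)
  one <- matrix(c(7, 0), 2, 1, dimnames = list(c("a", "b"), "c"))
  expect_equal(normalize_log(one)[1, 1], log1p(1e4))
  # strictly increasing in counts within a cell
  expect_true(all(diff(normalize_log(matrix(1:5, 5, 1,
    dimnames = list(paste0("g", 1:5), "c")))[, 1]) > 0))
  expect_error(normalize_log(matrix(0, 2, 1,
    dimnames = list(c("a", "b"), "c"))), "filter_cells")
})

test_that("log2 fold changes match a dense two-pass oracle and are antisymmetric", {
  norm <- normalize_log(random_counts(40, 60, lambda = 2, seed = 8,
                                      sparse = TRUE))
  a <- colnames(norm)[1:30]; b <- colnames(norm)[31:60]
  lfc <- log_fold_change(norm, a, b)
  dn <- as.matrix(norm)
  oracle <- log2((rowMeans(expm1(dn[, a])) + 1) /
                   (rowMeans(expm1(dn[, b])) + 1))
  expect_equal(lfc, oracle, tolerance = 1e-12)
  expect_equal(log_fold_change(norm, b, a), -lfc, tolerance = 1e-12)
  # groups with identical expression give exactly zero
  dup <- cbind(dn[, a], dn[, a])
  colnames(dup) <- c(paste0("L", 1:30), paste0("R", 1:30))
  expect_equal(unname(log_fold_change(dup, paste0("L", 1:30),
                                      paste0("R", 1:30))),
               rep(0, 40), tolerance = 1e-15)
  expect_error(log_fold_change(norm, a, character(0)))
  expect_error(log_fold_change(norm, a, a))
})

test_that("wilcoxon exact mode enumerates arrangements correctly", {
  # 2 of the C(6,3) = 20 assignments are as extreme as (1,2,3) vs (4,5,6)
  expect_equal(wilcoxon_test(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p, 0.1)
  expect_equal(wilcoxon_test(c(4, 5, 6), c(1, 2, 3), mode = "exact")$p, 0.1)
  expect_equal(wilcoxon_test(c(2, 2), c(2, 2))$p, 1)  # fully tied
  x <- c(3.2, 1.5, 8, 0.1, 2.2); y <- c(4.4, 9, 0.7, 6.1)
  expect_equal(wilcoxon_test(x, y, mode = "approx")$p,
               wilcoxon_test(y, x, mode = "approx")$p)  # label symmetry
  expect_error(wilcoxon_test(numeric(0), 1))
})

test_that("exact and approximate modes agree with stats::wilcox.test", {
  withr::with_seed(14, {
    for (i in 1:25) {
      a <- sample(100, 5); b <- sample(100, 6) + 0.5  # tie-free
      expect_equal(wilcoxon_test(a, b, mode = "exact")$p,
                   wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
      a2 <- rnorm(30); b2 <- rnorm(25)
      expect_equal(wilcoxon_test(a2, b2, mode = "approx")$p,
                   wilcox.test(a2, b2, exact = FALSE,
                               correct = TRUE)$p.value,
                   tolerance = 1e-12)
      # tied data: tie-corrected variance must match too
      a3 <- rpois(20, 2); b3 <- rpois(22, 2)
      expect_equal(wilcoxon_test(a3, b3, mode = "approx")$p,
                   suppressWarnings(wilcox.test(a3, b3, exact = FALSE,
                                                correct = TRUE)$p.value),
                   tolerance = 1e-12)
    }
  })
})

test_that("approximate p tracks exact p on small tie-free samples", {
  gap_by_n <- vapply(2:6, function(n) {
    sets <- combn(2 * n, n)
    ranks <- seq_len(2 * n)
    max(vapply(seq_len(ncol(sets)), function(j) {
      a <- ranks[sets[, j]]; b <- ranks[-sets[, j]]
      abs(wilcoxon_test(a, b, mode = "approx")$p -
            wilcoxon_test(a, b, mode = "exact")$p)
    }, numeric(1)))
  }, numeric(1))
  # the continuity-corrected normal approximation converges on the exact
  # distribution as n grows: within 0.02 from n = 5, within 0.04 at n = 3-4,
  # and structurally coarser at n = 2 (exact 1/3 vs approx 0.245 in the
  # extreme arrangement) - which is why exact mode is the automatic choice
  # whenever the total sample is 12 or smaller
  expect_lte(max(gap_by_n[4:5]), 0.02)
  expect_lte(max(gap_by_n[2:3]), 0.04)
  expect_lte(gap_by_n[1], 0.09)
  expect_true(all(diff(gap_by_n) < 0))
})

test_that("marker prefilters enforce the 1% detection and 0.1 log-fold rules", {
  withr::with_seed(5, {
    counts <- matrix(rpois(200 * 400, 1), 200, 400,
                     dimnames = list(sprintf("g%03d", 1:200),
                                     sprintf("c%03d", 1:400)))
    # gene detected in 0.5% of both groups must be absent
    counts["g001", ] <- 0
    counts["g001", c(1, 201)] <- 50
  })
  norm <- normalize_log(counts)
  a <- colnames(norm)[1:200]; b <- colnames(norm)[201:400]
  tab <- find_markers(norm, a, b)
  expect_false("g001" %in% tab$gene)
  expect_true(all(pmax(tab$pct_a, tab$pct_b) >= 0.01))
  expect_true(all(abs(tab$log2FC) >= 0.1 / log(2)))
  expect_true(all(tab$p_adj >= tab$p))
  expect_true(all(tab$p_adj <= 1))
  # relaxing the prefilters yields a superset
  relaxed <- find_markers(norm, a, b, min_pct = 0, logfc_threshold = 0.01)
  expect_true(all(tab$gene %in% relaxed$gene))
})

test_that("planted program genes are recovered with positive logFC", {
  cfg <- sim_cohort_config(
    n_groups = 1, group_names = "g", mice_per_group = 2,
    cells_per_mouse = 220, n_genes = 500, n_mito_genes = 0,
    state_names = c("DAM", "HM"), state_proportions = matrix(0.5, 1, 2),
    program_size = 20, program_log2_effect = 1,
    doublet_rate = 0, negative_rate = 0, seed = 77)
  sim <- simulate_cohort(cfg)
  norm <- normalize_log(sim$counts)
  dam <- sim$truth$barcode[sim$truth$true_state == "DAM"]
  hm <- sim$truth$barcode[sim$truth$true_state == "HM"]
  tab <- find_markers(norm, dam, hm, group_a = "DAM", group_b = "HM")
  prog <- sim$genes$gene[!is.na(sim$genes$program_state) &
                           sim$genes$program_state == "DAM"]
  hit <- prog %in% tab$gene[tab$p_adj < 0.05 & tab$log2FC > 0]
  expect_gte(mean(hit), 0.9)
})

test_that("one-vs-rest tables equal independent find_markers calls", {
  sim <- simulate_cohort(small_cohort_config(seed = 55))
  keep <- sim$truth$barcode[sim$truth$droplet_type == "singlet"][1:200]
  norm <- normalize_log(sim$counts[, keep])
  labels <- sim$truth$true_state[match(keep, sim$truth$barcode)]
  labels <- ifelse(labels %in% c("DAM", "HLA"), labels, "other")
  all_tabs <- find_all_markers(norm, labels)
  dam_cells <- keep[labels == "DAM"]
  direct <- find_markers(norm, dam_cells, setdiff(keep, dam_cells),
                         group_a = "DAM", group_b = "rest")
  expect_equal(all_tabs$DAM$gene, direct$gene)
  expect_equal(all_tabs$DAM$p, direct$p)
})
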