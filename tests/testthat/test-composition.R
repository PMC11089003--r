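test_that("composition tables tally proportions with zero-filled states", {
  tab <- proportions(labels = c("HM", "HM", "HM", "DAM"),
                     samples = rep("m1", 4), groups = c(m1 = "WT"))
  expect_equal(tab$HM, 0.75)
  expect_equal(tab$DAM, 0.25)

  withr::with_seed(9, {
    labs <- sample(c("A", "B", "C"), 500, replace = TRUE)
    samp <- sample(paste0("m", 1:6), 500, replace = TRUE)
  })
  groups <- setNames(rep(c("g1", "g2"), each = 3), paste0("m", 1:6))
  tab2 <- proportions(labs, samp, groups)
  expect_true(all(abs(rowSums(tab2[, c("A", "B", "C")]) - 1) < 1e-9))
  # brute-force tally oracle
  for (m in paste0("m", 1:6)) for (s in c("A", "B", "C"))
    expect_equal(tab2[[s]][tab2$sample == m],
                 sum(labs == s & samp == m) / sum(samp == m))
  expect_warning(proportions(labs, samp, c(groups, m7 = "g1")), "0 cells")
})

test_that("welch test matches the closed-form computation and its symmetries", {
  tab <- tibble::tibble(sample = paste0("m", 1:6),
                        group = rep(c("A", "B"), each = 3),
                        n_cells = 100,
                        DAM = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  res <- welch_test(tab, "DAM", "A", "B")
  # hand-evaluated Welch formula
  x <- c(0.1, 0.2, 0.3); y <- c(0.4, 0.5, 0.6)
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  # swapping groups negates t, keeps p
  swap <- welch_test(tab, "DAM", "B", "A")
  expect_equal(swap$statistic, -res$statistic)
  expect_equal(swap$p, res$p)
  # identical values: t = 0, p = 1
  tab$DAM <- 0.2
  degen <- welch_test(tab, "DAM", "A", "B")
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p, 1)
  expect_error(welch_test(tab[1:3, ], "DAM", "A", "B"))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$p.value, res$p)
})

test_that("anova/tukey hits the degenerate fixed points and routes k = 2 to welch", {
  tab <- tibble::tibble(sample = paste0("m", 1:9),
                        group = rep(c("A", "B", "C"), each = 3),
                        n_cells = 100,
                        HM = rep(0.5, 9))
  res <- anova_tukey(tab, "HM")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(nrow(res$pairwise), 3)
  expect_warning(two <- anova_tukey(tab[1:6, ], "HM"), "welch")
  expect_equal(two$method, "welch_t")
  tab_bad <- tab[c(1:4, 7), ]
  expect_error(anova_tukey(tab_bad, "HM"), "single sample")
  # matches aov on real data
  withr::with_seed(2, tab$HM <- runif(9, 0.2, 0.6))
  res2 <- anova_tukey(tab, "HM")
  ref <- summary(aov(HM ~ group, data = tab))[[1]]
  expect_equal(res2$statistic, ref$`F value`[1])
  expect_equal(res2$p, ref$`Pr(>F)`[1])
})

test_that("welch type-I error is controlled at nominal level", {
  withr::with_seed(31, {
    rej <- replicate(800, {
      tab <- tibble::tibble(sample = paste0("m", 1:12),
                            group = rep(c("A", "B"), each = 6),
                            n_cells = 100, s = rnorm(12, 0.3, 0.05))
      welch_test(tab, "s", "A", "B")$p < 0.05
    })
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("embedding density normalizes each sample's contribution", {
  # two well-separated samples with a 20x size imbalance: under per-sample
  # weighting each must carry mass 1/2 on its side of the midline
  withr::with_seed(4, {
    big <- cbind(rnorm(2000), rnorm(2000))
    small <- cbind(rnorm(100, 12), rnorm(100, 12))
  })
  emb <- rbind(big, small)
  samples <- c(rep("mBig", 2000), rep("mSmall", 100))
  dens <- embedding_density(emb, samples, c(mBig = "g", mSmall = "g"),
                            grid_n = 150)
  area <- attr(dens, "cell_area")
  expect_equal(sum(dens$density) * area, 1, tolerance = 1e-2)
  small_side <- dens$x + dens$y > 12
  expect_equal(sum(dens$density[small_side]) * area, 0.5, tolerance = 1e-2)
  expect_identical(dens$density,
                   embedding_density(emb, samples,
                                     c(mBig = "g", mSmall = "g"),
                                     grid_n = 150)$density)
  # single sample: grid integral is 1
  d1 <- embedding_density(big, rep("m", 2000), c(m = "g"), grid_n = 120)
  expect_equal(sum(d1$density) * attr(d1, "cell_area"), 1,
               tolerance = 1e-3)
})

test_that("pseudotime binning partitions mass per sample and group", {
  withr::with_seed(12, {
    pt <- runif(4000)
    samp <- sample(paste0("m", 1:8), 4000, replace = TRUE)
  })
  groups <- setNames(rep(c("A", "B"), each = 4), paste0("m", 1:8))
  bp <- bin_pseudotime(pt, samp, groups, n_bins = 20)
  sums <- tapply(bp$samples$prop, bp$samples$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # uniform pseudotime: each bin proportion near 1/20 within 3 s.e.
  per_group_n <- table(groups[samp])
  se <- sqrt(0.05 * 0.95 / min(per_group_n))
  expect_true(all(abs(bp$groups$prop - 0.05) < 3 * se + 0.01))
  expect_equal(nrow(bp$tests), 20)
  one <- bin_pseudotime(pt, samp, groups, n_bins = 1)
  expect_true(all(one$samples$prop == 1))
})
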