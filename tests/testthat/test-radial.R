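test_that("plaque detection finds disks with accurate centroids and areas", {
  expect_equal(nrow(detect_plaques(matrix(0, 50, 50), 1)), 0)
  img <- matrix(0, 101, 101)
  rows <- matrix(seq_len(101), 101, 101)
  cols <- t(rows)
  r <- 10
  disk <- (rows - 40)^2 + (cols - 60)^2 <= r^2
  img[disk] <- 1
  pl <- detect_plaques(img, 1, threshold = 0.5)
  expect_equal(nrow(pl), 1)
  expect_lt(sqrt((pl$center_row - 40)^2 + (pl$center_col - 60)^2), 1)
  expect_lt(abs(pl$area_um2 - pi * r^2) / (pi * r^2), 0.05)
  # two disjoint disks, 8-connectivity keeps a diagonal bridge whole
  img2 <- img
  img2[(rows - 85)^2 + (cols - 20)^2 <= 36] <- 1
  expect_equal(nrow(detect_plaques(img2, 1, threshold = 0.5)), 2)
  diagm <- matrix(0, 6, 6); diagm[cbind(1:4, 1:4)] <- 1
  expect_equal(nrow(detect_plaques(diagm, 1, threshold = 0.5,
                                   min_area_um2 = 1)), 1)
  # otsu threshold separates a bright disk from mild background noise
  withr::with_seed(5, img3 <- img + matrix(runif(101 * 101, 0, 0.2), 101))
  pl3 <- detect_plaques(img3, 1, threshold = "otsu")
  expect_equal(nrow(pl3), 1)
})

test_that("annulus means match a brute-force pixel loop on a step function", {
  im <- centered_plaque_image(size = 181)
  step <- list(step = (sqrt(outer((1:181 - 91)^2, (1:181 - 91)^2, `+`)) <
                         10) * 1)
  rows <- annulus_means(step, c(91, 91), 1)
  # annuli 0-2 cover 0-10 um: all inside the step
  expect_true(all(rows$mean_intensity[1:3] > 0.97))
  expect_true(all(rows$mean_intensity[4:24] < 0.03))
  # constant image: every annulus mean equals the constant
  const <- annulus_means(list(k = matrix(2.5, 181, 181)), c(91, 91), 1)
  expect_true(all(abs(const$mean_intensity - 2.5) < 1e-12))
  # pixel partition: annulus counts sum to the pixels within 80 um
  d <- sqrt(outer((1:181 - 91)^2, (1:181 - 91)^2, `+`))
  expect_equal(sum(rows$n_pixels), sum(d < 80))
  # brute-force mean oracle per annulus
  idx <- floor(d / (10 / 3))
  for (a in c(0, 5, 23)) {
    expect_equal(rows$mean_intensity[rows$annulus_index == a],
                 mean(step$step[idx == a]))
  }
  expect_error(annulus_means(step, c(500, 500), 1), "outside")
})

test_that("z-scoring standardizes channels and is affine-invariant", {
  im <- centered_plaque_image(size = 121)
  prof <- annulus_means(im$channels["up"], im$center, 1)
  z <- zscore_profiles(prof)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(sd(z$z), 1, tolerance = 1e-9)
  aff <- prof |> dplyr::mutate(mean_intensity = 3 * mean_intensity + 7)
  expect_equal(zscore_profiles(aff)$z, z$z, tolerance = 1e-9)
  # two-value channel under sample s.d.
  two <- tibble::tibble(plaque_id = 1, annulus_index = 0:1,
                        inner_radius_um = c(0, 1), outer_radius_um = c(1, 2),
                        channel = "x", mean_intensity = c(1, 3),
                        n_pixels = 5L)
  expect_equal(zscore_profiles(two)$z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("local regression is exact on lines, flat on constants, and matches WLS", {
  x <- seq(0, 10, length.out = 25)
  lin <- loess_curve(x, 2 * x + 1, span = 0.6)
  expect_lt(max(abs(lin$fitted - (2 * x + 1))), 1e-8)
  con <- loess_curve(x, rep(4, 25), span = 0.5)
  expect_lt(max(abs(con$fitted - 4)), 1e-10)
  expect_lt(max(con$se), 1e-8)
  withr::with_seed(8, y <- sin(x) + rnorm(25, 0, 0.2))
  fit <- loess_curve(x, y, span = 0.75, degree = 1)
  # per-point brute-force weighted least squares oracle
  n <- length(x); q <- ceiling(0.75 * n)
  for (i in c(1, 7, 13, 25)) {
    d <- abs(x - x[i]); dq <- sort(d)[q]
    w <- ifelse(d <= dq, (1 - pmin(d / dq, 1)^3)^3, 0)
    ora <- lm(y ~ I(x - x[i]), weights = w)
    expect_equal(fit$fitted[i], unname(coef(ora)[1]), tolerance = 1e-8)
  }
  expect_error(loess_curve(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(loess_curve(1:3, 1:3))
})

test_that("near/far testing detects planted gradients in the right direction", {
  cfg <- sim_image_config(image_size_px = c(420, 420), n_plaques = 8,
                          noise_sd = 0.05, psf_sigma_um = 1, seed = 61)
  img <- simulate_plaque_image(cfg)
  truth_pl <- img$truth |>
    dplyr::mutate(plaque_id = dplyr::row_number())
  prof <- radial_profile(img, truth_pl)
  z <- zscore_profiles(prof)
  up <- near_far_test(z, "CD9", alternative = "near_greater")
  expect_lt(up$p, 0.05)
  down_ok <- near_far_test(z, "P2RY12", alternative = "far_greater")
  expect_lt(down_ok$p, 0.05)
  down_bad <- near_far_test(z, "P2RY12", alternative = "near_greater")
  expect_gt(down_bad$p, 0.5)
  expect_s3_class(tidy(up), "tbl_df")
})

test_that("identical near and far values give t = 0, one-tailed p = 0.5", {
  flat <- tibble::tibble(
    plaque_id = rep(1:3, each = 24), annulus_index = rep(0:23, 3),
    inner_radius_um = rep(0:23, 3) * 10 / 3,
    outer_radius_um = rep(1:24, 3) * 10 / 3,
    channel = "c", mean_intensity = 1, n_pixels = 10L, z = 0)
  res <- near_far_test(flat, "c")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.5)
})

test_that("rotating a noise-free image changes annulus means by under 1%", {
  im <- centered_plaque_image(size = 161, lambda = 25)
  prof <- annulus_means(im$channels["up"], im$center, 1)
  rot <- list(up = t(im$channels$up)[ncol(im$channels$up):1, ])  # 90 degrees
  prof_rot <- annulus_means(rot, im$center, 1)
  rel <- abs(prof$mean_intensity - prof_rot$mean_intensity) /
    prof$mean_intensity
  expect_lt(max(rel), 0.01)
})

test_that("exponential decay length is recovered within 20% without noise", {
  for (lam in c(10, 25, 40)) {
    im <- centered_plaque_image(size = 181, lambda = lam)
    prof <- annulus_means(im$channels["up"], im$center, 1)
    fit <- fit_radial_decay(prof, "up", "up")
    expect_lt(abs(fit$decay_length_um - lam) / lam, 0.2)
  }
})

test_that("detected centers reproduce truth-center annulus means at high SNR", {
  cfg <- sim_image_config(image_size_px = c(300, 300), n_plaques = 4,
                          noise_sd = 0.01, psf_sigma_um = 1, seed = 33)
  img <- simulate_plaque_image(cfg)
  det <- detect_plaques(img$channels$plaque, img$pixel_size_um,
                        threshold = "otsu", min_area_um2 = 20)
  expect_equal(nrow(det), 4)
  truth_pl <- img$truth |> dplyr::mutate(plaque_id = dplyr::row_number())
  # match detected plaques to truth by nearest center
  ord <- apply(as.matrix(dist(rbind(
    as.matrix(det[, c("center_row", "center_col")]),
    as.matrix(truth_pl[, c("center_row", "center_col")])
  )))[seq_len(4), 4 + seq_len(4), drop = FALSE], 2, which.min)
  det_matched <- det[ord, ] |> dplyr::mutate(plaque_id = dplyr::row_number())
  p_true <- radial_profile(img, truth_pl, channels = "CD9")
  p_det <- radial_profile(img, det_matched, channels = "CD9")
  ok <- !is.na(p_true$mean_intensity) & !is.na(p_det$mean_intensity)
  rel <- abs(p_true$mean_intensity[ok] - p_det$mean_intensity[ok]) /
    pmax(p_true$mean_intensity[ok], 1e-9)
  expect_lt(max(rel), 0.02)
})
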