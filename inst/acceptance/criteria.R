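# Measurement harness for the package's headline checks. Every function
# runs the installed package on freshly generated inputs and returns the
# measured quantity; nothing here asserts. Used by tests/testthat/
# test-acceptance.R and scripts/acceptance.R.

acc_amplicons <- function() {
  ko <- mgstates::predict_genotyping_amplicons(755, c(148, 187))
  list(wt_amplicon_bp = ko$wt_amplicon_bp,
       ko_amplicon_bp = ko$mutant_amplicon_bp,
       deletion_total_bp = sum(c(148, 187)))
}

# exhaustive sweep over all tie-free rank arrangements, n_a = n_b = 2..6
acc_wilcoxon <- function() {
  exact_gap <- 0
  approx_gap <- numeric(5)
  for (n in 2:6) {
    sets <- utils::combn(2 * n, n)
    ranks <- seq_len(2 * n)
    for (j in seq_len(ncol(sets))) {
      a <- ranks[sets[, j]]; b <- ranks[-sets[, j]]
      pe <- mgstates::wilcoxon_test(a, b, mode = "exact")$p
      pa <- mgstates::wilcoxon_test(a, b, mode = "approx")$p
      # independent enumeration oracle
      po <- stats::wilcox.test(a, b, exact = TRUE)$p.value
      exact_gap <- max(exact_gap, abs(pe - po))
      approx_gap[n - 1] <- max(approx_gap[n - 1], abs(pa - pe))
    }
  }
  list(exact_max_gap = exact_gap,
       approx_max_gap = max(approx_gap),
       approx_max_gap_n5plus = max(approx_gap[4:5]))
}

# one random QC instance: genes x cells counts with depth/mito structure
acc_qc_instance <- function(seed, n_genes = 200, n_cells = 500) {
  withr::with_seed(seed, {
    gene_w <- rexp(n_genes) + 0.02
    gene_w[1:10] <- gene_w[1:10] * runif(1, 2, 8)  # mito block
    gene_w <- gene_w / sum(gene_w)
    depth <- exp(rnorm(n_cells, log(1100), 0.45))
    m <- matrix(rpois(n_genes * n_cells, outer(gene_w, depth)),
                n_genes, n_cells,
                dimnames = list(c(sprintf("MT-%02d", 1:10),
                                  sprintf("G%03d", 11:n_genes)),
                                sprintf("c%04d", seq_len(n_cells))))
  })
  m
}

acc_qc_agreement <- function(seed, n_matrices = 100) {
  ok <- logical(n_matrices)
  for (i in seq_len(n_matrices)) {
    m <- acc_qc_instance(seed + i)
    libs <- rep(c("L1", "L2"), length.out = ncol(m))
    qc <- mgstates::compute_cell_qc(m, library_id = libs)
    res <- suppressWarnings(mgstates::filter_cells(qc))
    kept_genes <- mgstates::filter_genes(m)

    # dense brute-force oracle, plain base R
    tot <- apply(m, 2, sum)
    ng <- apply(m > 0, 2, sum)
    mito <- apply(m[1:10, , drop = FALSE], 2, sum)
    mf <- ifelse(tot > 0, mito / tot, 0)
    qc_ok <- all(qc$total_counts == tot) && all(qc$n_genes == ng) &&
      max(abs(qc$mito_fraction - mf)) < 1e-12
    stage1 <- tot >= 1000 & ng >= 100 & mf <= 0.15
    removed <- colnames(m)[!stage1]
    for (lib in unique(libs)) {
      sel <- stage1 & libs == lib
      if (sum(sel) < 3) next
      for (x in list(tot[sel], ng[sel])) {
        if (stats::sd(x) == 0) next
        out <- abs(x - mean(x)) > 3 * stats::sd(x)
        removed <- union(removed, colnames(m)[sel][out])
      }
    }
    kept_oracle <- setdiff(colnames(m), removed)
    genes_oracle <- rownames(m)[apply(m > 0, 1, sum) >= 3]
    ok[i] <- qc_ok && setequal(res$kept, kept_oracle) &&
      identical(kept_genes, genes_oracle)
  }
  100 * mean(ok)
}

acc_demux <- function(seed, n_cohorts = 100) {
  acc <- rec <- matrix(NA_real_, n_cohorts, 2)
  for (i in seq_len(n_cohorts)) {
    cfg <- mgstates::sim_cohort_config(
      mice_per_group = 3, cells_per_mouse = 100, n_genes = 60,
      n_mito_genes = 6, program_size = 5, seed = seed + i)
    sim <- mgstates::simulate_cohort(cfg)
    calls <- suppressWarnings(mgstates::demultiplex_hashes(sim$hashes))
    tr <- merge(calls[, c("barcode", "call", "assigned_sample")],
                sim$truth, by = "barcode")
    sing <- tr[tr$droplet_type == "singlet" & tr$call == "singlet", ]
    dbl <- tr[tr$droplet_type == "doublet", ]
    acc[i, ] <- c(sum(sing$assigned_sample == sing$true_sample), nrow(sing))
    rec[i, ] <- c(sum(dbl$call == "doublet"), nrow(dbl))
  }
  list(singlet_accuracy_pct = 100 * sum(acc[, 1]) / sum(acc[, 2]),
       doublet_recall_pct = 100 * sum(rec[, 1]) / sum(rec[, 2]),
       n_cohorts = n_cohorts)
}

marker_cohort <- function(seed, n_states = 2, n_genes = 500,
                          cells_per_mouse = 220) {
  states <- paste0("S", seq_len(n_states))
  mgstates::sim_cohort_config(
    n_groups = 1, group_names = "g", mice_per_group = 2,
    cells_per_mouse = cells_per_mouse, n_genes = n_genes, n_mito_genes = 0,
    state_names = states,
    state_proportions = matrix(1 / n_states, 1, n_states),
    program_size = 20, program_log2_effect = 1,
    doublet_rate = 0, negative_rate = 0, seed = seed)
}

acc_marker_recovery <- function(seed, n_seeds = 5) {
  hit <- integer(0)
  for (i in seq_len(n_seeds)) {
    sim <- mgstates::simulate_cohort(marker_cohort(seed + i))
    norm <- mgstates::normalize_log(sim$counts)
    s1 <- sim$truth$barcode[sim$truth$true_state == "S1"]
    s2 <- sim$truth$barcode[sim$truth$true_state == "S2"]
    tab <- mgstates::find_markers(norm, s1, s2)
    prog <- sim$genes$gene[!is.na(sim$genes$program_state) &
                             sim$genes$program_state == "S1"]
    hit <- c(hit, prog %in% tab$gene[tab$p_adj < 0.05 & tab$log2FC > 0])
  }
  100 * mean(hit)
}

acc_marker_null_fwer <- function(seed, n_seeds = 100) {
  any_fp <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- mgstates::sim_cohort_config(
      n_groups = 1, group_names = "g", mice_per_group = 2,
      cells_per_mouse = 200, n_genes = 1000, n_mito_genes = 0,
      state_names = "HM", state_proportions = matrix(1, 1, 1),
      program_size = 20, doublet_rate = 0, negative_rate = 0,
      seed = seed + i)
    sim <- mgstates::simulate_cohort(cfg)
    norm <- mgstates::normalize_log(sim$counts)
    cells <- colnames(norm)
    grp <- withr::with_seed(seed + i + 500000L,
                            sample(cells, length(cells) / 2))
    tab <- mgstates::find_markers(norm, grp, setdiff(cells, grp))
    any_fp[i] <- any(tab$p_adj < 0.05)
  }
  mean(any_fp)
}

acc_mapping_recovery <- function(seed, n_seeds = 100) {
  ok <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    withr::with_seed(seed + i, {
      tab <- mgstates::make_ortholog_table(
        300, c(one_to_one = 0.7, one_to_many = 0.1, many_to_one = 0.1,
               unmapped = 0.1), fan_out = 2, seed = seed + i)
      genes_h <- unique(tab$human_gene)
      refs <- lapply(stats::setNames(1:4, paste0("ref", 1:4)), function(k)
        structure(stats::setNames(rnorm(length(genes_h)), genes_h),
                  class = "mg_signature"))
      href <- tibble::tibble(gene = genes_h,
                             log2FC = unname(refs[[1]][genes_h]))
      qrys <- lapply(stats::setNames(1:4, paste0("qry", 1:4)), function(k) {
        mouse_genes <- unique(tab$mouse_gene)
        # each mouse gene copies one of its human partners, plus noise
        vals <- vapply(mouse_genes, function(m) {
          h <- tab$human_gene[tab$mouse_gene == m]
          unname(refs[[k]][h[1]])
        }, numeric(1))
        sig <- structure(stats::setNames(vals + rnorm(length(vals), 0, 0.6),
                                         mouse_genes),
                         class = "mg_signature")
        mgstates::convert_orthologs(sig, tab, href)
      })
    })
    cm <- mgstates::correlate_signatures(refs, qrys)
    best <- vapply(paste0("ref", 1:4), function(rs) {
      sub <- cm[cm$ref_state == rs, ]
      sub$query_cluster[which.max(sub$r)]
    }, character(1))
    ok[i] <- all(best == paste0("qry", 1:4))
  }
  100 * mean(ok)
}

acc_mapping_null <- function(seed, n_seeds = 100, n_genes = 500) {
  small <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    withr::with_seed(seed + i, {
      g <- sprintf("G%03d", seq_len(n_genes))
      s1 <- structure(stats::setNames(rnorm(n_genes), g),
                      class = "mg_signature")
      s2 <- structure(stats::setNames(rnorm(n_genes), g),
                      class = "mg_signature")
    })
    cm <- mgstates::correlate_signatures(list(a = s1), list(b = s2))
    small[i] <- abs(cm$r) < 0.15
  }
  100 * mean(small)
}

acc_composition_recovery <- function(seed, n_seeds = 100) {
  planted <- c("DAM", "HLA", "CRM-1")
  flags <- logical(0)
  for (i in seq_len(n_seeds)) {
    # ~1,300 cells per mouse matches the scale of a real xenograft cohort
    cfg <- mgstates::sim_cohort_config(
      mice_per_group = 6, cells_per_mouse = 1300, n_genes = 20,
      n_mito_genes = 2, program_size = 2, doublet_rate = 0,
      negative_rate = 0, seed = seed + i)
    sim <- mgstates::simulate_cohort(cfg)
    tab <- mgstates::proportions(sim$truth$true_state,
                                 sim$truth$true_sample,
                                 sim$truth$true_group)
    for (st in planted) {
      wt <- mgstates::welch_test(tab, st, "App_NLGF", "App_WT")
      flags <- c(flags, wt$p < 0.05 && wt$estimate["mean_a"] >
                   wt$estimate["mean_b"])
    }
  }
  100 * mean(flags)
}

acc_welch_type1 <- function(seed, n_draws = 2000) {
  withr::with_seed(seed, {
    rej <- replicate(n_draws, {
      tab <- tibble::tibble(sample = paste0("m", 1:12),
                            group = rep(c("A", "B"), each = 6),
                            n_cells = 1, s = rnorm(12, 0.3, 0.05))
      mgstates::welch_test(tab, "s", "A", "B")$p < 0.05
    })
  })
  mean(rej)
}

acc_lambda_recovery <- function(seed) {
  rel <- vapply(c(10, 25, 40), function(lam) {
    cfg <- mgstates::sim_image_config(
      image_size_px = c(240, 240), n_plaques = 1, noise_sd = 0,
      psf_sigma_um = 0, margin_um = 85,
      channel_models = list(up = list(amplitude = 1, decay_length_um = lam,
                                      baseline = 0.2,
                                      direction = "up_near_plaque")),
      seed = seed)
    img <- mgstates::simulate_plaque_image(cfg)
    truth <- img$truth
    prof <- mgstates::annulus_means(img$channels["up"],
                                    c(truth$center_row, truth$center_col),
                                    img$pixel_size_um)
    fit <- mgstates::fit_radial_decay(prof, "up", "up")
    abs(fit$decay_length_um - lam) / lam
  }, numeric(1))
  100 * max(rel)
}

acc_nearfar_power <- function(seed, n_seeds = 100) {
  up_ok <- down_ok <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- mgstates::sim_image_config(
      image_size_px = c(420, 420), n_plaques = 8, noise_sd = 0.05,
      psf_sigma_um = 1, seed = seed + i)
    img <- mgstates::simulate_plaque_image(cfg)
    pls <- img$truth
    z <- mgstates::zscore_profiles(mgstates::radial_profile(img, pls))
    up_ok[i] <- mgstates::near_far_test(z, "CD9",
                                        alternative = "near_greater")$p < 0.05
    down_ok[i] <- mgstates::near_far_test(z, "P2RY12",
                                          alternative = "far_greater")$p < 0.05
  }
  list(up_pct = 100 * mean(up_ok), down_pct = 100 * mean(down_ok))
}

acc_rotation_invariance <- function(seed) {
  cfg <- mgstates::sim_image_config(
    image_size_px = c(301, 301), n_plaques = 1, noise_sd = 0,
    psf_sigma_um = 0, margin_um = 85, seed = seed)
  img <- mgstates::simulate_plaque_image(cfg)
  ctr <- c(img$truth$center_row, img$truth$center_col)
  prof <- mgstates::annulus_means(img$channels["CD9"], ctr,
                                  img$pixel_size_um)
  n <- nrow(img$channels$CD9)
  rot <- t(img$channels$CD9)[n:1, , drop = FALSE]        # 90 deg CCW
  ctr_rot <- c(n + 1 - ctr[2], ctr[1])
  prof_rot <- mgstates::annulus_means(list(CD9 = rot), ctr_rot,
                                      img$pixel_size_um)
  ok <- !is.na(prof$mean_intensity) & !is.na(prof_rot$mean_intensity)
  100 * max(abs(prof$mean_intensity[ok] - prof_rot$mean_intensity[ok]) /
              pmax(abs(prof$mean_intensity[ok]), 1e-12))
}

acc_loess <- function(seed) {
  withr::with_seed(seed, {
    x <- sort(runif(40, 0, 10))
    y <- sin(x) + rnorm(40, 0, 0.25)
  })
  fit <- mgstates::loess_curve(x, y, span = 0.75, degree = 1)
  n <- length(x); q <- ceiling(0.75 * n)
  gap <- max(vapply(seq_len(n), function(i) {
    d <- abs(x - x[i]); dq <- sort(d)[q]
    w <- ifelse(d <= dq, (1 - pmin(d / dq, 1)^3)^3, 0)
    ora <- stats::lm(y ~ I(x - x[i]), weights = w)
    abs(fit$fitted[i] - unname(stats::coef(ora)[1]))
  }, numeric(1)))
  lin <- mgstates::loess_curve(x, 3 * x - 2, span = 0.6, degree = 1)
  list(wls_max_abs_gap = gap,
       linear_max_abs_dev = max(abs(lin$fitted - (3 * x - 2))))
}
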