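#' Configuration for the synthetic droplet cohort simulator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults describe a two-genotype xenograft cohort in which the
#' disease-associated (DAM), antigen-presenting (HLA) and cytokine-response
#' (CRM-1) cell states double their share in the amyloid-pathology group,
#' while the homeostatic state shrinks correspondingly.
#'
#' @param n_groups number of experimental groups (e.g. host genotypes).
#' @param group_names character labels, length `n_groups`.
#' @param mice_per_group number of mice (samples) per group.
#' @param cells_per_mouse droplets emitted per mouse.
#' @param n_genes total genes in the matrix, including mitochondrial genes.
#' @param n_mito_genes number of genes in the designated mitochondrial block
#'   (named `MT-*`).
#' @param state_names cell-state labels.
#' @param state_proportions matrix `n_groups x n_states` of expected state
#'   proportions per group; rows must sum to 1. Default encodes the
#'   DAM/HLA/CRM-1 doubling described above.
#' @param program_size genes in each state's marker program; programs are
#'   disjoint blocks of non-mitochondrial genes.
#' @param program_log2_effect log2 shift applied to a program gene's mean in
#'   its own state.
#' @param nb_dispersion negative-binomial size parameter `theta`
#'   (variance `mu + mu^2/theta`).
#' @param baseline_mean_range per-gene baseline mean bounds; means are drawn
#'   log-uniformly between them.
#' @param program_baseline_range baseline mean bounds for program (marker)
#'   genes; cell-state markers are reliably detected genes, so their floor
#'   sits above the whole-transcriptome floor.
#' @param doublet_rate fraction of droplets containing two cells.
#' @param negative_rate fraction of droplets whose hash staining failed
#'   (background counts on every hash).
#' @param hash_signal_mean,hash_background_mean expected hashtag counts for a
#'   droplet's own sample(s) and for all other samples.
#' @param mito_fraction_beta_params shape pair of the Beta distribution of the
#'   per-cell mitochondrial read share.
#' @param dirichlet_concentration concentration of the per-mouse Dirichlet
#'   draw around the group's state proportions (between-mouse variability).
#' @param seed integer seed; identical configs with identical seeds give
#'   byte-identical output.
#' @return a validated list of class `mg_sim_config`.
#' @export
sim_cohort_config <- function(n_groups = 2,
                              group_names = NULL,
                              mice_per_group = 3,
                              cells_per_mouse = 300,
                              n_genes = 1000,
                              n_mito_genes = 10,
                              state_names = c("HM", "RM", "tCRM", "CRM-1",
                                              "CRM-2", "IRM", "DAM", "HLA"),
                              state_proportions = NULL,
                              program_size = 20,
                              program_log2_effect = 1,
                              nb_dispersion = 2,
                              baseline_mean_range = c(0.05, 5),
                              program_baseline_range = c(1, 5),
                              doublet_rate = 0.05,
                              negative_rate = 0.02,
                              hash_signal_mean = 200,
                              hash_background_mean = 5,
                              mito_fraction_beta_params = c(2, 38),
                              dirichlet_concentration = 200,
                              seed = 1L) {
  n_states <- length(state_names)
  if (is.null(group_names))
    group_names <- if (n_groups == 2) c("App_WT", "App_NLGF") else
      paste0("group", seq_len(n_groups))
  if (length(group_names) != n_groups)
    stop_bad_config("`group_names` must have length `n_groups`")
  if (is.null(state_proportions)) {
    base <- c(HM = 0.55, RM = 0.10, tCRM = 0.10, `CRM-1` = 0.05,
              `CRM-2` = 0.05, IRM = 0.05, DAM = 0.05, HLA = 0.05)
    if (!identical(state_names, names(base))) {
      base <- rep(1 / n_states, n_states)  # custom states: uniform default
      state_proportions <- matrix(base, n_groups, n_states, byrow = TRUE)
    } else {
      enr <- base
      enr[c("DAM", "HLA", "CRM-1")] <- 2 * enr[c("DAM", "HLA", "CRM-1")]
      enr["HM"] <- enr["HM"] - 0.15
      state_proportions <- matrix(base, n_groups, n_states, byrow = TRUE)
      if (n_groups >= 2)
        state_proportions[seq(2, n_groups, by = 2), ] <-
          matrix(enr, sum(seq_len(n_groups) %% 2 == 0), n_states, byrow = TRUE)
    }
  }
  state_proportions <- as.matrix(state_proportions)
  if (!all(dim(state_proportions) == c(n_groups, n_states)))
    stop_bad_config("`state_proportions` must be n_groups x n_states")
  if (any(abs(rowSums(state_proportions) - 1) > 1e-9))
    stop_bad_config("every row of `state_proportions` must sum to 1")
  if (any(state_proportions < 0))
    stop_bad_config("state proportions must be non-negative")
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop_bad_config("`doublet_rate` must be in [0, 1)")
  if (negative_rate < 0 || doublet_rate + negative_rate >= 1)
    stop_bad_config("`doublet_rate` + `negative_rate` must be < 1")
  counts_pos <- c(n_groups, mice_per_group, cells_per_mouse, n_genes,
                  program_size, nb_dispersion)
  if (any(counts_pos <= 0)) stop_bad_config("all counts must be positive")
  if (n_mito_genes < 0 || n_mito_genes >= n_genes)
    stop_bad_config("`n_mito_genes` must be in [0, n_genes)")
  if (program_size * n_states + n_mito_genes > n_genes)
    stop_bad_config("state programs plus mito block exceed `n_genes`")
  if (baseline_mean_range[1] <= 0 ||
      baseline_mean_range[2] < baseline_mean_range[1])
    stop_bad_config("`baseline_mean_range` must be increasing and positive")
  if (program_baseline_range[1] <= 0 ||
      program_baseline_range[2] < program_baseline_range[1])
    stop_bad_config("`program_baseline_range` must be increasing and positive")
  structure(list(
    n_groups = n_groups, group_names = group_names,
    mice_per_group = mice_per_group, cells_per_mouse = cells_per_mouse,
    n_genes = n_genes, n_mito_genes = n_mito_genes,
    state_names = state_names, state_proportions = state_proportions,
    program_size = program_size, program_log2_effect = program_log2_effect,
    nb_dispersion = nb_dispersion, baseline_mean_range = baseline_mean_range,
    program_baseline_range = program_baseline_range,
    doublet_rate = doublet_rate, negative_rate = negative_rate,
    hash_signal_mean = hash_signal_mean,
    hash_background_mean = hash_background_mean,
    mito_fraction_beta_params = mito_fraction_beta_params,
    dirichlet_concentration = dirichlet_concentration,
    seed = as.integer(seed)), class = "mg_sim_config")
}

#' Simulate a hashed droplet cohort with planted cell states
#'
#' Draws per-droplet UMI counts from a negative-binomial model in which each
#' cell state shifts the mean of its disjoint marker program, sums two parent
#' cells for doublets, allocates a Beta-distributed share of each droplet's
#' counts to the mitochondrial gene block, and emits hashtag counts with
#' Poisson signal on the droplet's sample(s) of origin and Poisson background
#' elsewhere. One hash corresponds to one mouse.
#'
#' @param config an `mg_sim_config` from [sim_cohort_config()].
#' @return an object of class `mg_sim_cohort`: a list with
#'   * `counts`: sparse genes x cells raw UMI matrix,
#'   * `hashes`: hashes x cells hashtag count matrix,
#'   * `truth`: per-droplet tibble (barcode, true_state, true_sample,
#'     true_group, droplet_type, parent states/samples for doublets,
#'     realized `mito_fraction`),
#'   * `genes`: per-gene tibble (gene, baseline_mean, program_state, is_mito),
#'   * `samples`: per-mouse tibble (sample, group, realized state proportions
#'     as a nested draw), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mg_sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_states <- length(cfg$state_names)
  n_mito <- cfg$n_mito_genes
  n_expr <- cfg$n_genes - n_mito
  genes <- c(sprintf("GENE%04d", seq_len(n_expr)),
             if (n_mito > 0) sprintf("MT-%02d", seq_len(n_mito)))
  is_mito <- c(rep(FALSE, n_expr), rep(TRUE, n_mito))

  base_mean <- 10^runif(cfg$n_genes, log10(cfg$baseline_mean_range[1]),
                        log10(cfg$baseline_mean_range[2]))
  program_state <- rep(NA_character_, cfg$n_genes)
  for (s in seq_len(n_states)) {
    idx <- ((s - 1) * cfg$program_size + 1):(s * cfg$program_size)
    program_state[idx] <- cfg$state_names[s]
  }
  in_prog <- !is.na(program_state)
  base_mean[in_prog] <- 10^runif(sum(in_prog),
                                 log10(cfg$program_baseline_range[1]),
                                 log10(cfg$program_baseline_range[2]))
  # state-specific mean matrix over non-mito genes
  state_means <- matrix(base_mean[seq_len(n_expr)], n_expr, n_states)
  for (s in seq_len(n_states)) {
    shift <- which(program_state[seq_len(n_expr)] == cfg$state_names[s])
    state_means[shift, s] <- state_means[shift, s] * 2^cfg$program_log2_effect
  }

  # mice and their state proportions
  mouse_group <- rep(seq_len(cfg$n_groups), each = cfg$mice_per_group)
  n_mice <- length(mouse_group)
  mouse_id <- sprintf("%s_m%d", cfg$group_names[mouse_group],
                      rep(seq_len(cfg$mice_per_group), cfg$n_groups))
  mouse_props <- matrix(NA_real_, n_mice, n_states)
  for (i in seq_len(n_mice)) {
    alpha <- cfg$dirichlet_concentration *
      pmax(cfg$state_proportions[mouse_group[i], ], 1e-6)
    mouse_props[i, ] <- rdirichlet(1, alpha)
  }

  n_cells <- n_mice * cfg$cells_per_mouse
  primary_mouse <- rep(seq_len(n_mice), each = cfg$cells_per_mouse)
  u <- runif(n_cells)
  droplet_type <- ifelse(u < cfg$doublet_rate, "doublet",
                         ifelse(u < cfg$doublet_rate + cfg$negative_rate,
                                "negative", "singlet"))

  draw_state <- function(mouse) {  # one state per entry of `mouse`
    vapply(mouse, function(m)
      sample.int(n_states, 1, prob = mouse_props[m, ]), integer(1))
  }
  state1 <- draw_state(primary_mouse)
  second_mouse <- ifelse(droplet_type == "doublet",
                         sample.int(n_mice, n_cells, replace = TRUE), NA)
  state2 <- rep(NA_integer_, n_cells)
  dbl <- which(droplet_type == "doublet")
  if (length(dbl)) state2[dbl] <- draw_state(second_mouse[dbl])

  # expression counts: one parent draw per droplet, plus one for doublets
  draw_cells <- function(states) {
    m <- matrix(0L, n_expr, length(states))
    for (s in sort(unique(states))) {
      j <- which(states == s)
      m[, j] <- matrix(rnbinom(n_expr * length(j),
                               mu = state_means[, s],
                               size = cfg$nb_dispersion),
                       n_expr, length(j))
    }
    m
  }
  expr <- draw_cells(state1)
  if (length(dbl)) expr[, dbl] <- expr[, dbl] + draw_cells(state2[dbl])

  # mitochondrial block: Beta-distributed target share of droplet counts
  mito <- matrix(0L, n_mito, n_cells)
  if (n_mito > 0) {
    f <- rbeta(n_cells, cfg$mito_fraction_beta_params[1],
               cfg$mito_fraction_beta_params[2])
    t_expr <- colSums(expr)
    m_tot <- round(t_expr * f / (1 - f))
    p_mito <- base_mean[is_mito] / sum(base_mean[is_mito])
    for (j in which(m_tot > 0))
      mito[, j] <- as.integer(stats::rmultinom(1, m_tot[j], p_mito))
  }
  counts <- rbind(expr, mito)
  barcodes <- sprintf("cell%06d", seq_len(n_cells))
  dimnames(counts) <- list(genes, barcodes)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")

  # hashtag counts: signal on parent mice, background elsewhere
  hashes <- matrix(rpois(n_mice * n_cells, cfg$hash_background_mean),
                   n_mice, n_cells, dimnames = list(mouse_id, barcodes))
  sig <- function(mouse_idx, cells)
    hashes[cbind(mouse_idx, cells)] <<-
      rpois(length(cells), cfg$hash_signal_mean)
  keep_sig <- which(droplet_type != "negative")
  sig(primary_mouse[keep_sig], keep_sig)
  if (length(dbl)) sig(second_mouse[dbl], dbl)

  tot <- Matrix::colSums(counts)
  mito_share <- if (n_mito > 0)
    Matrix::colSums(counts[is_mito, , drop = FALSE]) / pmax(tot, 1) else
    rep(0, n_cells)

  truth <- tibble(
    barcode = barcodes,
    true_state = cfg$state_names[state1],
    true_sample = mouse_id[primary_mouse],
    true_group = cfg$group_names[mouse_group[primary_mouse]],
    droplet_type = droplet_type,
    parent_state_2 = ifelse(is.na(state2), NA_character_,
                            cfg$state_names[state2]),
    parent_sample_2 = ifelse(is.na(second_mouse), NA_character_,
                             mouse_id[pmax(second_mouse, 1)]),
    mito_fraction = mito_share)

  structure(list(
    counts = counts,
    hashes = hashes,
    truth = truth,
    genes = tibble(gene = genes, baseline_mean = base_mean,
                   program_state = program_state, is_mito = is_mito),
    samples = tibble(sample = mouse_id,
                     group = cfg$group_names[mouse_group],
                     true_proportions = lapply(seq_len(n_mice), function(i)
                       setNames(mouse_props[i, ], cfg$state_names))),
    config = cfg), class = "mg_sim_cohort")
}

#' @export
print.mg_sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated droplet cohort: %d genes x %d droplets, %d mice\n",
              nrow(x$counts), ncol(x$counts), nrow(x$samples)))
  print(dplyr::count(x$truth, .data$droplet_type))
  invisible(x)
}
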