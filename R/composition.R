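#' Per-sample cell-state composition table
#'
#' Tallies per-cell state labels within samples (mice) and returns
#' proportions; states absent from a sample get 0, and every row sums to 1.
#' Samples with zero cells are excluded with a warning.
#'
#' @param labels per-cell state labels.
#' @param samples per-cell sample (mouse) identifiers, same length.
#' @param groups named vector mapping sample -> group, or a per-cell vector.
#' @return a `mg_composition` tibble: `sample`, `group`, `n_cells`, one
#'   proportion column per state.
#' @export
proportions <- function(labels, samples, groups) {
  if (length(labels) != length(samples))
    abort("`labels` and `samples` must have equal length")
  if (length(groups) == length(samples) && is.null(names(groups))) {
    gmap <- tapply(as.character(groups), samples, function(g) g[1])
  } else {
    gmap <- groups
    missing <- setdiff(unique(samples), names(gmap))
    if (length(missing))
      abort(sprintf("no group for sample(s): %s",
                    paste(missing, collapse = ", ")))
  }
  empty <- setdiff(names(gmap), unique(samples))
  if (length(empty))
    warn(sprintf("sample(s) with 0 cells excluded: %s",
                 paste(empty, collapse = ", ")))
  tab <- tibble(sample = as.character(samples),
                state = as.character(labels)) |>
    count(.data$sample, .data$state) |>
    group_by(.data$sample) |>
    mutate(prop = .data$n / sum(.data$n), n_cells = sum(.data$n)) |>
    ungroup()
  wide <- tab |>
    select("sample", "state", "prop") |>
    pivot_wider(names_from = "state", values_from = "prop",
                values_fill = 0)
  meta <- distinct(tab, .data$sample, .data$n_cells)
  out <- meta |>
    mutate(group = unname(gmap[.data$sample])) |>
    left_join(wide, by = "sample") |>
    select("sample", "group", "n_cells", dplyr::everything())
  structure(out, class = c("mg_composition", class(out)))
}

state_cols <- function(table) {
  setdiff(names(table), c("sample", "group", "n_cells"))
}

#' Welch two-sample t-test on per-mouse state proportions
#'
#' Unpaired t-test with Welch's correction (Satterthwaite degrees of
#' freedom), two-tailed. When both groups are constant with equal values the
#' result is `t = 0, p = 1`; constant groups with different values give
#' `p = 0`.
#'
#' @param table `mg_composition` from [proportions()] (or any tibble with a
#'   `group` column and the tested column).
#' @param state column (state) to test.
#' @param group_a,group_b group labels; each needs >= 2 samples.
#' @param transform `"none"` (default) or `"arcsine_sqrt"` applied to the
#'   proportions before testing.
#' @return an `mg_group_test` list: `state`, `method`, `statistic`, `df`,
#'   `p`, `estimate` (group means), `groups`.
#' @export
welch_test <- function(table, state, group_a, group_b,
                       transform = c("none", "arcsine_sqrt")) {
  transform <- match.arg(transform)
  x <- table[[state]][table$group == group_a]
  y <- table[[state]][table$group == group_b]
  if (length(x) < 2 || length(y) < 2)
    abort("each group needs at least 2 samples")
  if (transform == "arcsine_sqrt") {
    x <- asin(sqrt(x)); y <- asin(sqrt(y))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    res <- list(statistic = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = if (equal) 1 else 0)
  } else {
    tt <- t.test(x, y, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(list(state = state, method = "welch_t",
                 statistic = res$statistic, df = res$df, p = res$p,
                 estimate = c(mean_a = mean(x), mean_b = mean(y)),
                 groups = c(group_a, group_b), pairwise = NULL),
            class = "mg_group_test")
}

#' One-way ANOVA with Tukey HSD post hoc on state proportions
#'
#' With two groups the call defers to [welch_test()] with a warning. Groups
#' with a single sample are an error.
#'
#' @param table `mg_composition`.
#' @param state column (state) to test.
#' @param groups group labels to include (default: all in the table).
#' @return `mg_group_test` with F statistic, df, p and a `pairwise` tibble of
#'   Tukey-adjusted p-values.
#' @export
anova_tukey <- function(table, state, groups = unique(table$group)) {
  d <- table[table$group %in% groups, c("group", state)]
  names(d) <- c("group", "value")
  sizes <- table(d$group)
  if (any(sizes < 2))
    abort(sprintf("group(s) with a single sample: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  if (length(groups) == 2) {
    warn("only 2 groups; deferring to welch_test()")
    return(welch_test(table, state, groups[1], groups[2]))
  }
  d$group <- factor(d$group)
  if (var(d$value) == 0) {  # constant response: no effect by construction
    pairs <- combn(levels(d$group), 2)
    return(structure(list(
      state = state, method = "anova_tukey", statistic = 0,
      df = c(length(levels(d$group)) - 1,
             nrow(d) - length(levels(d$group))), p = 1,
      estimate = tapply(d$value, d$group, mean), groups = levels(d$group),
      pairwise = tibble(comparison = paste(pairs[2, ], pairs[1, ],
                                           sep = "-"),
                        diff = 0, p_adj = 1)), class = "mg_group_test"))
  }
  fit <- aov(value ~ group, data = d)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  structure(list(state = state, method = "anova_tukey",
                 statistic = sm$`F value`[1],
                 df = c(sm$Df[1], sm$Df[2]), p = sm$`Pr(>F)`[1],
                 estimate = tapply(d$value, d$group, mean),
                 groups = levels(d$group),
                 pairwise = tibble(comparison = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"])),
            class = "mg_group_test")
}

#' @export
print.mg_group_test <- function(x, ...) {
  cat(sprintf("%s on '%s': statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$state, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' @export
tidy.mg_group_test <- function(x, ...) {
  if (is.null(x$pairwise))
    tibble(state = x$state, method = x$method, statistic = x$statistic,
           df = x$df[1], p.value = x$p)
  else
    mutate(x$pairwise, state = x$state, method = x$method)
}

#' @export
glance.mg_group_test <- function(x, ...) {
  tibble(state = x$state, method = x$method, statistic = x$statistic,
         p.value = x$p, n_groups = length(x$groups))
}

#' Sample-size-normalized 2D embedding density per group
#'
#' Gaussian-kernel density over a common grid, where each sample contributes
#' total mass `1/n_samples_in_group` (every cell weighs
#' `1/(n_samples x n_cells_in_sample)`), so over-sampled mice do not dominate
#' the group density. Bandwidth is Scott's rule per group
#' (`sd * n^(-1/6)` per axis); the grid extends 3 bandwidths beyond the data
#' range so each group's grid integral is 1 up to truncation error.
#'
#' @param embedding two-column matrix or data frame of per-cell coordinates.
#' @param samples per-cell sample identifiers.
#' @param groups named sample -> group map or per-cell vector.
#' @param grid_n grid resolution per axis (default 100).
#' @return tibble `group`, `x`, `y`, `density`; grid spacing in
#'   `attr(, "cell_area")`.
#' @export
embedding_density <- function(embedding, samples, groups, grid_n = 100) {
  emb <- as.matrix(embedding)
  stopifnot(ncol(emb) == 2, all(is.finite(emb)))
  if (length(groups) == length(samples) && is.null(names(groups)))
    groups <- tapply(as.character(groups), samples, function(g) g[1])
  sample_group <- groups[unique(samples)]
  bw_all <- apply(emb, 2, sd) * nrow(emb)^(-1 / 6)
  lims <- c(range(emb[, 1]) + c(-3, 3) * bw_all[1],
            range(emb[, 2]) + c(-3, 3) * bw_all[2])
  out <- map_dfr(unique(sample_group), function(g) {
    g_samples <- names(sample_group)[sample_group == g]
    in_g <- samples %in% g_samples
    n_g <- sum(in_g)
    bw <- pmax(apply(emb[in_g, , drop = FALSE], 2, sd), 1e-8) * n_g^(-1 / 6)
    dens <- 0
    for (s in g_samples) {
      in_s <- samples == s
      # MASS::kde2d's h is 4x the Gaussian sd
      k <- MASS::kde2d(emb[in_s, 1], emb[in_s, 2], h = 4 * bw,
                       n = grid_n, lims = lims)
      dens <- dens + k$z / length(g_samples)
    }
    tidyr::expand_grid(x = k$x, y = k$y) |>
      arrange(.data$x, .data$y) |>
      mutate(group = g, density = as.vector(t(dens))) |>
      select("group", "x", "y", "density")
  })
  attr(out, "cell_area") <- diff(lims[1:2]) / (grid_n - 1) *
    diff(lims[3:4]) / (grid_n - 1)
  out
}

#' Binned-pseudotime composition per group
#'
#' Pseudotime is cut into `n_bins` equal-width bins over its observed range.
#' Per sample, bin proportions sum to 1; the group curve is the mean of its
#' sample curves. With exactly two groups a per-bin Welch test on the
#' per-sample proportions is included.
#'
#' @param pseudotime per-cell finite numeric values.
#' @param samples per-cell sample identifiers.
#' @param groups named sample -> group map or per-cell vector.
#' @param n_bins number of equal-width bins (default 20).
#' @return list with `samples` (per-sample per-bin proportions), `groups`
#'   (group mean curves) and `tests` (per-bin Welch results when 2 groups).
#' @export
bin_pseudotime <- function(pseudotime, samples, groups, n_bins = 20) {
  stopifnot(all(is.finite(pseudotime)))
  if (length(groups) == length(samples) && is.null(names(groups)))
    groups <- tapply(as.character(groups), samples, function(g) g[1])
  rng <- range(pseudotime)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(pseudotime, breaks, rightmost.closed = TRUE),
                   1), n_bins)
  per_sample <- tibble(sample = as.character(samples), bin = bin) |>
    count(.data$sample, .data$bin) |>
    complete(sample = unique(as.character(samples)), bin = seq_len(n_bins),
             fill = list(n = 0L)) |>
    group_by(.data$sample) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(group = unname(groups[.data$sample]))
  per_group <- per_sample |>
    group_by(.data$group, .data$bin) |>
    summarise(prop = mean(.data$prop), .groups = "drop")
  tests <- NULL
  gl <- unique(per_sample$group)
  if (length(gl) == 2) {
    tests <- map_dfr(seq_len(n_bins), function(b) {
      d <- per_sample |> filter(.data$bin == b)
      wt <- welch_test(tibble(sample = d$sample, group = d$group,
                              n_cells = 0, value = d$prop), "value",
                       gl[1], gl[2])
      tibble(bin = b, statistic = wt$statistic, df = wt$df, p = wt$p)
    })
  }
  list(samples = per_sample, groups = per_group, tests = tests,
       breaks = breaks)
}
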