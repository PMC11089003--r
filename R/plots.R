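#' Heatmap of a cross-dataset correlation map
#'
#' Tiles colored by Pearson r; masked cells (non-positive correlations under
#' `positive_only`) and pairs below the shared-gene minimum are blank.
#' Asterisks mark adjusted p below 0.05 / 0.01 / 0.001.
#'
#' @param object `mg_correlation_map` from [correlate_signatures()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mg_correlation_map <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(r_show = if_else(.data$masked, NA_real_, .data$r),
           stars = dplyr::case_when(
             is.na(.data$p_adj) | .data$masked ~ "",
             .data$p_adj <= 0.001 ~ "***",
             .data$p_adj <= 0.01 ~ "**",
             .data$p_adj <= 0.05 ~ "*",
             TRUE ~ ""))
  ggplot(d, aes(x = .data$query_cluster, y = .data$ref_state,
                fill = .data$r_show)) +
    geom_tile(color = "grey80") +
    ggplot2::geom_text(aes(label = .data$stars), size = 3) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         midpoint = 0, na.value = "grey95",
                         name = "Pearson r") +
    labs(x = "query cluster", y = "reference state") +
    theme_minimal()
}

#' Radial intensity profile with Loess smooth and standard-error ribbon
#'
#' Plots per-annulus z-scored intensities against the annulus mid-radius for
#' each channel, overlaid with the package's local-regression curve
#' ([loess_curve()]) and its pointwise standard error.
#'
#' @param table a z-scored `mg_radial_profile` (see [zscore_profiles()]).
#' @param span,degree passed to [loess_curve()].
#' @return a ggplot object.
#' @export
plot_radial_profile <- function(table, span = 0.75, degree = 1) {
  d <- as_tibble(table) |>
    filter(!is.na(.data$z)) |>
    mutate(mid = (.data$inner_radius_um + .data$outer_radius_um) / 2)
  curves <- d |>
    group_by(.data$channel) |>
    dplyr::group_modify(function(g, key)
      loess_curve(g$mid, g$z, span = span, degree = degree,
                  eval_at = sort(unique(g$mid)))) |>
    ungroup()
  ggplot(d, aes(x = .data$mid, y = .data$z, color = .data$channel)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_ribbon(data = curves,
                aes(x = .data$x, ymin = .data$fitted - .data$se,
                    ymax = .data$fitted + .data$se, fill = .data$channel),
                alpha = 0.25, inherit.aes = FALSE) +
    geom_line(data = curves,
              aes(x = .data$x, y = .data$fitted, color = .data$channel),
              linewidth = 0.8, inherit.aes = FALSE) +
    labs(x = "distance from plaque center (µm)",
         y = "z-scored intensity") +
    theme_minimal()
}

#' Per-mouse composition box plot
#'
#' One panel per state; each dot is a mouse, boxes summarize groups.
#'
#' @param object `mg_composition` from [proportions()].
#' @param states states to show (default all).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mg_composition <- function(object, states = NULL, ...) {
  sc <- state_cols(object)
  if (!is.null(states)) sc <- intersect(sc, states)
  d <- as_tibble(object) |>
    pivot_longer(dplyr::all_of(sc), names_to = "state",
                 values_to = "proportion")
  ggplot(d, aes(x = .data$group, y = .data$proportion,
                fill = .data$group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    geom_jitter(width = 0.15, size = 1.2) +
    facet_wrap(~state, scales = "free_y") +
    labs(x = NULL, y = "proportion of cells per mouse") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Sample-size-normalized embedding density plot
#'
#' @param density tibble from [embedding_density()].
#' @return a ggplot object (one facet per group).
#' @export
plot_embedding_density <- function(density) {
  ggplot(density, aes(x = .data$x, y = .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    facet_wrap(~group) +
    scale_fill_viridis_c(name = "density") +
    theme_minimal()
}
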