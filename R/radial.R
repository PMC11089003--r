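#' Detect plaques by thresholding and connected components
#'
#' Binarizes the plaque channel (Otsu's method by default, or an absolute
#' threshold), labels 8-connected components, drops those below
#' `min_area_um2`, and returns sub-pixel centroids (mean of member pixel
#' coordinates) and areas.
#'
#' @param plaque_channel 2D intensity matrix.
#' @param pixel_size_um physical pixel edge in micrometres.
#' @param threshold `"otsu"` or an absolute intensity value.
#' @param min_area_um2 minimum component area (default 10).
#' @return a `mg_plaque_set` tibble: `plaque_id`, `center_row`, `center_col`
#'   (pixel coordinates), `area_um2`, `n_pixels`. A blank image gives zero
#'   rows.
#' @export
detect_plaques <- function(plaque_channel, pixel_size_um,
                           threshold = "otsu", min_area_um2 = 10) {
  stopifnot(length(dim(plaque_channel)) == 2, pixel_size_um > 0)
  if (identical(threshold, "otsu")) {
    rng <- range(plaque_channel)
    if (diff(rng) == 0)
      return(empty_plaque_set())
    scaled <- (plaque_channel - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(EBImage::Image(scaled)) * diff(rng)
  } else thr <- as.numeric(threshold)
  mask <- plaque_channel > thr
  if (!any(mask)) return(empty_plaque_set())
  lab <- label_components8(mask)
  px <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  out <- tibble(comp = comp, row = px[, 1], col = px[, 2]) |>
    group_by(.data$comp) |>
    summarise(center_row = mean(.data$row), center_col = mean(.data$col),
              n_pixels = n(), .groups = "drop") |>
    mutate(area_um2 = .data$n_pixels * pixel_size_um^2) |>
    filter(.data$area_um2 >= min_area_um2) |>
    mutate(plaque_id = dplyr::row_number()) |>
    select("plaque_id", "center_row", "center_col", "area_um2", "n_pixels")
  structure(out, class = c("mg_plaque_set", class(out)))
}

empty_plaque_set <- function() {
  structure(tibble(plaque_id = integer(), center_row = numeric(),
                   center_col = numeric(), area_um2 = numeric(),
                   n_pixels = integer()),
            class = c("mg_plaque_set", class(tibble())))
}

# 8-connected component labeling by iterative flood fill
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb_r <- rep(r, each = 8L) + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
      nb_c <- rep(c, each = 8L) + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      idx <- unique((nb_c[ok] - 1L) * nr + nb_r[ok])
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- nxt
      frontier <- idx
    }
  }
  lab
}

#' Mean intensity in concentric annuli around a plaque center
#'
#' Pixel-center distances to the plaque center (in micrometres) are binned
#' into `n_annuli` contiguous annuli of width `annulus_width_um`
#' (annulus `i` covers `[i*w, (i+1)*w)`; the defaults, 24 annuli of 10/3 µm,
#' cover 0-80 µm with the near window 0-10 µm and the distant window
#' 70-80 µm). Area outside the image is simply absent; annuli with no pixels
#' report `n_pixels = 0` and a missing mean. When `restrict_mask` is given
#' (e.g. nearest-plaque assignment from [radial_profile()]), only `TRUE`
#' pixels contribute.
#'
#' @param channels named list of 2D intensity matrices (equal dims).
#' @param center `c(row, col)` plaque center in pixel coordinates.
#' @param pixel_size_um physical pixel edge.
#' @param n_annuli,annulus_width_um annulus geometry (defaults 24 x 10/3 µm).
#' @param restrict_mask optional logical matrix limiting contributing pixels.
#' @param plaque_id id recorded in the output rows.
#' @return tibble rows: `plaque_id`, `annulus_index` (0-based),
#'   `inner_radius_um`, `outer_radius_um`, `channel`, `mean_intensity`,
#'   `n_pixels`.
#' @export
annulus_means <- function(channels, center, pixel_size_um,
                          n_annuli = 24, annulus_width_um = 10 / 3,
                          restrict_mask = NULL, plaque_id = 1L) {
  stopifnot(is.list(channels), length(channels) > 0)
  dm <- dim(channels[[1]])
  if (center[1] < 1 || center[1] > dm[1] || center[2] < 1 ||
      center[2] > dm[2]) abort("center outside image")
  rows <- matrix(seq_len(dm[1]), dm[1], dm[2])
  cols <- matrix(seq_len(dm[2]), dm[1], dm[2], byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2) * pixel_size_um
  idx <- floor(d / annulus_width_um)
  use <- idx < n_annuli
  if (!is.null(restrict_mask)) use <- use & restrict_mask
  ann <- factor(idx[use], levels = 0:(n_annuli - 1))
  npx <- as.integer(table(ann))
  map_dfr(names(channels), function(nm) {
    v <- channels[[nm]][use]
    s <- tapply(v, ann, sum, default = 0)
    tibble(plaque_id = plaque_id, annulus_index = 0:(n_annuli - 1),
           inner_radius_um = (0:(n_annuli - 1)) * annulus_width_um,
           outer_radius_um = (1:n_annuli) * annulus_width_um,
           channel = nm,
           mean_intensity = ifelse(npx > 0, as.numeric(s) / npx, NA_real_),
           n_pixels = npx)
  })
}

#' Radial intensity profiles for every plaque of an image
#'
#' Runs [annulus_means()] around each plaque center, assigning every pixel
#' to its nearest plaque center only, so overlapping annuli never count a
#' pixel twice.
#'
#' @param image `mg_plaque_image` (or list with `channels`, `pixel_size_um`).
#' @param plaques `mg_plaque_set` (e.g. from [detect_plaques()]) or a tibble
#'   with `plaque_id`, `center_row`, `center_col`.
#' @param channels channel names to profile (default: all but `plaque`).
#' @param ... passed to [annulus_means()].
#' @return a `mg_radial_profile` tibble (rows as in [annulus_means()]).
#' @export
radial_profile <- function(image, plaques, channels = NULL, ...) {
  if (nrow(plaques) == 0) abort("no plaques to profile")
  chans <- image$channels
  if (is.null(channels)) channels <- setdiff(names(chans), "plaque")
  chans <- chans[channels]
  centers <- as.matrix(plaques[, c("center_row", "center_col")])
  nearest <- pixel_distance_um(dim(image$channels[[1]]), centers,
                               image$pixel_size_um)$nearest
  out <- map_dfr(seq_len(nrow(plaques)), function(k)
    annulus_means(chans, centers[k, ], image$pixel_size_um,
                  restrict_mask = nearest == k,
                  plaque_id = plaques$plaque_id[k], ...))
  structure(out, pixel_size_um = image$pixel_size_um,
            class = c("mg_radial_profile", class(out)))
}

#' Z-score radial profiles per channel
#'
#' Each channel's annulus means (across all plaques and annuli) are scaled
#' to mean 0 and unit sample standard deviation (n - 1). A zero-variance
#' channel yields zeros with a warning. Missing means stay missing.
#'
#' @param table `mg_radial_profile` tibble with `channel`, `mean_intensity`.
#' @return the table with a `z` column added.
#' @export
zscore_profiles <- function(table) {
  out <- table |>
    group_by(.data$channel) |>
    mutate(z = {
      x <- .data$mean_intensity
      ok <- !is.na(x)
      if (sum(ok) < 2) abort("need >= 2 defined values per channel")
      s <- sd(x[ok])
      if (s == 0) {
        warn(sprintf("channel %s has zero variance; z set to 0",
                     .data$channel[1]))
        ifelse(ok, 0, NA_real_)
      } else (x - mean(x[ok])) / s
    }) |>
    ungroup()
  structure(out, class = class(table))
}

#' Compare near-plaque and distant annuli with a one-tailed t-test
#'
#' Per replicate (plaque, or mouse after pooling that mouse's plaques), the
#' near value is the mean z over the first `near_annuli` annuli and the far
#' value the mean over the last `far_annuli`. Replicates with a missing
#' annulus in either window are dropped with a warning. The near values are
#' then compared to the far values by an unpaired one-tailed t-test in the
#' declared direction.
#'
#' @param table z-scored `mg_radial_profile` (see [zscore_profiles()]).
#' @param channel channel to test.
#' @param replicate_unit `"plaque"` or `"mouse"` (requires a `mouse` column).
#' @param near_annuli,far_annuli window sizes (default 3 and 3).
#' @param alternative `"near_greater"` (marker rises toward the plaque) or
#'   `"far_greater"`.
#' @param var_equal use the pooled-variance t-test (default `TRUE`,
#'   the plain unpaired t-test; `FALSE` gives Welch).
#' @return a `mg_near_far` list: `channel`, `near_mean`, `far_mean` (pooled),
#'   `per_replicate` tibble, `statistic`, `df`, `p`, `alternative`.
#' @export
near_far_test <- function(table, channel, replicate_unit = c("plaque",
                                                             "mouse"),
                          near_annuli = 3, far_annuli = 3,
                          alternative = c("near_greater", "far_greater"),
                          var_equal = TRUE) {
  replicate_unit <- match.arg(replicate_unit)
  alternative <- match.arg(alternative)
  d <- table |> filter(.data$channel == !!channel)
  if (nrow(d) == 0) abort(sprintf("channel %s not in table", channel))
  if (!"z" %in% names(d)) abort("table must be z-scored first")
  n_ann <- max(d$annulus_index) + 1
  near_idx <- 0:(near_annuli - 1)
  far_idx <- (n_ann - far_annuli):(n_ann - 1)
  unit <- if (replicate_unit == "mouse") {
    if (!"mouse" %in% names(d)) abort("replicate_unit='mouse' needs a `mouse` column")
    d$mouse
  } else d$plaque_id
  per <- d |>
    mutate(.unit = unit) |>
    group_by(.data$.unit) |>
    summarise(
      near = mean(.data$z[.data$annulus_index %in% near_idx]),
      far = mean(.data$z[.data$annulus_index %in% far_idx]),
      .groups = "drop") |>
    rename(replicate = ".unit")
  bad <- !complete.cases(per)
  if (any(bad)) {
    warn(sprintf("%d replicate(s) dropped for missing annuli", sum(bad)))
    per <- per[!bad, , drop = FALSE]
  }
  if (nrow(per) < 2) abort("need >= 2 replicates per side")
  alt <- if (alternative == "near_greater") "greater" else "less"
  if (sd(per$near) == 0 && sd(per$far) == 0 &&
      isTRUE(all.equal(mean(per$near), mean(per$far)))) {
    st <- list(statistic = 0, parameter = 2 * nrow(per) - 2, p.value = 0.5)
  } else {
    st <- t.test(per$near, per$far, alternative = alt, var.equal = var_equal)
  }
  structure(list(channel = channel, near_mean = mean(per$near),
                 far_mean = mean(per$far), per_replicate = per,
                 statistic = unname(st$statistic),
                 df = unname(st$parameter), p = st$p.value,
                 alternative = alternative),
            class = "mg_near_far")
}

#' @export
print.mg_near_far <- function(x, ...) {
  cat(sprintf(
    "near/far test (%s): near = %.3f, far = %.3f, t = %.3f, df = %.2f, one-tailed p = %.4g (%s)\n",
    x$channel, x$near_mean, x$far_mean, x$statistic, x$df, x$p,
    x$alternative))
  invisible(x)
}

#' @export
tidy.mg_near_far <- function(x, ...) {
  tibble(channel = x$channel, near_mean = x$near_mean, far_mean = x$far_mean,
         statistic = x$statistic, df = x$df, p.value = x$p,
         alternative = x$alternative)
}

#' Fit an exponential radial decay to annulus means
#'
#' Least-squares fit of `b + A * exp(-d / lambda)` (direction `"up"`) or
#' `b + A * (1 - exp(-d / lambda))` (`"down"`) to per-annulus mean
#' intensities, with `d` the annulus mid-radius. Used to recover the planted
#' decay length from simulated images.
#'
#' @param table `mg_radial_profile` rows for one channel (means are averaged
#'   across plaques per annulus first).
#' @param channel channel name.
#' @param direction `"up"` or `"down"`.
#' @return tibble `amplitude`, `decay_length_um`, `baseline`, `rss`.
#' @export
fit_radial_decay <- function(table, channel, direction = c("up", "down")) {
  direction <- match.arg(direction)
  d <- table |>
    filter(.data$channel == !!channel, !is.na(.data$mean_intensity)) |>
    group_by(.data$annulus_index) |>
    summarise(
      mid = (.data$inner_radius_um[1] + .data$outer_radius_um[1]) / 2,
      y = mean(.data$mean_intensity), .groups = "drop")
  if (nrow(d) < 4) abort("need >= 4 annuli to fit")
  obj <- function(par) {
    A <- par[1]; lam <- exp(par[2]); b <- par[3]
    dec <- exp(-d$mid / lam)
    mu <- if (direction == "up") b + A * dec else b + A * (1 - dec)
    sum((d$y - mu)^2)
  }
  rng <- diff(range(d$y))
  init <- c(max(rng, 1e-3), log(diff(range(d$mid)) / 3), min(d$y))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  tibble(amplitude = fit$par[1], decay_length_um = exp(fit$par[2]),
         baseline = fit$par[3], rss = fit$value)
}
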