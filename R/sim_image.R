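#' Configuration for the synthetic plaque-image simulator
#'
#' @param image_size_px `c(rows, cols)` image size in pixels.
#' @param pixel_size_um physical edge length of one pixel, in micrometres.
#' @param n_plaques number of plaques to place.
#' @param plaque_radius_um `c(min, max)` plaque disk radius range.
#' @param channel_models named list of marker-channel models, each a list with
#'   `amplitude` (A), `decay_length_um` (lambda), `baseline` (b) and
#'   `direction` (`"up_near_plaque"` or `"down_near_plaque"`). An "up" channel
#'   has intensity `b + A*exp(-d/lambda)` at distance `d` from the nearest
#'   plaque center; a "down" channel has `b + A*(1 - exp(-d/lambda))`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param psf_sigma_um Gaussian blur applied to the plaque channel (0 = none).
#' @param margin_um plaque centers are kept at least this far from the border.
#' @param seed integer seed.
#' @return a validated list of class `mg_image_config`.
#' @export
sim_image_config <- function(image_size_px = c(300, 300),
                             pixel_size_um = 1,
                             n_plaques = 5,
                             plaque_radius_um = c(5, 12),
                             channel_models = list(
                               CD9  = list(amplitude = 1, decay_length_um = 20,
                                           baseline = 0.2,
                                           direction = "up_near_plaque"),
                               P2RY12 = list(amplitude = 1,
                                             decay_length_um = 20,
                                             baseline = 0.2,
                                             direction = "down_near_plaque")),
                             noise_sd = 0.05,
                             psf_sigma_um = 1,
                             margin_um = NULL,
                             seed = 1L) {
  if (pixel_size_um <= 0) stop_bad_config("`pixel_size_um` must be positive")
  if (n_plaques < 0) stop_bad_config("`n_plaques` must be >= 0")
  for (cm in channel_models) {
    if (!cm$direction %in% c("up_near_plaque", "down_near_plaque"))
      stop_bad_config("channel direction must be up_near_plaque or down_near_plaque")
    if (cm$amplitude < 0 || cm$decay_length_um <= 0 || cm$baseline < 0)
      stop_bad_config("channel model parameters out of range")
  }
  margin_um <- margin_um %||% (max(plaque_radius_um) + 2 * pixel_size_um)
  structure(list(image_size_px = image_size_px,
                 pixel_size_um = pixel_size_um, n_plaques = n_plaques,
                 plaque_radius_um = plaque_radius_um,
                 channel_models = channel_models, noise_sd = noise_sd,
                 psf_sigma_um = psf_sigma_um, margin_um = margin_um,
                 seed = as.integer(seed)), class = "mg_image_config")
}

# distance (um) from every pixel center to its nearest center; centers in px
pixel_distance_um <- function(dim_px, centers_px, pixel_size_um) {
  rows <- matrix(seq_len(dim_px[1]), dim_px[1], dim_px[2])
  cols <- matrix(seq_len(dim_px[2]), dim_px[1], dim_px[2], byrow = TRUE)
  d <- matrix(Inf, dim_px[1], dim_px[2])
  nearest <- matrix(NA_integer_, dim_px[1], dim_px[2])
  for (k in seq_len(nrow(centers_px))) {
    dk <- sqrt((rows - centers_px[k, 1])^2 + (cols - centers_px[k, 2])^2) *
      pixel_size_um
    upd <- dk < d
    d[upd] <- dk[upd]
    nearest[upd] <- k
  }
  list(dist = d, nearest = nearest)
}

#' Simulate a multi-channel plaque image with known radial gradients
#'
#' Places plaque disks at random centers, blurs the plaque channel with a
#' Gaussian point-spread function, and builds each marker channel as a
#' deterministic function of the distance from each pixel center to the
#' nearest plaque center, plus Gaussian noise. Negative intensities are
#' clipped to zero. With zero plaques, marker channels reduce to baseline
#' plus noise.
#'
#' @param config an `mg_image_config` from [sim_image_config()].
#' @return an object of class `mg_plaque_image`: a list with `channels`
#'   (named list of matrices, first one `plaque`), `pixel_size_um`, and
#'   `truth` (tibble of plaque centers/radii plus a tibble of channel
#'   parameters in `attr(truth, "channel_models")`).
#' @export
simulate_plaque_image <- function(config) {
  stopifnot(inherits(config, "mg_image_config"))
  withr::with_seed(config$seed, simulate_plaque_image_impl(config))
}

simulate_plaque_image_impl <- function(cfg) {
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  mpx <- cfg$margin_um / cfg$pixel_size_um
  if (cfg$n_plaques > 0) {
    centers <- cbind(runif(cfg$n_plaques, 1 + mpx, nr - mpx),
                     runif(cfg$n_plaques, 1 + mpx, nc - mpx))
    radii <- runif(cfg$n_plaques, cfg$plaque_radius_um[1],
                   cfg$plaque_radius_um[2])
  } else {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
  }

  plaque <- matrix(0, nr, nc)
  if (cfg$n_plaques > 0) {
    dd <- pixel_distance_um(c(nr, nc), centers, cfg$pixel_size_um)
    for (k in seq_len(cfg$n_plaques))
      plaque <- pmax(plaque, (pixel_distance_um(c(nr, nc),
                     centers[k, , drop = FALSE],
                     cfg$pixel_size_um)$dist <= radii[k]) * 1)
    if (cfg$psf_sigma_um > 0)
      plaque <- matrix(as.numeric(EBImage::gblur(EBImage::Image(plaque),
                       sigma = cfg$psf_sigma_um / cfg$pixel_size_um)),
                       nr, nc)
    dist_um <- dd$dist
  } else {
    dist_um <- matrix(Inf, nr, nc)
  }

  channels <- list(plaque = pmax(plaque +
    if (cfg$noise_sd > 0) rnorm(nr * nc, 0, cfg$noise_sd) else 0, 0))
  for (nm in names(cfg$channel_models)) {
    cm <- cfg$channel_models[[nm]]
    decay <- exp(-dist_um / cm$decay_length_um)  # Inf distance -> 0
    mean_int <- if (cm$direction == "up_near_plaque")
      cm$baseline + cm$amplitude * decay else
      cm$baseline + cm$amplitude * (1 - decay)
    noise <- if (cfg$noise_sd > 0) rnorm(nr * nc, 0, cfg$noise_sd) else 0
    channels[[nm]] <- pmax(mean_int + noise, 0)
  }

  truth <- tibble(plaque_id = seq_len(cfg$n_plaques),
                  center_row = centers[, 1], center_col = centers[, 2],
                  radius_um = radii)
  attr(truth, "channel_models") <- cfg$channel_models
  structure(list(channels = channels, pixel_size_um = cfg$pixel_size_um,
                 truth = truth, config = cfg), class = "mg_plaque_image")
}

#' Write / read a plaque image as multi-page TIFF with a JSON sidecar
#'
#' Channels are stored as pages of a 32-bit float TIFF; channel names and the
#' physical pixel size go to `<path>.json`.
#'
#' @param image an `mg_plaque_image` (or a list with `channels` and
#'   `pixel_size_um`).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_plaque_tiff <- function(image, path) {
  tiff::writeTIFF(lapply(image$channels, function(m) {
    m <- m / max(max(m), 1e-12)  # writeTIFF expects [0,1]
    m
  }), path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um,
                            channel_names = names(image$channels),
                            channel_max = vapply(image$channels,
                                                 function(m) max(max(m), 1e-12),
                                                 numeric(1))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plaque_tiff
#' @export
read_plaque_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- purrr::map2(pages, meta$channel_max, function(p, mx) p * mx)
  names(channels) <- meta$channel_names
  structure(list(channels = channels, pixel_size_um = meta$pixel_size_um,
                 truth = NULL), class = "mg_plaque_image")
}
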