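#' Describe one synthetic marker channel
#'
#' Parameters of the punctate field simulated for a single marker. Puncta are
#' rendered as isotropic 2D Gaussians whose width varies from punctum to
#' punctum: `sigma_um` is the median width and `sigma_sdlog` the log-normal
#' spread, emulating the wide range of punctum sizes seen in labelled tissue.
#' Amplitudes (peak brightness above background) are drawn from a normal
#' distribution truncated at 10% of its mean so every punctum is a genuine
#' bright spot.
#'
#' @param name marker label, e.g. `"SV2A"`.
#' @param density_per_100um2 expected puncta density (puncta per 100 um^2);
#'   realised counts are Poisson.
#' @param sigma_um median Gaussian width of a punctum in micrometres. The
#'   default 0.12 um (full width at half maximum ~0.28 um, about 4 pixels at
#'   68 nm/px) matches a diffraction-limited punctum at numerical aperture
#'   1.45 with far-red emission, slightly broadened by the physical extent
#'   of a synaptic terminal.
#' @param sigma_sdlog log-normal sd of per-punctum width jitter.
#' @param amplitude_mean,amplitude_sd mean and sd of punctum peak amplitude
#'   above background (a.u.).
#' @return a `synth_channel` list.
#' @export
synth_channel <- function(name, density_per_100um2,
                          sigma_um = 0.12, sigma_sdlog = 0.15,
                          amplitude_mean = 400, amplitude_sd = 80) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (density_per_100um2 < 0) stop("density must be >= 0")
  if (sigma_um <= 0) stop("sigma_um must be > 0")
  if (amplitude_mean <= 0) stop("amplitude_mean must be > 0")
  if (amplitude_sd < 0) stop("amplitude_sd must be >= 0")
  structure(list(name = name, density_per_100um2 = density_per_100um2,
                 sigma_um = sigma_um, sigma_sdlog = sigma_sdlog,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd),
            class = "synth_channel")
}

#' Describe a cross-channel relation between two synthetic markers
#'
#' A fraction `fraction` of channel-B puncta are placed relative to distinct
#' channel-A puncta: in `"colocalized"` mode at the A centroid plus a uniform
#' jitter of at most one pixel (two markers in the same terminal); in
#' `"juxtaposed"` mode displaced by `offset_nm` in a uniform random direction
#' (a presynaptic punctum apposed to a postsynaptic punctum across the
#' synaptic cleft). The default 200 nm offset keeps juxtaposed pairs
#' resolvable yet adjacent at a 68 nm pixel size.
#'
#' @param a,b channel names (B puncta are placed relative to A puncta).
#' @param fraction fraction of B puncta paired with an A punctum, in `[0, 1]`.
#' @param mode `"colocalized"` or `"juxtaposed"`.
#' @param offset_nm centroid separation used in juxtaposed mode.
#' @return a `synth_pair` list.
#' @export
synth_pair <- function(a, b, fraction,
                       mode = c("colocalized", "juxtaposed"),
                       offset_nm = 200) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (offset_nm < 0) stop("offset_nm must be >= 0")
  if (identical(a, b)) stop("a pair needs two distinct channels")
  structure(list(a = a, b = b, fraction = fraction, mode = mode,
                 offset_nm = offset_nm),
            class = "synth_pair")
}

#' Configuration for a synthetic multi-channel field
#'
#' Collects everything needed to simulate one imaged field: its physical
#' size, the per-channel punctum statistics, optional cross-channel pairing
#' rules, and the camera model (flat background, optional Poisson shot noise
#' on signal plus background, additive Gaussian read noise). The defaults
#' give a signal-to-noise ratio of about 10 for an average punctum
#' (amplitude 400 over noise sd `sqrt(100 + 37^2)` ~ 39).
#'
#' @param field_size_um `c(width, height)` of the field in micrometres.
#' @param channels list of [synth_channel()] descriptions.
#' @param pairs list of [synth_pair()] relations; a channel may appear as the
#'   dependent (`b`) side of at most one pair.
#' @param background flat background level (a.u.).
#' @param read_noise_sd sd of additive Gaussian read noise (a.u.).
#' @param shot_noise apply Poisson shot noise to signal plus background?
#' @param pixel_size_nm,bit_depth acquisition geometry, as in [micrograph()].
#' @param seed default random seed used by [generate_field()].
#' @return a `synth_config` list.
#' @export
synth_config <- function(field_size_um = c(100, 100), channels,
                         pairs = list(), background = 100,
                         read_noise_sd = 37, shot_noise = TRUE,
                         pixel_size_nm = 68, bit_depth = 12, seed = NULL) {
  stopifnot(length(field_size_um) == 2, all(field_size_um > 0))
  if (inherits(channels, "synth_channel")) channels <- list(channels)
  stopifnot(length(channels) >= 1,
            all(vapply(channels, inherits, TRUE, "synth_channel")))
  if (inherits(pairs, "synth_pair")) pairs <- list(pairs)
  stopifnot(all(vapply(pairs, inherits, TRUE, "synth_pair")))
  if (background < 0) stop("background must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  names(channels) <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(names(channels))) stop("duplicate channel names")
  for (p in pairs) {
    if (!p$a %in% names(channels) || !p$b %in% names(channels)) {
      stop(sprintf("pair %s-%s names an unknown channel", p$a, p$b))
    }
    if (p$fraction > 0 && channels[[p$a]]$density_per_100um2 == 0) {
      stop(sprintf(
        "pair %s-%s: fraction > 0 but reference channel %s has density 0",
        p$a, p$b, p$a))
    }
  }
  bs <- vapply(pairs, `[[`, "", "b")
  if (anyDuplicated(bs)) {
    stop("a channel may appear as the dependent (b) side of at most one pair")
  }
  structure(list(field_size_um = as.numeric(field_size_um),
                 channels = channels, pairs = pairs,
                 background = background, read_noise_sd = read_noise_sd,
                 shot_noise = shot_noise, pixel_size_nm = pixel_size_nm,
                 bit_depth = as.integer(bit_depth), seed = seed),
            class = "synth_config")
}

#' Simulate a multi-channel punctate field with known ground truth
#'
#' Draws Poisson numbers of puncta per channel (mean `density * area / 100`),
#' places them uniformly (or relative to a partner channel for paired
#' puncta), renders each punctum as an isotropic Gaussian
#' `A * exp(-r^2 / (2 sigma^2))` on the flat background, and applies the
#' configured camera noise. The ground truth records every punctum before
#' noise: continuous centroid, amplitude, width and pairing.
#'
#' @param config a [synth_config()].
#' @param seed random seed; defaults to `config$seed`. The same seed yields
#'   bit-identical output.
#' @param render if `FALSE`, skip image rendering and return only the ground
#'   truth (fast path for point-pattern studies).
#' @return list with `images` (named list of [micrograph()], `NULL` when
#'   `render = FALSE`), `truth` (data frame: `channel`, `x_um`, `y_um`,
#'   `sigma_um`, `amplitude`, `pair_id`, `pair_channel`, `pair_mode`) and the
#'   echoed `config`.
#' @export
generate_field <- function(config, seed = config$seed, render = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  s <- config$pixel_size_nm / 1000
  nx <- round(config$field_size_um[1] / s)
  ny <- round(config$field_size_um[2] / s)
  w_um <- nx * s
  h_um <- ny * s
  max_sigma <- max(vapply(config$channels, `[[`, 0, "sigma_um"))
  if (min(w_um, h_um) < 6 * max_sigma) {
    stop(sprintf(
      "field (%.2f x %.2f um) is too small to hold one punctum of width %.2f um (needs >= %.2f um on each side)",
      w_um, h_um, max_sigma, 6 * max_sigma))
  }
  area <- w_um * h_um

  truth_parts <- list()
  for (ch in config$channels) {
    n <- stats::rpois(1, ch$density_per_100um2 * area / 100)
    sig <- ch$sigma_um * stats::rlnorm(n, 0, ch$sigma_sdlog)
    amp <- pmax(stats::rnorm(n, ch$amplitude_mean, ch$amplitude_sd),
                0.1 * ch$amplitude_mean)
    truth_parts[[ch$name]] <- data.frame(
      channel = rep(ch$name, n),
      x_um = stats::runif(n, 0, w_um),
      y_um = stats::runif(n, 0, h_um),
      sigma_um = sig, amplitude = amp,
      pair_id = rep(NA_integer_, n),
      pair_channel = rep(NA_character_, n),
      pair_mode = rep(NA_character_, n),
      stringsAsFactors = FALSE)
  }

  pair_counter <- 0L
  for (p in config$pairs) {
    a <- truth_parts[[p$a]]
    b <- truth_parts[[p$b]]
    nb <- nrow(b)
    if (nb == 0) next
    paired <- which(stats::runif(nb) < p$fraction)
    if (length(paired) > nrow(a)) {
      stop(sprintf(
        "pair %s-%s: %d puncta to pair but only %d available in channel %s",
        p$a, p$b, length(paired), nrow(a), p$a))
    }
    if (length(paired) > 0) {
      anchors <- sample(nrow(a), length(paired))
      if (p$mode == "colocalized") {
        # uniform jitter within one pixel of the anchor centroid
        r <- s * sqrt(stats::runif(length(paired)))
        th <- stats::runif(length(paired), 0, 2 * pi)
      } else {
        r <- rep(p$offset_nm / 1000, length(paired))
        th <- stats::runif(length(paired), 0, 2 * pi)
      }
      b$x_um[paired] <- a$x_um[anchors] + r * cos(th)
      b$y_um[paired] <- a$y_um[anchors] + r * sin(th)
      ids <- pair_counter + seq_along(paired)
      pair_counter <- pair_counter + length(paired)
      b$pair_id[paired] <- ids
      b$pair_channel[paired] <- p$a
      b$pair_mode[paired] <- p$mode
      a$pair_id[anchors] <- ids
      a$pair_channel[anchors] <- p$b
      a$pair_mode[anchors] <- p$mode
      truth_parts[[p$a]] <- a
    }
    truth_parts[[p$b]] <- b
  }

  truth <- do.call(rbind, truth_parts)
  rownames(truth) <- NULL

  images <- NULL
  if (render) {
    images <- lapply(config$channels, function(ch) {
      tr <- truth[truth$channel == ch$name, , drop = FALSE]
      px <- render_puncta(tr, nx, ny, s, config$background)
      px <- apply_camera_noise(px, config)
      micrograph(px, pixel_size_nm = config$pixel_size_nm,
                 bit_depth = config$bit_depth, channel = ch$name)
    })
  }
  list(images = images, truth = truth, config = config)
}

# Render puncta as Gaussians on a flat background. Noise-free: the integral
# of the rendered image equals background*area + sum(2*pi*sigma^2*A) up to
# pixel discretisation and edge truncation.
render_puncta <- function(truth, nx, ny, s, background) {
  px <- matrix(background, nrow = ny, ncol = nx)
  if (nrow(truth) == 0) return(px)
  xs <- (seq_len(nx) - 0.5) * s
  ys <- (seq_len(ny) - 0.5) * s
  for (k in seq_len(nrow(truth))) {
    sig <- truth$sigma_um[k]
    half <- ceiling(4 * sig / s) + 1L
    j0 <- floor(truth$x_um[k] / s) + 1L
    i0 <- floor(truth$y_um[k] / s) + 1L
    jj <- max(1L, j0 - half):min(nx, j0 + half)
    ii <- max(1L, i0 - half):min(ny, i0 + half)
    if (length(jj) == 0 || length(ii) == 0) next
    gx <- exp(-((xs[jj] - truth$x_um[k])^2) / (2 * sig^2))
    gy <- exp(-((ys[ii] - truth$y_um[k])^2) / (2 * sig^2))
    px[ii, jj] <- px[ii, jj] + truth$amplitude[k] * outer(gy, gx)
  }
  px
}

# Camera model: optional Poisson shot noise on (signal + background), then
# additive Gaussian read noise, then integer quantisation clipped to the
# container range. A noise-free configuration returns the ideal expectation
# image untouched (no quantisation).
apply_camera_noise <- function(px, config) {
  noisy <- config$shot_noise || config$read_noise_sd > 0
  if (config$shot_noise) {
    px <- matrix(stats::rpois(length(px), lambda = px),
                 nrow = nrow(px), ncol = ncol(px))
  }
  if (config$read_noise_sd > 0) {
    px <- px + stats::rnorm(length(px), 0, config$read_noise_sd)
  }
  if (noisy) px <- round(px)
  px[px < 0] <- 0
  maxval <- 2^config$bit_depth - 1
  px[px > maxval] <- maxval
  px
}

#' Split a micrograph into a dense grid of non-overlapping tiles
#'
#' Mirrors mosaic acquisition in which adjacent tiles are scanned without
#' overlap: concatenating the tiles in grid order reproduces the input
#' exactly. If the image is not an exact multiple of the tile shape, set
#' `pad = TRUE` to extend the bottom/right edge with `pad_value`.
#'
#' @param m a [micrograph()].
#' @param tile_shape_px `c(height, width)` of one tile in pixels; the default
#'   is the 942 x 920 acquisition tile.
#' @param pad pad the image to a whole number of tiles?
#' @param pad_value fill value used when padding.
#' @return a `tile_grid`: list with `tiles` (list-matrix of pixel matrices),
#'   `tile_shape_px`, `grid_dim`, and the shared `pixel_size_nm`,
#'   `bit_depth`, `channel`.
#' @export
tile_montage <- function(m, tile_shape_px = c(942, 920), pad = FALSE,
                         pad_value = 0) {
  stopifnot(inherits(m, "micrograph"))
  tile_shape_px <- as.integer(tile_shape_px)
  if (length(tile_shape_px) != 2 || any(tile_shape_px <= 0)) {
    stop("tile_shape_px must be two positive integers (height, width)")
  }
  px <- m$pixels
  th <- tile_shape_px[1]; tw <- tile_shape_px[2]
  if (nrow(px) %% th != 0 || ncol(px) %% tw != 0) {
    if (!pad) {
      stop(sprintf(
        "image %d x %d is not a whole number of %d x %d tiles; set pad = TRUE",
        nrow(px), ncol(px), th, tw))
    }
    nr <- ceiling(nrow(px) / th) * th
    nc <- ceiling(ncol(px) / tw) * tw
    padded <- matrix(pad_value, nr, nc)
    padded[seq_len(nrow(px)), seq_len(ncol(px))] <- px
    px <- padded
  }
  gr <- nrow(px) %/% th
  gc <- ncol(px) %/% tw
  tiles <- vector("list", gr * gc)
  dim(tiles) <- c(gr, gc)
  for (r in seq_len(gr)) {
    for (cc in seq_len(gc)) {
      tiles[[r, cc]] <- px[((r - 1) * th + 1):(r * th),
                           ((cc - 1) * tw + 1):(cc * tw)]
    }
  }
  structure(list(tiles = tiles, tile_shape_px = tile_shape_px,
                 grid_dim = c(gr, gc), pixel_size_nm = m$pixel_size_nm,
                 bit_depth = m$bit_depth, channel = m$channel),
            class = "tile_grid")
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching of detections to true centroids in ascending
#' distance order, accepting pairs closer than `match_dist_um`. Recall is the
#' matched fraction of the truth, precision the matched fraction of the
#' detections, and the localisation error is the root-mean-square matched
#' distance. With both sets empty, recall and precision are defined as 1
#' (nothing to find, nothing found).
#'
#' @param detected a [detect_puncta()] result or data frame with
#'   `x_um`/`y_um`.
#' @param truth ground-truth centroids for the same channel and field, same
#'   accepted forms.
#' @param match_dist_um maximum centroid distance for a valid match.
#' @return list with `recall`, `precision`, `rmse_um`, `n_matched`,
#'   `n_truth`, `n_detected`.
#' @export
evaluate_detection <- function(detected, truth, match_dist_um) {
  stopifnot(match_dist_um > 0)
  d <- point_coords(detected)
  t <- point_coords(truth)
  if (nrow(t) == 0 && nrow(d) == 0) {
    return(list(recall = 1, precision = 1, rmse_um = 0, n_matched = 0L,
                n_truth = 0L, n_detected = 0L))
  }
  mm <- greedy_match_points(d$x_um, d$y_um, t$x_um, t$y_um, match_dist_um)
  n <- nrow(mm)
  list(recall = if (nrow(t) == 0) 1 else n / nrow(t),
       precision = if (nrow(d) == 0) 1 else n / nrow(d),
       rmse_um = if (n == 0) NA_real_ else sqrt(mean(mm$dist^2)),
       n_matched = n, n_truth = nrow(t), n_detected = nrow(d))
}

#' Write a simulated field to disk as plain files
#'
#' One 16-bit TIFF per channel, the ground truth as CSV and the
#' configuration as YAML, so a simulated dataset can be consumed by the same
#' file-based workflow as an acquired one.
#'
#' @param field result of [generate_field()] with `render = TRUE`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir) {
  stopifnot(!is.null(field$images))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(field$images)) {
    write_micrograph_tiff(field$images[[nm]],
                          file.path(dir, paste0(nm, ".tif")))
  }
  utils::write.csv(field$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- field$config
  yaml::write_yaml(list(
    field_size_um = cfg$field_size_um,
    channels = lapply(unname(cfg$channels), unclass),
    pairs = lapply(unname(cfg$pairs), unclass),
    background = cfg$background, read_noise_sd = cfg$read_noise_sd,
    shot_noise = cfg$shot_noise, pixel_size_nm = cfg$pixel_size_nm,
    bit_depth = cfg$bit_depth, seed = cfg$seed
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}
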