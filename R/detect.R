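#' Detection parameters for one marker
#'
#' The three knobs of punctum detection: the expected punctum radius, a
#' quality threshold on the blob-filter response and an intensity threshold
#' on the disc-mean brightness. In practice these are established once per
#' antibody marker and then reused for batch processing.
#'
#' @param punctum_radius_um expected punctum radius in micrometres; the blob
#'   filter is matched to this scale (`sigma = radius / sqrt(2)`).
#' @param quality_threshold minimum filter response at the punctum centre, or
#'   `"auto"` to use the mean quality of all candidate maxima in the image
#'   (the "mean quality threshold" mode).
#' @param intensity_threshold minimum disc-mean intensity (a.u.) of a
#'   retained punctum.
#' @param subpixel refine centroids by a quadratic fit of the response peak?
#' @param exclude_border discard maxima within one radius of the image edge
#'   (avoids truncated-disc intensity bias)?
#' @return a `detection_params` list.
#' @export
detection_params <- function(punctum_radius_um = 0.2,
                             quality_threshold = "auto",
                             intensity_threshold = 0,
                             subpixel = TRUE,
                             exclude_border = TRUE) {
  if (!is.numeric(punctum_radius_um) || punctum_radius_um <= 0) {
    stop("punctum_radius_um must be > 0")
  }
  auto <- identical(quality_threshold, "auto")
  if (!auto && (!is.numeric(quality_threshold) ||
                !is.finite(quality_threshold))) {
    stop("quality_threshold must be a finite number or \"auto\"")
  }
  if (!is.numeric(intensity_threshold) || !is.finite(intensity_threshold)) {
    stop("intensity_threshold must be finite")
  }
  structure(list(punctum_radius_um = punctum_radius_um,
                 quality_threshold = quality_threshold,
                 intensity_threshold = intensity_threshold,
                 subpixel = isTRUE(subpixel),
                 exclude_border = isTRUE(exclude_border)),
            class = "detection_params")
}

#' Scale-normalised Laplacian-of-Gaussian blob response
#'
#' Convolves the image with the negated, scale-normalised
#' Laplacian-of-Gaussian kernel at `sigma = radius_um / sqrt(2)`, so bright
#' blobs of the matched size become positive peaks. The kernel is discretised
#' on a `+-4 sigma` support and recentred to exact zero sum, hence a constant
#' image maps to zero response; the filter is linear in the input. Borders
#' use edge replication.
#'
#' For a rendered Gaussian punctum of amplitude `A` and width equal to the
#' filter sigma the peak response is `A / 2`, which makes quality thresholds
#' directly interpretable on the amplitude scale.
#'
#' @param image a [micrograph()].
#' @param radius_um punctum radius the filter is matched to; must be at least
#'   one pixel.
#' @return numeric matrix of the same shape as the image.
#' @export
log_response <- function(image, radius_um) {
  stopifnot(inherits(image, "micrograph"))
  s <- px_um(image)
  if (radius_um < s) {
    stop(sprintf(
      "radius_um = %.3f um is below the 1-pixel minimum of %.3f um",
      radius_um, s))
  }
  sigma_px <- (radius_um / sqrt(2)) / s
  k <- log_kernel(sigma_px)
  EBImage::filter2(image$pixels, k, boundary = "replicate")
}

# Negated scale-normalised LoG kernel, zero-sum on its discrete support.
log_kernel <- function(sigma_px) {
  half <- max(2L, ceiling(4 * sigma_px))
  idx <- -half:half
  r2 <- outer(idx^2, idx^2, "+")
  g <- exp(-r2 / (2 * sigma_px^2)) / (2 * pi * sigma_px^2)
  k <- (2 - r2 / sigma_px^2) * g
  k - mean(k)
}

#' Detect puncta in one channel
#'
#' TrackMate-style spot detection: local maxima of the [log_response()] map
#' with a minimum separation of one punctum radius are taken as candidates;
#' candidates are kept when their quality (response at the maximum) reaches
#' the quality threshold and their disc-mean intensity reaches the intensity
#' threshold. Non-maximum suppression keeps the higher-quality punctum of any
#' conflicting pair, breaking exact ties by scan order, so the output is
#' deterministic. Optional subpixel refinement fits a separable quadratic to
#' the response peak. Maxima within one radius of the border (when
#' `exclude_border`) or outside the region mask are discarded.
#'
#' @param image a [micrograph()].
#' @param params a [detection_params()].
#' @param roi_mask optional logical (or 0/1) matrix congruent with the image;
#'   `NULL` means the whole image. Its `TRUE` pixel count defines the region
#'   area used for densities.
#' @param marker,region labels stored in the result; `marker` defaults to the
#'   image channel.
#' @return a `puncta_set`: list with `marker`, `region`, `puncta` (data frame
#'   ordered by descending quality: `x_um`, `y_um`, `quality`,
#'   `mean_intensity`, `radius_um`), `roi_area_um2` and `pixel_size_nm`.
#' @export
detect_puncta <- function(image, params, roi_mask = NULL,
                          marker = image$channel, region = "") {
  stopifnot(inherits(image, "micrograph"), inherits(params, "detection_params"))
  px <- image$pixels
  s <- px_um(image)
  if (max(px) >= 2^image$bit_depth - 1) {
    warning("image contains saturated pixels; intensities may be clipped")
  }
  if (!is.null(roi_mask)) {
    if (!all(dim(roi_mask) == dim(px))) {
      stop("roi_mask must be congruent with the image")
    }
    roi_mask <- roi_mask > 0
    area_um2 <- sum(roi_mask) * s^2
    if (area_um2 == 0) {
      warning("empty ROI: returning an empty puncta set with area 0")
      return(empty_puncta_set(marker, region, 0, image$pixel_size_nm,
                              flag = "empty_roi"))
    }
  } else {
    area_um2 <- length(px) * s^2
  }

  resp <- log_response(image, params$punctum_radius_um)
  rad_px <- params$punctum_radius_um / s
  m <- max(1L, round(rad_px))
  brush <- EBImage::makeBrush(2L * m + 1L, shape = "disc")
  # grayscale dilation == moving maximum over the disc neighbourhood
  shift <- min(resp)
  mx <- EBImage::dilate(resp - shift, brush) + shift
  # the shift round-trip perturbs mx by ~1 ulp; compare with a tolerance so
  # genuine peaks are not lost to floating-point noise
  tol <- 1e-9 * max(1, max(resp) - shift)
  cand <- which(resp + tol >= mx & resp > 0)
  res <- empty_puncta_set(marker, region, area_um2, image$pixel_size_nm)
  if (length(cand) == 0) return(res)

  ci <- ((cand - 1) %% nrow(resp)) + 1
  cj <- ((cand - 1) %/% nrow(resp)) + 1
  q <- resp[cand]
  # deterministic suppression: strongest first, scan order on exact ties
  o <- order(-q, ci, cj)
  ci <- ci[o]; cj <- cj[o]; q <- q[o]
  keep <- nms_keep(ci, cj, rad_px)
  ci <- ci[keep]; cj <- cj[keep]; q <- q[keep]

  if (params$exclude_border) {
    inside <- (ci - 0.5) * s >= params$punctum_radius_um &
      (cj - 0.5) * s >= params$punctum_radius_um &
      (nrow(px) - ci + 0.5) * s >= params$punctum_radius_um &
      (ncol(px) - cj + 0.5) * s >= params$punctum_radius_um
    ci <- ci[inside]; cj <- cj[inside]; q <- q[inside]
  }
  if (!is.null(roi_mask) && length(ci) > 0) {
    inroi <- roi_mask[cbind(ci, cj)]
    ci <- ci[inroi]; cj <- cj[inroi]; q <- q[inroi]
  }
  if (length(ci) == 0) return(res)

  qt <- if (identical(params$quality_threshold, "auto")) mean(q)
        else params$quality_threshold
  pass <- q >= qt
  ci <- ci[pass]; cj <- cj[pass]; q <- q[pass]
  if (length(ci) == 0) return(res)

  if (params$subpixel) {
    off <- quadratic_refine(resp, ci, cj)
  } else {
    off <- matrix(0, length(ci), 2)
  }
  x_um <- (cj - 0.5 + off[, 1]) * s
  y_um <- (ci - 0.5 + off[, 2]) * s

  mi <- vapply(seq_along(ci), function(k) {
    disc_mean_intensity(px, s, x_um[k], y_um[k], params$punctum_radius_um)
  }, 0)
  pass <- mi >= params$intensity_threshold
  res$puncta <- data.frame(
    x_um = x_um[pass], y_um = y_um[pass], quality = q[pass],
    mean_intensity = mi[pass],
    radius_um = rep(params$punctum_radius_um, sum(pass)))
  res
}

empty_puncta_set <- function(marker, region, area_um2, pixel_size_nm,
                             flag = NULL) {
  structure(list(
    marker = marker, region = region,
    puncta = data.frame(x_um = numeric(0), y_um = numeric(0),
                        quality = numeric(0), mean_intensity = numeric(0),
                        radius_um = numeric(0)),
    roi_area_um2 = area_um2, pixel_size_nm = pixel_size_nm, flag = flag),
    class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta, marker '%s', region '%s', %.1f um^2\n",
              nrow(x$puncta), x$marker, x$region, x$roi_area_um2))
  invisible(x)
}

# Keep candidates (already sorted strongest-first) that are farther than
# rad_px from every stronger kept candidate.
nms_keep <- function(ci, cj, rad_px) {
  n <- length(ci)
  keep <- logical(n)
  kept_i <- numeric(0)
  kept_j <- numeric(0)
  r2 <- rad_px^2
  for (k in seq_len(n)) {
    if (length(kept_i) == 0 ||
        all((kept_i - ci[k])^2 + (kept_j - cj[k])^2 > r2)) {
      keep[k] <- TRUE
      kept_i <- c(kept_i, ci[k])
      kept_j <- c(kept_j, cj[k])
    }
  }
  keep
}

# Separable quadratic (parabolic) refinement of a peak; offsets clamped to
# half a pixel. Returns cbind(dx, dy) in pixels.
quadratic_refine <- function(resp, ci, cj) {
  nr <- nrow(resp); nc <- ncol(resp)
  dx <- numeric(length(ci))
  dy <- numeric(length(ci))
  for (k in seq_along(ci)) {
    i <- ci[k]; j <- cj[k]
    if (j > 1 && j < nc) {
      den <- resp[i, j - 1] - 2 * resp[i, j] + resp[i, j + 1]
      if (den < 0) dx[k] <- 0.5 * (resp[i, j - 1] - resp[i, j + 1]) / den
    }
    if (i > 1 && i < nr) {
      den <- resp[i - 1, j] - 2 * resp[i, j] + resp[i + 1, j]
      if (den < 0) dy[k] <- 0.5 * (resp[i - 1, j] - resp[i + 1, j]) / den
    }
  }
  cbind(pmin(pmax(dx, -0.5), 0.5), pmin(pmax(dy, -0.5), 0.5))
}

# Mean of pixel values whose centres lie within radius_um of (x_um, y_um).
disc_mean_intensity <- function(px, s, x_um, y_um, radius_um) {
  jr <- max(1L, floor((x_um - radius_um) / s) + 1L):
        min(ncol(px), ceiling((x_um + radius_um) / s))
  ir <- max(1L, floor((y_um - radius_um) / s) + 1L):
        min(nrow(px), ceiling((y_um + radius_um) / s))
  xs <- (jr - 0.5) * s
  ys <- (ir - 0.5) * s
  inside <- outer((ys - y_um)^2, (xs - x_um)^2, "+") <= radius_um^2
  if (!any(inside)) return(NA_real_)
  mean(px[ir, jr][inside])
}

#' Mean intensity within a disc
#'
#' Arithmetic mean of the pixel values whose centres lie within `radius_um`
#' of the centroid — the disc-mean punctum intensity in arbitrary units.
#'
#' @param image a [micrograph()].
#' @param centroid `c(x_um, y_um)`.
#' @param radius_um disc radius in micrometres.
#' @return mean intensity (a.u.).
#' @export
measure_intensity <- function(image, centroid, radius_um) {
  stopifnot(inherits(image, "micrograph"), length(centroid) == 2,
            radius_um > 0)
  s <- px_um(image)
  w <- ncol(image$pixels) * s
  h <- nrow(image$pixels) * s
  if (centroid[1] + radius_um <= 0 || centroid[1] - radius_um >= w ||
      centroid[2] + radius_um <= 0 || centroid[2] - radius_um >= h) {
    stop("measurement disc lies fully outside the image")
  }
  v <- disc_mean_intensity(image$pixels, s, centroid[1], centroid[2],
                           radius_um)
  if (is.na(v)) stop("no pixel centre falls inside the measurement disc")
  v
}

#' Signal-to-noise ratio of a detected punctum population
#'
#' `SNR = (mean punctum peak intensity - background mean) / background sd`,
#' where the peak intensity of a punctum is the image value at the pixel
#' containing its centroid. The background is a user-supplied mask or, by
#' default, the lowest decile of image pixels (a signal-free surrogate).
#'
#' @param image a [micrograph()].
#' @param puncta a `puncta_set` (detections or ground-truth centroids).
#' @param background_mask optional logical matrix congruent with the image.
#' @return SNR scalar; `NaN` with a warning for an empty puncta set.
#' @export
compute_snr <- function(image, puncta, background_mask = NULL) {
  stopifnot(inherits(image, "micrograph"))
  pts <- point_coords(puncta)
  px <- image$pixels
  if (is.null(background_mask)) {
    background_mask <- px <= stats::quantile(px, 0.1)
  } else {
    if (!all(dim(background_mask) == dim(px))) {
      stop("background_mask must be congruent with the image")
    }
    background_mask <- background_mask > 0
    if (!any(background_mask)) stop("background mask is empty")
  }
  bg <- px[background_mask]
  if (stats::sd(bg) == 0) stop("background has zero variance; SNR undefined")
  if (nrow(pts) == 0) {
    warning("empty puncta set: SNR is NaN")
    return(NaN)
  }
  s <- px_um(image)
  i <- pmin(pmax(floor(pts$y_um / s) + 1L, 1L), nrow(px))
  j <- pmin(pmax(floor(pts$x_um / s) + 1L, 1L), ncol(px))
  peaks <- px[cbind(i, j)]
  (mean(peaks) - mean(bg)) / stats::sd(bg)
}

#' Write / read puncta tables as CSV
#'
#' The exported text format mirrors the workflow in which centroid
#' coordinates and intensities are written per channel and re-imported for
#' downstream statistics: columns `marker`, `region`, `x_um`, `y_um`,
#' `quality`, `mean_intensity`, `radius_um`, with the region area recorded in
#' a `# roi_area_um2:` header comment.
#'
#' @param ps a `puncta_set`.
#' @param path CSV path.
#' @return `path` (write) or a `puncta_set` (read).
#' @export
write_puncta_csv <- function(ps, path) {
  stopifnot(inherits(ps, "puncta_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# roi_area_um2: %.6f", ps$roi_area_um2), con)
  writeLines(sprintf("# pixel_size_nm: %.6f", ps$pixel_size_nm), con)
  df <- cbind(marker = ps$marker, region = ps$region, ps$puncta)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_puncta_csv
#' @export
read_puncta_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  area <- as.numeric(sub("# roi_area_um2: *", "", hdr[1]))
  psz <- as.numeric(sub("# pixel_size_nm: *", "", hdr[2]))
  df <- utils::read.csv(path, comment.char = "#")
  marker <- if (nrow(df) > 0) df$marker[1] else ""
  region <- if (nrow(df) > 0) df$region[1] else ""
  out <- empty_puncta_set(marker, region, area, psz)
  out$puncta <- df[, c("x_um", "y_um", "quality", "mean_intensity",
                       "radius_um")]
  out
}
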