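# Design-level validation harnesses: simulate-detect-recover experiments
# over a full marker x region design, colocalization recovery and the
# spatial-independence null. These drive the package's end-to-end
# correctness checks and the analysis scripts.

#' Density recovery across a marker-by-region design
#'
#' For every cell of a markers x regions density table, simulates one field
#' at that ground-truth density, runs detection with the matched-filter
#' radius, and compares the detected density with the realised ground-truth
#' density inside an interior region mask (both restricted to the same mask,
#' whose inset keeps truncated border puncta out of the comparison).
#'
#' @param densities markers x regions matrix of target densities (puncta per
#'   100 um^2).
#' @param seed base seed; each cell derives its own seed deterministically.
#' @param field_size_um simulated field edge length (square field).
#' @param inset_um interior mask inset from the image border.
#' @param quality_threshold absolute detection quality threshold (a.u.).
#' @param sigma_um median punctum width passed to [synth_channel()].
#' @return data frame with one row per cell: `marker`, `region`,
#'   `true_density` (realised, in-mask), `detected_density`, `ratio`,
#'   `recall`, `precision`, `rmse_um`, `n_truth`, `n_detected`, `n_matched`.
#' @export
recover_density_design <- function(densities, seed,
                                   field_size_um = 35, inset_um = 0.5,
                                   quality_threshold = 60,
                                   sigma_um = 0.12) {
  stopifnot(is.matrix(densities))
  radius <- sigma_um * sqrt(2)
  params <- detection_params(radius, quality_threshold = quality_threshold)
  out <- list()
  cell <- 0L
  for (ma in rownames(densities)) {
    for (re in colnames(densities)) {
      cell <- cell + 1L
      cfg <- synth_config(
        field_size_um = c(field_size_um, field_size_um),
        channels = list(synth_channel(ma, densities[ma, re],
                                      sigma_um = sigma_um)),
        seed = seed + cell)
      f <- generate_field(cfg)
      img <- f$images[[ma]]
      s <- img$pixel_size_nm / 1000
      n <- nrow(img$pixels)
      k <- ceiling(inset_um / s)
      mask <- matrix(FALSE, n, ncol(img$pixels))
      mask[(k + 1):(n - k), (k + 1):(ncol(img$pixels) - k)] <- TRUE
      ps <- detect_puncta(img, params, roi_mask = mask, region = re)
      tr <- f$truth
      i <- floor(tr$y_um / s) + 1
      j <- floor(tr$x_um / s) + 1
      ok <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
      ok[ok] <- mask[cbind(i[ok], j[ok])]
      tr <- tr[ok, , drop = FALSE]
      ev <- evaluate_detection(ps, tr, 2 * radius)
      true_d <- 100 * nrow(tr) / ps$roi_area_um2
      det_d <- puncta_density(ps)
      out[[cell]] <- data.frame(
        marker = ma, region = re, true_density = true_d,
        detected_density = det_d,
        ratio = if (true_d > 0) det_d / true_d else NA_real_,
        recall = ev$recall, precision = ev$precision, rmse_um = ev$rmse_um,
        n_truth = ev$n_truth, n_detected = ev$n_detected,
        n_matched = ev$n_matched)
    }
  }
  do.call(rbind, out)
}

#' Colocalized-fraction recovery from a simulated marker pair
#'
#' Simulates a two-channel point pattern with a configured paired fraction,
#' matches the channels with [match_puncta()] and corrects the observed
#' percentage for chance proximity under spatial independence:
#' `f_hat = (p_obs - p_chance) / (1 - p_chance)`, with `p_chance` from
#' [expected_chance_percent()] at the density of reference puncta not
#' consumed by true pairs. The returned half-width is the 95% binomial
#' confidence interval of `f_hat`.
#'
#' @param rho_A,rho_B channel densities (puncta per 100 um^2).
#' @param fraction configured paired fraction of channel B.
#' @param mode pairing mode, `"colocalized"` or `"juxtaposed"`.
#' @param max_dist_um matching distance; `NULL` for the mode default.
#' @param field_size_um square field edge length per replicate.
#' @param seed base random seed; replicate r uses `seed + r - 1`.
#' @param n_fields number of replicate fields whose counts are pooled
#'   before estimation, mirroring replication across subjects.
#' @return list with `f_hat`, `ci95`, `p_obs`, `p_chance`, `n_B`,
#'   `configured` (all fractions in [0, 1]).
#' @export
recover_coloc_fraction <- function(rho_A, rho_B, fraction,
                                   mode = c("colocalized", "juxtaposed"),
                                   max_dist_um = NULL,
                                   field_size_um = 200, seed = 1,
                                   n_fields = 1) {
  mode <- match.arg(mode)
  n_matched <- 0
  n_b <- 0
  n_avail <- 0
  area <- 0
  dist_used <- NA_real_
  for (r in seq_len(n_fields)) {
    cfg <- synth_config(
      field_size_um = c(field_size_um, field_size_um),
      channels = list(synth_channel("A", rho_A), synth_channel("B", rho_B)),
      pairs = list(synth_pair("A", "B", fraction, mode)),
      seed = seed + r - 1)
    tr <- generate_field(cfg, render = FALSE)$truth
    a <- tr[tr$channel == "A", ]
    b <- tr[tr$channel == "B", ]
    field_area <- prod(cfg$field_size_um)
    A <- puncta_from_truth(a, field_area)
    B <- puncta_from_truth(b, field_area, marker = "B")
    pairing <- match_puncta(A, B, max_dist_um, mode)
    n_matched <- n_matched + nrow(pairing$matches)
    n_b <- n_b + nrow(b)
    # reference puncta not holding a true pair are the chance pool
    n_avail <- n_avail + nrow(a) - sum(!is.na(b$pair_id))
    area <- area + field_area
    dist_used <- pairing$max_dist_um
  }
  p_obs <- n_matched / n_b
  rho_avail <- 100 * max(n_avail, 0) / area
  p_chance <- expected_chance_percent(rho_avail, dist_used) / 100
  f_hat <- (p_obs - p_chance) / (1 - p_chance)
  se <- sqrt(max(p_obs * (1 - p_obs), 1e-12) / n_b) / (1 - p_chance)
  list(f_hat = f_hat, ci95 = 1.96 * se, p_obs = p_obs,
       p_chance = p_chance, n_B = n_b, configured = fraction)
}

#' Null calibration of chance colocalization
#'
#' With independent channels (paired fraction 0), the observed percentage of
#' B puncta matched to an A punctum should equal the analytic Poisson chance
#' level. Returns, for each distance criterion, the observed and expected
#' percentages and the Monte-Carlo standard error of the observation.
#'
#' @param rho_A,rho_B channel densities (puncta per 100 um^2).
#' @param max_dists_um vector of distance criteria to evaluate.
#' @param field_size_um square field edge length.
#' @param seed random seed.
#' @return data frame: `max_dist_um`, `observed_pct`, `expected_pct`,
#'   `mc_se_pct`, `n_B`.
#' @export
null_coloc_calibration <- function(rho_A, rho_B,
                                   max_dists_um = c(0.2, 0.3, 0.5),
                                   field_size_um = 300, seed = 1) {
  cfg <- synth_config(
    field_size_um = c(field_size_um, field_size_um),
    channels = list(synth_channel("A", rho_A), synth_channel("B", rho_B)),
    seed = seed)
  tr <- generate_field(cfg, render = FALSE)$truth
  a <- tr[tr$channel == "A", ]
  b <- tr[tr$channel == "B", ]
  area <- prod(cfg$field_size_um)
  A <- puncta_from_truth(a, area)
  B <- puncta_from_truth(b, area, marker = "B")
  rho_real <- 100 * nrow(a) / area
  out <- lapply(max_dists_um, function(d) {
    pairing <- match_puncta(A, B, d)
    p_obs <- 100 * nrow(pairing$matches) / nrow(b)
    p_exp <- expected_chance_percent(rho_real, d)
    se <- 100 * sqrt(p_exp / 100 * (1 - p_exp / 100) / nrow(b))
    data.frame(max_dist_um = d, observed_pct = p_obs, expected_pct = p_exp,
               mc_se_pct = se, n_B = nrow(b))
  })
  do.call(rbind, out)
}

# Ground-truth rows -> puncta_set (centroids only).
puncta_from_truth <- function(tr, area_um2, marker = "A", region = "",
                              pixel_size_nm = 68) {
  ps <- empty_puncta_set(marker, region, area_um2, pixel_size_nm)
  n <- nrow(tr)
  ps$puncta <- data.frame(x_um = tr$x_um, y_um = tr$y_um,
                          quality = rep(1, n), mean_intensity = rep(1, n),
                          radius_um = rep(0.2, n))
  ps
}
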