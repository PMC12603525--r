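test_that("blob response of a constant image is zero and the filter is linear", {
  m <- micrograph(matrix(300, 80, 80))
  r <- log_response(m, 0.2)
  expect_lt(max(abs(r)), 1e-9)

  cfg <- one_channel_config(10, field = c(6, 6), seed = 2)
  img <- generate_field(cfg)$images$M
  r1 <- log_response(img, 0.2)
  img3 <- micrograph(img$pixels * 3, bit_depth = 14)
  r3 <- log_response(img3, 0.2)
  expect_equal(r3, 3 * r1, tolerance = 1e-9)
})

test_that("response radius below one pixel is rejected with the minimum named", {
  m <- micrograph(matrix(10, 20, 20))
  expect_error(log_response(m, 0.05), "1-pixel minimum")
})

test_that("response maximum lands on a rendered punctum centre", {
  tr <- data.frame(channel = "X", x_um = 3.27, y_um = 2.81, sigma_um = 0.12,
                   amplitude = 400, pair_id = NA, pair_channel = NA,
                   pair_mode = NA)
  px <- synmapr:::render_puncta(tr, 90, 90, 0.068, 100)
  r <- log_response(micrograph(px), matched_radius())
  peak <- which(r == max(r), arr.ind = TRUE)
  x <- (peak[1, 2] - 0.5) * 0.068
  y <- (peak[1, 1] - 0.5) * 0.068
  expect_lt(sqrt((x - 3.27)^2 + (y - 2.81)^2), 0.068)
  # matched-filter peak response is about half the punctum amplitude
  expect_equal(max(r), 200, tolerance = 0.05)
})

test_that("a blank noisy image yields no detections above the noise floor", {
  set.seed(9)
  px <- round(pmax(matrix(rpois(200 * 200, 100) + rnorm(200 * 200, 0, 37),
                          200, 200), 0))
  img <- micrograph(px)
  ps <- detect_puncta(img, detection_params(matched_radius(),
                                            quality_threshold = 60))
  expect_equal(nrow(ps$puncta), 0)
})

test_that("detection on a synthetic field recovers the ground truth", {
  cfg <- one_channel_config(15, field = c(30, 30), seed = 33)
  f <- generate_field(cfg)
  mask <- interior_mask(f$images$M)
  ps <- detect_puncta(f$images$M,
                      detection_params(matched_radius(),
                                       quality_threshold = 60),
                      roi_mask = mask)
  tr <- truth_in_mask(f$truth, mask)
  ev <- evaluate_detection(ps, tr, 0.3)
  expect_gte(ev$recall, 0.95)
  expect_gte(ev$precision, 0.95)
  expect_lt(ev$rmse_um, 0.05)
})

test_that("detection output is deterministic and ordered by quality", {
  cfg <- one_channel_config(12, field = c(15, 15), seed = 14)
  f <- generate_field(cfg)
  p <- detection_params(matched_radius(), quality_threshold = 60)
  ps1 <- detect_puncta(f$images$M, p)
  ps2 <- detect_puncta(f$images$M, p)
  expect_identical(ps1, ps2)
  expect_true(all(diff(ps1$puncta$quality) <= 0))
})

test_that("detection count is monotone in both thresholds", {
  cfg <- one_channel_config(15, field = c(20, 20), seed = 18)
  f <- generate_field(cfg)
  counts_q <- vapply(c(20, 60, 120, 180), function(q) {
    nrow(detect_puncta(f$images$M,
                       detection_params(matched_radius(),
                                        quality_threshold = q))$puncta)
  }, 0)
  expect_true(all(diff(counts_q) <= 0))
  counts_i <- vapply(c(0, 150, 250, 400), function(it) {
    nrow(detect_puncta(f$images$M,
                       detection_params(matched_radius(),
                                        quality_threshold = 60,
                                        intensity_threshold = it))$puncta)
  }, 0)
  expect_true(all(diff(counts_i) <= 0))
})

test_that("subpixel refinement reduces localisation error", {
  cfg <- one_channel_config(10, field = c(25, 25), seed = 27)
  f <- generate_field(cfg)
  mask <- interior_mask(f$images$M)
  tr <- truth_in_mask(f$truth, mask)
  rmse <- vapply(c(TRUE, FALSE), function(sp) {
    ps <- detect_puncta(f$images$M,
                        detection_params(matched_radius(),
                                         quality_threshold = 60,
                                         subpixel = sp),
                        roi_mask = mask)
    evaluate_detection(ps, tr, 0.3)$rmse_um
  }, 0)
  expect_lt(rmse[1], rmse[2])
})

test_that("auto quality threshold equals the mean candidate quality rule", {
  cfg <- one_channel_config(12, field = c(15, 15), seed = 40)
  f <- generate_field(cfg)
  auto <- detect_puncta(f$images$M,
                        detection_params(matched_radius(),
                                         quality_threshold = "auto"))
  low <- detect_puncta(f$images$M,
                       detection_params(matched_radius(),
                                        quality_threshold = 0))
  expect_equal(nrow(auto$puncta),
               sum(low$puncta$quality >= mean(low$puncta$quality)))
})

test_that("detection restricted to an empty ROI is flagged", {
  cfg <- one_channel_config(10, field = c(8, 8), seed = 2)
  f <- generate_field(cfg)
  mask <- matrix(FALSE, nrow(f$images$M$pixels), ncol(f$images$M$pixels))
  expect_warning(
    ps <- detect_puncta(f$images$M,
                        detection_params(matched_radius(),
                                         quality_threshold = 60),
                        roi_mask = mask),
    "empty ROI")
  expect_equal(nrow(ps$puncta), 0)
  expect_equal(ps$roi_area_um2, 0)
})

test_that("disc-mean intensity matches direct pixel enumeration", {
  # constant field: any disc averages to the constant
  m <- micrograph(matrix(300, 50, 50))
  expect_equal(measure_intensity(m, c(1.7, 1.7), 0.3), 300)

  # step edge through the disc centre: mean is the midpoint up to
  # single-pixel discretisation
  px <- matrix(100, 60, 60)
  px[, 31:60] <- 200
  m2 <- micrograph(px)
  centre <- c(30 * 0.068, 30 * 0.068) # on the step, pixel boundary
  v <- measure_intensity(m2, centre, 0.4)
  expect_equal(v, 150, tolerance = 0.05)

  # rendered punctum: oracle enumerates every pixel in the image
  tr <- data.frame(channel = "X", x_um = 2.05, y_um = 1.66, sigma_um = 0.12,
                   amplitude = 380, pair_id = NA, pair_channel = NA,
                   pair_mode = NA)
  px3 <- synmapr:::render_puncta(tr, 60, 60, 0.068, 120)
  m3 <- micrograph(px3)
  r <- 0.25
  acc <- c()
  for (i in 1:60) for (j in 1:60) {
    x <- (j - 0.5) * 0.068; y <- (i - 0.5) * 0.068
    if ((x - 2.05)^2 + (y - 1.66)^2 <= r^2) acc <- c(acc, px3[i, j])
  }
  expect_equal(measure_intensity(m3, c(2.05, 1.66), r), mean(acc))

  expect_error(measure_intensity(m, c(50, 50), 0.3), "outside")
})

test_that("SNR follows its defining formula and matches the camera model", {
  # formula arithmetic: peaks at 30 over background mean 10, sd 2
  px <- matrix(10, 40, 40)
  px[20, 20] <- 30
  bg <- matrix(TRUE, 40, 40); bg[20, 20] <- FALSE
  img <- micrograph(px)
  set.seed(1)
  px_noisy <- px
  px_noisy[bg] <- 10 + rep(c(-2, 2), length.out = sum(bg))
  img <- micrograph(px_noisy)
  ps <- as_puncta_set(19.5 * 0.068, 19.5 * 0.068, 100)
  snr <- compute_snr(img, ps, bg)
  sd_bg <- stats::sd(px_noisy[bg])
  expect_equal(snr, (30 - mean(px_noisy[bg])) / sd_bg)

  # degenerate cases
  expect_error(compute_snr(micrograph(matrix(5, 10, 10)), ps),
               "zero variance")
  expect_warning(
    out <- compute_snr(img, as_puncta_set(numeric(0), numeric(0), 100), bg),
    "empty")
  expect_true(is.nan(out))

  # Monte-Carlo: amplitude A over pure read noise sd r gives SNR ~ A / r,
  # with the background taken from a signal-free mask (pixels more than
  # 1 um away from every punctum)
  A <- 400; r <- 40
  snrs <- vapply(1:20, function(s) {
    cfg <- synth_config(field_size_um = c(20, 20),
                        channels = list(synth_channel("M", 8, sigma_sdlog = 0,
                                                      amplitude_sd = 0)),
                        background = 100, read_noise_sd = r,
                        shot_noise = FALSE, seed = 100 + s)
    f <- generate_field(cfg)
    n <- nrow(f$images$M$pixels)
    bg_mask <- matrix(TRUE, n, n)
    for (k in seq_len(nrow(f$truth))) {
      ii <- max(1, floor((f$truth$y_um[k] - 1) / 0.068)):
            min(n, ceiling((f$truth$y_um[k] + 1) / 0.068))
      jj <- max(1, floor((f$truth$x_um[k] - 1) / 0.068)):
            min(n, ceiling((f$truth$x_um[k] + 1) / 0.068))
      bg_mask[ii, jj] <- FALSE
    }
    compute_snr(f$images$M, f$truth, bg_mask)
  }, 0)
  expect_equal(mean(snrs), A / r, tolerance = 0.1)
})

test_that("puncta tables round-trip through the exported CSV format", {
  cfg <- one_channel_config(10, field = c(10, 10), seed = 6)
  f <- generate_field(cfg)
  ps <- detect_puncta(f$images$M,
                      detection_params(matched_radius(),
                                       quality_threshold = 60),
                      region = "CA1sr")
  path <- withr::local_tempfile(fileext = ".csv")
  write_puncta_csv(ps, path)
  back <- read_puncta_csv(path)
  expect_equal(back$puncta, ps$puncta)
  expect_equal(back$roi_area_um2, ps$roi_area_um2)
  expect_equal(back$region, "CA1sr")
})
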