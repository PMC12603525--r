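test_that("zero-density field is flat background with empty ground truth", {
  cfg <- synth_config(field_size_um = c(10, 10),
                      channels = list(synth_channel("A", 0),
                                      synth_channel("B", 0)),
                      background = 100, read_noise_sd = 0,
                      shot_noise = FALSE, seed = 3)
  f <- generate_field(cfg)
  expect_equal(nrow(f$truth), 0)
  for (img in f$images) {
    expect_true(all(img$pixels == 100))
  }
})

test_that("realised punctum counts are Poisson with mean rho * area / 100", {
  rho <- 17
  cfg <- one_channel_config(rho, field = c(20, 20))
  area <- (round(20 / 0.068) * 0.068)^2
  counts <- vapply(1:120, function(s) {
    nrow(generate_field(cfg, seed = s, render = FALSE)$truth)
  }, 0)
  expected <- rho * area / 100
  # mean within 3 standard errors of the Poisson mean, variance ~ mean
  se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  expect_lt(abs(var(counts) / expected - 1), 0.5)
})

test_that("colocalized fraction is recovered by a nearest-neighbour oracle", {
  f_cfg <- 0.65
  cfg <- synth_config(field_size_um = c(150, 150),
                      channels = list(synth_channel("A", 17),
                                      synth_channel("B", 16)),
                      pairs = list(synth_pair("A", "B", f_cfg)),
                      seed = 11)
  tr <- generate_field(cfg, render = FALSE)$truth
  a <- tr[tr$channel == "A", ]
  b <- tr[tr$channel == "B", ]
  # brute-force nearest-A distance for every B punctum
  nn <- vapply(seq_len(nrow(b)), function(k) {
    min(sqrt((a$x_um - b$x_um[k])^2 + (a$y_um - b$y_um[k])^2))
  }, 0)
  p_hat <- mean(nn <= 0.068) # jitter is at most one pixel
  # chance that an unpaired B lands within 1 px of some A
  p_chance <- 1 - exp(-(17 / 100) * pi * 0.068^2)
  expected <- f_cfg + (1 - f_cfg) * p_chance
  ci <- 1.96 * sqrt(expected * (1 - expected) / nrow(b))
  expect_lt(abs(p_hat - expected), ci + 0.01)
  # pairing bookkeeping: one-to-one per channel pair, partners exist
  expect_false(anyDuplicated(stats::na.omit(b$pair_id)) > 0)
  expect_true(all(stats::na.omit(b$pair_id) %in% a$pair_id))
})

test_that("juxtaposed partners sit at the configured offset", {
  cfg <- synth_config(field_size_um = c(80, 80),
                      channels = list(synth_channel("A", 15),
                                      synth_channel("B", 10)),
                      pairs = list(synth_pair("A", "B", 1, "juxtaposed",
                                              offset_nm = 200)),
                      seed = 5)
  tr <- generate_field(cfg, render = FALSE)$truth
  a <- tr[tr$channel == "A", ]
  b <- tr[tr$channel == "B", ]
  paired_b <- b[!is.na(b$pair_id), ]
  pa <- a[match(paired_b$pair_id, a$pair_id), ]
  d <- sqrt((pa$x_um - paired_b$x_um)^2 + (pa$y_um - paired_b$y_um)^2)
  expect_equal(d, rep(0.2, nrow(paired_b)), tolerance = 1e-10)
})

test_that("noise-free image integral conserves total rendered signal", {
  cfg <- synth_config(field_size_um = c(15, 15),
                      channels = list(synth_channel("A", 20)),
                      background = 50, read_noise_sd = 0, shot_noise = FALSE,
                      seed = 8)
  f <- generate_field(cfg)
  tr <- f$truth
  # keep the field free of edge truncation: drop fields whose puncta are
  # closer than 5 sigma to a border by regenerating deterministically
  s <- 0.068
  n <- nrow(f$images$A$pixels)
  area <- (n * s)^2
  interior <- all(tr$x_um > 5 * tr$sigma_um & tr$y_um > 5 * tr$sigma_um &
                  tr$x_um < n * s - 5 * tr$sigma_um &
                  tr$y_um < n * s - 5 * tr$sigma_um)
  integral <- sum(f$images$A$pixels) * s^2
  expected <- 50 * area + sum(2 * pi * tr$sigma_um^2 * tr$amplitude)
  tol <- if (interior) 1e-3 else 0.02
  expect_equal(integral, expected, tolerance = tol)
})

test_that("the same seed reproduces a field bit-identically", {
  cfg <- one_channel_config(12, field = c(12, 12), seed = 21)
  f1 <- generate_field(cfg)
  f2 <- generate_field(cfg)
  expect_identical(f1$truth, f2$truth)
  expect_identical(f1$images$M$pixels, f2$images$M$pixels)
})

test_that("degenerate configurations raise explicit errors", {
  expect_error(generate_field(one_channel_config(5, field = c(0.3, 0.3))),
               "too small")
  expect_error(
    synth_config(field_size_um = c(50, 50),
                 channels = list(synth_channel("A", 0),
                                 synth_channel("B", 10)),
                 pairs = list(synth_pair("A", "B", 0.5))),
    "density 0")
  expect_error(synth_pair("A", "B", 1.2), "\\[0, 1\\]")
  expect_error(synth_channel("A", -1), ">= 0")
})

test_that("tile_montage partitions exactly and pads when asked", {
  m <- micrograph(matrix(seq_len(1884 * 1840) %% 4096, 1884, 1840))
  g <- tile_montage(m, c(942, 920))
  expect_equal(g$grid_dim, c(2, 2))
  expect_identical(stitch_tiles(g)$pixels, m$pixels)

  one <- micrograph(matrix(7, 942, 920))
  g1 <- tile_montage(one, c(942, 920))
  expect_equal(g1$grid_dim, c(1, 1))
  expect_identical(g1$tiles[[1, 1]], one$pixels)

  odd <- micrograph(matrix(seq_len(1000 * 1000) %% 4096, 1000, 1000))
  expect_error(tile_montage(odd, c(942, 920)), "pad")
  gp <- tile_montage(odd, c(942, 920), pad = TRUE, pad_value = 0)
  expect_equal(gp$grid_dim, c(2, 2))
  st <- stitch_tiles(gp)
  expect_identical(st$pixels[1:1000, 1:1000], odd$pixels)
  expect_error(tile_montage(odd, c(0, 10)), "positive")
})

test_that("detection scoring handles identity, spurious and empty cases", {
  pts <- data.frame(x_um = c(1, 2, 3), y_um = c(1, 1.5, 0.5))
  ev <- evaluate_detection(pts, pts, 0.1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$rmse_um, 0)

  spurious <- rbind(pts, data.frame(x_um = 100 + 1:3, y_um = 100 + 1:3))
  ev2 <- evaluate_detection(spurious, pts, 0.1)
  expect_equal(ev2$recall, 1)
  expect_equal(ev2$precision, 0.5)

  empty <- pts[0, ]
  ev3 <- evaluate_detection(empty, empty, 0.1)
  expect_equal(ev3$recall, 1)
  expect_equal(ev3$precision, 1)
})

test_that("greedy scoring agrees with exhaustive assignment on a toy set", {
  # five truth points and five detections with distinct off-grid offsets
  tx <- c(1.0, 2.3, 3.7, 5.1, 6.4)
  ty <- c(1.2, 3.4, 0.8, 2.9, 4.6)
  dx <- tx + c(0.03, -0.05, 0.02, 0.04, -0.01)
  dy <- ty + c(-0.02, 0.01, 0.05, -0.03, 0.02)
  ev <- evaluate_detection(data.frame(x_um = dx, y_um = dy),
                           data.frame(x_um = tx, y_um = ty), 0.2)
  # oracle: enumerate all one-to-one assignments, minimise total distance
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  cost <- apply(perms, 1, function(p) {
    sum(sqrt((dx - tx[p])^2 + (dy - ty[p])^2))
  })
  best <- unlist(perms[which.min(cost), ])
  oracle_rmse <- sqrt(mean((dx - tx[best])^2 + (dy - ty[best])^2))
  expect_equal(ev$n_matched, 5)
  expect_equal(ev$rmse_um, oracle_rmse, tolerance = 1e-12)
})

test_that("a simulated field round-trips through plain files", {
  cfg <- synth_config(field_size_um = c(8, 8),
                      channels = list(synth_channel("A", 10),
                                      synth_channel("B", 8)),
                      pairs = list(synth_pair("A", "B", 0.5)),
                      seed = 4)
  f <- generate_field(cfg)
  dir <- withr::local_tempdir()
  write_field(f, dir)
  expect_setequal(list.files(dir),
                  c("A.tif", "B.tif", "ground_truth.csv", "config.yaml"))
  back <- read_micrograph_tiff(file.path(dir, "A.tif"), channel = "A")
  expect_equal(back$pixels, f$images$A$pixels)
  tr <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(tr), nrow(f$truth))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$channels[[1]]$density_per_100um2, 10)
})
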