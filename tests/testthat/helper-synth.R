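# Shared fixtures built in code.

# Rectangular ROI mask inset from every image border by `inset_um`, the
# standard evaluation domain that keeps truncated border puncta out of both
# the detections and the ground truth.
interior_mask <- function(image, inset_um = 0.5) {
  s <- image$pixel_size_nm / 1000
  n <- nrow(image$pixels)
  m <- ncol(image$pixels)
  k <- ceiling(inset_um / s)
  mask <- matrix(FALSE, n, m)
  mask[(k + 1):(n - k), (k + 1):(m - k)] <- TRUE
  mask
}

# Ground-truth rows restricted to the TRUE region of a mask.
truth_in_mask <- function(truth, mask, pixel_size_um = 0.068) {
  i <- floor(truth$y_um / pixel_size_um) + 1
  j <- floor(truth$x_um / pixel_size_um) + 1
  ok <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
  ok[ok] <- mask[cbind(i[ok], j[ok])]
  truth[ok, , drop = FALSE]
}

# One-channel config used across detection tests.
one_channel_config <- function(rho, field = c(30, 30), seed = 1, ...) {
  synth_config(field_size_um = field,
               channels = list(synth_channel("M", rho, ...)),
               seed = seed)
}

# Matched-filter detection radius for the generator's median punctum width.
matched_radius <- function(sigma_um = 0.12) sigma_um * sqrt(2)

# Puncta set built directly from coordinates (area in um^2).
as_puncta_set <- function(x_um, y_um, area_um2, marker = "A", region = "r",
                          pixel_size_nm = 68) {
  ps <- synmapr:::empty_puncta_set(marker, region, area_um2, pixel_size_nm)
  n <- length(x_um)
  ps$puncta <- data.frame(x_um = x_um, y_um = y_um, quality = rep(1, n),
                          mean_intensity = rep(1, n), radius_um = rep(0.2, n))
  ps
}

# Exhaustive maximum-cardinality one-to-one matching among pairs with
# distance <= max_dist: independent oracle for the greedy matcher on tiny
# instances (recursion over A indices).
brute_force_max_matching <- function(ax, ay, bx, by, max_dist) {
  na <- length(ax)
  nb <- length(bx)
  if (na == 0 || nb == 0) return(0L)
  feas <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2 <= max_dist^2
  best <- 0L
  rec <- function(a, used_b, count) {
    if (count + (na - a + 1) <= best) return()
    if (a > na) {
      best <<- max(best, count)
      return()
    }
    for (b in which(feas[a, ] & !used_b)) {
      used_b[b] <- TRUE
      rec(a + 1, used_b, count + 1L)
      used_b[b] <- FALSE
    }
    rec(a + 1, used_b, count)
    best <<- max(best, count)
  }
  rec(1L, rep(FALSE, nb), 0L)
  best
}
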