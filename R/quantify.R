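#' Puncta density of a region
#'
#' Number of puncta per 100 um^2 of region area: `100 * count / area`.
#'
#' @param ps a `puncta_set`.
#' @return density in puncta per 100 um^2.
#' @export
puncta_density <- function(ps) {
  stopifnot(inherits(ps, "puncta_set"))
  if (ps$roi_area_um2 <= 0) stop("region area is zero; density undefined")
  100 * nrow(ps$puncta) / ps$roi_area_um2
}

#' Mean punctum intensity of a region
#'
#' Arithmetic mean of the per-punctum disc-mean intensities (a.u.). An empty
#' set yields `NaN` with a warning so it can be excluded from replicate
#' aggregation.
#'
#' @param ps a `puncta_set`.
#' @return mean intensity (a.u.).
#' @export
mean_puncta_intensity <- function(ps) {
  stopifnot(inherits(ps, "puncta_set"))
  if (nrow(ps$puncta) == 0) {
    warning("empty puncta set: mean intensity is NaN")
    return(NaN)
  }
  mean(ps$puncta$mean_intensity)
}

#' Aggregate per-subject values to mean and SEM
#'
#' The replicate unit is the biological subject (animal or case), never the
#' individual image: per-subject values enter once each. The standard error
#' is `sd / sqrt(n)`; with a single replicate the SEM is reported as 0 and
#' flagged.
#'
#' @param values numeric vector, one value per subject; `NA`/`NaN` entries
#'   (e.g. empty-region intensities) are dropped.
#' @return list with `mean`, `sem`, `n` and logical `single_replicate`.
#' @export
aggregate_replicates <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no finite replicate values to aggregate")
  m <- mean(values)
  sem <- if (n == 1) 0 else stats::sd(values) / sqrt(n)
  list(mean = m, sem = sem, n = n, single_replicate = n == 1)
}

#' Marker-by-region summary table from per-subject measurements
#'
#' Collapses a tidy table of per-subject values into the marker x region
#' matrix-of-cells layout used for reporting: each cell holds the across-
#' subject mean, SEM and replicate count for one measure (density per
#' 100 um^2, mean intensity in a.u., or a percentage).
#'
#' @param df data frame with columns `marker`, `region`, `subject`, `value`.
#' @param measure name of the measure, stored on the result
#'   (`"density_per_100um2"`, `"mean_intensity_au"` or `"percent"`).
#' @return a `marker_region_table`: list of matrices `mean`, `sem`, `n`
#'   (markers x regions, in first-appearance order) plus `measure`.
#' @export
marker_region_table <- function(df, measure = "density_per_100um2") {
  stopifnot(all(c("marker", "region", "subject", "value") %in% names(df)))
  markers <- unique(df$marker)
  regions <- unique(df$region)
  mk <- function() matrix(NA_real_, length(markers), length(regions),
                          dimnames = list(markers, regions))
  mean_m <- mk(); sem_m <- mk(); n_m <- mk()
  for (ma in markers) {
    for (re in regions) {
      v <- df$value[df$marker == ma & df$region == re]
      if (length(v) == 0) next
      ag <- aggregate_replicates(v)
      mean_m[ma, re] <- ag$mean
      sem_m[ma, re] <- ag$sem
      n_m[ma, re] <- ag$n
    }
  }
  check_table_invariants(mean_m, measure)
  structure(list(mean = mean_m, sem = sem_m, n = n_m, measure = measure),
            class = "marker_region_table")
}

check_table_invariants <- function(mean_m, measure) {
  v <- mean_m[is.finite(mean_m)]
  if (measure %in% c("density_per_100um2", "mean_intensity_au") &&
      any(v < 0)) {
    stop("density/intensity cells must be non-negative")
  }
  if (measure == "percent" && (any(v < 0) || any(v > 100))) {
    stop("percent cells must lie in [0, 100]")
  }
  invisible(TRUE)
}

#' @export
print.marker_region_table <- function(x, ...) {
  cat(sprintf("<marker_region_table> %s, %d markers x %d regions\n",
              x$measure, nrow(x$mean), ncol(x$mean)))
  print(round(x$mean, 1))
  invisible(x)
}

#' Write a marker-region table as tidy and wide CSV
#'
#' The tidy file has one row per cell (`marker`, `region`, `mean`, `sem`,
#' `n`); the wide file mirrors the printed table layout with `mean+-sem`
#' cells rounded to integers (half away from zero).
#'
#' @param tab a [marker_region_table()].
#' @param path_tidy,path_wide output CSV paths (either may be `NULL`).
#' @return invisibly, the tidy data frame.
#' @export
write_table_csv <- function(tab, path_tidy = NULL, path_wide = NULL) {
  stopifnot(inherits(tab, "marker_region_table"))
  tidy <- expand.grid(marker = rownames(tab$mean),
                      region = colnames(tab$mean),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tidy$mean <- tab$mean[cbind(tidy$marker, tidy$region)]
  tidy$sem <- tab$sem[cbind(tidy$marker, tidy$region)]
  tidy$n <- tab$n[cbind(tidy$marker, tidy$region)]
  tidy$measure <- tab$measure
  if (!is.null(path_tidy)) utils::write.csv(tidy, path_tidy,
                                            row.names = FALSE)
  if (!is.null(path_wide)) {
    wide <- matrix(sprintf("%d±%d", round_half_away(tab$mean),
                           round_half_away(tab$sem)),
                   nrow = nrow(tab$mean), dimnames = dimnames(tab$mean))
    utils::write.csv(as.data.frame(wide), path_wide, row.names = TRUE)
  }
  invisible(tidy)
}
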