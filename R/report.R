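#' Round half away from zero
#'
#' Integer rounding matching printed summary tables (`0.5 -> 1`,
#' `-0.5 -> -1`), unlike R's banker's rounding.
#'
#' @param x numeric.
#' @return rounded numeric.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Reference marker fraction of a summed denominator
#'
#' `100 * rho_ref / sum(rho_others)`: the density of the reference marker as
#' a percentage of the combined density of a set of comparison markers
#' (e.g. SV2A against the summed excitatory plus inhibitory markers). If the
#' reference labelled every synapse this fraction would be at least 100;
#' values well below 100 indicate expression in a subpopulation.
#'
#' @param rho_ref reference density (puncta per 100 um^2).
#' @param rho_others vector of comparison densities whose sum forms the
#'   denominator.
#' @return the percentage at full precision (round with
#'   [round_half_away()] for display).
#' @export
marker_fraction <- function(rho_ref, rho_others) {
  denom <- sum(rho_others)
  if (denom <= 0) stop("combined comparison density is zero")
  100 * rho_ref / denom
}

#' Three-row fraction table: reference, summed denominator, percentage
#'
#' Builds the reporting layout with the reference marker's density on top,
#' the summed denominator densities in the middle and the percentage
#' `100 * row1 / row2` at the bottom, plus a trailing `"Mean"` column.
#'
#' In `"reproduction"` mode every input density is first rounded to integers
#' (half away from zero) and the `Mean` column is computed from those rounded
#' per-region values — the arithmetic a reader can check against a printed
#' table. In `"analysis"` mode full precision is kept throughout.
#'
#' @param density markers x regions matrix of mean densities (puncta per
#'   100 um^2), without a mean column.
#' @param ref_marker row name of the reference marker.
#' @param denom_markers row names summed into the denominator.
#' @param mode `"reproduction"` or `"analysis"`.
#' @return 3 x (regions + 1) matrix with rows `ref_marker`, the summed
#'   denominator label, and `% <ref_marker>`. In reproduction mode the
#'   percentage row is integer-rounded; full precision is kept in the
#'   `"percent_full"` attribute.
#' @export
build_fraction_table <- function(density, ref_marker, denom_markers,
                                 mode = c("reproduction", "analysis")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(density), !is.null(rownames(density)))
  missing <- setdiff(c(ref_marker, denom_markers), rownames(density))
  if (length(missing) > 0) {
    stop("density table is missing marker(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(density[c(ref_marker, denom_markers), ]))) {
    stop("density table holds non-finite cells for the requested markers")
  }
  d <- density[c(ref_marker, denom_markers), , drop = FALSE]
  if (mode == "reproduction") d <- round_half_away(d)
  d <- cbind(d, Mean = if (mode == "reproduction") {
    round_half_away(rowMeans(d))
  } else rowMeans(d))
  ref <- d[ref_marker, ]
  denom <- colSums(d[denom_markers, , drop = FALSE])
  pct <- 100 * ref / denom
  out <- rbind(ref, denom,
               if (mode == "reproduction") round_half_away(pct) else pct)
  rownames(out) <- c(ref_marker, paste(denom_markers, collapse = " + "),
                     paste0("% ", ref_marker))
  attr(out, "percent_full") <- pct
  out
}

#' Row-wise min-max normalisation
#'
#' Maps every row to `[0, 1]` via `(x - min) / (max - min)`, the colour
#' scaling used for per-marker heatmaps: each marker's regional profile
#' attains 0 and 1 regardless of its absolute level. Constant rows carry no
#' profile and map to 0.5, flagged in the `"constant_rows"` attribute. The
#' operation is idempotent.
#'
#' @param m numeric matrix with at least one column.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
row_normalize <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 1)
  rng <- t(apply(m, 1, range))
  span <- rng[, 2] - rng[, 1]
  const <- span == 0
  out <- (m - rng[, 1]) / ifelse(const, 1, span)
  out[const, ] <- 0.5
  attr(out, "constant_rows") <- which(const)
  out
}

#' Dendrogram leaf order from hierarchical clustering
#'
#' Agglomerative hierarchical clustering (average linkage on Euclidean
#' distances of the row-normalised values) along the requested axis;
#' returns the deterministic dendrogram leaf order used to arrange heatmap
#' rows or columns "by similarity". A single item returns the identity
#' permutation.
#'
#' @param m numeric matrix.
#' @param axis `"row"` or `"col"`.
#' @param normalize row-normalise before clustering (the heatmap
#'   convention)?
#' @return integer permutation of the axis indices.
#' @export
cluster_order <- function(m, axis = c("row", "col"), normalize = TRUE) {
  axis <- match.arg(axis)
  x <- if (normalize) row_normalize(m) else m
  if (axis == "col") x <- t(x)
  if (nrow(x) < 2) return(seq_len(nrow(x)))
  stats::hclust(stats::dist(x, method = "euclidean"),
                method = "average")$order
}

#' Clustered, row-normalised heatmap of a marker-by-region matrix
#'
#' Renders the standard report figure: values min-max normalised per marker
#' (row) and both axes ordered by average-linkage hierarchical clustering.
#'
#' @param m markers x regions numeric matrix (raw values; normalisation is
#'   applied internally).
#' @param file output image path (`.png`), or `NULL` to draw on the active
#'   device.
#' @param main plot title.
#' @param cluster_cols also cluster the columns?
#' @return invisibly, a `heatmap_spec` list with the normalised `matrix`,
#'   `row_order` and `col_order`.
#' @export
plot_marker_heatmap <- function(m, file = NULL, main = "",
                                cluster_cols = TRUE) {
  norm <- row_normalize(m)
  ro <- cluster_order(m, "row")
  co <- if (cluster_cols && ncol(m) >= 2) cluster_order(m, "col")
        else seq_len(ncol(m))
  args <- list(mat = norm[ro, co, drop = FALSE], cluster_rows = FALSE,
               cluster_cols = FALSE, main = main, silent = !is.null(file))
  if (!is.null(file)) {
    args$filename <- file
    args$width <- 6
    args$height <- 4
  }
  do.call(pheatmap::pheatmap, args)
  invisible(structure(list(matrix = norm, row_order = ro, col_order = co,
                           measure = main),
                      class = "heatmap_spec"))
}
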