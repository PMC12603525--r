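#' Match puncta across two channels
#'
#' Object-based colocalization: candidate pairs are all cross-channel
#' centroid pairs within `max_dist_um`; they are accepted greedily in
#' ascending distance under a one-to-one constraint (each punctum joins at
#' most one pair, exact distance ties broken by (A index, B index)), and the
#' greedy matching is then augmented along alternating paths until it
#' reaches maximum cardinality among all distance-feasible one-to-one
#' matchings. One-to-one matching prevents double counting at high
#' densities; the augmentation ensures no punctum pair is left unmatched
#' merely because of the greedy visit order. The procedure is deterministic.
#'
#' The two modes run the identical algorithm and differ only in the default
#' distance criterion: `"colocalized"` (two markers in the same terminal,
#' default 0.3 um, about one punctum radius at the diffraction limit) and
#' `"juxtaposed"` (pre- apposed to postsynaptic marker across the cleft,
#' default 0.5 um).
#'
#' @param A reference-channel `puncta_set` (e.g. SV2A).
#' @param B partner-channel `puncta_set`, same region and coordinate frame.
#' @param max_dist_um maximum centroid distance; `NULL` uses the mode
#'   default.
#' @param mode `"colocalized"` or `"juxtaposed"`.
#' @return a `pairing`: list with `mode`, `max_dist_um` and `matches` (data
#'   frame `a`, `b`, `dist` of row indices into the two puncta tables).
#' @export
match_puncta <- function(A, B, max_dist_um = NULL,
                         mode = c("colocalized", "juxtaposed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(A, "puncta_set"), inherits(B, "puncta_set"))
  if (!isTRUE(all.equal(A$pixel_size_nm, B$pixel_size_nm))) {
    stop("puncta sets use different pixel sizes; coordinate frames differ")
  }
  if (is.null(max_dist_um)) {
    max_dist_um <- if (mode == "colocalized") 0.3 else 0.5
  }
  if (max_dist_um <= 0) stop("max_dist_um must be > 0")
  mm <- match_points_max(A$puncta$x_um, A$puncta$y_um,
                         B$puncta$x_um, B$puncta$y_um, max_dist_um)
  structure(list(mode = mode, max_dist_um = max_dist_um, matches = mm,
                 n_A = nrow(A$puncta), n_B = nrow(B$puncta)),
            class = "pairing")
}

#' @export
print.pairing <- function(x, ...) {
  cat(sprintf("<pairing> %s, d <= %.2f um: %d matches (%d A, %d B)\n",
              x$mode, x$max_dist_um, nrow(x$matches), x$n_A, x$n_B))
  invisible(x)
}

#' Percentage of partner puncta containing the reference marker
#'
#' `100 * n_matched / n_B`: the fraction of marker-B puncta whose terminal
#' also contains (or, in juxtaposed mode, abuts) a reference-marker punctum.
#' The direction follows the reporting convention "percentage of marker
#' puncta that contain the reference"; the reverse percentage differs
#' whenever the two densities differ.
#'
#' @param pairing result of [match_puncta()].
#' @param B the partner `puncta_set` the pairing was built on.
#' @return a `coloc_result`: list with `marker_A`, `marker_B`, `region`,
#'   `percent_B_with_A`, `n_B`, `n_matched`, `mode`. With `n_B = 0` the
#'   percentage is `NA` (flagged, excluded from aggregation).
#' @export
percent_with_reference <- function(pairing, B) {
  stopifnot(inherits(pairing, "pairing"), inherits(B, "puncta_set"))
  if (nrow(B$puncta) != pairing$n_B) {
    stop("pairing was not built on this B puncta set")
  }
  n_b <- nrow(B$puncta)
  n_m <- nrow(pairing$matches)
  pct <- if (n_b == 0) NA_real_ else 100 * n_m / n_b
  if (n_b == 0) warning("no partner puncta: percentage undefined (NA)")
  structure(list(marker_A = NA_character_, marker_B = B$marker,
                 region = B$region, percent_B_with_A = pct,
                 n_B = n_b, n_matched = n_m, mode = pairing$mode),
            class = "coloc_result")
}

#' Chance colocalization percentage under spatial independence
#'
#' Probability (as a percentage) that a partner punctum has at least one
#' independent reference punctum within `max_dist_um`, when the reference
#' channel is a homogeneous spatial Poisson process of intensity `rho_A` per
#' 100 um^2: `100 * (1 - exp(-(rho_A / 100) * pi * max_dist_um^2))`. This is
#' the null level against which observed colocalization percentages are
#' calibrated.
#'
#' @param rho_A reference density in puncta per 100 um^2.
#' @param max_dist_um distance criterion in micrometres.
#' @return percentage in `[0, 100]`.
#' @export
expected_chance_percent <- function(rho_A, max_dist_um) {
  stopifnot(rho_A >= 0, max_dist_um >= 0)
  100 * (1 - exp(-(rho_A / 100) * pi * max_dist_um^2))
}
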