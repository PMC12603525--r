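# Published reference measurements bundled for table reconstruction and for
# calibrating the synthetic generator. All matrices are markers x regions;
# densities are puncta per 100 um^2, intensities arbitrary units,
# colocalization values percentages. `mean` and `sem` are across biological
# replicates (mouse n = 7 animals, human n = 3 cases).

mouse_regions <- c("CA1sr", "CA2sr", "CA3sr", "DGpo", "SMSL2/3", "SMSL5",
                   "ENTIL4/5", "STRcp", "THpo")
human_layers <- c("L1", "L2", "L3", "L4", "L5", "L6")

ref_matrix <- function(values, markers, regions) {
  matrix(values, nrow = length(markers), byrow = TRUE,
         dimnames = list(markers, regions))
}

#' Reference synaptic marker measurements
#'
#' Published mean +- SEM reference tables for seven synaptic markers across
#' nine mouse brain regions and four markers across the six layers of human
#' temporal cortex: puncta densities (per 100 um^2), mean punctum
#' intensities (a.u.) and percentage colocalization with SV2A. These printed
#' summary values are the inputs for marker-fraction reconstruction and the
#' calibration targets for the synthetic field generator.
#'
#' Regions: hippocampal CA1/CA2/CA3 stratum radiatum (CA1sr, CA2sr, CA3sr),
#' dentate gyrus polymorphic layer (DGpo), somatosensory cortex layers 2/3
#' and 5 (SMSL2/3, SMSL5), entorhinal cortex layer 4/5 (ENTIL4/5),
#' caudoputamen (STRcp) and posterior thalamus (THpo); human layers L1-L6.
#'
#' @return list with `mean` and `sem` matrices (markers x regions).
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
ref_mouse_density <- function() {
  mk <- c("SV2A", "SYP", "SYN", "VGLUT1", "VGAT", "PSD95", "GPHN")
  list(
    mean = ref_matrix(c(
      19, 18, 18, 16, 18, 17, 18, 16, 15,
      17, 15, 14, 12, 13, 13,  9, 13,  9,
      17, 14, 11, 11, 12, 12, 14, 13,  8,
      19, 19, 17, 16, 16, 18, 14, 15, 12,
      10, 10, 11,  5, 12,  9, 16,  9,  6,
      39, 37, 28, 18, 34, 33, 35, 29, 27,
      27, 25, 22, 22, 23, 22, 21, 18, 22), mk, mouse_regions),
    sem = ref_matrix(c(
      1, 1, 1, 1, 1, 1, 1, 1, 1,
      3, 3, 3, 1, 1, 1, 6, 4, 4,
      3, 3, 2, 1, 1, 1, 4, 4, 4,
      1, 3, 3, 3, 2, 3, 1, 1, 1,
      3, 4, 3, 2, 3, 1, 3, 1, 2,
      1, 2, 3, 3, 1, 1, 1, 4, 1,
      1, 1, 2, 1, 1, 1, 3, 2, 1), mk, mouse_regions))
}

#' @rdname reference_tables
#' @export
ref_mouse_intensity <- function() {
  mk <- c("SV2A", "SYP", "SYN", "VGLUT1", "VGAT", "PSD95", "GPHN")
  list(
    mean = ref_matrix(c(
      328, 331, 346, 519, 494, 367, 353, 350, 384,
      378, 358, 349, 377, 321, 330, 279, 341, 298,
      395, 375, 378, 487, 373, 324, 385, 381, 366,
      232, 250, 229, 240, 230, 224, 226, 255, 238,
      276, 301, 293, 270, 301, 271, 338, 272, 293,
      325, 283, 214, 231, 309, 259, 264, 266, 208,
      257, 252, 243, 260, 280, 270, 267, 258, 260), mk, mouse_regions),
    sem = ref_matrix(c(
      69, 76, 80, 109, 92, 69, 58, 92, 77,
      74, 41, 38,  93, 36, 22,  7, 73, 26,
      76, 68, 94, 111, 39, 24, 99, 89, 101,
      22, 21, 11,  19, 14, 13, 14, 30, 22,
      37, 51, 41,  27, 36, 15, 71, 20, 20,
      55, 59, 29,  34, 65, 44, 50, 42, 20,
       5,  9,  3,   1,  2,  2,  8,  6,  7), mk, mouse_regions))
}

#' @rdname reference_tables
#' @export
ref_mouse_coloc <- function() {
  mk <- c("SYP", "SYN", "VGLUT1", "VGAT", "PSD95", "GPHN")
  list(
    mean = ref_matrix(c(
      65, 70, 78, 85, 74, 69, 77, 75, 79,
      57, 49, 62, 80, 56, 51, 57, 62, 69,
      57, 70, 65, 84, 77, 64, 57, 64, 61,
      74, 68, 72, 52, 62, 92, 59, 71, 76,
      32, 33, 39, 49, 44, 42, 41, 48, 43,
      41, 44, 43, 34, 45, 44, 38, 40, 40), mk, mouse_regions),
    sem = ref_matrix(c(
       1,  8,  5, 3,  1,  2,  7,  3,  4,
      10, 11, 12, 6, 19, 19, 13, 13, 11,
       2,  5,  3, 6,  6,  4,  6,  1,  8,
       3,  7,  7, 8,  5, 12,  9,  7,  6,
       9,  5,  3, 6,  2,  1,  7,  3,  3,
       2,  3,  3, 1,  2,  1,  3,  6,  3), mk, mouse_regions))
}

#' @rdname reference_tables
#' @export
ref_human_density <- function() {
  mk <- c("SV2A", "SYP", "PSD95", "GPHN")
  list(
    mean = ref_matrix(c(
      18, 19, 19, 18, 18, 17,
      20, 21, 22, 20, 20, 19,
      41, 44, 42, 40, 36, 32,
      37, 34, 36, 35, 34, 32), mk, human_layers),
    sem = ref_matrix(c(
      1, 1, 1, 1, 1, 1,
      5, 2, 2, 4, 3, 3,
      3, 3, 4, 2, 3, 1,
      8, 4, 3, 5, 9, 8), mk, human_layers))
}

#' @rdname reference_tables
#' @export
ref_human_intensity <- function() {
  mk <- c("SV2A", "SYP", "PSD95", "GPHN")
  list(
    mean = ref_matrix(c(
      442, 403, 396, 376, 382, 388,
      300, 270, 282, 276, 280, 296,
      321, 327, 321, 292, 275, 256,
      277, 266, 262, 259, 247, 235), mk, human_layers),
    sem = ref_matrix(c(
      54, 37, 44, 46, 44, 47,
      47, 23, 25, 41, 55, 75,
      29, 42, 19, 16, 23, 16,
      71, 26, 11, 22, 67, 61), mk, human_layers))
}

#' @rdname reference_tables
#' @export
ref_human_coloc <- function() {
  mk <- c("SYP", "PSD95", "GPHN")
  list(
    mean = ref_matrix(c(
      68, 68, 65, 65, 67, 71,
      27, 26, 30, 29, 32, 34,
      21, 26, 25, 22, 22, 22), mk, human_layers),
    sem = ref_matrix(c(
      2, 1, 3, 3, 3, 1,
      4, 2, 2, 1, 1, 4,
      6, 7, 6, 7, 8, 7), mk, human_layers))
}

#' @rdname reference_tables
#' @export
ref_mouse_fraction_rows <- function() {
  list(
    presynaptic = stats::setNames(
      c(66, 62, 64, 76, 64, 63, 60, 67, 83, 65), c(mouse_regions, "Mean")),
    postsynaptic = stats::setNames(
      c(29, 29, 36, 40, 32, 31, 32, 34, 31, 32), c(mouse_regions, "Mean")))
}

#' @rdname reference_tables
#' @export
ref_human_fraction_row <- function() {
  stats::setNames(c(23, 25, 24, 24, 25, 27, 25), c(human_layers, "Mean"))
}
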