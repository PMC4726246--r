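# Bundled calibration tables for the sliding-window coiled-coil score.
#
# Two residue-propensity tables are shipped: "MTK" (derived from myosin,
# tropomyosin and keratin sequences) and "MTIDK" (myosin, tropomyosin,
# intermediate filaments, desmosomal proteins, kinesins).  Rows are the 20
# amino acids, columns the seven heptad positions a-g.  A propensity of 0
# means the residue was not observed at that heptad position in the
# reference set; a window containing such a residue-position combination
# scores 0.
#
# The probability calibration is a pair of Gaussians (coiled-coil vs
# globular score distributions) per (matrix, window, weighting) combination;
# see coils_probability().

.coils_aa <- c("L","I","V","M","F","Y","G","A","K","R",
               "H","E","D","Q","N","S","T","C","W","P")

.coils_mtk <- matrix(c(
  # a      b      c      d      e      f      g
  3.167, 0.297, 0.398, 3.902, 0.585, 0.501, 0.483,  # L
  2.597, 0.098, 0.345, 0.894, 0.514, 0.471, 0.431,  # I
  1.665, 0.403, 0.386, 0.949, 0.211, 0.342, 0.360,  # V
  2.240, 0.370, 0.480, 1.409, 0.541, 0.772, 0.663,  # M
  0.531, 0.076, 0.403, 0.662, 0.189, 0.106, 0.013,  # F
  1.417, 0.090, 0.122, 1.659, 0.190, 0.130, 0.155,  # Y
  0.045, 0.275, 0.578, 0.216, 0.211, 0.426, 0.156,  # G
  1.297, 1.551, 1.084, 2.612, 0.377, 1.248, 0.877,  # A
  1.375, 2.639, 1.763, 0.191, 1.815, 1.961, 2.795,  # K
  0.659, 1.163, 1.210, 0.031, 1.358, 1.937, 1.798,  # R
  0.347, 0.275, 0.679, 0.395, 0.294, 0.579, 0.213,  # H
  0.262, 3.496, 3.108, 0.998, 5.685, 2.494, 3.048,  # E
  0.030, 2.352, 2.268, 0.237, 0.663, 1.620, 1.448,  # D
  0.179, 2.114, 1.778, 0.631, 2.550, 1.578, 2.526,  # Q
  0.835, 1.475, 1.534, 0.039, 1.722, 2.456, 2.280,  # N
  0.382, 0.583, 1.052, 0.419, 0.525, 0.916, 0.628,  # S
  0.169, 0.702, 0.955, 0.654, 0.791, 0.843, 0.647,  # T
  0.824, 0.022, 0.308, 0.152, 0.180, 0.156, 0.044,  # C
  0.240, 0.000, 0.000, 0.456, 0.019, 0.000, 0.000,  # W
  0.000, 0.008, 0.000, 0.013, 0.000, 0.000, 0.000), # P
  nrow = 20, byrow = TRUE,
  dimnames = list(.coils_aa, letters[1:7]))

.coils_mtidk <- matrix(c(
  # a      b      c      d      e      f      g
  2.998, 0.269, 0.367, 3.852, 0.510, 0.514, 0.562,  # L
  2.408, 0.261, 0.345, 0.931, 0.402, 0.440, 0.289,  # I
  1.525, 0.479, 0.350, 0.887, 0.286, 0.350, 0.362,  # V
  2.161, 0.605, 0.442, 1.441, 0.607, 0.457, 0.570,  # M
  0.490, 0.075, 0.391, 0.639, 0.125, 0.081, 0.038,  # F
  1.319, 0.064, 0.081, 1.526, 0.204, 0.118, 0.096,  # Y
  0.084, 0.215, 0.432, 0.111, 0.153, 0.367, 0.125,  # G
  1.283, 1.364, 1.077, 2.219, 0.490, 1.265, 0.903,  # A
  1.233, 2.194, 1.817, 0.611, 2.095, 1.686, 2.027,  # K
  1.014, 1.476, 1.771, 0.114, 1.667, 2.006, 1.844,  # R
  0.590, 0.646, 0.584, 0.842, 0.307, 0.611, 0.396,  # H
  0.281, 3.351, 2.998, 0.789, 4.868, 2.735, 3.812,  # E
  0.068, 2.103, 1.646, 0.182, 0.664, 1.581, 1.401,  # D
  0.311, 2.290, 2.330, 0.811, 2.596, 2.155, 2.585,  # Q
  1.231, 1.683, 2.157, 0.197, 1.653, 2.430, 2.065,  # N
  0.332, 0.753, 0.930, 0.424, 0.734, 0.801, 0.518,  # S
  0.197, 0.543, 0.647, 0.680, 0.905, 0.643, 0.808,  # T
  0.918, 0.002, 0.385, 0.440, 0.138, 0.432, 0.079,  # C
  0.066, 0.064, 0.065, 0.747, 0.006, 0.115, 0.014,  # W
  0.004, 0.108, 0.018, 0.006, 0.010, 0.004, 0.007), # P
  nrow = 20, byrow = TRUE,
  dimnames = list(.coils_aa, letters[1:7]))

# Gaussian score-distribution parameters: one row per
# (matrix, window, weighted) combination.  "weighted" refers to the default
# 2.5-fold up-weighting of the hydrophobic core positions a and d;
# weighting 1 uses the unweighted row.
.coils_gauss <- data.frame(
  matrix_id = rep(c("MTIDK", "MTK"), each = 6),
  window    = rep(c(28L, 28L, 21L, 21L, 14L, 14L), 2),
  weighted  = rep(c(TRUE, FALSE), 6),
  m_cc      = c(1.628, 1.601, 1.599, 1.550, 1.541, 1.516,
                1.702, 1.665, 1.665, 1.630, 1.618, 1.596),
  sd_cc     = c(0.243, 0.256, 0.242, 0.251, 0.227, 0.243,
                0.244, 0.257, 0.245, 0.255, 0.231, 0.247),
  m_g       = c(0.826, 0.770, 0.837, 0.779, 0.889, 0.841,
                0.801, 0.737, 0.817, 0.753, 0.869, 0.816),
  sd_g      = c(0.190, 0.211, 0.206, 0.230, 0.223, 0.260,
                0.182, 0.201, 0.199, 0.221, 0.216, 0.249),
  stringsAsFactors = FALSE)

#' Bundled coiled-coil propensity matrices
#'
#' Returns one of the bundled 20 x 7 residue propensity tables used by
#' [coils_score()].  Rows are one-letter amino-acid codes, columns heptad
#' positions `a`-`g`.
#'
#' @param matrix_id `"MTIDK"` (default) or `"MTK"`.
#' @return A numeric matrix with 20 rows and 7 columns.
#' @export
#' @examples
#' coils_matrix("MTIDK")["L", ]
coils_matrix <- function(matrix_id = c("MTIDK", "MTK")) {
  matrix_id <- match.arg(matrix_id)
  if (matrix_id == "MTIDK") .coils_mtidk else .coils_mtk
}

#' Gaussian calibration parameters for coiled-coil probabilities
#'
#' Looks up the mean/SD of the coiled-coil and globular score distributions
#' for a given propensity matrix, window and a/d weighting.  Calibrations
#' exist for windows 14, 21 and 28 with weighting 1 (unweighted) or 2.5
#' (the default core weighting).
#'
#' @param matrix_id Propensity matrix name, see [coils_matrix()].
#' @param window Sliding-window length: 14, 21 or 28.
#' @param weighting a/d weighting factor; must be 1 or 2.5.
#' @return A one-row data frame with columns `m_cc`, `sd_cc`, `m_g`, `sd_g`.
#' @export
coils_gaussian <- function(matrix_id = c("MTIDK", "MTK"), window = 28,
                           weighting = 2.5) {
  matrix_id <- match.arg(matrix_id)
  if (!window %in% c(14L, 21L, 28L))
    stop("no Gaussian calibration for window ", window,
         "; available windows: 14, 21, 28")
  if (!weighting %in% c(1, 2.5))
    stop("no Gaussian calibration for weighting ", weighting,
         "; available weightings: 1, 2.5")
  row <- .coils_gauss[.coils_gauss$matrix_id == matrix_id &
                        .coils_gauss$window == window &
                        .coils_gauss$weighted == (weighting == 2.5), ]
  stopifnot(nrow(row) == 1L)
  row[, c("m_cc", "sd_cc", "m_g", "sd_g")]
}
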