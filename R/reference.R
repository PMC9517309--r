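#' Published per-angle activity thresholds and importances
#'
#' The reference comparison table for the two cohorts: per-angle activity
#' ranges (degrees) for the elderly group (60-75) and the young control
#' group (20-25), together with the neural-network importance index of each
#' angle and its normalization by the maximum. The elderly trunk-angle range,
#' printed with its endpoints reversed in the source table, is stored in
#' ascending order ([131.583, 143]).
#'
#' These are reference constants for worked examples and direction-of-effect
#' checks; the cohorts behind them are not distributed, so the values are not
#' recomputable from data.
#'
#' @return Data frame with columns `angle`, `label`, `elderly_lower`,
#'   `elderly_upper`, `control_lower`, `control_upper`, `importance`,
#'   `normalized`.
#' @export
reference_thresholds <- function() {
  data.frame(
    angle = angle_ids(),
    label = c("neck bending angle", "torso arm angle (L)", "torso arm angle (R)",
              "elbow bending angle (L)", "elbow bending angle (R)",
              "torso bending angle", "torso thigh angle (L)",
              "torso thigh angle (R)", "thigh calf angle (L)",
              "thigh calf angle (R)", "calf-ground angle (L)",
              "calf-ground angle (R)"),
    elderly_lower = c(3.814, 89.643, 89.730, 74.931, 76.759, 131.583,
                      146.745, 115.049, 130.672, 115.049, 83.659, 81.869),
    elderly_upper = c(47.489, 89.742, 89.742, 75.508, 91.324, 143.000,
                      179.969, 179.456, 154.731, 179.849, 96.340, 108.435),
    control_lower = c(3.814, 89.815, 89.820, 79.695, 89.454, 136.789,
                      135.553, 135.779, 68.036, 75.134, 91.975, 83.991),
    control_upper = c(47.489, 89.900, 89.895, 179.774, 179.496, 179.334,
                      179.976, 179.951, 179.754, 179.864, 112.166, 111.448),
    importance = c(0.112, 0.096, 0.076, 0.090, 0.111, 0.096,
                   0.053, 0.122, 0.090, 0.048, 0.076, 0.030),
    normalized = c(92.1, 78.6, 62.2, 73.7, 91.2, 78.4,
                   43.6, 100.0, 73.8, 39.6, 61.9, 24.4),
    stringsAsFactors = FALSE
  )
}

#' Worked-example AHP inputs for the furniture criterion layer
#'
#' The criterion-layer feature vector (function, shape, colour, material),
#' the reported maximum eigenvalue of the 4x4 judgment matrix, and the
#' matrix order. The raw 30-expert judgment matrix itself is not available,
#' so the feature-vector path reproduces the published weighting.
#'
#' @return List with `feature_vector` (named), `lambda_max`, `n`.
#' @export
reference_ahp_example <- function() {
  list(feature_vector = c(B1_function = 1.908, B2_shape = 0.609,
                          B3_colour = 0.329, B4_material = 1.154),
       lambda_max = 4.067, n = 4L)
}

#' Worked-example survey counts
#'
#' Questionnaires sent, returned and valid in the needs survey of elderly
#' users (recovery rate 91.4%, effective rate 87.4%).
#'
#' @return Named numeric vector `c(sent, returned, valid)`.
#' @export
reference_survey_counts <- function() {
  c(sent = 500, returned = 457, valid = 437)
}
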