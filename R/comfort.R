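#' Thigh length proxy from anthropometry
#'
#' The seat-geometry thigh length x is taken as the sitting lower-limb
#' length minus the calf-plus-foot height (Z9 - Z7), in mm. Configurable at
#' the call sites that use it.
#'
#' @param anthro An `anthropometry` record.
#' @return Thigh length in mm.
#' @export
thigh_length <- function(anthro) {
  x <- anthro$sitting[["Z9"]] - anthro$sitting[["Z7"]]
  if (!is.finite(x) || x <= 0) {
    s2s_error("Z9 - Z7 must be positive to derive a thigh length", "s2s_domain_error")
  }
  x
}

#' Seat-surface angle band from a motion threshold range
#'
#' Converts a thigh-angle activity range measured against gravity (90 =
#' horizontal thigh, 180 = standing) into the thigh-to-seat-surface
#' convention of [seat_thigh_angle()] by `theta_seat = theta - 90` (the
#' thigh's elevation above the horizontal), clipped to (0, 90]. The two
#' conventions are not equivalent descriptions of one geometry; this
#' conversion is the package's documented bridge between them.
#'
#' @param range Numeric length-2 `[lower, upper]` in degrees (gravity
#'   convention).
#' @return Numeric length-2 band in (0, 90].
#' @export
seat_angle_band <- function(range) {
  if (length(range) != 2 || any(!is.finite(range)) || range[1] > range[2]) {
    s2s_error("range must be a finite [lower, upper] pair", "s2s_domain_error")
  }
  band <- pmin(pmax(range - 90, 1e-6), 90)
  unname(band)
}

#' Recommended seat-height interval for a thigh-angle band
#'
#' For a comfort band `[theta_lower, theta_upper]` in the seat-surface
#' convention (0, 90], the admissible seat heights are
#' `[x tan(90 - theta_upper), x tan(90 - theta_lower)]` -- monotone
#' decreasing in theta. Heights are relative to the knee pivot (add the
#' calf-plus-foot height Z7 for a floor-relative seat height).
#'
#' @param anthro An `anthropometry` record (thigh length via
#'   [thigh_length()]), or `NULL` if `x` is given.
#' @param theta5_range Numeric `[lower, upper]`, each in (0, 90].
#' @param x Optional thigh length override in mm.
#' @return Numeric `[min_height, max_height]` in mm.
#' @export
recommend_seat_height <- function(anthro, theta5_range, x = NULL) {
  if (is.null(x)) x <- thigh_length(anthro)
  if (length(theta5_range) != 2 || any(!is.finite(theta5_range)) ||
      theta5_range[1] > theta5_range[2]) {
    s2s_error("theta5_range must be an ordered [lower, upper] pair", "s2s_domain_error")
  }
  if (theta5_range[1] <= 0 || theta5_range[2] > 90) {
    s2s_error("theta5_range must lie within (0, 90] degrees", "s2s_domain_error")
  }
  c(seat_height_for_angle(theta5_range[2], x),
    seat_height_for_angle(theta5_range[1], x))
}

#' The published element-to-body-value-to-angle mapping
#'
#' The ten furniture elements of the comfort model (backrest A: E1-E3,
#' armrest B: F1-F2, seat surface C: G1-G4, legs D: H1), each mapped to an
#' anthropometric body value and, where given, to a joint angle. The seat
#' width -> right elbow angle link (G1) is carried verbatim from the source
#' mapping; lacking a geometric proxy it is rated dimensionally.
#'
#' @return Object of class `comfort_mapping`: data frame with columns
#'   `code`, `element`, `body_value` (L/Z id), `body_label`, `angle`
#'   (angle id or NA), `spec_field` (the matching `seat_spec` field).
#' @export
default_mapping <- function() {
  df <- data.frame(
    code = c("E1", "E2", "E3", "F1", "F2", "G1", "G2", "G3", "G4", "H1"),
    element = c("backrest inclination", "backrest height", "backrest width",
                "armrest height", "armrest spacing", "seat width",
                "seat depth", "seat height", "seat inclination",
                "chair leg height"),
    body_value = c("Z2", "Z2", "L14", "Z11", "Z13", "Z14", "Z3", "Z7",
                   "Z7", "Z7"),
    body_label = c("sitting shoulder height", "sitting shoulder height",
                   "maximum body width (shoulder width proxy)",
                   "sitting elbow height", "bilateral inter-elbow width",
                   "sitting hip width", "sitting depth",
                   "calf plus foot height", "calf plus foot height",
                   "calf plus foot height"),
    angle = c("theta1", "theta4", NA, NA, "theta3_1", "theta3_2", NA,
              "theta5_1", "theta5_2", "theta6_1"),
    spec_field = c("backrest_inclination", "backrest_height", "backrest_width",
                   "armrest_height", "armrest_spacing", "seat_width",
                   "seat_depth", "seat_height", "seat_inclination",
                   "chair_leg_height"),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("comfort_mapping", "data.frame"))
}

#' Construct a seat specification
#'
#' Furniture-element parameters: lengths in mm (> 0), inclinations in
#' degrees within [0, 90).
#'
#' @param backrest_inclination,seat_inclination Degrees.
#' @param backrest_height,backrest_width,armrest_height,armrest_spacing,seat_width,seat_depth,seat_height,chair_leg_height
#'   Millimeters.
#' @return Object of class `seat_spec` (named list).
#' @export
seat_spec <- function(backrest_inclination, backrest_height, backrest_width,
                      armrest_height, armrest_spacing, seat_width, seat_depth,
                      seat_height, seat_inclination, chair_leg_height) {
  s <- list(backrest_inclination = backrest_inclination,
            backrest_height = backrest_height,
            backrest_width = backrest_width,
            armrest_height = armrest_height,
            armrest_spacing = armrest_spacing,
            seat_width = seat_width, seat_depth = seat_depth,
            seat_height = seat_height, seat_inclination = seat_inclination,
            chair_leg_height = chair_leg_height)
  lens <- unlist(s[setdiff(names(s), c("backrest_inclination", "seat_inclination"))])
  incs <- unlist(s[c("backrest_inclination", "seat_inclination")])
  if (any(!is.finite(unlist(s)))) {
    s2s_error("seat spec values must be finite", "s2s_invalid_seat")
  }
  if (any(lens <= 0)) {
    s2s_error("seat spec lengths must be positive", "s2s_invalid_seat")
  }
  if (any(incs < 0) || any(incs >= 90)) {
    s2s_error("inclinations must lie in [0, 90) degrees", "s2s_invalid_seat")
  }
  structure(s, class = "seat_spec")
}

#' Default seat specification
#'
#' Seat inclination (3 degrees) and armrest spacing (545 mm) follow the
#' realized age-friendly sofa; the remaining dimensions are chosen near the
#' default elderly anthropometry.
#'
#' @return A `seat_spec`.
#' @export
default_seat_spec <- function() {
  seat_spec(backrest_inclination = 10, backrest_height = 560,
            backrest_width = 480, armrest_height = 230, armrest_spacing = 545,
            seat_width = 520, seat_depth = 450, seat_height = 420,
            seat_inclination = 3, chair_leg_height = 390)
}

# Integer 1-5 rating: 5 inside the range, minus one point per started 25% of
# the range width outside it, floored at 1.
.rate_angle <- function(induced, lower, upper) {
  if (induced >= lower && induced <= upper) return(5L)
  width <- upper - lower
  dist <- max(lower - induced, induced - upper)
  if (width <= 0) return(1L)
  max(1L, 5L - as.integer(ceiling(dist / (0.25 * width))))
}

# Dimensional rating: 5 within +/-10% of the body value, minus one point per
# further started 10% of relative deviation, floored at 1.
.rate_dimension <- function(dim, body) {
  r <- abs(dim - body) / body
  if (r <= 0.10) return(5L)
  max(1L, 5L - as.integer(ceiling((r - 0.10) / 0.10)))
}

.threshold_range <- function(thresholds, cohort, angle) {
  row <- thresholds[thresholds$cohort == cohort & thresholds$angle == angle, ]
  if (nrow(row) != 1) return(NULL)
  c(row$lower, row$upper)
}

#' Rate a seat specification against a user's activity thresholds
#'
#' For each mapped furniture element the induced joint angle is computed
#' from the seat geometry and compared with the user's per-angle activity
#' range; the rating is 5 inside the range and decreases by one point per
#' 25% of the range width outside it (floor 1). Elements without a usable
#' angle link (E3, F1, G2, and G1 whose published angle link has no
#' geometric proxy) are rated by dimensional tolerance: 5 within 10% of the
#' mapped body value, decreasing per further 10% of deviation.
#'
#' Induced-angle proxies (documented conventions, not measurements):
#' \itemize{
#'   \item E1: the neck flexes with the backrest, so induced theta1 =
#'     backrest inclination.
#'   \item E2: a backrest reaching the sitting shoulder height (Z2) supports
#'     an upright trunk (theta4 = backrest inclination in the
#'     upright-is-zero convention); each missing fraction of Z2 adds
#'     proportional slump up to 90 degrees.
#'   \item F2: induced elbow angle = 90 * spacing / Z13 (spacing equal to
#'     the inter-elbow width yields a right-angle elbow).
#'   \item G3/G4: thigh-to-seat angle from [seat_thigh_angle()] with
#'     `y = seat height - Z7` (height above the knee pivot), compared with
#'     [seat_angle_band()] of the user's thigh-angle range; G4 adds the seat
#'     inclination to the angle before comparison.
#'   \item H1: seated knee angle = 90 + atan((leg height - Z7)/x) degrees.
#' }
#'
#' @param spec A `seat_spec`.
#' @param anthro The user's `anthropometry`.
#' @param thresholds A `threshold_table` (e.g. from [extract_thresholds()]),
#'   covering the mapped angles for `cohort`.
#' @param mapping A `comfort_mapping`; default [default_mapping()].
#' @param cohort Which cohort's thresholds to rate against.
#' @return Object of class `comfort_report`: data frame with columns `code`,
#'   `element`, `basis` ("angle" or "dimension"), `induced`, `lower`,
#'   `upper`, `within`, `rating`.
#' @export
evaluate_seat <- function(spec, anthro, thresholds, mapping = default_mapping(),
                          cohort = "elderly") {
  if (!inherits(spec, "seat_spec")) {
    s2s_error("spec must be a seat_spec", "s2s_invalid_seat")
  }
  dimensional_only <- c("E3", "F1", "G1", "G2")
  x <- thigh_length(anthro)
  z7 <- anthro$sitting[["Z7"]]
  body_of <- function(id) {
    if (startsWith(id, "L")) anthro$standing[[id]] else anthro$sitting[[id]]
  }
  rows <- lapply(seq_len(nrow(mapping)), function(i) {
    mrow <- mapping[i, ]
    dim_val <- spec[[mrow$spec_field]]
    if (is.na(mrow$angle) || mrow$code %in% dimensional_only) {
      body <- body_of(mrow$body_value)
      rel <- abs(dim_val - body) / body
      return(data.frame(code = mrow$code, element = mrow$element,
                        basis = "dimension", induced = NA_real_,
                        lower = 0.9 * body, upper = 1.1 * body,
                        within = rel <= 0.10,
                        rating = .rate_dimension(dim_val, body),
                        stringsAsFactors = FALSE))
    }
    rng <- .threshold_range(thresholds, cohort, mrow$angle)
    if (is.null(rng)) {
      s2s_error(sprintf("no %s threshold for angle '%s' (element %s)",
                        cohort, mrow$angle, mrow$code), "s2s_missing_threshold")
    }
    induced <- switch(mrow$code,
      E1 = spec$backrest_inclination,
      E2 = spec$backrest_inclination +
        90 * max(0, 1 - spec$backrest_height / body_of("Z2")),
      F2 = 90 * spec$armrest_spacing / body_of("Z13"),
      G3 = , G4 = {
        y <- max(0, spec$seat_height - z7)
        a <- seat_thigh_angle(x, y)
        if (mrow$code == "G4") a <- a + spec$seat_inclination
        a
      },
      H1 = 90 + atan((spec$chair_leg_height - z7) / x) * 180 / pi
    )
    if (mrow$code %in% c("G3", "G4")) rng <- seat_angle_band(rng)
    data.frame(code = mrow$code, element = mrow$element, basis = "angle",
               induced = induced, lower = rng[1], upper = rng[2],
               within = induced >= rng[1] && induced <= rng[2],
               rating = .rate_angle(induced, rng[1], rng[2]),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("comfort_report", "data.frame"))
}

#' @export
print.comfort_report <- function(x, ...) {
  cat("<comfort_report>\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
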