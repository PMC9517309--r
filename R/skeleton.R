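#' The 25 tracked skeletal key-points
#'
#' Joint identifiers for the depth-sensor skeleton, in the fixed order used by
#' the motion file schema (see [motion_schema()]). Coordinates are expressed in
#' the camera frame: origin at the sensor, x lateral (towards the subject's
#' right as seen by the camera, i.e. the device's left), y up, z along the view
#' direction, all in meters.
#'
#' @return Character vector of 25 joint names.
#' @export
#' @examples
#' kinect_joints()
kinect_joints <- function() {
  c("head", "neck", "spine_shoulder", "shoulder_left", "shoulder_right",
    "spine_mid", "elbow_left", "elbow_right", "spine_base", "hip_left",
    "hip_right", "wrist_left", "wrist_right", "hand_left", "hand_right",
    "thumb_left", "thumb_right", "hand_tip_left", "hand_tip_right",
    "knee_left", "knee_right", "ankle_left", "ankle_right",
    "foot_left", "foot_right")
}

.cohorts <- c("elderly", "control")

s2s_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "s2s_error", "error")))
}

#' Construct a skeletal frame
#'
#' A frame holds the 3D position of all 25 joints at one timestamp. Frames with
#' missing joints or non-finite coordinates are rejected (no imputation).
#'
#' @param timestamp Time in seconds (finite, non-negative).
#' @param positions Either a 25 x 3 numeric matrix with rownames from
#'   [kinect_joints()] and columns x, y, z (meters), or a named list of
#'   length-3 numeric vectors.
#' @return An object of class `skeleton_frame`: the position matrix with a
#'   `timestamp` attribute.
#' @export
#' @examples
#' pos <- matrix(0, 25, 3, dimnames = list(kinect_joints(), c("x", "y", "z")))
#' pos[, "y"] <- seq(1.7, 0, length.out = 25)
#' f <- skeleton_frame(0, pos)
skeleton_frame <- function(timestamp, positions) {
  if (is.list(positions)) {
    positions <- do.call(rbind, positions)
  }
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  f <- structure(positions, timestamp = as.numeric(timestamp),
                 class = "skeleton_frame")
  report <- validate_frame(f)
  if (length(report) > 0) {
    s2s_error(paste0("invalid skeleton frame: ",
                     paste(report, collapse = "; ")), "s2s_invalid_frame")
  }
  f
}

#' Validate a skeletal frame
#'
#' Report-based validation: returns a character vector of violated invariants
#' (missing joints, unknown joints, non-finite coordinates, bad timestamp).
#' An empty vector means the frame is valid.
#'
#' @param frame A `skeleton_frame`, or any matrix-like object with joint
#'   rownames and a `timestamp` attribute.
#' @return Character vector of violations (length 0 if valid).
#' @export
validate_frame <- function(frame) {
  report <- character(0)
  joints <- kinect_joints()
  rn <- rownames(frame)
  if (is.null(rn)) {
    return("positions have no joint names")
  }
  missing <- setdiff(joints, rn)
  for (j in missing) report <- c(report, sprintf("missing joint '%s'", j))
  unknown <- setdiff(rn, joints)
  for (j in unknown) report <- c(report, sprintf("unknown joint '%s'", j))
  ts <- attr(frame, "timestamp")
  if (is.null(ts) || !is.finite(ts) || ts < 0) {
    report <- c(report, "timestamp must be finite and non-negative")
  }
  present <- intersect(joints, rn)
  bad <- present[!apply(is.finite(unclass(frame)[present, , drop = FALSE]), 1, all)]
  for (j in bad) report <- c(report, sprintf("non-finite coordinate for joint '%s'", j))
  report
}

#' @export
print.skeleton_frame <- function(x, ...) {
  cat(sprintf("<skeleton_frame> t = %.3f s, 25 joints (m)\n", attr(x, "timestamp")))
  print(utils::head(unclass(x), 4))
  cat("...\n")
  invisible(x)
}

#' Construct a motion sequence
#'
#' An ordered recording of skeletal frames for one subject, with strictly
#' increasing timestamps.
#'
#' @param frames List of `skeleton_frame` objects (at least one).
#' @param subject_id Subject identifier (character scalar).
#' @param cohort One of `"elderly"` or `"control"`.
#' @return Object of class `motion_sequence`.
#' @export
motion_sequence <- function(frames, subject_id, cohort = c("elderly", "control")) {
  cohort <- match.arg(cohort)
  if (!is.list(frames) || length(frames) < 1) {
    s2s_error("a motion sequence needs at least one frame", "s2s_invalid_sequence")
  }
  for (i in seq_along(frames)) {
    rep_i <- validate_frame(frames[[i]])
    if (length(rep_i) > 0) {
      s2s_error(sprintf("frame %d invalid: %s", i, paste(rep_i, collapse = "; ")),
                "s2s_invalid_sequence")
    }
  }
  ts <- vapply(frames, function(f) attr(f, "timestamp"), numeric(1))
  if (any(diff(ts) <= 0)) {
    s2s_error("frame timestamps must be strictly increasing", "s2s_invalid_sequence")
  }
  structure(list(subject_id = as.character(subject_id), cohort = cohort,
                 frames = frames),
            class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  ts <- timestamps(x)
  cat(sprintf("<motion_sequence> subject '%s' (%s): %d frames, %.1f-%.1f s\n",
              x$subject_id, x$cohort, length(x$frames), min(ts), max(ts)))
  invisible(x)
}

#' Frame timestamps of a motion sequence
#'
#' @param seq A `motion_sequence`.
#' @return Numeric vector of timestamps in seconds.
#' @export
timestamps <- function(seq) {
  vapply(seq$frames, function(f) attr(f, "timestamp"), numeric(1))
}

.l_labels <- c(L1 = "height", L2 = "upper arm length", L3 = "forearm length",
  L4 = "greater trochanteric height", L5 = "lower leg length",
  L6 = "eye height", L7 = "shoulder height", L8 = "elbow height",
  L9 = "hand functional height", L10 = "bilateral arm functional supination height",
  L11 = "tibial point height", L12 = "bilateral arm functional spread width",
  L13 = "bilateral elbow spread width", L14 = "maximum body width")

.z_labels <- c(Z1 = "sitting height", Z2 = "sitting shoulder height",
  Z3 = "sitting depth", Z4 = "sitting thigh thickness",
  Z5 = "sitting knee height", Z6 = "sitting eye height",
  Z7 = "calf plus foot height", Z8 = "forearm plus hand functional reach",
  Z9 = "sitting lower limb length", Z10 = "sitting external occipital ridge height",
  Z11 = "sitting elbow height", Z12 = "sitting upper limb functional reach",
  Z13 = "bilateral inter-elbow width", Z14 = "sitting hip width")

#' Construct an anthropometry record
#'
#' Standing measures L1..L14 and sitting measures Z1..Z14, in millimeters.
#' Basic plausibility invariants are enforced: all values positive, the greater
#' trochanteric height (L4) below stature (L1), and the sitting knee height
#' (Z5) below sitting height plus lower-limb length (Z1 + Z9).
#'
#' @param standing Named numeric vector L1..L14 (mm).
#' @param sitting Named numeric vector Z1..Z14 (mm).
#' @return Object of class `anthropometry`.
#' @export
anthropometry <- function(standing, sitting) {
  ln <- paste0("L", 1:14); zn <- paste0("Z", 1:14)
  if (!all(ln %in% names(standing))) {
    s2s_error("standing measures must be named L1..L14", "s2s_invalid_anthropometry")
  }
  if (!all(zn %in% names(sitting))) {
    s2s_error("sitting measures must be named Z1..Z14", "s2s_invalid_anthropometry")
  }
  standing <- as.numeric(standing[ln]); names(standing) <- ln
  sitting <- as.numeric(sitting[zn]); names(sitting) <- zn
  if (any(!is.finite(c(standing, sitting))) || any(c(standing, sitting) <= 0)) {
    s2s_error("all anthropometric values must be finite and positive",
              "s2s_invalid_anthropometry")
  }
  if (standing["L4"] >= standing["L1"]) {
    s2s_error("L4 (greater trochanteric height) must be below L1 (height)",
              "s2s_invalid_anthropometry")
  }
  if (sitting["Z5"] >= sitting["Z1"] + sitting["Z9"]) {
    s2s_error("Z5 (sitting knee height) must be below Z1 + Z9",
              "s2s_invalid_anthropometry")
  }
  structure(list(standing = standing, sitting = sitting), class = "anthropometry")
}

#' @export
print.anthropometry <- function(x, ...) {
  cat(sprintf("<anthropometry> L1 (height) %.0f mm, Z1 (sitting height) %.0f mm\n",
              x$standing["L1"], x$sitting["Z1"]))
  invisible(x)
}
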