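#' The 12 joint-angle identifiers
#'
#' Paired angles use the suffix `_1` for the left limb and `_2` for the right
#' limb. All angles are unsigned, in degrees, within [0, 180].
#'
#' @return Character vector of 12 angle ids.
#' @export
angle_ids <- function() {
  c("theta1", "theta2_1", "theta2_2", "theta3_1", "theta3_2", "theta4",
    "theta5_1", "theta5_2", "theta6_1", "theta6_2", "theta7_1", "theta7_2")
}

.reference_vectors <- list(
  gravity = c(0, -1, 0),
  anti_gravity = c(0, 1, 0),
  forward_horizontal = c(0, 0, 1)
)

.EPS_LEN <- 1e-12

#' Angle at a vertex between two points
#'
#' The unsigned angle at `vertex` between the vectors vertex->p1 and
#' vertex->p2, computed as arccos of the normalized dot product. Symmetric in
#' `p1`, `p2`; invariant under rigid rotation and uniform scaling.
#'
#' @param vertex,p1,p2 Numeric length-3 points.
#' @param label Optional label used in degenerate-geometry error messages.
#' @return Angle in degrees, in [0, 180].
#' @export
#' @examples
#' vector_angle(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0)) # 90
vector_angle <- function(vertex, p1, p2, label = "vector_angle") {
  u <- as.numeric(p1) - as.numeric(vertex)
  v <- as.numeric(p2) - as.numeric(vertex)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < .EPS_LEN || nv < .EPS_LEN) {
    s2s_error(sprintf("%s: zero-length vector (coincident points)", label),
              "s2s_degenerate_geometry")
  }
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Angle between a body segment and a reference direction
#'
#' The unsigned angle between the vector a->b and a reference direction,
#' optionally after projection onto the sagittal plane. The sagittal plane is
#' taken as the camera's y-z plane (the x component is dropped), which assumes
#' a subject facing the sensor.
#'
#' @param a,b Numeric length-3 points (segment from `a` to `b`).
#' @param reference A unit reference: one of `"gravity"` ((0,-1,0)),
#'   `"anti_gravity"` ((0,1,0)), `"forward_horizontal"` ((0,0,1)), or a
#'   numeric length-3 vector.
#' @param sagittal If `TRUE`, drop the x component of a->b before measuring.
#' @param label Optional label for error messages.
#' @return Angle in degrees, in [0, 180].
#' @export
segment_reference_angle <- function(a, b, reference = "gravity",
                                    sagittal = FALSE,
                                    label = "segment_reference_angle") {
  if (is.character(reference)) {
    if (!reference %in% names(.reference_vectors)) {
      s2s_error(sprintf("unknown reference '%s'", reference), "s2s_domain_error")
    }
    reference <- .reference_vectors[[reference]]
  }
  v <- as.numeric(b) - as.numeric(a)
  if (isTRUE(sagittal)) v[1] <- 0
  nv <- sqrt(sum(v^2)); nr <- sqrt(sum(reference^2))
  if (nv < .EPS_LEN) {
    s2s_error(sprintf("%s: segment collapses to a zero vector%s", label,
                      if (isTRUE(sagittal)) " after sagittal projection" else ""),
              "s2s_degenerate_geometry")
  }
  acos(max(-1, min(1, sum(v * reference) / (nv * nr)))) * 180 / pi
}

#' Default definitions of the 12 joint angles
#'
#' Conventions (all overridable by editing the returned list):
#' \itemize{
#'   \item `theta1` neck bend: neck->head vs the anti-gravity vector (0 when
#'     the head is straight above the neck).
#'   \item `theta2_1/2` torso-arm: shoulder->elbow, sagittal projection, vs
#'     gravity (0 for an arm hanging straight down).
#'   \item `theta3_1/2` elbow bend: three-point angle at the elbow between
#'     shoulder and wrist (180 = fully extended arm).
#'   \item `theta4` trunk bend: neck->spine-base vs gravity (0 for an upright
#'     trunk, growing with forward lean).
#'   \item `theta5_1/2` thigh elevation: knee->hip, sagittal projection, vs
#'     gravity (90 for a horizontal thigh, 180 standing).
#'   \item `theta6_1/2` knee bend: three-point angle at the knee between hip
#'     and ankle (180 = straight leg).
#'   \item `theta7_1/2` shin-ground: ankle->knee, sagittal projection, vs the
#'     forward horizontal (90 for a vertical shin).
#' }
#'
#' Each definition is a list with fields `id`, `mode` (`"three_point"` with
#' `joints = c(vertex, p1, p2)`, or `"segment_ref"` with `joints = c(a, b)`),
#' `reference`, and `sagittal`.
#'
#' @return Named list of 12 angle definitions, in [angle_ids()] order.
#' @export
default_angle_definitions <- function() {
  seg <- function(id, a, b, reference, sagittal) {
    list(id = id, mode = "segment_ref", joints = c(a, b),
         reference = reference, sagittal = sagittal)
  }
  tri <- function(id, vertex, p1, p2) {
    list(id = id, mode = "three_point", joints = c(vertex, p1, p2),
         reference = NULL, sagittal = FALSE)
  }
  defs <- list(
    seg("theta1", "neck", "head", "anti_gravity", FALSE),
    seg("theta2_1", "shoulder_left", "elbow_left", "gravity", TRUE),
    seg("theta2_2", "shoulder_right", "elbow_right", "gravity", TRUE),
    tri("theta3_1", "elbow_left", "shoulder_left", "wrist_left"),
    tri("theta3_2", "elbow_right", "shoulder_right", "wrist_right"),
    seg("theta4", "neck", "spine_base", "gravity", FALSE),
    seg("theta5_1", "knee_left", "hip_left", "gravity", TRUE),
    seg("theta5_2", "knee_right", "hip_right", "gravity", TRUE),
    tri("theta6_1", "knee_left", "hip_left", "ankle_left"),
    tri("theta6_2", "knee_right", "hip_right", "ankle_right"),
    seg("theta7_1", "ankle_left", "knee_left", "forward_horizontal", TRUE),
    seg("theta7_2", "ankle_right", "knee_right", "forward_horizontal", TRUE)
  )
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  defs
}

#' Extract the 12 joint angles from one frame
#'
#' @param frame A valid `skeleton_frame`.
#' @param defs Angle definitions, as from [default_angle_definitions()].
#' @return Named numeric vector of angles (degrees) in definition order, with
#'   a `timestamp` attribute.
#' @export
extract_angles <- function(frame, defs = default_angle_definitions()) {
  report <- validate_frame(frame)
  if (length(report) > 0) {
    s2s_error(paste0("invalid frame: ", paste(report, collapse = "; ")),
              "s2s_invalid_frame")
  }
  pos <- unclass(frame)
  vals <- vapply(defs, function(d) {
    tryCatch({
      if (d$mode == "three_point") {
        vector_angle(pos[d$joints[1], ], pos[d$joints[2], ], pos[d$joints[3], ],
                     label = d$id)
      } else {
        segment_reference_angle(pos[d$joints[1], ], pos[d$joints[2], ],
                                reference = d$reference, sagittal = d$sagittal,
                                label = d$id)
      }
    }, s2s_degenerate_geometry = function(e) {
      s2s_error(sprintf("degenerate geometry for angle '%s' (joints: %s)",
                        d$id, paste(d$joints, collapse = ", ")),
                "s2s_degenerate_geometry")
    })
  }, numeric(1))
  names(vals) <- names(defs)
  attr(vals, "timestamp") <- attr(frame, "timestamp")
  vals
}

#' Per-frame angle table for one or more motion sequences
#'
#' Applies [extract_angles()] to every frame. Frames with degenerate geometry
#' are skipped with a warning reporting the count (or re-raised with
#' `on_degenerate = "error"`); an error is raised if every frame of a sequence
#' is degenerate.
#'
#' @param sequences A `motion_sequence` or list of them.
#' @param defs Angle definitions.
#' @param on_degenerate `"skip"` (default) or `"error"`.
#' @return Data frame with columns `subject_id`, `cohort`, `timestamp` and the
#'   12 angle columns.
#' @export
extract_angle_table <- function(sequences, defs = default_angle_definitions(),
                                on_degenerate = c("skip", "error")) {
  on_degenerate <- match.arg(on_degenerate)
  if (inherits(sequences, "motion_sequence")) sequences <- list(sequences)
  out <- vector("list", length(sequences))
  n_skipped <- 0L
  for (s in seq_along(sequences)) {
    sq <- sequences[[s]]
    rows <- vector("list", length(sq$frames))
    for (i in seq_along(sq$frames)) {
      ang <- tryCatch(extract_angles(sq$frames[[i]], defs),
                      s2s_degenerate_geometry = function(e) {
                        if (on_degenerate == "error") stop(e)
                        NULL
                      })
      if (is.null(ang)) { n_skipped <- n_skipped + 1L; next }
      rows[[i]] <- data.frame(subject_id = sq$subject_id, cohort = sq$cohort,
                              timestamp = attr(ang, "timestamp"),
                              as.list(ang), stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) {
      s2s_error(sprintf("all frames of subject '%s' are degenerate", sq$subject_id),
                "s2s_degenerate_geometry")
    }
    out[[s]] <- do.call(rbind, rows)
  }
  if (n_skipped > 0) {
    warning(sprintf("skipped %d degenerate frame(s)", n_skipped))
  }
  do.call(rbind, out)
}

#' Mirror a frame about the sagittal plane
#'
#' Negates every x coordinate and swaps left/right joint labels, producing the
#' frame of the mirror-image subject. Extracting angles from the mirrored
#' frame swaps the left/right members of each angle pair exactly.
#'
#' @param frame A `skeleton_frame`.
#' @return The mirrored `skeleton_frame`.
#' @export
mirror_frame <- function(frame) {
  pos <- unclass(frame)
  pos[, "x"] <- -pos[, "x"]
  rn <- rownames(pos)
  swapped <- ifelse(grepl("_left$", rn), sub("_left$", "_right", rn),
                    ifelse(grepl("_right$", rn), sub("_right$", "_left", rn), rn))
  rownames(pos) <- swapped
  pos <- pos[kinect_joints(), , drop = FALSE]
  skeleton_frame(attr(frame, "timestamp"), pos)
}

#' Thigh-to-seat-surface angle from seat geometry
#'
#' For a seat surface of height `y` (mm, relative to the knee pivot) and a
#' thigh of length `x` (mm) rotating about the knee, the angle between the
#' thigh and the seat surface is `90 - atan(y/x)` degrees.
#'
#' @param thigh_length Thigh length x in mm (> 0).
#' @param seat_height Seat surface height y in mm (>= 0).
#' @return Angle in degrees, in (0, 90].
#' @export
#' @examples
#' seat_thigh_angle(400, 400) # 45
seat_thigh_angle <- function(thigh_length, seat_height) {
  if (!is.finite(thigh_length) || thigh_length <= 0) {
    s2s_error("thigh length x must be positive", "s2s_domain_error")
  }
  if (!is.finite(seat_height) || seat_height < 0) {
    s2s_error("seat height y must be non-negative", "s2s_domain_error")
  }
  90 - atan(seat_height / thigh_length) * 180 / pi
}

#' Seat height realizing a thigh-to-seat angle
#'
#' Inverse of [seat_thigh_angle()]: `y = x * tan(90 - theta5)` (degrees).
#'
#' @param theta5 Target angle in degrees, in (0, 90].
#' @param thigh_length Thigh length x in mm (> 0).
#' @return Seat height y in mm (relative to the knee pivot).
#' @export
#' @examples
#' seat_height_for_angle(45, 400) # 400
seat_height_for_angle <- function(theta5, thigh_length) {
  if (!is.finite(theta5) || theta5 <= 0 || theta5 > 90) {
    s2s_error("theta5 must lie in (0, 90] degrees", "s2s_domain_error")
  }
  if (!is.finite(thigh_length) || thigh_length <= 0) {
    s2s_error("thigh length x must be positive", "s2s_domain_error")
  }
  thigh_length * tan((90 - theta5) * pi / 180)
}
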