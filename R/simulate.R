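#' @rdname stage_keyframe
#' @export
stage_names <- function() c("pre_rise", "hip_raise", "mid_rise", "upright")

# Angles the planar chain can realize independently. theta5_1/2 are implied
# by theta6 and theta7 (the thigh direction follows from the shin direction
# and the knee angle), so they are derived, not free.
.free_angles <- c("theta1", "theta2_1", "theta2_2", "theta3_1", "theta3_2",
                  "theta4", "theta6_1", "theta6_2", "theta7_1", "theta7_2")

.wrap180 <- function(a) ((a + 180) %% 360) - 180

.implied_theta5 <- function(theta6, theta7) {
  alpha_shin <- 90 - theta7
  alpha_thigh <- .wrap180(alpha_shin + 180 - theta6)
  180 - abs(alpha_thigh)
}

#' Construct a stage keyframe
#'
#' A keyframe fixes the target joint angles at the start of one of the four
#' transition stages (pre-rise, hip-raise, mid-rise, upright) and the stage
#' duration. The planar chain has ten free angles (`theta1`, `theta2_*`,
#' `theta3_*`, `theta4`, `theta6_*`, `theta7_*`); the thigh elevations
#' `theta5_*` are implied by `theta6_*` and `theta7_*` and may be supplied
#' only as a consistency check (rejected if more than 2 degrees from the
#' implied value).
#'
#' @param stage One of [stage_names()].
#' @param target_angles Named numeric vector of target angles in degrees.
#' @param duration Stage duration in seconds (> 0).
#' @return Object of class `stage_keyframe`.
#' @export
stage_keyframe <- function(stage, target_angles, duration) {
  stage <- match.arg(stage, stage_names())
  if (!is.finite(duration) || duration <= 0) {
    s2s_error("keyframe duration must be positive", "s2s_invalid_keyframe")
  }
  missing <- setdiff(.free_angles, names(target_angles))
  if (length(missing) > 0) {
    s2s_error(sprintf("keyframe '%s' lacks target(s): %s", stage,
                      paste(missing, collapse = ", ")), "s2s_invalid_keyframe")
  }
  ta <- target_angles[intersect(names(target_angles), angle_ids())]
  if (any(!is.finite(ta)) || any(ta < 0) || any(ta > 180)) {
    s2s_error(sprintf("keyframe '%s' has targets outside [0, 180] degrees", stage),
              "s2s_invalid_keyframe")
  }
  for (side in 1:2) {
    t5 <- sprintf("theta5_%d", side)
    if (t5 %in% names(ta)) {
      implied <- .implied_theta5(ta[[sprintf("theta6_%d", side)]],
                                 ta[[sprintf("theta7_%d", side)]])
      if (abs(ta[[t5]] - implied) > 2) {
        s2s_error(sprintf(
          "keyframe '%s': %s = %.2f is inconsistent with the value %.2f implied by theta6/theta7",
          stage, t5, ta[[t5]], implied), "s2s_invalid_keyframe")
      }
    }
  }
  structure(list(stage = stage, target_angles = ta, duration = duration),
            class = "stage_keyframe")
}

#' Default stage keyframes per cohort
#'
#' Fixture parameters for the synthetic cohorts, not claims about real
#' subjects: targets are placed inside the published per-cohort activity
#' ranges for each angle (the trunk angle after conversion to the
#' upright-is-zero convention of [default_angle_definitions()]). The elderly
#' keyframes span a narrower trunk range and a narrower knee range than the
#' young-control keyframes, reproducing the direction of the reported group
#' difference. Knee angles increase monotonically from the hip-raise stage
#' onward so the hip rises monotonically during standing up.
#'
#' @param cohort `"elderly"` or `"control"`.
#' @return List of 4 `stage_keyframe` objects.
#' @export
default_keyframes <- function(cohort = c("elderly", "control")) {
  cohort <- match.arg(cohort)
  kf <- function(stage, ...) stage_keyframe(stage, c(...), duration = 3)
  if (cohort == "elderly") {
    list(
      kf("pre_rise", theta1 = 10, theta2_1 = 89.65, theta2_2 = 89.732,
         theta3_1 = 75.0, theta3_2 = 77.0, theta4 = 48,
         theta6_1 = 131.0, theta6_2 = 116.0, theta7_1 = 84.0, theta7_2 = 82.5),
      kf("hip_raise", theta1 = 45, theta2_1 = 89.74, theta2_2 = 89.74,
         theta3_1 = 75.5, theta3_2 = 88.0, theta4 = 47,
         theta6_1 = 133.0, theta6_2 = 120.0, theta7_1 = 88.0, theta7_2 = 86.0),
      kf("mid_rise", theta1 = 30, theta2_1 = 89.70, theta2_2 = 89.735,
         theta3_1 = 75.3, theta3_2 = 91.0, theta4 = 42,
         theta6_1 = 145.0, theta6_2 = 155.0, theta7_1 = 92.0, theta7_2 = 95.0),
      kf("upright", theta1 = 5, theta2_1 = 89.66, theta2_2 = 89.731,
         theta3_1 = 75.1, theta3_2 = 80.0, theta4 = 37.5,
         theta6_1 = 154.5, theta6_2 = 179.0, theta7_1 = 90.0, theta7_2 = 90.0)
    )
  } else {
    list(
      kf("pre_rise", theta1 = 8, theta2_1 = 89.82, theta2_2 = 89.825,
         theta3_1 = 80.0, theta3_2 = 90.0, theta4 = 43,
         theta6_1 = 69.0, theta6_2 = 76.0, theta7_1 = 92.5, theta7_2 = 84.5),
      kf("hip_raise", theta1 = 40, theta2_1 = 89.90, theta2_2 = 89.895,
         theta3_1 = 100.0, theta3_2 = 110.0, theta4 = 40,
         theta6_1 = 90.0, theta6_2 = 95.0, theta7_1 = 95.0, theta7_2 = 90.0),
      kf("mid_rise", theta1 = 25, theta2_1 = 89.85, theta2_2 = 89.86,
         theta3_1 = 150.0, theta3_2 = 160.0, theta4 = 20,
         theta6_1 = 140.0, theta6_2 = 150.0, theta7_1 = 105.0, theta7_2 = 100.0),
      kf("upright", theta1 = 4, theta2_1 = 89.83, theta2_2 = 89.84,
         theta3_1 = 179.0, theta3_2 = 179.0, theta4 = 1.0,
         theta6_1 = 177.0, theta6_2 = 178.0, theta7_1 = 92.5, theta7_2 = 90.0)
    )
  }
}

# Direction in the sagittal (y-z) plane: alpha measured in degrees from the
# +y (up) axis towards +z (away from the sensor, i.e. behind the subject).
.sag_dir <- function(alpha) {
  a <- alpha * pi / 180
  c(0, cos(a), sin(a))
}

.segment_lengths <- function(anthro) {
  st <- anthro$standing / 1000; si <- anthro$sitting / 1000
  thigh <- si[["Z9"]] - si[["Z7"]]
  if (thigh <= 0) {
    s2s_error("Z9 - Z7 (thigh length proxy) must be positive", "s2s_invalid_anthropometry")
  }
  head_len <- 0.6 * (si[["Z1"]] - si[["Z2"]])
  if (head_len <= 0) {
    s2s_error("Z1 must exceed Z2 (head above shoulders)", "s2s_invalid_anthropometry")
  }
  list(shank = st[["L5"]], thigh = thigh, trunk = 0.95 * si[["Z2"]],
       head = head_len, upper_arm = st[["L2"]], forearm = st[["L3"]],
       hand = 0.09, hand_tip = 0.06, foot = 0.15,
       hip_off = 0.45 * si[["Z14"]], shoulder_off = 0.45 * st[["L14"]])
}

# Forward kinematics: realize one set of free angle targets on the planar
# chain. Subject faces the sensor (forward = -z); feet on the floor plane
# y = 0 at depth z0.
.pose_from_angles <- function(ang, len, z0 = 2, ankle_y = 0.08) {
  pos <- matrix(NA_real_, 25, 3, dimnames = list(kinect_joints(), c("x", "y", "z")))
  hips <- list()
  for (side in c("left", "right")) {
    i <- if (side == "left") 1L else 2L
    sx <- if (side == "left") 1 else -1
    off <- sx * len$hip_off
    theta6 <- ang[[sprintf("theta6_%d", i)]]
    theta7 <- ang[[sprintf("theta7_%d", i)]]
    alpha_shin <- 90 - theta7
    alpha_thigh <- .wrap180(alpha_shin + 180 - theta6)
    ankle <- c(off, ankle_y, z0)
    knee <- ankle + len$shank * .sag_dir(alpha_shin)
    hip <- knee + len$thigh * .sag_dir(alpha_thigh)
    foot <- ankle + c(0, -0.05, -len$foot)
    pos[paste0("ankle_", side), ] <- ankle
    pos[paste0("knee_", side), ] <- knee
    pos[paste0("hip_", side), ] <- hip
    pos[paste0("foot_", side), ] <- foot
    hips[[side]] <- hip
  }
  spine_base <- c(0, (hips$left[2] + hips$right[2]) / 2,
                  (hips$left[3] + hips$right[3]) / 2)
  alpha_trunk <- -ang[["theta4"]]   # lean forward = towards the sensor
  trunk_dir <- .sag_dir(alpha_trunk)
  neck <- spine_base + len$trunk * trunk_dir
  pos["spine_base", ] <- spine_base
  pos["spine_mid", ] <- spine_base + 0.45 * len$trunk * trunk_dir
  pos["spine_shoulder", ] <- spine_base + 0.88 * len$trunk * trunk_dir
  pos["neck", ] <- neck
  pos["head", ] <- neck + len$head * .sag_dir(-ang[["theta1"]])
  for (side in c("left", "right")) {
    i <- if (side == "left") 1L else 2L
    sx <- if (side == "left") 1 else -1
    shoulder <- pos["spine_shoulder", ] + c(sx * len$shoulder_off, 0, 0)
    alpha_ua <- ang[[sprintf("theta2_%d", i)]] - 180
    alpha_fa <- alpha_ua + 180 - ang[[sprintf("theta3_%d", i)]]
    elbow <- shoulder + len$upper_arm * .sag_dir(alpha_ua)
    wrist <- elbow + len$forearm * .sag_dir(alpha_fa)
    hand <- wrist + len$hand * .sag_dir(alpha_fa)
    pos[paste0("shoulder_", side), ] <- shoulder
    pos[paste0("elbow_", side), ] <- elbow
    pos[paste0("wrist_", side), ] <- wrist
    pos[paste0("hand_", side), ] <- hand
    pos[paste0("hand_tip_", side), ] <- hand + len$hand_tip * .sag_dir(alpha_fa)
    pos[paste0("thumb_", side), ] <- hand + c(sx * 0.025, 0.01, -0.015)
  }
  pos
}

# Cosine-eased interpolation of the free angles between keyframe starts.
.angles_at_time <- function(t, keyframes) {
  K <- t(vapply(keyframes, function(k) k$target_angles[.free_angles], numeric(10)))
  durs <- vapply(keyframes, `[[`, numeric(1), "duration")
  starts <- cumsum(c(0, durs[-length(durs)]))
  if (t >= starts[length(starts)]) {
    out <- K[nrow(K), ]
  } else {
    i <- findInterval(t, starts)
    p <- (t - starts[i]) / (starts[i + 1] - starts[i])
    e <- (1 - cos(p * pi)) / 2
    out <- (1 - e) * K[i, ] + e * K[i + 1, ]
  }
  names(out) <- .free_angles
  out
}

#' Simulate one sit-to-stand recording
#'
#' Realizes keyframe postures on a planar kinematic chain (ankle -> knee ->
#' hip -> spine -> neck -> head, plus arms) with segment lengths derived from
#' the subject's anthropometry, interpolates the free joint angles between
#' stage keyframes with cosine easing, and adds independent Gaussian noise to
#' every coordinate. Identical seeds give identical output.
#'
#' @param anthro An `anthropometry` record.
#' @param keyframes List of 4 `stage_keyframe`s (pre-rise, hip-raise,
#'   mid-rise, upright), e.g. [default_keyframes()].
#' @param noise_sd Coordinate noise standard deviation in meters (default
#'   0.005, i.e. 5 mm).
#' @param interval Sampling interval in seconds (default 1, the capture rate
#'   the pipeline assumes; smaller values give more frames per stage).
#' @param seed Integer seed for the coordinate noise.
#' @param subject_id,cohort Sequence metadata.
#' @param z0 Depth of the subject's ankles in the camera frame (m).
#' @return A `motion_sequence` sampled at `t = 0, interval, ...` over the
#'   summed stage durations.
#' @export
simulate_subject <- function(anthro, keyframes = default_keyframes("elderly"),
                             noise_sd = 0.005, interval = 1, seed = 1,
                             subject_id = "subject1",
                             cohort = c("elderly", "control"), z0 = 2) {
  cohort <- match.arg(cohort)
  if (!inherits(anthro, "anthropometry")) {
    s2s_error("anthro must be an anthropometry record", "s2s_invalid_anthropometry")
  }
  if (length(keyframes) != 4) {
    s2s_error("exactly 4 stage keyframes are required", "s2s_invalid_keyframe")
  }
  keyframes <- lapply(keyframes, function(k) {
    if (!inherits(k, "stage_keyframe")) {
      stage_keyframe(k$stage, k$target_angles, k$duration)
    } else k
  })
  if (!is.finite(noise_sd) || noise_sd < 0) {
    s2s_error("noise_sd must be non-negative", "s2s_domain_error")
  }
  if (!is.finite(interval) || interval <= 0) {
    s2s_error("interval must be positive", "s2s_domain_error")
  }
  len <- .segment_lengths(anthro)
  total <- sum(vapply(keyframes, `[[`, numeric(1), "duration"))
  times <- seq(0, total, by = interval)
  set.seed(as.integer(seed))
  frames <- lapply(times, function(t) {
    pos <- .pose_from_angles(.angles_at_time(t, keyframes), len, z0 = z0)
    if (noise_sd > 0) {
      pos <- pos + matrix(stats::rnorm(75, sd = noise_sd), 25, 3)
    }
    skeleton_frame(t, pos)
  })
  motion_sequence(frames, subject_id = subject_id, cohort = cohort)
}

#' Default anthropometry distribution per cohort
#'
#' Mean and standard deviation (mm) for each L/Z measure; fixture values
#' representative of able-bodied Chinese adults (elderly 60-75 vs controls
#' 20-25, the latter slightly taller). Standard deviations are 4% of the mean.
#'
#' @param cohort `"elderly"` or `"control"`.
#' @return Data frame with columns `measure`, `mean`, `sd`.
#' @export
default_anthropometry_distribution <- function(cohort = c("elderly", "control")) {
  cohort <- match.arg(cohort)
  m <- c(L1 = 1620, L2 = 300, L3 = 240, L4 = 820, L5 = 380, L6 = 1510,
         L7 = 1330, L8 = 1000, L9 = 730, L10 = 2030, L11 = 430, L12 = 1620,
         L13 = 960, L14 = 450,
         Z1 = 850, Z2 = 560, Z3 = 450, Z4 = 130, Z5 = 480, Z6 = 740,
         Z7 = 390, Z8 = 340, Z9 = 960, Z10 = 620, Z11 = 230, Z12 = 800,
         Z13 = 450, Z14 = 360)
  if (cohort == "control") m <- round(m * 1.05)
  data.frame(measure = names(m), mean = unname(m), sd = unname(round(0.04 * m)),
             stringsAsFactors = FALSE)
}

.draw_anthropometry <- function(dist) {
  vals <- stats::rnorm(nrow(dist), dist$mean, dist$sd)
  vals <- pmin(pmax(vals, 0.7 * dist$mean), 1.3 * dist$mean)
  names(vals) <- dist$measure
  # keep the record invariants under extreme draws
  vals["L4"] <- min(vals["L4"], 0.95 * vals["L1"])
  vals["Z2"] <- min(vals["Z2"], 0.92 * vals["Z1"])
  anthropometry(vals[paste0("L", 1:14)], vals[paste0("Z", 1:14)])
}

#' Construct a cohort simulation specification
#'
#' @param n_subjects Number of subjects (>= 1; the study recruited 21 per
#'   group, the default).
#' @param cohort `"elderly"` or `"control"`.
#' @param anthro_dist Anthropometry distribution data frame
#'   (measure/mean/sd in mm), as [default_anthropometry_distribution()].
#' @param keyframes List of 4 `stage_keyframe`s.
#' @param noise_sd Coordinate noise sd in meters (>= 0).
#' @param interval Sampling interval in seconds (> 0).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, cohort = c("elderly", "control"),
                        anthro_dist = default_anthropometry_distribution(cohort),
                        keyframes = default_keyframes(cohort),
                        noise_sd = 0.005, interval = 1, seed = 1) {
  cohort <- match.arg(cohort)
  if (!is.finite(n_subjects) || n_subjects < 1) {
    s2s_error("n_subjects must be at least 1", "s2s_domain_error")
  }
  if (any(anthro_dist$sd < 0)) {
    s2s_error("anthropometry sds must be non-negative", "s2s_domain_error")
  }
  if (!is.finite(interval) || interval <= 0) {
    s2s_error("interval must be positive", "s2s_domain_error")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    s2s_error("noise_sd must be non-negative", "s2s_domain_error")
  }
  structure(list(n_subjects = as.integer(n_subjects), cohort = cohort,
                 anthro_dist = anthro_dist, keyframes = keyframes,
                 noise_sd = noise_sd, interval = interval,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param ... Passed to [cohort_spec()].
#' @export
default_cohort_spec <- function(cohort = c("elderly", "control"),
                                n_subjects = 21, seed = 1, ...) {
  cohort <- match.arg(cohort)
  cohort_spec(n_subjects = n_subjects, cohort = cohort, seed = seed, ...)
}

#' Simulate a cohort of sit-to-stand recordings
#'
#' Draws per-subject anthropometry from the specified distribution and
#' simulates each subject with a derived per-subject seed; fully reproducible
#' under `spec$seed`.
#'
#' @param spec A `cohort_spec`.
#' @return List of `motion_sequence` objects, with the drawn `anthropometry`
#'   records attached as attribute `"anthropometry"`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    s2s_error("spec must be a cohort_spec", "s2s_domain_error")
  }
  set.seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)
  anthros <- lapply(seq_len(spec$n_subjects), function(i) .draw_anthropometry(spec$anthro_dist))
  seqs <- lapply(seq_len(spec$n_subjects), function(i) {
    simulate_subject(anthros[[i]], keyframes = spec$keyframes,
                     noise_sd = spec$noise_sd, interval = spec$interval,
                     seed = subject_seeds[i],
                     subject_id = sprintf("%s_%02d", spec$cohort, i),
                     cohort = spec$cohort)
  })
  names(seqs) <- vapply(seqs, `[[`, character(1), "subject_id")
  names(anthros) <- names(seqs)
  attr(seqs, "anthropometry") <- anthros
  seqs
}
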