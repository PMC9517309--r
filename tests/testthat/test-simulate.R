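test_that("noise-free simulation realizes keyframe targets at stage starts", {
  a <- mean_anthropometry()
  for (cohort in c("elderly", "control")) {
    kfs <- default_keyframes(cohort)
    s <- simulate_subject(a, kfs, noise_sd = 0, interval = 1, seed = 1,
                          cohort = cohort)
    tab <- extract_angle_table(s)
    starts <- c(0, 3, 6, 9)
    for (i in seq_along(kfs)) {
      row <- tab[tab$timestamp == starts[i], ]
      tg <- kfs[[i]]$target_angles
      expect_equal(unlist(row[names(tg)]), tg, tolerance = 0.5,
                   ignore_attr = TRUE)
      # implied thigh elevations match the chain geometry oracle
      expect_equal(row$theta5_1,
                   oracle_theta5(tg[["theta6_1"]], tg[["theta7_1"]]),
                   tolerance = 0.5)
      expect_equal(row$theta5_2,
                   oracle_theta5(tg[["theta6_2"]], tg[["theta7_2"]]),
                   tolerance = 0.5)
    }
  }
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  a <- mean_anthropometry()
  s1 <- simulate_subject(a, default_keyframes("elderly"), noise_sd = 0.005,
                         interval = 1, seed = 9)
  s2 <- simulate_subject(a, default_keyframes("elderly"), noise_sd = 0.005,
                         interval = 1, seed = 9)
  s3 <- simulate_subject(a, default_keyframes("elderly"), noise_sd = 0.005,
                         interval = 1, seed = 10)
  expect_identical(lapply(s1$frames, unclass), lapply(s2$frames, unclass))
  expect_false(identical(unclass(s1$frames[[1]]), unclass(s3$frames[[1]])))
  # schema identical regardless of seed
  expect_identical(dimnames(unclass(s3$frames[[1]])),
                   dimnames(unclass(s1$frames[[1]])))
})

test_that("noise-free chains conserve segment lengths and raise the hip monotonically", {
  a <- mean_anthropometry()
  for (cohort in c("elderly", "control")) {
    s <- simulate_subject(a, default_keyframes(cohort), noise_sd = 0,
                          interval = 0.5, seed = 1, cohort = cohort)
    segs <- list(c("ankle_left", "knee_left"), c("knee_left", "hip_left"),
                 c("ankle_right", "knee_right"), c("knee_right", "hip_right"),
                 c("spine_base", "neck"), c("neck", "head"),
                 c("shoulder_left", "elbow_left"), c("elbow_right", "wrist_right"))
    for (seg in segs) {
      d <- vapply(s$frames, function(f) {
        sqrt(sum((unclass(f)[seg[1], ] - unclass(f)[seg[2], ])^2))
      }, numeric(1))
      expect_lt(max(d) - min(d), 1e-9)
    }
    hip_y <- vapply(s$frames, function(f) {
      mean(unclass(f)[c("hip_left", "hip_right"), "y"])
    }, numeric(1))
    ts <- timestamps(s)
    rise <- hip_y[ts >= 3]   # hip-raise stage onward
    expect_true(all(diff(rise) >= -1e-9))
  }
})

test_that("keyframe validation rejects out-of-range and inconsistent targets", {
  ok <- default_keyframes("elderly")[[1]]
  bad <- ok$target_angles; bad["theta6_1"] <- 190
  expect_error(stage_keyframe("pre_rise", bad, 3), class = "s2s_invalid_keyframe")
  expect_error(stage_keyframe("pre_rise", ok$target_angles, 0),
               class = "s2s_invalid_keyframe")
  expect_error(stage_keyframe("pre_rise", ok$target_angles[-1], 3),
               class = "s2s_invalid_keyframe")
  # a theta5 target inconsistent with theta6/theta7 is refused
  with_t5 <- c(ok$target_angles, theta5_1 = 30)
  expect_error(stage_keyframe("pre_rise", with_t5, 3),
               class = "s2s_invalid_keyframe")
  consistent <- c(ok$target_angles,
                  theta5_1 = oracle_theta5(ok$target_angles[["theta6_1"]],
                                           ok$target_angles[["theta7_1"]]))
  expect_s3_class(stage_keyframe("pre_rise", consistent, 3), "stage_keyframe")
})

test_that("simulate_cohort draws reproducible per-subject anthropometry", {
  spec <- default_cohort_spec("elderly", n_subjects = 21, seed = 4)
  seqs <- simulate_cohort(spec)
  expect_length(seqs, 21)
  for (s in seqs) {
    expect_s3_class(s, "motion_sequence")
    expect_identical(s$cohort, "elderly")
  }
  anthros <- attr(seqs, "anthropometry")
  expect_length(anthros, 21)
  # subjects differ, reruns do not
  expect_false(identical(anthros[[1]]$standing, anthros[[2]]$standing))
  seqs2 <- simulate_cohort(default_cohort_spec("elderly", n_subjects = 21, seed = 4))
  expect_identical(lapply(seqs$elderly_01$frames, unclass),
                   lapply(seqs2$elderly_01$frames, unclass))
  expect_error(cohort_spec(0, "elderly"), class = "s2s_domain_error")
})
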