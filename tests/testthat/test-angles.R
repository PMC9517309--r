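test_that("vector_angle matches the arccos oracle and its invariants", {
  expect_equal(vector_angle(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0)), 90)
  expect_equal(vector_angle(c(0, 0, 0), c(0, 1, 0), c(0, 3, 0)), 0)

  oracle <- function(vertex, p1, p2) {
    u <- p1 - vertex; v <- p2 - vertex
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  set.seed(101)
  for (i in 1:100) {
    pts <- matrix(rnorm(9), 3)
    got <- vector_angle(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(got, oracle(pts[1, ], pts[2, ], pts[3, ]), tolerance = 1e-9)
    # symmetry in the two endpoints
    expect_identical(got, vector_angle(pts[1, ], pts[3, ], pts[2, ]))
  }

  # invariance under rigid rotation and uniform scaling
  set.seed(102)
  theta <- runif(1, 0, 2 * pi)
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
  for (i in 1:20) {
    pts <- matrix(rnorm(9), 3)
    s <- runif(1, 0.1, 10)
    base <- vector_angle(pts[1, ], pts[2, ], pts[3, ])
    moved <- s * t(R %*% t(pts))
    expect_equal(vector_angle(moved[1, ], moved[2, ], moved[3, ]), base,
                 tolerance = 1e-9)
  }

  expect_error(vector_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "s2s_degenerate_geometry")
})

test_that("segment_reference_angle handles references and sagittal projection", {
  expect_equal(segment_reference_angle(c(0, 0, 0), c(0, -1, 0), "gravity"), 0)
  expect_equal(segment_reference_angle(c(0, 0, 0), c(0, 0, 1), "gravity",
                                       sagittal = TRUE), 90)
  # projection drops x: (1,1,0) -> (0,1,0), opposite to gravity
  expect_equal(segment_reference_angle(c(0, 0, 0), c(1, 1, 0), "gravity",
                                       sagittal = TRUE), 180)
  # a purely lateral segment collapses under projection
  expect_error(segment_reference_angle(c(0, 0, 0), c(1, 0, 0), "gravity",
                                       sagittal = TRUE),
               class = "s2s_degenerate_geometry")
  expect_error(segment_reference_angle(c(0, 0, 0), c(0, 1, 0), "sideways"),
               class = "s2s_domain_error")
})

test_that("extract_angles realizes the documented conventions on constructed frames", {
  up <- upright_frame()
  ang <- extract_angles(up)
  expect_named(ang, angle_ids())
  expect_true(all(ang >= 0 & ang <= 180))
  expect_equal(unname(ang["theta4"]), 0, tolerance = 1e-9)
  expect_equal(unname(ang["theta1"]), 0, tolerance = 1e-9)
  expect_equal(unname(ang["theta6_1"]), 180, tolerance = 1e-9)
  expect_equal(unname(ang["theta7_2"]), 90, tolerance = 1e-9)
  # straight vertical thigh: knee->hip anti-parallel to gravity
  expect_equal(unname(ang["theta5_2"]), 180, tolerance = 1e-9)

  # right thigh horizontal (hip and knee at equal height): theta5_2 = 90
  kfs <- static_keyframes(theta1 = 5, theta2_1 = 10, theta2_2 = 10,
                          theta3_1 = 120, theta3_2 = 120, theta4 = 10,
                          theta6_1 = 90, theta6_2 = 90,
                          theta7_1 = 90, theta7_2 = 90)
  seated <- simulate_subject(mean_anthropometry(), kfs, noise_sd = 0,
                             interval = 1, seed = 1)$frames[[1]]
  sang <- extract_angles(seated)
  expect_equal(unname(sang["theta5_2"]), 90, tolerance = 1e-9)
  hipz <- unclass(seated)[c("hip_right", "knee_right"), "y"]
  expect_equal(unname(hipz[1]), unname(hipz[2]), tolerance = 1e-12)

  # coincident neck and head -> degenerate theta1, identified by id
  pos <- unclass(up)
  pos["head", ] <- pos["neck", ]
  broken <- structure(pos, timestamp = 0, class = "skeleton_frame")
  err <- expect_error(extract_angles(broken), class = "s2s_degenerate_geometry")
  expect_match(conditionMessage(err), "theta1")
})

test_that("mirroring a frame swaps left and right angle values exactly", {
  a <- mean_anthropometry()
  # deliberately asymmetric posture
  kfs <- static_keyframes(theta1 = 12, theta2_1 = 20, theta2_2 = 80,
                          theta3_1 = 70, theta3_2 = 150, theta4 = 25,
                          theta6_1 = 100, theta6_2 = 160,
                          theta7_1 = 80, theta7_2 = 100)
  f <- simulate_subject(a, kfs, noise_sd = 0.01, interval = 1, seed = 5)$frames[[2]]
  ang <- extract_angles(f)
  mang <- extract_angles(mirror_frame(f))
  expect_equal(as.numeric(mang[swap_left_right(names(ang))]), as.numeric(ang),
               tolerance = 1e-12)
})

test_that("seat geometry follows theta5 = 90 - atan(y/x) and round-trips", {
  expect_equal(seat_thigh_angle(400, 0), 90)
  expect_equal(seat_thigh_angle(400, 400), 45)
  expect_equal(seat_thigh_angle(450, 260), 90 - atan(260 / 450) * 180 / pi)
  expect_equal(seat_thigh_angle(450, 260), 59.98, tolerance = 1e-3)
  expect_equal(seat_height_for_angle(90, 400), 0)
  expect_equal(seat_height_for_angle(45, 400), 400)
  expect_equal(seat_height_for_angle(60, 450), 450 * tan(pi / 6), tolerance = 1e-9)

  for (theta in seq(5, 90, by = 5)) {
    y <- seat_height_for_angle(theta, 437)
    expect_equal(seat_thigh_angle(437, y), theta, tolerance = 1e-9)
  }
  expect_error(seat_thigh_angle(0, 100), class = "s2s_domain_error")
  expect_error(seat_height_for_angle(95, 400), class = "s2s_domain_error")
  expect_error(seat_height_for_angle(0, 400), class = "s2s_domain_error")
})
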