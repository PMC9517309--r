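test_that("the default element mapping carries the published ten rows", {
  m <- default_mapping()
  expect_equal(nrow(m), 10)
  expect_false(any(duplicated(m$code)))
  expect_identical(m$angle[m$code == "G4"], "theta5_2")
  expect_identical(m$angle[m$code == "G3"], "theta5_1")
  expect_true(is.na(m$angle[m$code == "E3"]))
  expect_identical(m$angle[m$code == "G1"], "theta3_2")
  expect_identical(m$body_value[m$code == "H1"], "Z7")
})

test_that("recommend_seat_height inverts the seat geometry over a band", {
  expect_equal(recommend_seat_height(NULL, c(45, 90), x = 400), c(0, 400))
  h <- recommend_seat_height(NULL, c(60, 60), x = 450)
  expect_equal(h, rep(450 * tan(pi / 6), 2), tolerance = 1e-9)
  expect_error(recommend_seat_height(NULL, c(80, 60), x = 400),
               class = "s2s_domain_error")
  expect_error(recommend_seat_height(NULL, c(0, 45), x = 400),
               class = "s2s_domain_error")

  a <- mean_anthropometry()
  band <- c(35, 75)
  hh <- recommend_seat_height(a, band)
  expect_equal(seat_thigh_angle(thigh_length(a), hh[1]), band[2], tolerance = 1e-9)
  expect_equal(seat_thigh_angle(thigh_length(a), hh[2]), band[1], tolerance = 1e-9)
  # monotone decreasing in theta
  expect_true(hh[1] < hh[2])
})

test_that("seat_angle_band converts gravity-convention ranges into (0, 90]", {
  expect_equal(seat_angle_band(c(115.049, 179.456)), c(25.049, 89.456))
  expect_equal(seat_angle_band(c(80, 200)), c(1e-6, 90))
  expect_error(seat_angle_band(c(120, 100)), class = "s2s_domain_error")
})

make_threshold_fixture <- function() {
  a <- mean_anthropometry()
  seqs <- list(simulate_subject(a, default_keyframes("elderly"), noise_sd = 0,
                                interval = 0.5, seed = 3, subject_id = "e1",
                                cohort = "elderly"))
  list(anthro = a, thresholds = extract_thresholds(seqs))
}

test_that("a seat at the recommended height rates 5 on seat height", {
  fx <- make_threshold_fixture()
  a <- fx$anthro; thr <- fx$thresholds
  rng <- unlist(thr[thr$angle == "theta5_1", c("lower", "upper")])
  band <- seat_angle_band(rng)
  heights <- recommend_seat_height(a, band)
  spec <- default_seat_spec()
  spec$seat_height <- a$sitting[["Z7"]] + mean(heights)
  rep <- evaluate_seat(spec, a, thr)
  expect_equal(rep$rating[rep$code == "G3"], 5L)
  expect_true(rep$within[rep$code == "G3"])
})

test_that("ratings fall with distance from the range and never below 1", {
  fx <- make_threshold_fixture()
  a <- fx$anthro; thr <- fx$thresholds
  rng <- unlist(thr[thr$angle == "theta5_1", c("lower", "upper")])
  band <- seat_angle_band(rng)
  x <- thigh_length(a)
  width <- band[2] - band[1]
  # seat height putting theta5 one full band-width below the lower bound
  target <- max(band[1] - width, 1e-3)
  spec <- default_seat_spec()
  spec$seat_height <- a$sitting[["Z7"]] + seat_height_for_angle(target, x)
  rep <- evaluate_seat(spec, a, thr)
  expect_lte(rep$rating[rep$code == "G3"], 2L)
  expect_gte(rep$rating[rep$code == "G3"], 1L)

  # moving the induced angle towards the band midpoint never lowers the rating
  targets <- seq(max(band[1] - width, 1e-3), mean(band), length.out = 12)
  ratings <- vapply(targets, function(tg) {
    sp <- default_seat_spec()
    sp$seat_height <- a$sitting[["Z7"]] + seat_height_for_angle(tg, x)
    r <- evaluate_seat(sp, a, thr)
    r$rating[r$code == "G3"]
  }, integer(1))
  expect_true(all(diff(ratings) >= 0))
  expect_true(all(ratings >= 1 & ratings <= 5))
})

test_that("dimension-only elements use the ten-percent tolerance rule", {
  fx <- make_threshold_fixture()
  a <- fx$anthro; thr <- fx$thresholds
  spec <- default_seat_spec()
  spec$backrest_width <- a$standing[["L14"]] * 1.05  # within 10% of shoulder width
  rep <- evaluate_seat(spec, a, thr)
  expect_equal(rep$rating[rep$code == "E3"], 5L)
  expect_identical(rep$basis[rep$code == "E3"], "dimension")

  spec$backrest_width <- a$standing[["L14"]] * 1.35
  rep2 <- evaluate_seat(spec, a, thr)
  expect_lt(rep2$rating[rep2$code == "E3"], 5L)

  # the published seat-width -> elbow-angle link is rated dimensionally
  expect_identical(rep$basis[rep$code == "G1"], "dimension")
})

test_that("evaluate_seat names the element when a threshold is missing", {
  fx <- make_threshold_fixture()
  thr <- fx$thresholds[fx$thresholds$angle != "theta5_2", ]
  err <- expect_error(evaluate_seat(default_seat_spec(), fx$anthro, thr),
                      class = "s2s_missing_threshold")
  expect_match(conditionMessage(err), "G4")
})

test_that("seat_spec validates lengths and inclinations", {
  expect_error(seat_spec(10, -5, 480, 230, 545, 520, 450, 420, 3, 390),
               class = "s2s_invalid_seat")
  expect_error(seat_spec(95, 560, 480, 230, 545, 520, 450, 420, 3, 390),
               class = "s2s_invalid_seat")
  expect_s3_class(default_seat_spec(), "seat_spec")
})
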