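test_that("cluster_postures recovers separable posture blobs", {
  set.seed(21)
  n <- 60
  blob <- function(center) {
    m <- matrix(rnorm(n * 12, sd = 2), n, 12, dimnames = list(NULL, angle_ids()))
    sweep(m, 2, center, "+")
  }
  X <- rbind(blob(rep(60, 12)), blob(rep(100, 12)))  # 40 degrees apart
  truth <- rep(1:2, each = n)
  df <- data.frame(timestamp = seq_len(2 * n), X)
  cl <- cluster_postures(df, k = 2, seed = 3)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1.0)
  # centroid equals the member mean
  for (j in 1:2) {
    expect_equal(unname(cl$centroids[j, ]),
                 unname(colMeans(X[cl$cluster == j, ])), tolerance = 1e-9)
  }
})

test_that("cluster_postures handles k = 1, degenerate input, and frame order", {
  set.seed(22)
  X <- matrix(runif(30 * 12, 0, 180), 30, 12, dimnames = list(NULL, angle_ids()))
  df <- as.data.frame(X)
  one <- cluster_postures(df, k = 1, seed = 1)
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(X)), tolerance = 1e-12)

  # all-identical vectors: empty clusters re-seeded, assignments still total
  same <- as.data.frame(matrix(90, 10, 12, dimnames = list(NULL, angle_ids())))
  deg <- cluster_postures(same, k = 2, seed = 1)
  expect_length(deg$cluster, 10)
  expect_true(all(deg$centroids == 90))

  # result invariant to frame order under the same seed
  perm <- sample(nrow(X))
  cl1 <- cluster_postures(df, k = 3, seed = 7)
  cl2 <- cluster_postures(df[perm, ], k = 3, seed = 7)
  expect_equal(cl1$tot_withinss, cl2$tot_withinss, tolerance = 1e-8)
  expect_equal(cl1$centroids[order(cl1$centroids[, 1]), ],
               cl2$centroids[order(cl2$centroids[, 1]), ], tolerance = 1e-8)
  expect_error(cluster_postures(df, k = 31, seed = 1), class = "s2s_domain_error")
})

test_that("extract_thresholds reproduces analytic extremes of noise-free cohorts", {
  a <- mean_anthropometry()
  seqs <- list(
    simulate_subject(a, default_keyframes("elderly"), noise_sd = 0,
                     interval = 1, seed = 1, subject_id = "e1", cohort = "elderly"),
    simulate_subject(mean_anthropometry("control"), default_keyframes("control"),
                     noise_sd = 0, interval = 1, seed = 2,
                     subject_id = "c1", cohort = "control")
  )
  thr <- extract_thresholds(seqs)
  expect_s3_class(thr, "threshold_table")
  expect_true(all(thr$lower <= thr$upper))

  times <- 0:12
  for (cohort in c("elderly", "control")) {
    kfs <- default_keyframes(cohort)
    for (id in setdiff(angle_ids(), c("theta5_1", "theta5_2"))) {
      vals <- oracle_eased_angles(times, kfs, id)
      row <- thr[thr$cohort == cohort & thr$angle == id, ]
      expect_equal(row$lower, min(vals), tolerance = 1e-9)
      expect_equal(row$upper, max(vals), tolerance = 1e-9)
    }
    # implied thigh elevation: oracle applied to the eased theta6/theta7 path
    for (side in 1:2) {
      t6 <- oracle_eased_angles(times, kfs, sprintf("theta6_%d", side))
      t7 <- oracle_eased_angles(times, kfs, sprintf("theta7_%d", side))
      vals <- oracle_theta5(t6, t7)
      row <- thr[thr$cohort == cohort & thr$angle == sprintf("theta5_%d", side), ]
      expect_equal(row$lower, min(vals), tolerance = 1e-9)
      expect_equal(row$upper, max(vals), tolerance = 1e-9)
    }
  }
})

test_that("threshold bounds are tight and constant angles collapse the range", {
  a <- mean_anthropometry()
  s <- simulate_subject(a, default_keyframes("elderly"), noise_sd = 0.003,
                        interval = 0.5, seed = 13)
  thr <- extract_thresholds(list(s))
  tab <- extract_angle_table(s)
  for (id in angle_ids()) {
    row <- thr[thr$angle == id, ]
    expect_true(any(abs(tab[[id]] - row$lower) < 1e-12))
    expect_true(any(abs(tab[[id]] - row$upper) < 1e-12))
  }

  held <- simulate_subject(a, static_keyframes(
    theta1 = 10, theta2_1 = 15, theta2_2 = 15, theta3_1 = 100, theta3_2 = 100,
    theta4 = 20, theta6_1 = 120, theta6_2 = 120, theta7_1 = 90, theta7_2 = 90),
    noise_sd = 0, interval = 1, seed = 1)
  thr2 <- extract_thresholds(list(held))
  expect_equal(thr2$lower, thr2$upper, tolerance = 1e-9)
})

test_that("elderly default cohort spans a strictly narrower trunk range than controls", {
  seqs <- c(
    simulate_cohort(default_cohort_spec("elderly", n_subjects = 3, seed = 5)),
    simulate_cohort(default_cohort_spec("control", n_subjects = 3, seed = 6))
  )
  thr <- extract_thresholds(seqs)
  width <- function(cohort) {
    row <- thr[thr$cohort == cohort & thr$angle == "theta4", ]
    row$upper - row$lower
  }
  expect_lt(width("elderly"), width("control"))
})

test_that("rank_importance finds a planted informative angle and keeps its contracts", {
  fix <- planted_angle_data(n = 300, seed = 31)
  res <- rank_importance(fix$angles, fix$labels, seed = 8)
  expect_equal(sum(res$importance), 1, tolerance = 1e-9)
  expect_equal(max(res$normalized), 100)
  top <- res$angle[which.max(res$importance)]
  expect_identical(top, "theta5_2")
  expect_identical(res$angle[res$normalized == 100], "theta5_2")
  expect_equal(attr(res, "train_n") + attr(res, "test_n"), 300)

  # a pure-noise column's raw accuracy drop is within permutation noise
  noise_row <- which(res$angle == "theta3_1")
  expect_lt(res$raw_drop[noise_row], 2 * res$perm_se[noise_row] + 1e-9)

  expect_error(rank_importance(fix$angles, rep("a", 300)), class = "s2s_domain_error")
  expect_error(rank_importance(fix$angles, fix$labels, split = 1.2),
               class = "s2s_domain_error")
})

test_that("stage_report orders stages in time and partitions fine into coarse", {
  seqs <- simulate_cohort(default_cohort_spec("elderly", n_subjects = 4,
                                              seed = 17, interval = 0.25))
  tab <- extract_angle_table(seqs)
  cl4 <- cluster_postures(tab, k = 4, seed = 2)
  rep4 <- stage_report(cl4)
  expect_equal(nrow(rep4), 4)
  expect_true(all(diff(rep4$mean_time) > 0))
  # first stage resembles the pre-rise posture, last the upright posture
  pre <- default_keyframes("elderly")[[1]]$target_angles
  up <- default_keyframes("elderly")[[4]]$target_angles
  expect_lt(abs(rep4$theta6_2[1] - pre[["theta6_2"]]),
            abs(rep4$theta6_2[1] - up[["theta6_2"]]))
  expect_lt(abs(rep4$theta6_2[4] - up[["theta6_2"]]),
            abs(rep4$theta6_2[4] - pre[["theta6_2"]]))

  cl9 <- cluster_postures(tab, k = 9, seed = 2)
  rep93 <- stage_report(cl9, coarse = 3)
  cm <- attr(rep93, "coarse_map")
  expect_length(cm, 9)
  expect_true(all(cm %in% 1:3))
  expect_setequal(unique(cm), 1:3)
})
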