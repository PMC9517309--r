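# Shared fixtures built in code: cohort-mean anthropometry, constructed
# frames, and independent re-implementations used as oracles.

mean_anthropometry <- function(cohort = "elderly") {
  dist <- default_anthropometry_distribution(cohort)
  m <- stats::setNames(dist$mean, dist$measure)
  anthropometry(m[paste0("L", 1:14)], m[paste0("Z", 1:14)])
}

# A single posture held over all four stages (useful for constructed frames).
static_keyframes <- function(...) {
  targets <- c(...)
  lapply(stage_names(), function(s) stage_keyframe(s, targets, duration = 3))
}

# Fully upright standing posture: vertical trunk/neck/legs, arms hanging.
upright_frame <- function(anthro = mean_anthropometry()) {
  kfs <- static_keyframes(theta1 = 0, theta2_1 = 0, theta2_2 = 0,
                          theta3_1 = 180, theta3_2 = 180, theta4 = 0,
                          theta6_1 = 180, theta6_2 = 180,
                          theta7_1 = 90, theta7_2 = 90)
  simulate_subject(anthro, kfs, noise_sd = 0, interval = 1, seed = 1)$frames[[1]]
}

# Independent oracle for the implied thigh elevation of the planar chain.
oracle_theta5 <- function(theta6, theta7) {
  alpha <- (90 - theta7) + 180 - theta6
  alpha <- ((alpha + 180) %% 360) - 180
  180 - abs(alpha)
}

# Independent re-implementation of the cosine-eased keyframe interpolation,
# used to derive analytic angle extremes at the sampled times.
oracle_eased_angles <- function(times, keyframes, id) {
  K <- vapply(keyframes, function(k) k$target_angles[[id]], numeric(1))
  durs <- vapply(keyframes, `[[`, numeric(1), "duration")
  starts <- cumsum(c(0, durs[-length(durs)]))
  vapply(times, function(t) {
    if (t >= starts[length(starts)]) return(K[length(K)])
    i <- findInterval(t, starts)
    p <- (t - starts[i]) / (starts[i + 1] - starts[i])
    e <- (1 - cos(p * pi)) / 2
    (1 - e) * K[i] + e * K[i + 1]
  }, numeric(1))
}

swap_left_right <- function(ids) {
  ifelse(grepl("_1$", ids), sub("_1$", "_2", ids),
         ifelse(grepl("_2$", ids), sub("_2$", "_1", ids), ids))
}

# Planted-informative-angle fixture: labels depend only on theta5_2.
planted_angle_data <- function(n = 250, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(n * 12, 60, 120), n, 12,
              dimnames = list(NULL, angle_ids()))
  labels <- cut(X[, "theta5_2"], breaks = c(-Inf, 80, 100, Inf),
                labels = c("pre", "mid", "up"))
  list(angles = as.data.frame(X), labels = labels)
}
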