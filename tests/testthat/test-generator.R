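test_that("subject draws honour the configured population model", {
  cfg <- cohort_config(seed = 5)
  err <- error_model()
  # determinism: same substream, same subject
  s1 <- sample_subject(cfg, err, 3)
  s2 <- sample_subject(cfg, err, 3)
  expect_identical(s1$ic_targets, s2$ic_targets)
  expect_identical(s1$seg$height, s2$seg$height)
  # zero between-subject variance: identical targets for everyone
  err0 <- error_model(sd_subject = 0)
  t1 <- sample_subject(cfg, err0, 1)$ic_targets
  t2 <- sample_subject(cfg, err0, 2)$ic_targets
  expect_equal(t1, t2)
  expect_equal(unname(t1["hip"]), 33.06)
  # segment lengths scale with stature
  tall <- segment_model(1.9); short <- segment_model(1.5)
  expect_gt(tall$thigh_length, short$thigh_length)
  expect_equal(tall$thigh_length / tall$height, 0.245)
})

test_that("Monte-Carlo hip target draws match the configured mean and SD", {
  cfg <- cohort_config(seed = 8)
  err <- error_model()
  draws <- vapply(1:4000, function(i) sample_subject(cfg, err, i)$ic_targets["hip"],
                  numeric(1))
  n <- length(draws)
  se_mean <- 5.7 / sqrt(n)
  expect_lt(abs(mean(draws) - 33.06), 3 * se_mean)
  se_sd <- 5.7 / sqrt(2 * (n - 1))
  expect_lt(abs(stats::sd(draws) - 5.7), 3 * se_sd)
})

test_that("forward kinematics round-trips through the angle extraction", {
  set.seed(14)
  for (i in 1:25) {
    tg <- c(hip = runif(1, 15, 45), knee = runif(1, -5, 20),
            ankle = runif(1, -20, 10))
    pr <- gait_profile(tg)
    seg <- segment_model(runif(1, 1.5, 1.9))
    t <- runif(1)
    pose <- pose_leg(pr, seg, t, x_offset = runif(1, -1, 1))
    fr <- frame_from_track(cbind(pose, frame = 0L, time_s = 0), 1)
    expect_equal(hip_angle(fr), pr$angle("hip", t), tolerance = 1e-6)
    expect_equal(knee_angle(fr), pr$angle("knee", t), tolerance = 1e-6)
    expect_equal(ankle_angle(fr), pr$angle("ankle", t), tolerance = 1e-6)
  }
  # profile passes exactly through its IC targets at phase 0
  pr <- gait_profile(c(hip = 33.06, knee = 4.55, ankle = -7.77))
  expect_equal(pr$angle("knee", 0), 4.55, tolerance = 1e-12)
  # markers stay at their fixed mediolateral depth
  pose <- pose_leg(pr, segment_model(1.7), seq(0, 0.99, by = 0.11))
  expect_equal(unique(pose$LFC_z), segment_model(1.7)$marker_z[["LFC"]])
  expect_error(pose_leg(gait_profile(c(hip = 80, knee = 5, ankle = 0)),
                        segment_model(1.7), 0), "guard")
})

test_that("camera projection follows the pinhole closed form", {
  cam_o <- camera_model(projection = "orthographic")
  p <- cbind(runif(5, -1, 1), runif(5, 0, 2), runif(5, 0, 0.1))
  uv <- project_markers(p, cam_o)
  expect_equal(uv[, "u"], p[, 1])
  expect_equal(uv[, "v"], p[, 2])
  cam_p <- camera_model()
  # point on the optical axis projects to the principal point
  expect_equal(unname(project_markers(c(0, 1.0, 0), cam_p)[1, ]), c(640, 360))
  # 0.5 m above camera height at 2.5 m: offset = focal * 0.5 / 2.5
  uv2 <- project_markers(c(0, 1.5, 0), cam_p)
  expect_equal(unname(uv2[1, "v"] - 360), 1000 * 0.5 / 2.5)
  expect_error(project_markers(c(0, 1, 3.0), cam_p), "behind the camera")
  # orthographic is the long-distance limit of perspective (up to scale)
  far <- camera_model(lateral_distance = 2.5e6, focal_length = 1e6 * 1000)
  uv_far <- project_markers(p, far)
  scale <- 1e6 * 1000 / 2.5e6
  expect_equal((uv_far[, "u"] - 640) / scale, p[, 1], tolerance = 1e-5)
})

test_that("synthetic ground reaction force encodes its own threshold crossing", {
  grf <- synth_grf(650, tc_time = 1.1, rate = 1000, sd_noise = 0)
  expect_identical(detect_ic_force(grf$signal), grf$true_crossing_sample)
  # force rises through the threshold (upward crossing)
  s <- grf$signal$samples
  i <- grf$true_crossing_sample + 1
  expect_lt(s[i - 1], 20); expect_gte(s[i], 20)
  # doubling the rate doubles the crossing index (+/- 1)
  grf2 <- synth_grf(650, tc_time = 1.1, rate = 2000, sd_noise = 0)
  expect_lte(abs(grf2$true_crossing_sample - 2 * grf$true_crossing_sample), 1)
  # peak force near body weight
  expect_gt(max(s), 650); expect_lt(max(s), 1.2 * 650)
})

test_that("trial simulation partitions variance as configured", {
  cfg <- cohort_config(seed = 9)
  cam <- camera_model(projection = "orthographic")
  # all-zero error model: observed angles equal ground truth
  subj <- sample_subject(cfg, error_model_zero(), 1)
  tr <- simulate_trial(subj, NULL, error_model_zero(), cam, seed = 4)
  obs <- tr$observers[[1]]
  fr <- frame_from_track(obs$track, obs$ic_frame + 1)
  a <- angles_at_ic(fr, warn_guard = FALSE)
  expect_equal(a$hip_deg, unname(tr$true_angles_ic["hip"]), tolerance = 1e-9)
  expect_equal(a$knee_deg, unname(tr$true_angles_ic["knee"]), tolerance = 1e-9)
  expect_equal(a$ankle_deg, unname(tr$true_angles_ic["ankle"]), tolerance = 1e-9)
  # session noise without observer noise: observers agree exactly within a
  # session but sessions disagree
  err_s <- error_model(sd_session = 0.005, sd_observer_frame = 0,
                       sd_digitize = 0, sd_residual = 0, sd_system = 0,
                       sd_system_subject = 0,
                       system_bias = c(hip = 0, knee = 0, ankle = 0))
  co <- simulate_cohort(cohort_config(n_subjects = 3, seed = 12), err_s, cam)
  v <- co[co$system == "video", ]
  o1 <- v[v$observer == 1, ]; o2 <- v[v$observer == 2, ]
  expect_equal(o1$angle_deg, o2$angle_deg, tolerance = 1e-12)
  s1 <- v[v$session == 1 & v$observer == 1 & v$repetition == 1, ]
  s2 <- v[v$session == 2 & v$observer == 1 & v$repetition == 1, ]
  expect_gt(max(abs(s1$angle_deg - s2$angle_deg)), 1e-3)
})

test_that("a one-frame selection error shifts angles along the gait curve", {
  cfg <- cohort_config(seed = 16)
  cam <- camera_model(projection = "orthographic")
  subj <- sample_subject(cfg, error_model_zero(), 2)
  tr <- simulate_trial(subj, NULL, error_model_zero(), cam, seed = 6)
  track <- tr$observers[[1]]$track
  i0 <- tr$true_ic_frame + 1
  a0 <- angles_at_ic(frame_from_track(track, i0), warn_guard = FALSE)
  a1 <- angles_at_ic(frame_from_track(track, i0 + 1), warn_guard = FALSE)
  dphase <- 1 / (cam$fps * subj$cadence_s)
  for (j in c("hip", "knee", "ankle")) {
    want <- subj$profile$angle(j, dphase) - subj$profile$angle(j, 0)
    got <- a1[[paste0(j, "_deg")]] - a0[[paste0(j, "_deg")]]
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("cohort tables have the full crossed design and are reproducible", {
  cfg <- tiny_cohort_config()
  co1 <- simulate_cohort(cfg, error_model(), camera_model())
  co2 <- simulate_cohort(cfg, error_model(), camera_model())
  expect_identical(co1$angle_deg, co2$angle_deg)
  expect_equal(nrow(co1), 8 * 2 * 5 * 2 * 2 * 3)
  expect_equal(sum(co1$joint == "knee"), 8 * 2 * 5 * 2 * 2)
  expect_named(co1, c("subject", "session", "observer", "system",
                      "repetition", "joint", "angle_deg"))
  # adding subjects leaves existing subjects' rows untouched
  co_big <- simulate_cohort(cohort_config(n_subjects = 9, seed = cfg$seed),
                            error_model(), camera_model())
  sub <- co_big[co_big$subject <= 8, ]
  rownames(sub) <- NULL
  expect_equal(sub$angle_deg, co1$angle_deg)
})

test_that("default calibration lands intra-rater ICC near 0.87 and inter-rater above 0.95", {
  intra <- matrix(NA_real_, 3, 3, dimnames = list(c("hip", "knee", "ankle"), NULL))
  inter <- intra
  for (s in 1:3) {
    co <- simulate_cohort(cohort_config(seed = 200 + s), error_model(),
                          camera_model())
    agg <- aggregate_repetitions(co)
    for (j in rownames(intra)) {
      m1 <- gaitagree:::.contrast_matrix(agg, j, "intra_rater", observer = 1)
      m2 <- gaitagree:::.contrast_matrix(agg, j, "inter_rater")
      intra[j, s] <- icc_single(m1)$estimate
      inter[j, s] <- icc_single(m2)$estimate
    }
  }
  expect_true(all(rowMeans(intra) > 0.82 & rowMeans(intra) < 0.93))
  expect_true(all(inter >= 0.95))
  # inter-rater exceeds intra-rater: observer noise < session noise
  expect_true(all(inter > intra))
})
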