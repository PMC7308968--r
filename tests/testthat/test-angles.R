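test_that("vertex angle tool reproduces analytic angles and rejects degenerate input", {
  expect_equal(angle_at_vertex(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(angle_at_vertex(c(1, 0), c(0, 0), c(-1, 0)), 180)
  expect_equal(angle_at_vertex(c(1, 0), c(0, 0), c(1, 1)), 45)
  expect_error(angle_at_vertex(c(0, 0), c(0, 0), c(1, 1)), "coincides")
})

test_that("signed angle is anterior-positive from a caudal reference and antisymmetric", {
  down <- c(0, -1)
  expect_equal(signed_angle_from(down, down), 0)
  rot <- function(v, deg) {
    a <- deg * pi / 180
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
  }
  expect_equal(signed_angle_from(down, rot(down, 30)), 30)
  expect_equal(signed_angle_from(down, rot(down, -30)), -30)
  for (d in c(5, 47.5, 120)) {
    expect_equal(signed_angle_from(down, rot(down, d)),
                 -signed_angle_from(down, rot(down, -d)))
  }
  expect_error(signed_angle_from(c(0, 0), down), "zero vector")
})

test_that("neutral poses read zero at every joint", {
  fr <- oracle_pose(0, 0, 0)
  expect_equal(hip_angle(fr), 0, tolerance = 1e-12)
  expect_equal(knee_angle(fr), 0, tolerance = 1e-12)
  expect_equal(ankle_angle(fr), 0, tolerance = 1e-12)
  a <- angles_at_ic(fr)
  expect_equal(unlist(a[c("hip_deg", "knee_deg", "ankle_deg")]),
               c(hip_deg = 0, knee_deg = 0, ankle_deg = 0), tolerance = 1e-12)
})

test_that("single-joint rotations are recovered with the documented signs", {
  # hip flexion positive; pelvis-only tilt shifts the hip reading by -tilt
  expect_equal(hip_angle(oracle_pose(30, 0, 0)), 30, tolerance = 1e-9)
  expect_equal(hip_angle(oracle_pose(0, 0, 0, tilt = 10)), 0, tolerance = 1e-9)
  fr_tilt <- oracle_pose(0, 0, 0)
  # tilting only the pelvis (thigh kept vertical): thigh is 10 deg posterior
  # of the tilted perpendicular
  pelvis_only <- oracle_pose(10, 0, 0, tilt = 10)  # thigh vertical in world
  expect_equal(hip_angle(pelvis_only) - hip_angle(fr_tilt), 10, tolerance = 1e-9)
  # knee: 180 - inner angle, flexion positive, hyperextension negative
  expect_equal(knee_angle(oracle_pose(0, 20, 0)), 20, tolerance = 1e-9)
  expect_equal(angle_at_vertex(.mk_test(oracle_pose(0, 20, 0), "GT"),
                               .mk_test(oracle_pose(0, 20, 0), "LFC"),
                               .mk_test(oracle_pose(0, 20, 0), "LM")),
               160, tolerance = 1e-9)
  expect_equal(knee_angle(oracle_pose(0, -5, 0)), -5, tolerance = 1e-9)
  # ankle: dorsiflexion positive, plantar flexion negative
  expect_equal(ankle_angle(oracle_pose(0, 0, 7.5)), 7.5, tolerance = 1e-9)
  expect_equal(ankle_angle(oracle_pose(0, 0, -10)), -10, tolerance = 1e-9)
})

test_that("angle constructions match the rotation-matrix oracle on random poses", {
  set.seed(42)
  for (i in 1:200) {
    hip <- runif(1, -20, 45); knee <- runif(1, -10, 60)
    ankle <- runif(1, -30, 25); tilt <- runif(1, -15, 25)
    fr <- oracle_pose(hip, knee, ankle, tilt,
                      gt = runif(2, -2, 2),
                      scale = runif(1, 0.3, 400),
                      rotate = runif(1, -40, 40),
                      translate = runif(2, -500, 500))
    expect_equal(hip_angle(fr), hip, tolerance = 1e-6)
    expect_equal(knee_angle(fr), knee, tolerance = 1e-6)
    expect_equal(ankle_angle(fr), ankle, tolerance = 1e-6)
  }
})

test_that("angles are invariant to similarity transforms and pixel units", {
  base <- oracle_pose(33, 4.5, -8, tilt = 8)
  px <- oracle_pose(33, 4.5, -8, tilt = 8, scale = 400, translate = c(640, 360))
  expect_equal(hip_angle(px), hip_angle(base), tolerance = 1e-9)
  expect_equal(knee_angle(px), knee_angle(base), tolerance = 1e-9)
  expect_equal(ankle_angle(px), ankle_angle(base), tolerance = 1e-9)
})

test_that("frames are mirrored so progression is +x before signed angles", {
  fr <- oracle_pose(25, 10, -5)
  mirrored <- lapply(fr$markers, function(p) c(-p[1], p[2]))
  fr2 <- do.call(marker_frame, mirrored)
  expect_equal(hip_angle(fr2), hip_angle(fr), tolerance = 1e-9)
  expect_equal(knee_angle(fr2), knee_angle(fr), tolerance = 1e-9)
  expect_equal(ankle_angle(fr2), ankle_angle(fr), tolerance = 1e-9)
})

test_that("degenerate marker configurations raise errors", {
  fr <- oracle_pose(10, 10, 0)
  fr$markers$PSIS <- fr$markers$ASIS
  expect_error(hip_angle(fr), "coincide")
  fr2 <- oracle_pose(10, 10, 0)
  fr2$markers$MT2 <- fr2$markers$CAL
  expect_error(ankle_angle(fr2), "coincide")
  expect_error(marker_frame(ASIS = c(0, 0)), "missing markers")
})
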