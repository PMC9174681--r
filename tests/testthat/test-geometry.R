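test_that("pose rotation honours the reference pose and half-turn", {
  expect_equal(pose_rotation(0, 0), diag(3))
  d180 <- pose_rotation(180, 0) %*% c(1, 0, 0)
  expect_equal(as.numeric(d180), c(-1, 0, 0))
  d90 <- pose_rotation(90, 0) %*% c(1, 0, 0)
  expect_equal(as.numeric(d90), c(0, -1, 0))    # ventral at 90 deg extension
  dab <- pose_rotation(0, 90) %*% c(1, 0, 0)
  expect_equal(as.numeric(dab), c(0, 0, 1))     # lateral at 90 deg abduction
  expect_error(pose_rotation(190, 0), "extension")
  expect_error(pose_rotation(10, -5), "abduction")
})

test_that("posing the femur is a rigid rotation about the joint centre", {
  m <- generate_hip_model(seed = 1)
  p0 <- pose_femur(m, 0, 0)
  expect_equal(p0$insertion, m$insertion)
  for (pose in list(c(40, 0), c(90, 30), c(170, 60))) {
    p <- pose_femur(m, pose[1], pose[2])
    expect_equal(sqrt(sum((p$insertion - p$cor)^2)),
                 sqrt(sum((m$insertion - m$cor)^2)), tolerance = 1e-12)
    expect_equal(sqrt(sum((p$insertion - p$femur_axis_point)^2)),
                 sqrt(sum((m$insertion - m$femur_axis_point)^2)),
                 tolerance = 1e-12)
    expect_equal(p$origin, m$origin)            # pelvis side untouched
  }
})

test_that("moment arm is the point-to-infinite-line distance", {
  r <- compute_imma(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(r$imma_cm, 1)
  expect_equal(r$foot_point, c(0, 1, 0))
  expect_true(r$on_segment)
  ## centre on the line: zero arm, not an error
  expect_equal(compute_imma(c(0.5, 1, 0), c(0, 1, 0), c(1, 1, 0))$imma_cm, 0)
  ## projection beyond the attachments is allowed and flagged
  r2 <- compute_imma(c(0, 0, 0), c(5, 1, 0), c(0.2, 1, 0))
  expect_equal(r2$imma_cm, 1)
  expect_false(r2$on_segment)
  expect_error(compute_imma(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("moment arm equals the in-lever exactly at perpendicularity", {
  ## insertion 1 cm above the centre, line of action horizontal: the
  ## in-lever is perpendicular to the line, so IMMA = in-lever
  r <- compute_imma(c(0, 0, 0), c(5, 1, 0), c(0, 1, 0))
  il <- sqrt(sum(c(0, 1, 0)^2))
  expect_equal(r$imma_cm, il)
})

test_that("moment arm matches |IL| sin(angle) on randomized configurations", {
  set.seed(101)
  for (i in 1:200) {
    cor <- rnorm(3); ins <- rnorm(3); ori <- rnorm(3)
    if (sum((ins - ori)^2) < 1e-6 || sum((ins - cor)^2) < 1e-6) next
    il_vec <- ins - cor
    u <- (ins - ori) / sqrt(sum((ins - ori)^2))
    ang <- acos(pmin(1, pmax(-1, sum(il_vec * u) / sqrt(sum(il_vec^2)))))
    oracle <- sqrt(sum(il_vec^2)) * sin(ang)
    got <- compute_imma(cor, ori, ins)$imma_cm
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_lte(got, sqrt(sum(il_vec^2)) * (1 + 1e-9))
  }
})

test_that("moment arm and in-lever are rigid-motion invariant and homogeneous", {
  set.seed(102)
  for (i in 1:25) {
    cor <- rnorm(3); ins <- rnorm(3) + c(2, 0, 0); ori <- rnorm(3) + c(0, 3, 0)
    base <- compute_imma(cor, ori, ins)$imma_cm
    R <- random_rotation(); tr <- rnorm(3)
    moved <- compute_imma(as.numeric(R %*% cor + tr),
                          as.numeric(R %*% ori + tr),
                          as.numeric(R %*% ins + tr))$imma_cm
    expect_equal(moved, base, tolerance = 1e-9)
    s <- runif(1, 0.1, 10)
    expect_equal(compute_imma(s * cor, s * ori, s * ins)$imma_cm, s * base,
                 tolerance = 1e-9)
  }
})

test_that("in-lever is the insertion-centre distance and scales linearly", {
  m <- hip_model("t", origin = c(2, 1, 0), insertion = c(0, 1, 0),
                 cor = c(0, 0, 0), femur_axis_point = c(5, 0, 0),
                 femoral_diameter = 0.4)
  expect_equal(compute_in_lever(m), 1)
  m2 <- hip_model("t", origin = c(6, 3, 0), insertion = c(0, 3, 0),
                  cor = c(0, 0, 0), femur_axis_point = c(15, 0, 0),
                  femoral_diameter = 1.2)
  expect_equal(compute_in_lever(m2), 3)
  expect_error(hip_model("t", origin = c(2, 1, 0), insertion = c(0, 0, 0),
                         cor = c(0, 0, 0), femur_axis_point = c(5, 0, 0),
                         femoral_diameter = 0.4), "insertion")
})

test_that("pose grid is the inclusive cartesian product in protocol order", {
  g <- generate_pose_grid()
  expect_equal(nrow(g), 57)
  expect_equal(unique(g$abduction_deg), c(0, 30, 60))
  expect_equal(g$extension_deg[1:19], seq(0, 180, 10))
  g2 <- generate_pose_grid(0, 180, 90, 0)
  expect_equal(g2$extension_deg, c(0, 90, 180))
  expect_error(generate_pose_grid(ext_step = -10), "positive")
  expect_error(generate_pose_grid(abductions = numeric(0)), "nonempty")
})

test_that("metric scaling averages the measurement ratios", {
  expect_equal(scale_to_metric(c(2, 3), c(2, 3)), 1)
  expect_equal(scale_to_metric(c(1.0, 1.034), c(1, 1)), 1.017)
  expect_error(scale_to_metric(1, 0), "positive")
  expect_error(scale_to_metric(numeric(0), numeric(0)), "at least one")
})

test_that("normalization divides by the femoral diameter and keeps flags", {
  m <- generate_hip_model(seed = 3)
  p <- profile_imma(m, generate_pose_grid(0, 60, 20, 30))
  np <- normalize_profile(p, 0.5)
  expect_equal(np$poses$imma_cm, p$poses$imma_cm / 0.5)
  expect_equal(np$in_lever_cm, p$in_lever_cm / 0.5)
  expect_equal(np$poses$feasible, p$poses$feasible)
  expect_equal(normalize_profile(p, 1)$poses$imma_cm, p$poses$imma_cm)
  expect_error(normalize_profile(p, 0), "positive")
})

test_that("profiles are bounded by the in-lever and single-peaked by default", {
  m <- generate_hip_model(geometry_params(landmark_sd = 0))
  grid <- generate_pose_grid()
  p <- profile_imma(m, grid)
  expect_true(all(p$poses$imma_cm <= p$in_lever_cm * (1 + 1e-9)))
  for (b in c(0, 30, 60)) {
    dense <- generate_pose_grid(0, 180, 1, b)
    v <- profile_imma(m, dense)$poses$imma_cm
    flips <- sum(diff(sign(diff(v))) != 0)
    expect_lte(flips, 1)                       # one interior peak at most
    coarse <- p$poses$imma_cm[p$poses$abduction_deg == b]
    expect_gte(max(v), max(coarse))            # dense sweep bounds the grid max
  }
})

test_that("profiles are invariant under mirroring through the sagittal plane", {
  m <- generate_hip_model(seed = 8)
  flip <- function(v) v * c(1, 1, -1)
  m2 <- hip_model(m$species, flip(m$origin), flip(m$insertion), flip(m$cor),
                  flip(m$femur_axis_point), m$femoral_diameter)
  g <- generate_pose_grid(0, 180, 10, 0)       # extension is in-plane at 0 abduction
  expect_equal(profile_imma(m2, g)$poses$imma_cm,
               profile_imma(m, g)$poses$imma_cm, tolerance = 1e-12)
})

test_that("collision checking needs meshes and flags close poses", {
  m <- generate_hip_model(seed = 4)
  expect_error(profile_imma(m, generate_pose_grid(), collision_min_sep = 0),
               "mesh")
  mm <- generate_hip_model(include_meshes = TRUE, seed = 4)
  g <- generate_pose_grid(0, 180, 30, 30)
  p_all <- profile_imma(mm, g, collision_min_sep = 1e9)
  expect_false(any(p_all$poses$feasible))      # impossible separation demand
  p0 <- profile_imma(mm, g, collision_min_sep = 0)
  expect_true(all(p0$poses$feasible))
})
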