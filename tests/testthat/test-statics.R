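test_that("trunk flexion splits 40% sacral / 60% distributed lumbar", {
  m <- make_stick_model()
  p0 <- flexion_posture(m, 0)
  expect_true(all(p0$flexion_deg == 0) && p0$sacral_tilt_deg == 0)
  p <- flexion_posture(m, 30)
  expect_equal(p$sacral_tilt_deg, 12)
  expect_equal(sum(p$flexion_deg), 18)
  expect_equal(unname(p$flexion_deg[["L1/L2"]]), 18 * 0.255)
  expect_equal(unname(p$flexion_deg[["L1/L2"]]), 4.59)
  expect_equal(unname(p$flexion_deg[["L5/S1"]]), 18 * 0.125)
  expect_equal(unname(p$flexion_deg[["T12/L1"]]), 0)
  expect_warning(flexion_posture(m, 60), "outside")
})

test_that("net joint moments reproduce the m*g*d closed form", {
  # 10 kg thorax point mass 0.2 m anterior of every joint, no passives
  m <- make_stick_model(masses = c(thorax = 10),
                        thorax_com = c(200, 200, 0))
  M <- net_joint_moments(m, posture(m))
  # anterior mass flexes the trunk; muscles must supply extension, which
  # is positive about the lateral axis
  expect_equal(unname(M[, "M_z"]), rep(10 * 9.81 * 0.2, 6),
               tolerance = 1e-9)
  expect_equal(unname(M[, "M_x"]), rep(0, 6), tolerance = 1e-12)
  # mass straight above the joints: fully balanced
  m2 <- make_stick_model(masses = c(thorax = 10),
                         thorax_com = c(0, 200, 0))
  expect_equal(max(abs(net_joint_moments(m2, posture(m2)))), 0,
               tolerance = 1e-12)
})

test_that("gravity and external load moments superpose", {
  m <- make_stick_model(masses = c(thorax = 10),
                        thorax_com = c(50, 200, 0))
  case <- load_case("hold", hand_mass_kg = 5, load_offset_mm = 100,
                    reference = "chest")
  m$points$chest <- list(body = "thorax", point = c(100, 190, 0))
  m$points$sacrum_sup <- list(body = "sacrum", point = c(0, 0, 0))
  ml <- apply_load_case(m, case)
  M_both <- net_joint_moments(ml, posture(ml))
  m_only_load <- make_stick_model(masses = c(thorax = 0))
  m_only_load$points <- m$points
  M_load <- net_joint_moments(apply_load_case(m_only_load, case),
                              posture(m_only_load))
  M_grav <- net_joint_moments(m, posture(m))
  expect_equal(M_both, M_grav + M_load, tolerance = 1e-9)
  # external force magnitude is m*g at the offset point
  expect_equal(ml$external[[1]]$force_n, c(0, -5 * 9.81, 0))
  expect_equal(ml$external[[1]]$point, c(200, 190, 0))
})

test_that("moment at L5/S1 grows monotonically with the load offset", {
  m <- make_stick_model()
  m$points$chest <- list(body = "thorax", point = c(100, 190, 0))
  mz <- vapply(c(100, 300, 500), function(off) {
    ml <- apply_load_case(m, load_case("x", hand_mass_kg = 10,
                                       load_offset_mm = off))
    abs(net_joint_moments(ml, posture(ml))["L5/S1", "M_z"])
  }, numeric(1))
  expect_true(all(diff(mz) > 0))
  expect_error(apply_load_case(m, load_case("x", hand_mass_kg = 1,
                                            reference = "nowhere")),
               "unknown load-case reference")
  # zero hand mass leaves the model unchanged
  m0 <- apply_load_case(m, load_case("none"))
  expect_length(m0$external, 0)
})

test_that("a ligament acting through the joint origin adds no moment", {
  m <- make_stick_model(masses = c(thorax = 10),
                        thorax_com = c(50, 200, 0))
  M0 <- net_joint_moments(m, posture(m))
  lig <- derive_ligament_params("ALL", "L3/L4", c(0, 150, 0), c(0, 60, 0),
                                1, 0.1, 0.2, 0.4, 100, 300)
  lig$body_a <- "L2"; lig$body_b <- "L5"
  m$ligaments <- list(`ALL L3/L4` = lig)
  M1 <- net_joint_moments(m, posture(m))
  # line of action passes through the L3/L4 origin (0, 90, 0)
  expect_equal(M1["L3/L4", ], M0["L3/L4", ], tolerance = 1e-9)
  # but it is taut (pre-strained), so it loads the joint in compression
  r0 <- joint_reactions(m, posture(m))
  expect_gt(r0$compression_n[r0$joint == "L3/L4"], 10 * 9.81 + 1)
})

test_that("symmetric model and load give zero frontal moment everywhere", {
  m <- fx_model("lordotic")$model
  M <- net_joint_moments(m, fx_neutral("lordotic"))
  expect_lt(max(abs(M[, "M_x"])), 0.5)
  ml <- apply_load_case(m, load_case("x", hand_mass_kg = 20,
                                     load_offset_mm = 200))
  Ml <- net_joint_moments(ml, fx_neutral("lordotic"))
  expect_lt(max(abs(Ml[, "M_x"])), 0.5)
})

test_that("frame equivariance: rigidly rotated gravity leaves joint-frame moments unchanged", {
  # rotating the whole model about the vertical axis is a symmetry of
  # gravity, so joint-frame moments must be identical
  m <- fx_model("lordotic")$model
  Rz <- spineload:::rot_axis(c(0, 1, 0), 37)
  T <- spineload:::rigid_transform(Rz, c(0, 0, 0))
  m2 <- m
  for (bn in names(m2$bodies))
    m2$bodies[[bn]]$com <- as.numeric(Rz %*% m2$bodies[[bn]]$com)
  for (jn in names(m2$joints)) {
    m2$joints[[jn]]$origin <- as.numeric(Rz %*% m2$joints[[jn]]$origin)
    m2$joints[[jn]]$R <- Rz %*% m2$joints[[jn]]$R
  }
  for (ln in names(m2$ligaments)) {
    m2$ligaments[[ln]]$attach_a <- as.numeric(Rz %*% m2$ligaments[[ln]]$attach_a)
    m2$ligaments[[ln]]$attach_b <- as.numeric(Rz %*% m2$ligaments[[ln]]$attach_b)
  }
  p <- posture(m, flexion_deg = c("L3/L4" = 7))
  expect_equal(net_joint_moments(m2, p), net_joint_moments(m, p),
               tolerance = 1e-6)
})

test_that("neutral posture optimization balances and is deterministic", {
  # already-balanced stick model stays at zero
  m <- make_stick_model(masses = c(thorax = 20),
                        thorax_com = c(0, 200, 0))
  p <- neutral_posture(m)
  expect_equal(max(abs(p$flexion_deg)), 0, tolerance = 1e-6)
  expect_equal(attr(p, "objective"), 0, tolerance = 1e-9)
  # anteriorly shifted mass: optimizer strictly improves on zero posture
  m2 <- make_stick_model(masses = c(thorax = 20),
                         thorax_com = c(20, 200, 0), disc_stiffness = 1)
  obj0 <- sum(net_joint_moments(m2, posture(m2))[, "M_z"]^2)
  p2 <- neutral_posture(m2)
  expect_lt(attr(p2, "objective"), obj0)
  expect_gt(max(abs(p2$flexion_deg)), 1e-3)
  # determinism
  p3 <- neutral_posture(m2)
  expect_identical(p2$flexion_deg, p3$flexion_deg)
})

test_that("flexion raises the sagittal moment magnitude at L5/S1", {
  m <- fx_model("lordotic")$model
  np <- fx_neutral("lordotic")
  mz <- vapply(c(0, 10, 20, 30), function(f) {
    pose <- posture_add(np, flexion_posture(m, f))
    abs(net_joint_moments(m, pose)["L5/S1", "M_z"])
  }, numeric(1))
  expect_true(all(diff(mz) > 0))
})
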