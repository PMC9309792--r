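test_that("moment arm follows the r x u geometry", {
  # vertical fascicle passing 50 mm posterior of the joint
  ma <- moment_arm(c(-50, 100, 0), c(-50, 0, 0), c(0, 80, 0))
  expect_equal(ma, c(0, 0, 0.05), tolerance = 1e-12)
  # through the joint origin: zero arm
  expect_equal(moment_arm(c(0, 100, 0), c(0, 0, 0), c(0, 50, 0)),
               c(0, 0, 0), tolerance = 1e-12)
  # mirrored fascicle negates the frontal (about-anterior) component
  a <- moment_arm(c(0, 100, 30), c(0, 0, 30), c(0, 50, 0))
  b <- moment_arm(c(0, 100, -30), c(0, 0, -30), c(0, 50, 0))
  expect_equal(a[1], -b[1], tolerance = 1e-12)
})

test_that("solver recovers the toy closed forms within tight tolerance", {
  s1 <- solve_static(make_toy_problem("single_muscle"), tol = 0.005)
  expect_equal(unname(s1$forces), 200, tolerance = 0.005 * 200 / 100)
  expect_lt(abs(unname(s1$forces) - 200) / 200, 0.005)
  s2 <- solve_static(make_toy_problem("antagonist_pair"), tol = 0.005)
  expect_equal(unname(s2$forces), c(200, 0), tolerance = 1)
  s3 <- solve_static(make_toy_problem("two_agonists"), tol = 0.005)
  expect_equal(unname(s3$forces[2] / s3$forces[1]), 2^1.5,
               tolerance = 0.01 * 2^1.5)
})

test_that("solver matches a dense grid oracle on every toy problem", {
  for (nm in c("single_muscle", "antagonist_pair", "two_agonists")) {
    prob <- make_toy_problem(nm)
    sol <- solve_static(prob, tol = 0.005)
    A <- prob$moment_arms; P <- prob$pcsa
    ub <- prob$sigma_max_mpa * 100 * P
    if (ncol(A) == 1) {
      grid_cost <- (prob$target / A[1, 1] / P)^3
    } else {
      f1 <- seq(0, ub[1], by = 1)
      f2 <- (prob$target - A[1, 1] * f1) / A[1, 2]
      ok <- f2 >= 0 & f2 <= ub[2]
      grid_cost <- min((f1[ok] / P[1])^3 + (f2[ok] / P[2])^3)
    }
    expect_lt(abs(sol$cost - grid_cost) / grid_cost, 1e-3,
              label = paste(nm, "cost vs grid"))
  }
})

test_that("bounds are respected exactly and infeasibility is reported", {
  prob <- make_toy_problem("single_muscle")
  prob$target <- 1000            # needs 20 kN; bound is 600 N
  err <- tryCatch(solve_static(prob), spineload_infeasible = identity)
  expect_s3_class(err, "spineload_infeasible")
  expect_match(conditionMessage(err), "c1")
  sol <- solve_static(make_toy_problem("antagonist_pair"))
  ub <- 0.6 * 100 * make_toy_problem("antagonist_pair")$pcsa
  expect_true(all(sol$forces >= 0 & sol$forces <= ub + 1e-9))
})

test_that("deterministic multi-start agrees with the single start", {
  for (nm in c("two_agonists", "antagonist_pair")) {
    prob <- make_toy_problem(nm)
    s1 <- solve_static(prob, tol = 0.005, n_starts = 1)
    s10 <- solve_static(prob, tol = 0.005, n_starts = 10, seed = 7L)
    expect_equal(s10$cost, s1$cost, tolerance = 1e-3)
  }
})

test_that("relaxing the stress bound keeps an already-feasible optimum", {
  fm <- fx_model("lordotic")$model
  np <- fx_neutral("lordotic")
  prob06 <- build_problem(fm, np, sigma_max_mpa = 0.6)
  prob10 <- build_problem(fm, np, sigma_max_mpa = 1.0)
  s06 <- solve_static(prob06, tol = 0.05)
  s10 <- solve_static(prob10, tol = 0.05)
  expect_equal(s10$cost, s06$cost, tolerance = 0.01 * max(s06$cost, 1))
})

test_that("joint reactions decompose weight along the joint axes", {
  # 60 kg thorax straight above vertical joints: pure compression
  m <- make_stick_model(masses = c(thorax = 60),
                        thorax_com = c(0, 200, 0))
  r <- joint_reactions(m, posture(m))
  expect_equal(r$compression_n, rep(60 * 9.81, 6), tolerance = 1e-9)
  expect_equal(r$ap_shear_n, rep(0, 6), tolerance = 1e-12)
  expect_equal(r$lateral_shear_n, rep(0, 6), tolerance = 1e-12)
  # a vertical muscle pair adds pure compression below its span
  m$muscles <- data.frame(
    group = c("LL", "LL"), side = c("left", "right"),
    origin_name = "o", origin_body = "thorax",
    ox = c(-30, -30), oy = 200, oz = c(30, -30),
    insertion_name = "i", insertion_body = "sacrum",
    ix = c(-30, -30), iy = 0, iz = c(30, -30), pcsa_cm2 = 10)
  r2 <- joint_reactions(m, posture(m), forces = c(100, 100))
  expect_equal(r2$compression_n, rep(60 * 9.81 + 200, 6), tolerance = 1e-9)
  expect_equal(r2$ap_shear_n, rep(0, 6), tolerance = 1e-12)
  expect_equal(r2$lateral_shear_n, rep(0, 6), tolerance = 1e-12)
})

test_that("compression normalization is anchored at standing", {
  r <- list(standing = data.frame(joint = c("A", "B"),
                                  compression_n = c(100, 200),
                                  ap_shear_n = 0, lateral_shear_n = 0),
            flexed = data.frame(joint = c("A", "B"),
                                compression_n = c(150, 500),
                                ap_shear_n = 0, lateral_shear_n = 0))
  nz <- normalize_to_standing(r)
  expect_equal(nz$standing, c(1, 1))
  expect_equal(nz$flexed, c(1.5, 2.5))
  # doubling all loads leaves normalized values unchanged
  r2 <- lapply(r, function(x) { x$compression_n <- 2 * x$compression_n; x })
  expect_equal(normalize_to_standing(r2)$flexed, nz$flexed)
  r$standing$compression_n[1] <- 0
  expect_error(normalize_to_standing(r), "zero standing compression")
  expect_error(normalize_to_standing(list(flexed = r$flexed)),
               "standing")
})

test_that("ligament utilization is F/F_B with the documented anchors", {
  m <- fx_model("lordotic")$model
  np <- fx_neutral("lordotic")
  u <- ligament_utilization(m, np)
  expect_true(all(u$utilization >= 0))
  lig <- m$ligaments[[1]]
  expect_equal(ligament_force(lig, lig$l_B) / lig$F_B, 1, tolerance = 1e-9)
  expect_equal(ligament_force(lig, lig$l_0) / lig$F_B, 0)
  # posterior ligament utilization grows with flexion on the fixture
  isl <- function(pose) {
    uu <- ligament_utilization(m, pose)
    mean(uu$utilization[uu$ligament == "ISL"])
  }
  vals <- vapply(c(0, 10, 20, 30), function(f)
    isl(posture_add(np, flexion_posture(m, f))), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("solved battery balances moments and respects symmetry", {
  r <- fx_battery("lordotic")
  # moment-balance residual below tolerance on every solved case
  for (nm in names(r$solutions))
    expect_lt(max(abs(r$solutions[[nm]]$residuals)), 0.1, label = nm)
  # mirror symmetry: lateral shear vanishes in upright standing
  expect_lt(max(abs(r$reactions$standing$lateral_shear_n)), 2)
  # normalized standing compression is identically 1
  expect_equal(r$normalized$standing, rep(1, 6))
  # flexed and loaded cases raise L4/L5 compression above standing
  for (nm in setdiff(names(r$reactions), "standing"))
    expect_gte(r$normalized[[nm]][r$normalized$joint == "L4/L5"], 1)
})
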