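ref_lig <- function(eps_pre = 0.05, n = 1) {
  derive_ligament_params("ISL", "L4/L5", c(0, 10, 0), c(0, 0, 0), n,
                         eps_pre, eps_A = 0.1, eps_B = 0.3,
                         F_A = 100, F_B = 400)
}

test_that("derived ligament parameters match the hand-computed chain", {
  lig <- ref_lig()
  expect_equal(lig$l_neut, 10)
  expect_equal(lig$l_0, 9.5)
  expect_equal(lig$l_A, 10.45)
  expect_equal(lig$l_B, 12.35)
  expect_equal(lig$K_lin, 300 / 1.9, tolerance = 1e-12)
  expect_equal(lig$eps_lin, 100 / (300 / 1.9 * 9.5), tolerance = 1e-12)
  expect_equal(lig$exp_nll, 1.5, tolerance = 1e-12)
  expect_equal(lig$K_nl, 100 / 0.95^1.5, tolerance = 1e-9)
  expect_equal(ligament_force(lig, 10), 100 / 0.95^1.5 * 0.5^1.5,
               tolerance = 1e-9)
  expect_equal(ligament_force(lig, 10), 38.18, tolerance = 0.01)
})

test_that("force law boundaries and validation behave as specified", {
  lig <- ref_lig()
  expect_equal(ligament_force(lig, lig$l_0), 0)
  expect_equal(ligament_force(lig, lig$l_0 - 1), 0)
  expect_equal(ligament_force(lig, lig$l_A), lig$F_A, tolerance = 1e-9)
  expect_equal(ligament_force(lig, lig$l_B), lig$F_B, tolerance = 1e-9)
  expect_error(ligament_force(lig, -1), "non-negative")
  expect_error(derive_ligament_params("X", "j", c(0, 1, 0), c(0, 0, 0), 1,
                                      0, 0.3, 0.1, 10, 20), "eps_A < eps_B")
  expect_error(derive_ligament_params("X", "j", c(0, 1, 0), c(0, 0, 0), 1,
                                      0, 0.1, 0.3, 20, 10), "F_A < F_B")
  expect_error(derive_ligament_params("X", "j", c(0, 0, 0), c(0, 0, 0), 1,
                                      0, 0.1, 0.3, 10, 20), "coincident")
  # n parallel components split the per-component force but not the total
  lig2 <- ref_lig(n = 4)
  expect_equal(ligament_force(lig2, lig2$l_A), 100, tolerance = 1e-9)
})

test_that("pre-strain controls the neutral-length force", {
  l0 <- ref_lig(eps_pre = 0)
  expect_equal(l0$l_0, l0$l_neut)
  expect_equal(ligament_force(l0, l0$l_neut), 0)
  lp <- ref_lig(eps_pre = 0.05)
  expect_gt(ligament_force(lp, lp$l_neut), 0)
  ln <- ref_lig(eps_pre = -0.10)     # slack in neutral posture (SSL-like)
  expect_equal(ligament_force(ln, ln$l_neut), 0)
})

test_that("force law is C0/C1-continuous and monotone for random draws", {
  set.seed(42)
  h <- 1e-6
  for (i in 1:1000) {
    eps_A <- runif(1, 0.02, 0.3)
    eps_B <- eps_A + runif(1, 0.05, 0.4)
    F_A <- runif(1, 10, 300)
    # valid sets have a toe secant no stiffer than the linear region
    F_B <- F_A * eps_B / eps_A * runif(1, 1, 2.5)
    lig <- derive_ligament_params(
      "X", "j", c(0, runif(1, 5, 60), 0), c(0, 0, 0),
      n = sample(1:4, 1), eps_pre = runif(1, -0.15, min(0.2, eps_A - 0.01)),
      eps_A = eps_A, eps_B = eps_B, F_A = F_A, F_B = F_B)
    # C0: both branches agree exactly at the transition
    expect_lt(abs(lig$K_nl * (lig$l_A - lig$l_0)^lig$exp_nll * lig$n -
                    lig$F_A), 1e-6 * lig$F_A)
    # C1: one-sided numeric derivatives match
    d_toe <- (ligament_force(lig, lig$l_A) -
                ligament_force(lig, lig$l_A - h)) / h
    d_lin <- (ligament_force(lig, lig$l_A + h) -
                ligament_force(lig, lig$l_A)) / h
    expect_lt(abs(d_toe - d_lin) / d_lin, 1e-3)
    # monotone non-decreasing, zero below slack
    ls <- seq(0.8 * lig$l_0, 1.1 * lig$l_B, length.out = 40)
    fs <- ligament_force(lig, ls)
    expect_true(all(diff(fs) >= -1e-9))
    expect_true(all(fs[ls <= lig$l_0] == 0))
    expect_gte(lig$exp_nll, 1)
  }
  # the convexity guard rejects a toe stiffer than the linear region
  expect_error(derive_ligament_params("X", "j", c(0, 10, 0), c(0, 0, 0), 1,
                                      0, 0.1, 0.3, 100, 120),
               "toe-region secant")
})

test_that("default parameter file ships the five documented systems", {
  lp <- default_ligament_params()
  expect_setequal(names(lp), c("ALL", "PLL", "LF", "ISL", "SSL"))
  expect_equal(lp$LF$eps_pre, 0.05)
  expect_lt(lp$SSL$eps_pre, 0)
})

test_that("disc moments are zero in the neutral zone and odd beyond it", {
  d <- disc_element("L4/L5", c(frontal = 2, axial = 1, sagittal = 2),
                    c(frontal = 1, axial = 1, sagittal = 1))
  expect_equal(unname(disc_moment(d, c(frontal = 1, axial = 0,
                                       sagittal = -1.5))), c(0, 0, 0))
  m <- disc_moment(d, c(frontal = 0, axial = 0, sagittal = 5))
  expect_equal(unname(m[["sagittal"]]), -3)
  m2 <- disc_moment(d, c(frontal = 0, axial = 0, sagittal = -5))
  expect_equal(m2[["sagittal"]], -m[["sagittal"]])
})
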