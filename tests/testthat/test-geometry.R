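test_that("craniocaudal realignment maps the T1-L5 line onto vertical", {
  cen <- rbind(T1 = c(0, 400, 0), L5 = c(0, 0, 0))
  expect_equal(realign_craniocaudal(cen), diag(4), tolerance = 1e-12)

  cen <- rbind(T1 = c(50, 400, 0), L5 = c(0, 0, 0))
  tr <- realign_craniocaudal(cen)
  t1 <- spineload:::apply_transform(tr, cen["T1", ])
  l5 <- spineload:::apply_transform(tr, cen["L5", ])
  expect_equal(t1[c(1, 3)], l5[c(1, 3)], tolerance = 1e-9)
  expect_gt(t1[2], l5[2])
  # rigid: rotation orthonormal with unit determinant
  R <- tr[1:3, 1:3]
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  # idempotent on aligned input
  tr2 <- realign_craniocaudal(rbind(T1 = t1, L5 = l5))
  expect_equal(tr2[1:3, 1:3], diag(3), tolerance = 1e-9)
  expect_error(realign_craniocaudal(rbind(T1 = c(0, 1, 0))), "L5")
})

test_that("extreme-value landmarks recover the fixture's analytic shape", {
  g <- fx_geometry("straight")
  lay <- fx_spine("straight")$layout
  l3 <- g$geometries$L3
  vs <- 2
  # spinous process posterior tip: x = -(a_x + 36) from the body centre
  expect_equal(l3$landmarks$spinous_posterior[1],
               l3$body_centroid[1] - (lay$a_x + 36), tolerance = 1.5 * vs)
  # most lateral body points at the ellipse's lateral radius
  expect_equal(abs(l3$landmarks$body_left_lateral[3] - l3$body_centroid[3]),
               lay$a_z, tolerance = 1.5 * vs)
  expect_equal(abs(l3$landmarks$body_right_lateral[3] - l3$body_centroid[3]),
               lay$a_z, tolerance = 1.5 * vs)
  # left/right landmark pairs mirror about the sagittal midplane
  for (pair in list(c("transverse_left_lateral", "transverse_right_lateral"),
                    c("body_left_lateral", "body_right_lateral"))) {
    a <- l3$landmarks[[pair[1]]]; b <- l3$landmarks[[pair[2]]]
    expect_equal(a[1], b[1], tolerance = vs)
    expect_equal(a[2], b[2], tolerance = vs)
    expect_equal(a[3], -b[3], tolerance = vs)
  }
  # all landmarks inside the instance bounding box dilated by one voxel
  pts <- label_points(fx_spine("straight")$instances, 15)  # L3 label
  lo <- apply(pts, 2, min) - vs; hi <- apply(pts, 2, max) + vs
  for (lm in l3$landmarks)
    expect_true(all(lm >= lo - 1e-9 & lm <= hi + 1e-9))
})

test_that("missing subregions raise named landmark errors", {
  s <- fx_spine("straight")
  sub2 <- s$subregions
  sub2$voxels[s$instances$voxels == 15 & sub2$voxels == 3L] <- 0L
  expect_error(extract_landmarks(sub2, s$instances, "L3"),
               "spinous_process.*L3")
  expect_error(extract_landmarks(s$subregions, s$instances, "C7"),
               "unknown|not present")
})

test_that("joint centre is the endplate midpoint of adjacent levels only", {
  g <- fx_geometry("lordotic")$geometries
  jc <- joint_center(g$L5, g$L4)
  expect_equal(jc, (g$L5$endplate_superior_center +
                      g$L4$endplate_inferior_center) / 2)
  expect_error(joint_center(g$L5, g$L3), "adjacent")
  # symmetric fixture: joint centre on the sagittal midplane
  expect_lt(abs(jc[3]), 1)
})

test_that("joint orientation is a proper rotation with sensible axes", {
  # collinear vertical centroids: identity in the straight-spine limit
  cen <- cbind(0, seq(0, 170, by = 10), 0)
  R <- joint_orientation(cen, 5)
  expect_equal(R, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  # planar sagittal curve keeps the lateral axis equal to world lateral
  cen2 <- cbind(sin(seq(0, 1, length.out = 18)) * 40,
                seq(0, 470, length.out = 18), 0)
  R2 <- joint_orientation(cen2, 7)
  expect_equal(abs(R2[, 3]), c(0, 0, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(crossprod(R2), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(det(R2), 1, tolerance = 1e-12)
  expect_error(joint_orientation(cen[1:3, , drop = FALSE], 1),
               "at least 4")
  cen3 <- cen; cen3[6, ] <- cen3[5, ]
  expect_error(joint_orientation(cen3, 2), "degenerate")
})

test_that("alignment metrics recover the generator's curvature settings", {
  expect_equal(unlist(fx_geometry("straight")$alignment),
               c(lordosis_deg = 0, kyphosis_deg = 0, cobb_deg = 0),
               tolerance = 1)
  al <- fx_geometry("lordotic")$alignment
  expect_equal(al$lordosis_deg, 29, tolerance = 3)
  expect_equal(al$kyphosis_deg, 31, tolerance = 3)
  expect_equal(al$cobb_deg, 0, tolerance = 1)
  als <- fx_geometry("scoliotic")$alignment
  expect_equal(als$cobb_deg, 18, tolerance = 3)
  g <- fx_geometry("lordotic")$geometries
  expect_error(measure_alignment(g[setdiff(names(g), "T12")]), "T12")
})

test_that("joint centres are strictly ordered along the superior axis", {
  j <- fx_geometry("lordotic")$joints
  ys <- vapply(j, function(x) x$origin[2], numeric(1))
  expect_true(all(diff(ys[c("L5/S1", "L4/L5", "L3/L4", "L2/L3", "L1/L2",
                            "T12/L1")]) > 0))
})

test_that("halving the voxel size moves landmarks less than a coarse voxel", {
  g4 <- extract_geometry(
    generate_spine_volume(spine_preset("lordotic", voxel_size = 4))$instances,
    generate_spine_volume(spine_preset("lordotic", voxel_size = 4))$subregions)
  g2 <- fx_geometry("lordotic")
  for (nm in c("spinous_posterior", "transverse_left_lateral",
               "body_ant_center")) {
    d <- sqrt(sum((g4$geometries$L3$landmarks[[nm]] -
                     g2$geometries$L3$landmarks[[nm]])^2))
    expect_lt(d, 4.5, label = paste("landmark", nm))
  }
})
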