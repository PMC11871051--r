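test_that("C2 pyramidalization moves the right atoms by the stated angle", {
  g <- build_s0()
  expect_identical(apply_c2_pyramidalization(g, 0), g)
  expect_error(apply_c2_pyramidalization(g, 91), "unphysical")

  g2 <- apply_c2_pyramidalization(g, 30)
  # C4, C5, C6 (and S, O) untouched
  for (s in c("C4", "C5", "C6", "S", "O")) {
    expect_equal(site_pos(g2, s), site_pos(g, s), tolerance = 1e-12)
  }
  expect_setequal(g2$element, g$element)
  # improper dihedral at C2, measured independently from emitted coordinates:
  # the planar ring has torsion(C2-N1-N3-C4) = 180; the pucker tilts it by
  # the stated angle
  d0 <- dihedral4(site_pos(g, "C2"), site_pos(g, "N1"),
                  site_pos(g, "N3"), site_pos(g, "C4"))
  d1 <- dihedral4(site_pos(g2, "C2"), site_pos(g2, "N1"),
                  site_pos(g2, "N3"), site_pos(g2, "C4"))
  expect_equal(abs(d0), 180, tolerance = 1e-9)
  expect_equal(abs(abs(d1) - 180), 30, tolerance = 0.1 / 30)

  # +a and -a are mirror images through the ring plane (z = 0)
  gm <- apply_c2_pyramidalization(g, -30)
  expect_equal(g2$z, -gm$z, tolerance = 1e-12)
  expect_equal(g2$x, gm$x, tolerance = 1e-12)
  expect_equal(planarity_rms(g2), planarity_rms(gm), tolerance = 1e-12)
  expect_gt(planarity_rms(g2), 0)
})

test_that("sulfur out-of-plane bend and stretch follow their contracts", {
  g <- build_s0()
  expect_identical(apply_sulfur_oop(g, 0, 0), g)
  expect_error(apply_sulfur_oop(g, 10, -2), "non-positive")

  g3 <- apply_sulfur_oop(g, 40, 0.1)
  d0 <- sqrt(sum((site_pos(g, "S") - site_pos(g, "C2"))^2))
  d1 <- sqrt(sum((site_pos(g3, "S") - site_pos(g3, "C2"))^2))
  expect_equal(d1 - d0, 0.1, tolerance = 0.001 / 0.1)
  for (s in setdiff(g$site, "S")) {
    expect_equal(site_pos(g3, s), site_pos(g, s), tolerance = 1e-12)
  }
  # |z_S| strictly increases with the bend angle on [0, 60]
  zs <- vapply(seq(0, 60, by = 10),
               function(a) abs(site_pos(apply_sulfur_oop(g, a, 0), "S")[3]),
               numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_gt(planarity_rms(g3), 0)
})

test_that("deformation operators commute with global rotations", {
  g <- build_s0()
  R <- rot3(11)
  for (op in list(function(x) apply_c2_pyramidalization(x, 25, h_factor = 2),
                  function(x) apply_sulfur_oop(x, 35, 0.08))) {
    a <- rotate_geom(op(g), R)
    b <- op(rotate_geom(g, R))
    expect_equal(as.matrix(a[, c("x", "y", "z")]),
                 as.matrix(b[, c("x", "y", "z")]), tolerance = 1e-9)
  }
})

test_that("thermal ensembles are seed-reproducible with the stated spread", {
  g <- build_s0()
  e0 <- thermal_ensemble(g, 0, 5, seed = 3)
  for (gg in e0$geometry) expect_identical(gg$z, g$z)

  e1 <- thermal_ensemble(g, 0.05, 20, seed = 7)
  e2 <- thermal_ensemble(g, 0.05, 20, seed = 7)
  expect_identical(e1$geometry, e2$geometry)

  # law of large numbers: sample sd of the sulfur out-of-plane coordinate
  big <- thermal_ensemble(g, 0.05, 10000, seed = 5)
  zs <- vapply(big$geometry, function(gg) site_pos(gg, "S")[3], numeric(1))
  expect_equal(sd(zs), 0.05, tolerance = 0.002 / 0.05)
  expect_lt(abs(mean(zs)), 0.002)

  # mass weighting damps heavy-atom motion relative to protons
  mw <- thermal_ensemble(g, 0.05, 4000, seed = 9, mass_weighted = TRUE)
  zS <- vapply(mw$geometry, function(gg) site_pos(gg, "S")[3], numeric(1))
  zH <- vapply(mw$geometry, function(gg) site_pos(gg, "H9")[3], numeric(1))
  expect_lt(sd(zS), sd(zH) / 3)
})

test_that("staged-onset trajectories ramp between S0 and the late geometry", {
  p <- deformation_params()
  tr <- synth_excited_trajectory(p, t_end = 1000, dt = 5, seed = 2,
                                 sigma_oop = 0)
  expect_equal(length(unique(tr$t_fs)), 201)

  g0 <- traj_frame(tr, 0)
  # before the onset the geometry is the (here unsmeared) ground state:
  # pucker amplitude below 5 percent of the preset
  d0 <- dihedral4(site_pos(g0, "C2"), site_pos(g0, "N1"),
                  site_pos(g0, "N3"), site_pos(g0, "C4"))
  expect_lt(abs(abs(d0) - 180), 0.05 * p$pucker_angle)
  expect_equal(co_cs_angle(g0), 116, tolerance = 0.01)

  # late frames reach the G3 preset including the 104-degree bond angle
  expect_equal(co_cs_angle(traj_frame(tr, 1000)), 104, tolerance = 1 / 104)
  expect_gt(planarity_rms(traj_frame(tr, 1000)), 0.1)

  # onset ordering in the geometry itself: at 65 fs the pucker is in but the
  # sulfur is still planar
  g65 <- traj_frame(tr, 65)
  d65 <- dihedral4(site_pos(g65, "C2"), site_pos(g65, "N1"),
                   site_pos(g65, "N3"), site_pos(g65, "C4"))
  expect_gt(abs(abs(d65) - 180), 0.9 * p$pucker_angle)
  expect_lt(abs(site_pos(g65, "S")[3]), 0.05)

  expect_error(synth_excited_trajectory(p, t_end = 100, dt = 200), "dt")
  expect_error(traj_frame(tr, 3), "not a stored frame")
})

test_that("trajectory ensembles are reproducible and jittered", {
  p <- deformation_params()
  e1 <- synth_trajectory_ensemble(4, p, seed = 21, times = c(0, 500))
  e2 <- synth_trajectory_ensemble(4, p, seed = 21, times = c(0, 500))
  expect_identical(e1$trajectory, e2$trajectory)
  expect_true(all(e1$sign_pucker %in% c(-1, 1)))
  expect_gt(stats::sd(e1$amp_pucker), 0)
})
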